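#' Tidy a two-component construct mixture fit
#'
#' @param x `gmm2` object from [fit_construct_mixture()].
#' @param ... unused.
#' @return tibble with one row per mixture component: `component` (`low`,
#'   `high` by mean), `mean`, `sd`, `weight`.
#' @export
tidy.gmm2 <- function(x, ...) {
  ord <- order(x$mu)
  tibble::tibble(
    component = c("low", "high"),
    mean = x$mu[ord],
    sd = x$sigma[ord],
    weight = x$lambda[ord]
  )
}

#' Glance at a two-component construct mixture fit
#'
#' @param x `gmm2` object.
#' @param ... unused.
#' @return one-row tibble: `loglik`, `n_iter`, `separable`,
#'   `delta_mean` (high minus low component mean).
#' @export
glance.gmm2 <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_iter = x$n_iter,
    separable = x$separable,
    delta_mean = abs(diff(x$mu))
  )
}

#' Tidy a multiallelic cluster model
#'
#' @param x `cluster_model` object from [cluster_multiallelic()].
#' @param ... unused.
#' @return tibble of cluster assignments (`member`, `type`, `cluster`)
#'   joined with cluster centers.
#' @export
tidy.cluster_model <- function(x, ...) {
  dplyr::left_join(x$assignments, x$clusters, by = "cluster")
}

#' Glance at a multiallelic cluster model
#'
#' @param x `cluster_model` object.
#' @param ... unused.
#' @return one-row tibble: `n_clusters`, `n_points`.
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, n_points = sum(x$clusters$n))
}

#' Tidy an ancestry mosaic
#'
#' @param x `ancestry_mosaic` object from [viterbi_mosaic()].
#' @param ... unused.
#' @return the segment tibble.
#' @export
tidy.ancestry_mosaic <- function(x, ...) {
  x$segments
}

#' Glance at an ancestry mosaic
#'
#' @param x `ancestry_mosaic` object.
#' @param ... unused.
#' @return one-row tibble: `loglik`, `n_segments`, `n_donors`.
#' @export
glance.ancestry_mosaic <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_segments = nrow(x$segments),
    n_donors = length(x$donors)
  )
}
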