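#' Trio-informed multiallelic cluster detection for one probe
#'
#' Two-step nonparametric clustering of samples in the normalized `(x, y)`
#' intensity plane. Step 1 seeds one cluster per founder strain (the
#' centroid of its replicates) and iteratively merges clusters that are
#' mutual nearest neighbors with centroids closer than
#' `merge_dist_factor` times the median within-cluster point spread.
#' Step 2 assigns each F1 class to its parents' cluster when the parents
#' share one, otherwise creates a candidate heterozygous cluster at the F1
#' centroid; the merge pass is then repeated over all clusters. Cluster
#' labels are ordered by the angle `theta` of their centroid.
#'
#' @param founder_points tibble with `founder`, `x`, `y` (one or more
#'   replicate points per founder strain).
#' @param f1_points tibble with `parent_1`, `parent_2`, `x`, `y`, or `NULL`.
#' @param merge_dist_factor merge radius in units of the median
#'   within-cluster spread (default 2.0).
#' @param per_point if `TRUE`, merge decisions use minimum point-to-point
#'   distances instead of centroid distances (default `FALSE`, centroid
#'   mode).
#' @return object of class `cluster_model`: list with `clusters` (tibble:
#'   `cluster`, `x`, `y`, `n`, `theta`), `assignments` (tibble: member,
#'   type, cluster), `n_clusters`.
#' @export
cluster_multiallelic <- function(founder_points, f1_points = NULL,
                                 merge_dist_factor = 2.0, per_point = FALSE) {
  fp <- tibble::as_tibble(founder_points)
  founders <- unique(fp$founder)
  if (any(!founders %in% fp$founder)) abort("founder with no points")
  if (length(founders) < 1) abort("need at least one founder")

  # members: list of point matrices per cluster
  members <- lapply(founders, function(f) {
    as.matrix(fp[fp$founder == f, c("x", "y")])
  })
  labels <- lapply(founders, function(f) list(founders = f, f1s = character(0)))

  spread_of <- function(pts, ctr) {
    if (nrow(pts) < 2) return(NA_real_)
    mean(sqrt(rowSums((pts - matrix(ctr, nrow(pts), 2, byrow = TRUE))^2)))
  }
  state_spread <- function(members, centers) {
    sp <- vapply(seq_along(members), function(i) spread_of(members[[i]], centers[i, ]),
                 numeric(1))
    m <- median(sp, na.rm = TRUE)
    if (!is.finite(m) || m == 0) m <- 1e-6
    m
  }
  centers_of <- function(members) {
    t(vapply(members, colMeans, numeric(2)))
  }
  clus_dist <- function(members, centers, i, j) {
    if (per_point) {
      min(sqrt(outer(rowSums(members[[i]]^2), rowSums(members[[j]]^2), "+") -
                 2 * members[[i]] %*% t(members[[j]])))
    } else {
      sqrt(sum((centers[i, ] - centers[j, ])^2))
    }
  }

  merge_pass <- function(members, labels) {
    repeat {
      k <- length(members)
      if (k < 2) break
      centers <- centers_of(members)
      spread <- state_spread(members, centers)
      dm <- matrix(Inf, k, k)
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        dm[i, j] <- dm[j, i] <- clus_dist(members, centers, i, j)
      }
      nn <- apply(dm, 1, which.min)
      merged <- FALSE
      for (i in seq_len(k)) {
        j <- nn[i]
        if (nn[j] == i && i < j && dm[i, j] <= merge_dist_factor * spread) {
          members[[i]] <- rbind(members[[i]], members[[j]])
          labels[[i]] <- list(
            founders = union(labels[[i]]$founders, labels[[j]]$founders),
            f1s = union(labels[[i]]$f1s, labels[[j]]$f1s)
          )
          members[[j]] <- NULL
          labels[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    list(members = members, labels = labels)
  }

  st <- merge_pass(members, labels)
  members <- st$members; labels <- st$labels

  if (!is.null(f1_points) && nrow(f1_points) > 0) {
    f1 <- tibble::as_tibble(f1_points)
    f1$class <- paste(pmin(f1$parent_1, f1$parent_2),
                      pmax(f1$parent_1, f1$parent_2), sep = "x")
    for (cls in unique(f1$class)) {
      rows <- f1[f1$class == cls, ]
      p1 <- rows$parent_1[1]; p2 <- rows$parent_2[1]
      find_cluster <- function(f) {
        which(vapply(labels, function(l) f %in% l$founders, logical(1)))[1]
      }
      c1 <- find_cluster(p1); c2 <- find_cluster(p2)
      pts <- as.matrix(rows[, c("x", "y")])
      if (!is.na(c1) && !is.na(c2) && c1 == c2) {
        members[[c1]] <- rbind(members[[c1]], pts)
        labels[[c1]]$f1s <- union(labels[[c1]]$f1s, cls)
      } else {
        members[[length(members) + 1]] <- pts
        labels[[length(labels) + 1]] <- list(founders = character(0), f1s = cls)
      }
    }
    st <- merge_pass(members, labels)
    members <- st$members; labels <- st$labels
  }

  centers <- centers_of(members)
  theta <- (2 / pi) * atan2(centers[, 2], centers[, 1])
  ord <- order(theta)
  clusters <- tibble::tibble(
    cluster = seq_along(ord),
    x = centers[ord, 1], y = centers[ord, 2],
    n = vapply(members, nrow, integer(1))[ord],
    theta = theta[ord]
  )
  assign_rows <- purrr::map2_dfr(seq_along(ord), ord, function(new_id, old_id) {
    l <- labels[[old_id]]
    tibble::tibble(
      member = c(l$founders, l$f1s),
      type = c(rep("founder", length(l$founders)), rep("f1", length(l$f1s))),
      cluster = new_id
    )
  })
  structure(
    list(clusters = clusters, assignments = assign_rows,
         n_clusters = nrow(clusters)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model>", x$n_clusters, "cluster(s)\n")
  print(x$clusters)
  invisible(x)
}

#' Fit a two-component Gaussian mixture to log10 sum intensities
#'
#' Univariate two-component mixture fitted by expectation-maximization,
#' initialized at the 25th/75th percentiles of the data with equal weights
#' and the overall standard deviation. Convergence at absolute
#' log-likelihood change below `tol` or `max_iter` iterations. The fit is
#' flagged non-separable when the component means differ by less than
#' twice the pooled standard deviation, or when the mixture does not beat
#' a single-component Gaussian on BIC (which catches EM splitting one
#' tight mode into two overlapping components).
#'
#' @param s numeric vector (log10 sum intensities).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class `gmm2`: list with `mu`, `sigma`, `lambda`
#'   (mixing weights), `loglik`, `loglik_trace`, `n_iter`, `separable`,
#'   `posterior_high` (per-observation posterior of the higher-mean
#'   component).
#' @export
fit_construct_mixture <- function(s, tol = 1e-8, max_iter = 500) {
  s <- s[is.finite(s)]
  n <- length(s)
  if (n < 2) abort("need at least two observations")
  mu <- unname(quantile(s, c(0.25, 0.75)))
  sig <- rep(max(sd(s), 1e-4), 2)
  lam <- c(0.5, 0.5)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- lam[1] * dnorm(s, mu[1], sig[1])
    d2 <- lam[2] * dnorm(s, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    g <- d1 / tot
    lam <- c(mean(g), mean(1 - g))
    mu <- c(sum(g * s) / sum(g), sum((1 - g) * s) / sum(1 - g))
    sig <- sqrt(c(sum(g * (s - mu[1])^2) / sum(g),
                  sum((1 - g) * (s - mu[2])^2) / sum(1 - g)))
    sig <- pmax(sig, 1e-6)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  hi <- which.max(mu)
  lo <- 3 - hi
  pooled_sd <- sqrt(lam[lo] * sig[lo]^2 + lam[hi] * sig[hi]^2)
  # separability: the component means must differ by at least twice the
  # pooled sd AND the mixture must beat a single Gaussian on BIC (guards
  # against EM splitting one tight mode into two overlapping components)
  ll1 <- sum(dnorm(s, mean(s), sqrt(mean((s - mean(s))^2)), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * trace[length(trace)] + 5 * log(n)
  separable <- abs(mu[hi] - mu[lo]) >= 2 * pooled_sd && bic2 < bic1
  d_hi <- lam[hi] * dnorm(s, mu[hi], sig[hi])
  d_lo <- lam[lo] * dnorm(s, mu[lo], sig[lo])
  structure(
    list(mu = mu, sigma = sig, lambda = lam,
         loglik = trace[length(trace)], loglik_trace = trace, n_iter = it,
         separable = separable, component_high = hi,
         posterior_high = d_hi / (d_hi + d_lo)),
    class = "gmm2"
  )
}

#' Presence/absence calls for engineered-construct probe sets
#'
#' For each construct target, sums the raw intensity along each probe's
#' informative axis across the probes of the target (flooring raw values
#' at 1 before the log), takes `log10`, and fits a two-component
#' absence-vs-presence Gaussian mixture ([fit_construct_mixture()]). A
#' sample is called present when its posterior for the higher-mean
#' component exceeds 0.5. Raw (not normalized) intensities are used
#' because single-allele construct probes acquire artifacts under the
#' standard two-allele normalization. Non-separable targets are flagged
#' and all their calls set to absent with a warning.
#'
#' @param raw tibble with `sample_id`, `probe_id`, `x_raw`, `y_raw`.
#' @param targets tibble with `probe_id`, `target`, `informative_axis`
#'   (`"x"` or `"y"`).
#' @param floor raw-intensity floor applied before log10 (default 1).
#' @return tibble of class `construct_calls`: per sample x target
#'   `log10_sum`, `posterior_present`, `call`, `non_separable`; the fitted
#'   mixtures are attached as attribute `fits`.
#' @export
call_constructs <- function(raw, targets, floor = 1) {
  if (nrow(targets) == 0) abort("no construct targets")
  d <- dplyr::inner_join(raw, targets, by = "probe_id")
  missing_targets <- setdiff(targets$target, d$target)
  if (length(missing_targets) > 0) {
    abort(paste0("target(s) with no probes in the data: ",
                 paste(missing_targets, collapse = ", ")))
  }
  d$signal <- ifelse(d$informative_axis == "y", d$y_raw, d$x_raw)
  sums <- d |>
    dplyr::group_by(.data$sample_id, .data$target) |>
    dplyr::summarise(log10_sum = log10(sum(pmax(.data$signal, floor))),
                     .groups = "drop")
  fits <- list()
  out <- sums |>
    dplyr::group_by(.data$target) |>
    dplyr::group_modify(function(g, key) {
      fit <- fit_construct_mixture(g$log10_sum)
      fits[[as.character(key$target)]] <<- fit
      if (fit$separable) {
        post <- fit$posterior_high
        call <- ifelse(post > 0.5, "present", "absent")
      } else {
        warn(paste0("target ", key$target,
                    " is non-separable; all calls set to absent"))
        post <- rep(NA_real_, nrow(g))
        call <- rep("absent", nrow(g))
      }
      tibble::tibble(sample_id = g$sample_id, log10_sum = g$log10_sum,
                     posterior_present = post, call = call,
                     non_separable = !fit$separable)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "target", "log10_sum", "posterior_present",
                  "call", "non_separable")
  attr(out, "fits") <- fits
  class(out) <- c("construct_calls", class(out))
  out
}
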