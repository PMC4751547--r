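#' Polar transform of two-channel intensities
#'
#' Maps channel intensities `(x, y)` to the sum intensity `R = x + y` and
#' the normalized angle `theta = (2/pi) * atan2(y, x)`, so `theta = 0` at
#' pure reference-allele signal and `theta = 1` at pure alternate-allele
#' signal. When both channels are zero the angle is undefined and returned
#' as `NA`.
#'
#' @param x,y nonnegative channel intensities (vectorized).
#' @return tibble with columns `R`, `theta`.
#' @export
polar_transform <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    abort("intensities must be nonnegative")
  }
  theta <- (2 / pi) * atan2(y, x)
  theta[x == 0 & y == 0] <- NA_real_
  tibble::tibble(R = x + y, theta = theta)
}

#' Estimate genotype-cluster centroids per marker
#'
#' For each marker and each called cluster (`AA`, `AB`, `BB`), estimates
#' the cluster centroid as the trimmed mean of `theta` and `R` among the
#' samples carrying that call, omitting the most extreme `trim` fraction
#' of values (`trim/2` from each tail of each variable independently, by
#' rank). Clusters with no supporting samples are absent from the output.
#'
#' @param polar tibble with `marker_id`, `sample_id`, `R`, `theta`.
#' @param calls tibble with `marker_id`, `sample_id`, `call`.
#' @param trim total trimmed fraction (default 0.05).
#' @return tibble per marker x cluster: `call`, `theta_mean`, `R_mean`,
#'   `n_support`.
#' @export
estimate_centroids <- function(polar, calls, trim = 0.05) {
  d <- dplyr::inner_join(polar, calls, by = c("marker_id", "sample_id")) |>
    dplyr::filter(.data$call %in% c("AA", "AB", "BB"),
                  !is.na(.data$theta), !is.na(.data$R))
  d |>
    dplyr::group_by(.data$marker_id, .data$call) |>
    dplyr::summarise(
      theta_mean = mean(.data$theta, trim = trim / 2),
      R_mean = mean(.data$R, trim = trim / 2),
      n_support = dplyr::n(),
      .groups = "drop"
    )
}

# piecewise-linear BAF map and expected-R interpolation for one marker;
# centroids: named list/vectors with theta and R for present clusters
.baf_lrr_one <- function(theta, R, cent) {
  # cent: tibble with call, theta_mean, R_mean, oriented theta_AA<=theta_AB<=theta_BB
  anchors_theta <- cent$theta_mean
  anchors_baf <- c(AA = 0, AB = 0.5, BB = 1)[cent$call]
  ord <- order(anchors_theta)
  at <- anchors_theta[ord]
  ab <- unname(anchors_baf[ord])
  ar <- cent$R_mean[ord]
  if (length(at) >= 2) {
    baf <- approx(at, ab, xout = theta, rule = 2, ties = "ordered")$y
    r_exp <- approx(at, ar, xout = theta, rule = 2, ties = "ordered")$y
  } else {
    baf <- rep(NA_real_, length(theta))
    r_exp <- rep(ar[1], length(theta))
  }
  baf <- pmin(pmax(baf, 0), 1)
  lrr <- ifelse(r_exp > 0, log2(R / r_exp), NA_real_)
  list(baf = baf, lrr = lrr)
}

#' Compute B-allele frequency and log-R-ratio
#'
#' BAF is the piecewise-linear map of `theta` anchored at the cluster
#' centroids (0 at the AA centroid, 0.5 at AB, 1 at BB; clipped to `[0,1]`
#' outside the anchors). The expected total intensity at the observed
#' `theta` is the linear interpolation of the centroid `R` values
#' (clamped to the nearest centroid outside the anchor range) and
#' `LRR = log2(R / R_expected)`. Markers with a single observed cluster
#' get `BAF = NA` and LRR computed against that cluster's `R`; markers
#' with fewer than two centroids are flagged low-confidence.
#'
#' @param polar tibble with `marker_id`, `sample_id`, `R`, `theta`.
#' @param centroids tibble from [estimate_centroids()].
#' @return tibble per observation: `marker_id`, `sample_id`, `BAF`, `LRR`,
#'   `low_confidence`.
#' @export
compute_baf_lrr <- function(polar, centroids) {
  cent_by_marker <- split(centroids, centroids$marker_id)
  out <- polar |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::group_modify(function(g, key) {
      cent <- cent_by_marker[[as.character(key$marker_id)]]
      if (is.null(cent) || nrow(cent) == 0) {
        return(tibble::tibble(sample_id = g$sample_id, BAF = NA_real_,
                              LRR = NA_real_, low_confidence = TRUE))
      }
      v <- .baf_lrr_one(g$theta, g$R, cent)
      tibble::tibble(sample_id = g$sample_id, BAF = v$baf, LRR = v$lrr,
                     low_confidence = nrow(cent) < 2)
    }) |>
    dplyr::ungroup()
  dplyr::select(out, "marker_id", "sample_id", "BAF", "LRR", "low_confidence")
}

#' Reference quantiles for thresholded quantile normalization
#'
#' Computes per-channel reference quantiles from a designated reference
#' batch as the mean of the sorted channel values across reference samples
#' (classic quantile-normalization target).
#'
#' @param intensities tibble with `sample_id`, `marker_id`, `x_raw`,
#'   `y_raw` for the reference batch.
#' @return list with `probs` and per-channel quantile vectors `xq`, `yq`.
#' @export
tqn_reference <- function(intensities) {
  if (nrow(intensities) == 0) abort("empty reference batch")
  by_sample <- split(intensities, intensities$sample_id)
  n <- min(vapply(by_sample, nrow, integer(1)))
  probs <- (seq_len(n) - 0.5) / n
  # per-sample empirical quantile function on the same (rank - 0.5)/n
  # plotting positions used by the normalizer, averaged across samples
  chan_q <- function(col) {
    qs <- vapply(by_sample, function(s) {
      v <- sort(s[[col]])
      p_s <- (seq_along(v) - 0.5) / length(v)
      approx(p_s, v, xout = probs, rule = 2, ties = "ordered")$y
    }, numeric(n))
    rowMeans(as.matrix(qs))
  }
  list(probs = probs, xq = chan_q("x_raw"), yq = chan_q("y_raw"))
}

#' Thresholded quantile normalization of channel intensities
#'
#' Quantile-normalizes each channel of each sample to the reference
#' distribution, then caps the per-probe adjustment so the
#' normalized/raw intensity ratio stays within `[1/ratio_cap, ratio_cap]`.
#' Probes whose adjustment hit the cap are flagged.
#'
#' @param intensities tibble with `sample_id`, `marker_id`, `x_raw`,
#'   `y_raw`.
#' @param reference list from [tqn_reference()].
#' @param ratio_cap cap on the normalized/raw ratio (default 1.5).
#' @return tibble with `sample_id`, `marker_id`, `x`, `y`, `x_capped`,
#'   `y_capped`.
#' @export
tqn_normalize <- function(intensities, reference, ratio_cap = 1.5) {
  if (is.null(reference$xq) || length(reference$xq) == 0) abort("empty reference")
  norm_chan <- function(v, refq, probs) {
    p <- (rank(v, ties.method = "average") - 0.5) / length(v)
    approx(probs, refq, xout = p, rule = 2, ties = "ordered")$y
  }
  intensities |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      xn <- norm_chan(g$x_raw, reference$xq, reference$probs)
      yn <- norm_chan(g$y_raw, reference$yq, reference$probs)
      x_cap <- pmin(pmax(xn, g$x_raw / ratio_cap), g$x_raw * ratio_cap)
      y_cap <- pmin(pmax(yn, g$y_raw / ratio_cap), g$y_raw * ratio_cap)
      tibble::tibble(
        marker_id = g$marker_id, x = x_cap, y = y_cap,
        x_capped = x_cap != xn, y_capped = y_cap != yn
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "marker_id", "x", "y", "x_capped", "y_capped")
}

#' Normalize an intensity table to BAF/LRR in one call
#'
#' Convenience pipeline: polar transform, centroid estimation from the
#' provided calls, then BAF/LRR.
#'
#' @param intensities tibble with `sample_id`, `marker_id`, `x`, `y`.
#' @param calls tibble with `sample_id`, `marker_id`, `call`.
#' @param trim centroid trimmed-mean fraction (default 0.05).
#' @return tibble from [compute_baf_lrr()].
#' @export
normalize_intensities <- function(intensities, calls, trim = 0.05) {
  pol <- dplyr::bind_cols(
    dplyr::select(intensities, "sample_id", "marker_id"),
    polar_transform(intensities$x, intensities$y)
  )
  cent <- estimate_centroids(pol, calls, trim = trim)
  compute_baf_lrr(pol, cent)
}
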