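#' Plot per-array intensity distributions
#'
#' Histogram of the per-probe total-intensity statistic `d` per sample,
#' with the reference normal density overlaid; the canonical first look
#' at array quality (a good array is symmetric around ~1, a failed array
#' right-skewed toward 0, a diverged sample bimodal with a spike near 0).
#'
#' @param intensities tibble with `sample_id`, `x`, `y`.
#' @param config [qc_config()] list (for the reference curve).
#' @return a ggplot object.
#' @export
plot_d_distribution <- function(intensities, config = qc_config()) {
  d <- intensities |>
    dplyr::mutate(d = sqrt(.data$x^2 + .data$y^2))
  ref <- tibble::tibble(
    d = seq(0, max(d$d, na.rm = TRUE), length.out = 200)
  )
  ref$dens <- dnorm(ref$d, config$ref_mean, config$ref_sd)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70", color = NA) +
    ggplot2::geom_line(data = ref, ggplot2::aes(y = .data$dens),
                       color = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = "total intensity d", y = "density") +
    ggplot2::theme_minimal()
}

#' Autoplot a QC report
#'
#' Per-sample mean intensity vs the Kolmogorov-Smirnov statistic `K`,
#' colored by PASS/FAIL with the flag threshold marked.
#'
#' @param object `muga_qc` tibble from [qc_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.muga_qc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d_mean, y = .data$K,
                                       color = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.1, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(PASS = "steelblue", FAIL = "firebrick")) +
    ggplot2::labs(x = "mean d", y = "K") +
    ggplot2::theme_minimal()
}

#' Autoplot a multiallelic cluster model
#'
#' Cluster centers in the `(x, y)` intensity plane, sized by membership.
#'
#' @param object `cluster_model` from [cluster_multiallelic()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cluster_model <- function(object, ...) {
  ggplot2::ggplot(object$clusters,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               size = .data$n,
                               label = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, color = "steelblue") +
    ggplot2::geom_text(size = 3, vjust = -1) +
    ggplot2::labs(x = "x intensity", y = "y intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Autoplot an ancestry mosaic
#'
#' Genome track of donor segments per chromosome.
#'
#' @param object `ancestry_mosaic` from [viterbi_mosaic()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ancestry_mosaic <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                   y = .data$chromosome, yend = .data$chromosome,
                   color = .data$donor_group),
      linewidth = 4
    ) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome", color = "donor") +
    ggplot2::theme_minimal()
}

#' Plot BAF and LRR along a chromosome
#'
#' Standard two-panel copy-number inspection track for one sample.
#'
#' @param signal tibble from [compute_baf_lrr()] with `marker_id`, `BAF`,
#'   `LRR`.
#' @param markers tibble with `marker_id`, `chromosome`, `position_bp`.
#' @param sample one sample id to display (required when `signal` covers
#'   several).
#' @return a ggplot object.
#' @export
plot_baf_lrr <- function(signal, markers, sample = NULL) {
  d <- signal
  if (!is.null(sample)) d <- d[d$sample_id == sample, ]
  d <- dplyr::inner_join(d, markers, by = "marker_id") |>
    tidyr::pivot_longer(c("BAF", "LRR"), names_to = "layer",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position_bp / 1e6,
                                  y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$layer),
                        ggplot2::vars(.data$chromosome),
                        scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
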