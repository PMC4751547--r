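#' Flag paralogous SNP candidates from a pileup summary
#'
#' A pileup site is a paralogous-SNP candidate when it shows both
#' pseudoheterozygosity (at least two nucleotides each supported by more
#' than 3 reads, i.e. `>= min_alt_reads`) and excess coverage (depth
#' `> 50`, i.e. `>= min_depth`). Flagged sites closer than
#' `min_spacing_bp` to a previously flagged site are dropped in a
#' left-to-right scan.
#'
#' @param sites tibble sorted by position with `chromosome` (optional),
#'   `position_bp`, `depth`, and per-base read counts `A`, `C`, `G`, `T`.
#' @param min_alt_reads minimum reads per base to count it as supported
#'   (default 4, i.e. strictly more than 3).
#' @param min_depth minimum depth (default 51, i.e. strictly more than 50).
#' @param min_spacing_bp minimum spacing between retained flagged sites
#'   (default 51, i.e. strictly more than 50 bp apart).
#' @return tibble: the flagged, spacing-filtered sites.
#' @export
flag_paralogous <- function(sites, min_alt_reads = 4, min_depth = 51,
                            min_spacing_bp = 51) {
  s <- tibble::as_tibble(sites)
  if (!"chromosome" %in% names(s)) s$chromosome <- "1"
  for (ch in unique(s$chromosome)) {
    if (is.unsorted(s$position_bp[s$chromosome == ch])) {
      abort("pileup sites must be sorted by position")
    }
  }
  counts <- as.matrix(s[, c("A", "C", "G", "T")])
  pseudo_het <- rowSums(counts >= min_alt_reads) >= 2
  excess <- s$depth >= min_depth
  flagged <- s[pseudo_het & excess, ]
  keep <- logical(nrow(flagged))
  for (ch in unique(flagged$chromosome)) {
    idx <- which(flagged$chromosome == ch)
    last <- -Inf
    for (i in idx) {
      if (flagged$position_bp[i] - last >= min_spacing_bp) {
        keep[i] <- TRUE
        last <- flagged$position_bp[i]
      }
    }
  }
  flagged[keep, ]
}

#' Summarize LRR over regions for copy-number screening
#'
#' Mean log-R-ratio per sample per region; regions with at least
#' `min_probes` probes are called `gain` when the mean exceeds
#' `+gain_threshold`, `loss` below `-gain_threshold`, `normal` otherwise.
#' Regions with fewer probes get the call withheld (`NA`). This is a
#' screening summary, not a segmentation.
#'
#' @param lrr tibble with `sample_id`, `marker_id`, `LRR`.
#' @param markers tibble with `marker_id`, `chromosome`, `position_bp`.
#' @param regions tibble with `chromosome`, `start_bp`, `end_bp` (1-based
#'   inclusive) and optionally `name`.
#' @param gain_threshold symmetric LRR threshold (default 0.3).
#' @param min_probes minimum probes per region for a call (default 3).
#' @return tibble per sample x region: `mean_LRR`, `n_probes`, `call`.
#' @export
summarize_region_lrr <- function(lrr, markers, regions, gain_threshold = 0.3,
                                 min_probes = 3) {
  rg <- tibble::as_tibble(regions)
  if (!"name" %in% names(rg)) {
    rg$name <- paste0(rg$chromosome, ":", rg$start_bp, "-", rg$end_bp)
  }
  d <- dplyr::inner_join(lrr, markers, by = "marker_id")
  out <- list()
  for (r in seq_len(nrow(rg))) {
    in_r <- d$chromosome == rg$chromosome[r] &
      d$position_bp >= rg$start_bp[r] & d$position_bp <= rg$end_bp[r]
    sub <- d[in_r, ]
    smry <- sub |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(mean_LRR = mean(.data$LRR, na.rm = TRUE),
                       n_probes = sum(!is.na(.data$LRR)), .groups = "drop") |>
      dplyr::mutate(
        region = rg$name[r],
        call = dplyr::case_when(
          .data$n_probes < min_probes ~ NA_character_,
          .data$mean_LRR > gain_threshold ~ "gain",
          .data$mean_LRR < -gain_threshold ~ "loss",
          TRUE ~ "normal"
        )
      )
    out[[r]] <- smry
  }
  dplyr::bind_rows(out) |>
    dplyr::select("sample_id", "region", "mean_LRR", "n_probes", "call")
}
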