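#' Quality-control configuration
#'
#' Thresholds used by the array-level QC checks. The absolute count
#' thresholds are calibrated to a full-size array (141,090 SNP probes, 83
#' Y-chromosome markers); when QC is run on a marker subset they are
#' rescaled by the fraction of markers present (see [qc_report()]).
#'
#' @param ref_mean,ref_sd reference normal distribution of the per-probe
#'   total-intensity statistic `d` on a successful array (defaults 0.97,
#'   0.42).
#' @param k_threshold Kolmogorov-Smirnov flag threshold (default 0.1).
#' @param max_missing_musculus max missing calls for *M. musculus* samples
#'   (strict `>` flags; default 15000).
#' @param max_missing_other_mus max missing calls for other *Mus* species
#'   (default 45000).
#' @param max_het_classical max heterozygous calls for classical inbred
#'   strains (default 2000).
#' @param female_max_y_calls,male_min_y_calls bounds on good (nonmissing,
#'   nonheterozygous) Y-chromosome calls defining female / male;
#'   in between is ambiguous (defaults 33 and 42).
#' @param tier_nocall_rate strict no-call-rate bound for quality tiers 1-3
#'   (default 0.10).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(ref_mean = 0.97, ref_sd = 0.42, k_threshold = 0.1,
                      max_missing_musculus = 15000L,
                      max_missing_other_mus = 45000L,
                      max_het_classical = 2000L,
                      female_max_y_calls = 33L, male_min_y_calls = 42L,
                      tier_nocall_rate = 0.10) {
  stopifnot(female_max_y_calls < male_min_y_calls,
            ref_sd > 0, k_threshold > 0, tier_nocall_rate > 0)
  structure(
    list(ref_mean = ref_mean, ref_sd = ref_sd, k_threshold = k_threshold,
         max_missing_musculus = max_missing_musculus,
         max_missing_other_mus = max_missing_other_mus,
         max_het_classical = max_het_classical,
         female_max_y_calls = female_max_y_calls,
         male_min_y_calls = male_min_y_calls,
         tier_nocall_rate = tier_nocall_rate),
    class = "qc_config"
  )
}

#' Per-probe total-intensity statistic
#'
#' `d` is the Euclidean norm of the two-channel intensity vector `(x, y)`;
#' the companion statistic `R = x + y` is the channel sum. `d` is the
#' better total-intensity measure in heterozygous samples since by the
#' triangle inequality the norm never exceeds the sum.
#'
#' @param x,y nonnegative channel intensities (vectorized).
#' @return tibble with columns `d` and `R`.
#' @export
compute_d <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE)) {
    abort("intensities must be nonnegative")
  }
  tibble::tibble(d = sqrt(x^2 + y^2), R = x + y)
}

#' Kolmogorov-Smirnov flag for the within-array intensity distribution
#'
#' Computes the two-sided KS statistic `K` of the empirical distribution of
#' per-probe `d` values against the reference Normal(`ref_mean`, `ref_sd`)
#' and flags the array when `K` exceeds the threshold. The ECDF is taken
#' right-continuous; `K` is the maximum over sample points of the larger of
#' the upper and lower ECDF deviations.
#'
#' @param d_values numeric vector of per-probe `d` values (>= 100 values).
#' @param config [qc_config()] list.
#' @return tibble with one row: `K`, `flagged`.
#' @export
ks_flag <- function(d_values, config = qc_config()) {
  d_values <- d_values[!is.na(d_values)]
  n <- length(d_values)
  if (n < 100) abort("need >= 100 d values for a stable K statistic")
  xs <- sort(d_values)
  phi <- pnorm(xs, mean = config$ref_mean, sd = config$ref_sd)
  i <- seq_len(n)
  K <- max(pmax(abs(i / n - phi), abs((i - 1) / n - phi)))
  tibble::tibble(K = K, flagged = K > config$k_threshold)
}

# musculus-type groups for the missing-call threshold
.MUSCULUS_GROUPS <- c("classical_inbred", "wild_derived", "f1", "cc_f1", "do",
                      "wild_musculus")
.VALID_GROUPS <- c(.MUSCULUS_GROUPS, "other_mus")

#' Call-rate and heterozygosity flags
#'
#' Counts missing (`N`) and heterozygous (`AB`) calls per sample and
#' applies group-specific thresholds: *M. musculus* samples are flagged
#' above `max_missing_musculus` missing calls, other *Mus* species above
#' `max_missing_other_mus`; the heterozygosity check applies only to
#' classical inbred strains (above `max_het_classical`). Thresholds are
#' strict (`>`) and rescaled by `scale` for subsetted arrays.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param samples tibble with `sample_id`, `group` (one of
#'   `classical_inbred`, `wild_derived`, `f1`, `cc_f1`, `do`,
#'   `wild_musculus`, `other_mus`).
#' @param config [qc_config()] list.
#' @param scale multiplier applied to the absolute count thresholds
#'   (markers present / full array size); default 1.
#' @return tibble per sample: `n_missing`, `n_het`, `missing_fail`,
#'   `het_fail`.
#' @export
callrate_flags <- function(genotypes, samples, config = qc_config(), scale = 1) {
  bad <- setdiff(unique(samples$group), .VALID_GROUPS)
  if (length(bad) > 0) abort(paste0("unknown sample group(s): ", paste(bad, collapse = ", ")))
  counts <- genotypes |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_missing = sum(.data$call == "N"),
                     n_het = sum(.data$call == "AB"), .groups = "drop")
  out <- dplyr::left_join(dplyr::select(samples, "sample_id", "group"),
                          counts, by = "sample_id") |>
    dplyr::mutate(
      n_missing = dplyr::coalesce(.data$n_missing, 0L),
      n_het = dplyr::coalesce(.data$n_het, 0L),
      missing_bound = ifelse(.data$group == "other_mus",
                             config$max_missing_other_mus * scale,
                             config$max_missing_musculus * scale),
      missing_fail = .data$n_missing > .data$missing_bound,
      het_fail = .data$group == "classical_inbred" &
        .data$n_het > config$max_het_classical * scale
    )
  dplyr::select(out, "sample_id", "group", "n_missing", "n_het",
                "missing_fail", "het_fail")
}

#' Sex inference and concordance check
#'
#' Counts good calls (nonmissing, nonheterozygous) at Y-chromosome markers
#' per sample: at or below the female bound infers female, at or above the
#' male bound infers male. Samples in the ambiguous range are resolved by
#' X-chromosome intensity: mean `d` over X markers below the midpoint
#' between the batch means of known-female and known-male samples infers
#' male (females carry two X copies, hence higher intensity). A mismatch
#' is flagged when the resolved sex differs from a known sex.
#'
#' The Y-call bounds are calibrated to 83 Y markers and are rescaled to the
#' number of Y markers present in the manifest.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param intensities tibble with `sample_id`, `marker_id`, `x`, `y`.
#' @param manifest manifest tibble (needs `marker_id`, `chromosome`).
#' @param samples tibble with `sample_id`, `known_sex` in
#'   `{"F", "M", "unknown"}`.
#' @param config [qc_config()] list.
#' @return tibble per sample: `y_good_calls`, `x_mean_d`, `inferred_sex`,
#'   `sex_mismatch`.
#' @export
sex_check <- function(genotypes, intensities, manifest, samples,
                      config = qc_config()) {
  y_markers <- manifest$marker_id[manifest$chromosome == "Y"]
  x_markers <- manifest$marker_id[manifest$chromosome == "X"]
  if (length(y_markers) == 0) abort("manifest contains no Y-chromosome markers")
  y_scale <- length(y_markers) / .FULL_ARRAY_Y_MARKERS
  f_max <- floor(config$female_max_y_calls * y_scale)
  m_min <- ceiling(config$male_min_y_calls * y_scale)

  yc <- genotypes |>
    dplyr::filter(.data$marker_id %in% y_markers) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(y_good_calls = sum(.data$call %in% c("AA", "BB")),
                     .groups = "drop")
  xd <- intensities |>
    dplyr::filter(.data$marker_id %in% x_markers) |>
    dplyr::mutate(d = sqrt(.data$x^2 + .data$y^2)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(x_mean_d = mean(.data$d, na.rm = TRUE), .groups = "drop")

  out <- dplyr::select(samples, "sample_id", "known_sex") |>
    dplyr::left_join(yc, by = "sample_id") |>
    dplyr::left_join(xd, by = "sample_id") |>
    dplyr::mutate(y_good_calls = dplyr::coalesce(.data$y_good_calls, 0L))

  out$inferred_sex <- dplyr::case_when(
    out$y_good_calls <= f_max ~ "F",
    out$y_good_calls >= m_min ~ "M",
    TRUE ~ "ambiguous"
  )
  amb <- out$inferred_sex == "ambiguous"
  if (any(amb)) {
    mean_f <- mean(out$x_mean_d[out$known_sex == "F" & !amb], na.rm = TRUE)
    mean_m <- mean(out$x_mean_d[out$known_sex == "M" & !amb], na.rm = TRUE)
    if (is.finite(mean_f) && is.finite(mean_m)) {
      midpoint <- (mean_f + mean_m) / 2
      out$inferred_sex[amb] <- ifelse(out$x_mean_d[amb] < midpoint, "M", "F")
    }
  }
  out$sex_mismatch <- out$inferred_sex %in% c("F", "M") &
    out$known_sex %in% c("F", "M") & out$inferred_sex != out$known_sex
  dplyr::select(out, "sample_id", "y_good_calls", "x_mean_d", "inferred_sex",
                "sex_mismatch")
}

#' Assign probes to quality tiers
#'
#' Four mutually exclusive, exhaustive tiers of decreasing quality, judged
#' on a reference panel: tier 1 requires at least one sample called each of
#' `AA`, `BB` and `AB` with no-call rate strictly below the bound; tier 2
#' requires `AA` and `BB` (no `AB` needed) below the bound; tier 3 only the
#' no-call bound; tier 4 is everything else.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call` over the
#'   reference panel.
#' @param config [qc_config()] list (uses `tier_nocall_rate`).
#' @return tibble per marker: `n_AA`, `n_AB`, `n_BB`, `n_N`, `nocall_rate`,
#'   `tier` (integer 1-4).
#' @export
assign_tiers <- function(genotypes, config = qc_config()) {
  tab <- genotypes |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(
      n_AA = sum(.data$call == "AA"),
      n_AB = sum(.data$call == "AB"),
      n_BB = sum(.data$call == "BB"),
      n_N = sum(.data$call == "N"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_total = .data$n_AA + .data$n_AB + .data$n_BB + .data$n_N,
      nocall_rate = .data$n_N / .data$n_total,
      tier = dplyr::case_when(
        nocall_rate < config$tier_nocall_rate & n_AA > 0 & n_BB > 0 & n_AB > 0 ~ 1L,
        nocall_rate < config$tier_nocall_rate & n_AA > 0 & n_BB > 0 ~ 2L,
        nocall_rate < config$tier_nocall_rate ~ 3L,
        TRUE ~ 4L
      )
    )
  dplyr::select(tab, "marker_id", "n_AA", "n_AB", "n_BB", "n_N",
                "nocall_rate", "tier")
}

#' Full array-level QC report
#'
#' Runs the three array-level checks — intensity distribution (`d` summary
#' and KS flag), call-rate / heterozygosity counts, and sex concordance —
#' and combines them into one row per sample with failure flags and an
#' overall PASS/FAIL status (FAIL iff any flag is set). Count thresholds
#' are rescaled by the fraction of the full array present.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param intensities tibble with `sample_id`, `marker_id`, `x`, `y`.
#' @param samples tibble with `sample_id`, `group`, `known_sex`.
#' @param manifest manifest tibble.
#' @param config [qc_config()] list.
#' @return tibble of class `muga_qc`: one row per sample with `d_mean`,
#'   `d_sd`, `K`, counts, inferred sex, individual flags and `status`.
#' @export
qc_report <- function(genotypes, intensities, samples, manifest,
                      config = qc_config()) {
  # call-rate counting excludes the Y chromosome (83 of 141,090 markers on
  # the full array, immaterial there): female samples have no Y calls by
  # construction, which would otherwise dominate the rescaled threshold on
  # small marker subsets
  nonY <- manifest$marker_id[manifest$chromosome != "Y"]
  scale <- length(nonY) / (.FULL_ARRAY_SNPS - .FULL_ARRAY_Y_MARKERS)

  # the intensity-distribution check targets the diploid genome: hemizygous
  # X/Y probes shift d in males by construction, which is negligible on the
  # full array but not on small marker subsets
  auto_markers <- manifest$marker_id[!manifest$chromosome %in% c("X", "Y", "M")]
  dsum <- intensities |>
    dplyr::filter(.data$marker_id %in% auto_markers) |>
    dplyr::mutate(d = sqrt(.data$x^2 + .data$y^2)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      d_mean = mean(.data$d, na.rm = TRUE),
      d_sd = sd(.data$d, na.rm = TRUE),
      K = ks_flag(.data$d, config)$K,
      .groups = "drop"
    ) |>
    dplyr::mutate(intensity_fail = .data$K > config$k_threshold)

  cr <- callrate_flags(dplyr::filter(genotypes, .data$marker_id %in% nonY),
                       samples, config, scale = scale)
  sx <- sex_check(genotypes, intensities, manifest, samples, config)

  out <- dplyr::select(samples, "sample_id", "group", "known_sex") |>
    dplyr::left_join(dsum, by = "sample_id") |>
    dplyr::left_join(dplyr::select(cr, -"group"), by = "sample_id") |>
    dplyr::left_join(sx, by = "sample_id") |>
    dplyr::mutate(
      status = ifelse(.data$intensity_fail | .data$missing_fail |
                        .data$het_fail | .data$sex_mismatch, "FAIL", "PASS")
    )
  class(out) <- c("muga_qc", class(out))
  out
}
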