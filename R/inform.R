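#' Count informative markers between two samples
#'
#' A marker is informative for a pair when it belongs to an allowed quality
#' tier and the two samples carry opposite homozygous calls (one `AA`, the
#' other `BB`).
#'
#' @param calls_a,calls_b character vectors of calls aligned to a shared
#'   manifest.
#' @param tiers integer vector of marker tiers, same length.
#' @param allowed_tiers tiers counted (default `c(1, 2)`).
#' @return integer count.
#' @export
count_informative <- function(calls_a, calls_b, tiers = NULL,
                              allowed_tiers = c(1L, 2L)) {
  if (length(calls_a) != length(calls_b)) abort("call vectors differ in length")
  if (is.null(tiers)) tiers <- rep(1L, length(calls_a))
  if (length(tiers) != length(calls_a)) abort("tiers length mismatch")
  ok <- tiers %in% allowed_tiers
  sum(ok & ((calls_a == "AA" & calls_b == "BB") |
              (calls_a == "BB" & calls_b == "AA")))
}

#' Genotype concordance between two samples
#'
#' Fraction of markers, nonmissing in both samples, with identical calls.
#'
#' @param calls_a,calls_b aligned call vectors.
#' @return numeric in `[0, 1]`.
#' @export
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) abort("call vectors differ in length")
  both <- calls_a != "N" & calls_b != "N"
  if (sum(both) == 0) abort("no overlapping nonmissing markers")
  mean(calls_a[both] == calls_b[both])
}

#' Concordance between an F1 hybrid and its predicted genotypes
#'
#' Restricted to autosomal markers where both parents carry nonmissing
#' homozygous calls, the predicted F1 genotype is `AB` when the parents
#' differ and the shared homozygote otherwise. Returns the fraction of
#' nonmissing F1 calls matching the prediction.
#'
#' @param f1,parent_1,parent_2 aligned call vectors.
#' @param chromosome chromosome label per marker (X, Y, M are excluded);
#'   if `NULL` all markers are treated as autosomal.
#' @return numeric in `[0, 1]`.
#' @export
f1_concordance <- function(f1, parent_1, parent_2, chromosome = NULL) {
  n <- length(f1)
  if (length(parent_1) != n || length(parent_2) != n) abort("length mismatch")
  auto <- if (is.null(chromosome)) rep(TRUE, n) else
    !normalize_chrom(chromosome) %in% c("X", "Y", "M")
  eligible <- auto & parent_1 %in% c("AA", "BB") & parent_2 %in% c("AA", "BB") &
    f1 != "N"
  if (sum(eligible) == 0) abort("no eligible markers")
  pred <- ifelse(parent_1[eligible] == parent_2[eligible],
                 parent_1[eligible], "AB")
  mean(f1[eligible] == pred)
}

# per-sample carrier status of the alternate/reference allele from a call
.carries <- function(call, allele) {
  if (allele == "A") call %in% c("AA", "AB") else call %in% c("BB", "AB")
}

#' Per-subspecies allele frequencies
#'
#' Computes allele counts and minor-allele frequency per marker within each
#' subspecies from a labeled genotype panel.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param samples tibble with `sample_id`, `subspecies` (e.g. `dom`,
#'   `mus`, `cas`).
#' @return tibble per marker x subspecies: `n_A`, `n_B` (allele counts),
#'   `n_samples`, `maf`.
#' @export
allele_frequencies <- function(genotypes, samples) {
  d <- dplyr::inner_join(genotypes,
                         dplyr::select(samples, "sample_id", "subspecies"),
                         by = "sample_id")
  d |>
    dplyr::group_by(.data$marker_id, .data$subspecies) |>
    dplyr::summarise(
      n_A = sum(2 * (.data$call == "AA") + (.data$call == "AB")),
      n_B = sum(2 * (.data$call == "BB") + (.data$call == "AB")),
      n_samples = sum(.data$call != "N"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      maf = ifelse(.data$n_A + .data$n_B > 0,
                   pmin(.data$n_A, .data$n_B) / (.data$n_A + .data$n_B),
                   NA_real_)
    )
}

#' Identify subspecies-diagnostic markers
#'
#' A marker is diagnostic for a subspecies when one of its alleles is
#' carried by at least one sample of that subspecies and by at most
#' `max_mismatch` carrier individuals outside it (a carrier is a sample
#' with at least one copy of the allele).
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param samples tibble with `sample_id`, `subspecies`.
#' @param max_mismatch allowed carriers outside the focal subspecies
#'   (default 2).
#' @return tibble per diagnostic (marker, subspecies): `diagnostic_for`,
#'   `allele` (`A` or `B`), `n_carriers_inside`, `n_carriers_outside`.
#' @export
find_diagnostic <- function(genotypes, samples, max_mismatch = 2) {
  d <- dplyr::inner_join(genotypes,
                         dplyr::select(samples, "sample_id", "subspecies"),
                         by = "sample_id")
  subspp <- unique(samples$subspecies)
  carr <- d |>
    dplyr::group_by(.data$marker_id, .data$subspecies) |>
    dplyr::summarise(
      carriers_A = sum(.data$call %in% c("AA", "AB")),
      carriers_B = sum(.data$call %in% c("BB", "AB")),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("carriers_A", "carriers_B"),
                        names_to = "allele", values_to = "n_carriers",
                        names_prefix = "carriers_")
  totals <- carr |>
    dplyr::group_by(.data$marker_id, .data$allele) |>
    dplyr::summarise(total_carriers = sum(.data$n_carriers), .groups = "drop")
  out <- carr |>
    dplyr::left_join(totals, by = c("marker_id", "allele")) |>
    dplyr::mutate(n_outside = .data$total_carriers - .data$n_carriers) |>
    dplyr::filter(.data$n_carriers >= 1, .data$n_outside <= max_mismatch) |>
    dplyr::transmute(
      marker_id = .data$marker_id,
      diagnostic_for = .data$subspecies,
      allele = .data$allele,
      n_carriers_inside = .data$n_carriers,
      n_carriers_outside = .data$n_outside
    )
  out
}

# gaps > target_bp between consecutive positions (with 0 and L as bounds)
.max_gap_ok <- function(pos, L, target_bp) {
  bounds <- c(0, sort(pos), L)
  all(diff(bounds) <= target_bp)
}

#' Augment diagnostic-marker density
#'
#' Two-stage augmentation of a diagnostic catalog. Stage 1: per subspecies
#' and chromosome, while any inter-marker gap (chromosome ends included)
#' exceeds `target_bp`, iterate a descending MAF threshold ladder; at each
#' step add candidate markers with MAF above the threshold, chosen by the
#' uniform-spacing greedy (largest-gap midpoint), until the density is met
#' or the ladder is exhausted. Stage 2: for each recombination interval
#' still lacking a diagnostic marker for a subspecies, pick one uniformly
#' at random (seeded) from the available candidates. The output is a
#' superset of the input catalog; unmeetable densities are reported, not
#' raised.
#'
#' @param catalog tibble of already-diagnostic markers: `marker_id`,
#'   `chromosome`, `position_bp`, `diagnostic_for`.
#' @param candidates tibble of candidate markers with `marker_id`,
#'   `chromosome`, `position_bp`, `diagnostic_for`, `maf`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param target_bp density target: no gap wider than this (default 3e5).
#' @param recomb_intervals optional tibble `chromosome`, `start_bp`,
#'   `end_bp` of recombination intervals.
#' @param maf_steps descending MAF threshold ladder (default 0.45 to 0 by
#'   0.05).
#' @param seed seed for the stage-2 random picks.
#' @return list with `selection` (tibble: catalog plus additions, with
#'   `stage` in `{"catalog", "density", "interval"}`) and `deficits`
#'   (tibble of (chromosome, subspecies) or intervals that could not be
#'   satisfied).
#' @export
augment_density <- function(catalog, candidates, chrom_lengths,
                            target_bp = 3e5, recomb_intervals = NULL,
                            maf_steps = seq(0.45, 0, by = -0.05),
                            seed = 20151218) {
  set.seed(seed)
  sel <- dplyr::mutate(tibble::as_tibble(catalog), stage = "catalog")
  deficits <- list()
  subspp <- unique(c(catalog$diagnostic_for, candidates$diagnostic_for))
  for (ss in subspp) {
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      have <- sel[sel$diagnostic_for == ss & sel$chromosome == ch, ]
      pool <- candidates[candidates$diagnostic_for == ss &
                           candidates$chromosome == ch &
                           !candidates$marker_id %in% have$marker_id, ]
      pos <- have$position_bp
      if (.max_gap_ok(pos, L, target_bp)) next
      for (thr in maf_steps) {
        step_pool <- pool[pool$maf > thr, ]
        repeat {
          if (.max_gap_ok(pos, L, target_bp) || nrow(step_pool) == 0) break
          bounds <- c(0, sort(pos), L)
          gaps <- diff(bounds)
          gi <- which.max(gaps)
          mid <- (bounds[gi] + bounds[gi + 1]) / 2
          pick <- step_pool[which.min(abs(step_pool$position_bp - mid)), ]
          pos <- c(pos, pick$position_bp)
          sel <- dplyr::bind_rows(sel, dplyr::mutate(
            dplyr::select(pick, "marker_id", "chromosome", "position_bp",
                          "diagnostic_for"), stage = "density"))
          step_pool <- step_pool[step_pool$marker_id != pick$marker_id, ]
          pool <- pool[pool$marker_id != pick$marker_id, ]
        }
        if (.max_gap_ok(pos, L, target_bp)) break
      }
      if (!.max_gap_ok(pos, L, target_bp)) {
        deficits[[length(deficits) + 1]] <- tibble::tibble(
          type = "density", chromosome = ch, subspecies = ss,
          start_bp = NA_integer_, end_bp = NA_integer_)
      }
    }
  }
  if (!is.null(recomb_intervals)) {
    for (r in seq_len(nrow(recomb_intervals))) {
      iv <- recomb_intervals[r, ]
      for (ss in subspp) {
        in_iv <- sel$diagnostic_for == ss & sel$chromosome == iv$chromosome &
          sel$position_bp >= iv$start_bp & sel$position_bp <= iv$end_bp
        if (any(in_iv)) next
        pool <- candidates[candidates$diagnostic_for == ss &
                             candidates$chromosome == iv$chromosome &
                             candidates$position_bp >= iv$start_bp &
                             candidates$position_bp <= iv$end_bp &
                             !candidates$marker_id %in% sel$marker_id, ]
        if (nrow(pool) == 0) {
          deficits[[length(deficits) + 1]] <- tibble::tibble(
            type = "interval", chromosome = iv$chromosome, subspecies = ss,
            start_bp = as.integer(iv$start_bp), end_bp = as.integer(iv$end_bp))
          next
        }
        pick <- pool[sample.int(nrow(pool), 1), ]
        sel <- dplyr::bind_rows(sel, dplyr::mutate(
          dplyr::select(pick, "marker_id", "chromosome", "position_bp",
                        "diagnostic_for"), stage = "interval"))
      }
    }
  }
  list(selection = sel, deficits = dplyr::bind_rows(deficits))
}

#' Recode genotype calls for phylogeny export
#'
#' Recodes calls at haploid-lineage (Y, mitochondrial) markers into
#' single-nucleotide characters: `AA` becomes the reference nucleotide,
#' `BB` the alternate; heterozygous calls and no-calls are assigned
#' distinct random nonallelic nucleotides (seeded, fixed per marker and
#' shared across samples), so that aberrant hybridization patterns carry
#' phylogenetic signal instead of being dropped. At every marker the four
#' codes are pairwise distinct.
#'
#' @param calls tibble with `sample_id`, `marker_id`, `call`.
#' @param alleles tibble with `marker_id`, `allele_ref`, `allele_alt`
#'   (distinct nucleotides).
#' @param seed integer seed for the nonallelic-code draws.
#' @return list with `sequences` (named character vector, one per sample;
#'   markers in sorted `marker_id` order) and `codes` (tibble of the
#'   per-marker code table).
#' @export
recode_for_phylogeny <- function(calls, alleles, seed = 20151218) {
  al <- tibble::as_tibble(alleles)
  al$allele_ref <- toupper(al$allele_ref)
  al$allele_alt <- toupper(al$allele_alt)
  if (any(al$allele_ref == al$allele_alt)) abort("degenerate alleles")
  if (any(!c(al$allele_ref, al$allele_alt) %in% c("A", "C", "G", "T"))) {
    abort("alleles must be nucleotides")
  }
  set.seed(seed)
  nucs <- c("A", "C", "G", "T")
  codes <- al |>
    dplyr::arrange(.data$marker_id) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      het_code = sample(setdiff(nucs, c(.data$allele_ref, .data$allele_alt)), 1)
    ) |>
    dplyr::mutate(
      n_code = setdiff(nucs, c(.data$allele_ref, .data$allele_alt,
                               .data$het_code))[1]
    ) |>
    dplyr::ungroup()
  d <- dplyr::inner_join(calls, codes, by = "marker_id") |>
    dplyr::mutate(char = dplyr::case_when(
      .data$call == "AA" ~ .data$allele_ref,
      .data$call == "BB" ~ .data$allele_alt,
      .data$call == "AB" ~ .data$het_code,
      TRUE ~ .data$n_code
    )) |>
    dplyr::arrange(.data$sample_id, .data$marker_id)
  seqs <- d |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(seq = paste(.data$char, collapse = ""), .groups = "drop")
  list(sequences = setNames(seqs$seq, seqs$sample_id), codes = codes)
}
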