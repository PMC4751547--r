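test_that("informative-marker counting requires opposite homozygotes in tier", {
  a <- c("AA", "BB", "AB", "AA", "AA")
  b <- c("BB", "AA", "AA", "AA", "BB")
  tiers <- c(1L, 1L, 1L, 2L, 3L)
  expect_equal(count_informative(a, b, tiers), 2L)      # AB and tier-3 excluded
  expect_equal(count_informative(a, a, tiers), 0L)
  expect_equal(count_informative(a, b, tiers), count_informative(b, a, tiers))
  expect_error(count_informative(a, b[1:3], tiers), "length")
})

test_that("concordance is the co-called identity fraction", {
  a <- rep("AA", 100); b <- a; b[1] <- "BB"
  expect_equal(concordance(a, b), 0.99)
  expect_equal(concordance(a, a), 1)
  expect_error(concordance(a, rep("N", 100)), "nonmissing")
})

test_that("F1 concordance restricts to informative parental homozygotes", {
  p1 <- c("AA", "AA", "AB", "AA")
  p2 <- c("BB", "AA", "BB", "BB")
  f1_good <- c("AB", "AA", "AA", "AB")
  # marker 3 excluded (parent AB); the other three match predictions
  expect_equal(f1_concordance(f1_good, p1, p2), 1)
  f1_bad <- c("AA", "AA", "AA", "AB")
  expect_equal(f1_concordance(f1_bad, p1, p2), 2 / 3)
  # X chromosome excluded
  expect_equal(f1_concordance(f1_bad, p1, p2,
                              chromosome = c("X", "1", "1", "1")), 1)
  expect_error(f1_concordance("AB", "AB", "AA"), "eligible")
})

diag_panel <- function(calls_by_subsp) {
  # calls_by_subsp: named list subspecies -> call vector (one marker)
  rows <- purrr::imap_dfr(calls_by_subsp, function(calls, ss) {
    tibble::tibble(sample_id = paste0(ss, seq_along(calls)),
                   subspecies = ss, call = calls)
  })
  list(
    genotypes = dplyr::transmute(rows, sample_id, marker_id = "m1", call),
    samples = dplyr::distinct(rows, sample_id, subspecies)
  )
}

test_that("diagnostic markers allow up to the stated mismatches", {
  # allele B exclusive to dom
  p <- diag_panel(list(dom = c("BB", "BB", "AB"), mus = rep("AA", 3),
                       cas = rep("AA", 3)))
  d <- find_diagnostic(p$genotypes, p$samples)
  expect_equal(d$diagnostic_for[d$allele == "B"], "dom")

  # two carriers outside: still diagnostic
  p2 <- diag_panel(list(dom = c("BB", "BB", "BB"), mus = c("AB", "AB", "AA"),
                        cas = rep("AA", 3)))
  d2 <- find_diagnostic(p2$genotypes, p2$samples, max_mismatch = 2)
  expect_true("dom" %in% d2$diagnostic_for[d2$allele == "B"])

  # three carriers outside: not diagnostic
  p3 <- diag_panel(list(dom = c("BB", "BB", "BB"), mus = c("AB", "AB", "AB"),
                        cas = rep("AA", 3)))
  d3 <- find_diagnostic(p3$genotypes, p3$samples, max_mismatch = 2)
  expect_false("dom" %in% d3$diagnostic_for[d3$allele == "B"])
})

test_that("no allele is diagnostic for two subspecies at zero mismatches", {
  set.seed(21)
  for (rep in 1:10) {
    geno <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:9),
                               marker_id = sprintf("m%d", 1:5)) |>
      dplyr::mutate(call = sample(c("AA", "AB", "BB"), dplyr::n(),
                                  replace = TRUE))
    samples <- tibble::tibble(sample_id = sprintf("s%d", 1:9),
                              subspecies = rep(c("dom", "mus", "cas"), 3))
    d <- find_diagnostic(geno, samples, max_mismatch = 0)
    dup <- d |>
      dplyr::count(.data$marker_id, .data$allele) |>
      dplyr::filter(.data$n > 1)
    expect_equal(nrow(dup), 0)
  }
})

test_that("density augmentation fills gaps and preserves the catalog", {
  chrom_lengths <- c("1" = 3e6)
  catalog <- tibble::tibble(marker_id = c("d1", "d2"), chromosome = "1",
                            position_bp = c(100e3, 350e3),
                            diagnostic_for = "dom")
  # high-MAF candidates every 150 kb across the chromosome
  cand_pos <- seq(150e3, 2.95e6, by = 150e3)
  candidates <- tibble::tibble(
    marker_id = sprintf("c%02d", seq_along(cand_pos)), chromosome = "1",
    position_bp = cand_pos, diagnostic_for = "dom", maf = 0.5
  )
  aug <- augment_density(catalog, candidates, chrom_lengths, target_bp = 3e5)
  sel <- aug$selection[aug$selection$diagnostic_for == "dom", ]
  gaps <- diff(c(0, sort(sel$position_bp), 3e6))
  expect_true(all(gaps <= 3e5))
  expect_true(all(catalog$marker_id %in% sel$marker_id))
  expect_equal(nrow(aug$deficits), 0)

  # already-dense region: no additions
  dense_cat <- tibble::tibble(marker_id = sprintf("d%d", 1:10),
                              chromosome = "1",
                              position_bp = seq(150e3, 2.85e6, by = 3e5),
                              diagnostic_for = "dom")
  aug2 <- augment_density(dense_cat, candidates, chrom_lengths)
  expect_equal(nrow(aug2$selection), nrow(dense_cat))

  # no candidates for a subspecies: reported deficit, no selection
  aug3 <- augment_density(catalog,
                          candidates[0, ], chrom_lengths,
                          recomb_intervals = tibble::tibble(
                            chromosome = "1", start_bp = 2e6, end_bp = 2.5e6))
  expect_gt(nrow(aug3$deficits), 0)
  expect_equal(nrow(aug3$selection), nrow(catalog))
})

test_that("interval-stage picks are seeded and within the interval", {
  chrom_lengths <- c("1" = 1e6)
  catalog <- tibble::tibble(marker_id = "d1", chromosome = "1",
                            position_bp = 500e3, diagnostic_for = "mus")
  candidates <- tibble::tibble(marker_id = sprintf("c%d", 1:5),
                               chromosome = "1",
                               position_bp = seq(820e3, 980e3, by = 40e3),
                               diagnostic_for = "mus", maf = 0.1)
  iv <- tibble::tibble(chromosome = "1", start_bp = 800e3, end_bp = 1e6)
  a1 <- augment_density(catalog, candidates, chrom_lengths, target_bp = 2e6,
                        recomb_intervals = iv, seed = 5)
  a2 <- augment_density(catalog, candidates, chrom_lengths, target_bp = 2e6,
                        recomb_intervals = iv, seed = 5)
  expect_identical(a1$selection, a2$selection)
  added <- a1$selection[a1$selection$stage == "interval", ]
  expect_equal(nrow(added), 1)
  expect_true(added$position_bp >= 800e3 && added$position_bp <= 1e6)
})

test_that("phylogeny recoding yields four distinct per-marker codes", {
  alleles <- tibble::tibble(marker_id = c("m1", "m2"),
                            allele_ref = c("T", "A"), allele_alt = c("G", "C"))
  calls <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3", "s4"),
                              marker_id = c("m1", "m2"))
  calls$call <- c("AA", "AB", "BB", "N", "AA", "N", "AB", "BB")
  rec <- recode_for_phylogeny(calls, alleles, seed = 9)
  # per-marker codes pairwise distinct and nonallelic for AB/N
  for (r in seq_len(nrow(rec$codes))) {
    cd <- rec$codes[r, ]
    four <- c(cd$allele_ref, cd$allele_alt, cd$het_code, cd$n_code)
    expect_equal(length(unique(four)), 4)
    expect_false(cd$het_code %in% c(cd$allele_ref, cd$allele_alt))
  }
  # at a [T/G] SNP the het and no-call codes are drawn from {A, C}
  m1 <- rec$codes[rec$codes$marker_id == "m1", ]
  expect_setequal(c(m1$het_code, m1$n_code), c("A", "C"))
  # hom calls map to their alleles; codes shared across samples
  expect_equal(substr(rec$sequences[["s1"]], 1, 1), "T")
  expect_equal(substr(rec$sequences[["s2"]], 1, 1), "G")
  # determinism
  rec2 <- recode_for_phylogeny(calls, alleles, seed = 9)
  expect_identical(rec2$sequences, rec$sequences)
  expect_error(recode_for_phylogeny(
    calls, dplyr::mutate(alleles, allele_alt = allele_ref)), "degenerate")
})
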