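test_that("candidate filtering applies the assayability rules", {
  v <- tibble::tibble(
    marker_id = sprintf("m%d", 1:5),
    chromosome = "1",
    position_bp = c(100L, 149L, 400L, 800L, 2000L),
    allele_ref = c("A", "C", "A", "A", "C"),
    allele_alt = c("G", "T", "T", "G", "T"),
    flank_unique = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  out <- filter_candidates(v, min_neighbor_bp = 50)
  # m1/m2 are 49 bp apart -> both removed; m3 is [A/T] (two-bead);
  # m4 has non-unique flank; m5 is an isolated transition -> retained
  expect_equal(out$marker_id, "m5")
  # output is a subset preserving order
  all_kept <- filter_candidates(dplyr::mutate(v, flank_unique = TRUE,
                                              position_bp = c(100L, 500L, 1000L,
                                                              1500L, 2000L)))
  expect_equal(all_kept$marker_id, c("m1", "m2", "m4", "m5"))  # A/T still excluded
  expect_error(filter_candidates(v[c(2, 1), ]), "sorted")
})

test_that("interval partitioning keeps intervals uniform and nonempty", {
  cand <- tibble::tibble(position_cM = seq(0.5, 9.5, length.out = 10))
  p <- partition_intervals(cand, n = 5)
  expect_equal(nrow(p), 5)
  expect_equal(p$n_candidates, rep(2L, 5))
  expect_equal(diff(p$lo_cM), rep(1.8, 4))

  # clustered candidates: feasibility checked against brute force over n'
  clustered <- tibble::tibble(position_cM = c(0.1, 0.2, 0.3, 0.4, 9.9))
  p2 <- partition_intervals(clustered, n = 4, min_n = 2)
  brute_feasible <- function(cm, n) {
    br <- seq(min(cm), max(cm), length.out = n + 1)
    idx <- pmin(pmax(findInterval(cm, br, rightmost.closed = TRUE), 1), n)
    all(tabulate(idx, n) > 0)
  }
  best_n <- max(Filter(function(n) brute_feasible(clustered$position_cM, n), 4:2))
  expect_equal(nrow(p2), best_n)
  expect_true(all(p2$n_candidates > 0))

  expect_error(partition_intervals(cand, n = 1, min_n = 5), "n must be")
})

test_that("window score matches hand-enumerated configurations", {
  mono <- matrix(0, 8, 5)
  expect_equal(window_score(mono), 1)
  # one private allele in founder 1: founder-1 hom, founder-1 hets, rest
  priv <- mono; priv[1, 3] <- 1
  expect_equal(window_score(priv), 3)
  # fully distinguishing window never exceeds the state count
  expect_lte(window_score(matrix(rbinom(40, 1, 0.5), 8, 5)), 36)
})

test_that("window score equals the exhaustive enumeration oracle", {
  set.seed(42)
  for (rep in 1:25) {
    fa <- matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), 8, 5)
    expect_equal(window_score(fa), oracle_window_score(fa))
  }
  # smaller founder sets too
  for (rep in 1:10) {
    n_f <- sample(2:6, 1)
    w <- sample(1:5, 1)
    fa <- matrix(rbinom(n_f * w, 1, 0.5), n_f, w)
    expect_equal(window_score(fa), oracle_window_score(fa))
  }
})

test_that("window score is invariant to founder relabeling and allele flips", {
  set.seed(7)
  for (rep in 1:10) {
    fa <- matrix(rbinom(40, 1, 0.5), 8, 5)
    k <- window_score(fa)
    expect_equal(window_score(fa[sample(8), ]), k)
    flip <- sample(5, 2)
    fa2 <- fa; fa2[, flip] <- 1 - fa2[, flip]
    expect_equal(window_score(fa2), k)
  }
})

test_that("missing founder alleles reduce the score conservatively", {
  set.seed(8)
  fa <- matrix(rbinom(40, 1, 0.5), 8, 5)
  fa_na <- fa; fa_na[1, 1] <- NA
  expect_lte(window_score(fa_na), window_score(fa))
  expect_gte(window_score(fa_na), 1)
})

test_that("beam search on a forced path returns its window score", {
  set.seed(3)
  cand <- tibble::tibble(marker_id = sprintf("m%d", 1:5),
                         position_cM = c(0.5, 2.5, 4.5, 6.5, 8.5))
  fa <- matrix(rbinom(40, 1, 0.5), 8, 5,
               dimnames = list(LETTERS[1:8], cand$marker_id))
  sel <- beam_select(cand, fa, n_intervals = 5, window_size = 5)
  expect_equal(nrow(sel$selected), 5)
  expect_equal(sel$score, window_score(fa))
})

test_that("a wide beam attains the exhaustive optimum; width is monotone", {
  for (seed in 1:10) {
    inst <- random_beam_instance(seed)
    oracle <- oracle_best_path(inst$slots, inst$fa, w = 5)
    wide <- beam_select(inst$cand, inst$fa, n_intervals = inst$n_iv,
                        window_size = 5, beam_width = 1e5)
    expect_equal(wide$score, oracle)
    scores <- vapply(c(1, 10, 100, 1e5), function(bw) {
      beam_select(inst$cand, inst$fa, n_intervals = inst$n_iv,
                  window_size = 5, beam_width = bw)$score
    }, numeric(1))
    expect_true(all(diff(scores) >= 0))
    expect_lte(scores[1], oracle)  # greedy is admissible
  }
})

test_that("suffix deduplication preserves optimality on small instances", {
  inst <- random_beam_instance(99)
  oracle <- oracle_best_path(inst$slots, inst$fa, w = 5)
  dd <- beam_select(inst$cand, inst$fa, n_intervals = inst$n_iv,
                    window_size = 5, beam_width = 1e5, dedup_suffix = TRUE)
  expect_equal(dd$score, oracle)
})

test_that("hotspot selection maximizes local score with stated tie-breaks", {
  set.seed(5)
  cand <- tibble::tibble(marker_id = sprintf("m%d", 1:6),
                         position_bp = c(100L, 200L, 260L, 330L, 400L, 520L))
  fa <- matrix(rbinom(48, 1, 0.5), 8, 6,
               dimnames = list(LETTERS[1:8], cand$marker_id))
  hs <- hotspot_select(cand, fa, center_start = 280, center_end = 380)
  runs <- lapply(1:3, function(s) cand$marker_id[s:(s + 3)])
  scores <- vapply(runs, function(r) oracle_window_score(fa[, r]), numeric(1))
  overlapping <- vapply(1:3, function(s) {
    cand$position_bp[s] <= 380 && cand$position_bp[s + 3] >= 280
  }, logical(1))
  best <- max(scores[overlapping])
  expect_equal(hs$score, best)
  expect_false(hs$off_center)

  # forced: exactly 4 candidates straddling the center
  hs2 <- hotspot_select(cand[2:5, ], fa[, 2:5], 280, 380)
  expect_equal(hs2$selected$marker_id, cand$marker_id[2:5])

  # no run overlapping the center -> off-center flag
  hs3 <- hotspot_select(cand, fa, center_start = 5000, center_end = 5100)
  expect_true(hs3$off_center)
})

test_that("hotspot ties break toward the smaller span", {
  # monomorphic founders make every run score 1: pure tie-break test
  cand <- tibble::tibble(marker_id = sprintf("m%d", 1:5),
                         position_bp = c(100L, 300L, 320L, 340L, 600L))
  fa <- matrix(0, 8, 5, dimnames = list(LETTERS[1:8], cand$marker_id))
  hs <- hotspot_select(cand, fa, center_start = 250, center_end = 450)
  # runs: (100..340) span 240, (300..600) span 300 -> smaller span wins
  expect_equal(hs$selected$marker_id, cand$marker_id[1:4])
})

test_that("uniform-spacing selection covers the domain evenly", {
  cand <- tibble::tibble(chromosome = "1", position_bp = 1:1000)
  sel <- select_uniform_spacing(cand, k = 7, chrom_lengths = c("1" = 1000))
  gaps <- diff(c(0, sel$position_bp, 1000))
  expect_lte(max(gaps), 2 * min(gaps))
  # k = all candidates -> identity
  small <- tibble::tibble(chromosome = "1", position_bp = c(10L, 20L, 30L))
  expect_equal(select_uniform_spacing(small, 3, c("1" = 40))$position_bp,
               small$position_bp)
  expect_error(select_uniform_spacing(small, 0), "positive")
})

test_that("uniform-spacing greedy matches the exhaustive subset oracle", {
  # clustered instance: greedy should minimize the largest residual gap
  cand <- tibble::tibble(chromosome = "1",
                         position_bp = c(50L, 60L, 70L, 500L, 510L,
                                         940L, 950L, 960L))
  L <- 1000
  sel <- select_uniform_spacing(cand, k = 3, chrom_lengths = c("1" = L))
  max_gap <- function(pos) max(diff(c(0, sort(pos), L)))
  combos <- combn(cand$position_bp, 3)
  oracle_best <- min(apply(combos, 2, max_gap))
  expect_equal(max_gap(sel$position_bp), oracle_best)
})

test_that("wild-SNP placement honors slots, MAF rank and spacing", {
  # exactly satisfiable window: two transitions (one per half) + central
  # transversion, all >= 100 kb apart
  nov <- tibble::tibble(
    chromosome = "1",
    position_bp = c(100e3, 250e3, 450e3, 550e3, 700e3, 900e3),
    is_transition = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    maf = c(0.30, 0.40, 0.20, 0.35, 0.10, 0.45)
  )
  picks <- place_wild_snps(nov, chrom_lengths = c("1" = 1e6))
  expect_equal(nrow(picks), 3)
  expect_setequal(picks$slot, c("transition_1", "transversion_mid", "transition_2"))
  expect_false(any(picks$spacing_violation))
  # MAF-descending within slot: first-half transitions are 0.30 vs 0.40
  expect_equal(picks$position_bp[picks$slot == "transition_1"], 250e3)

  # transitions only in the first half -> second transition slot empty
  nov2 <- nov[nov$position_bp < 5e5 & nov$is_transition, ]
  picks2 <- place_wild_snps(nov2, chrom_lengths = c("1" = 1e6))
  expect_equal(sort(picks2$slot), "transition_1")
})

test_that("wild-SNP spacing violations occur only when unavoidable", {
  # every feasible pairing is < 100 kb apart
  nov <- tibble::tibble(
    chromosome = "1",
    position_bp = c(440e3, 470e3, 530e3),
    is_transition = c(TRUE, FALSE, TRUE),
    maf = c(0.4, 0.3, 0.2)
  )
  picks <- place_wild_snps(nov, chrom_lengths = c("1" = 1e6))
  # brute force over slot assignments: no arrangement of these three
  # candidates satisfies 100-kb spacing for more than one pick
  pos <- nov$position_bp
  compliant_pairs <- abs(outer(pos, pos, "-")) >= 1e5
  diag(compliant_pairs) <- TRUE
  expect_false(any(compliant_pairs[lower.tri(compliant_pairs)]))
  expect_equal(nrow(picks), 3)
  expect_equal(sum(picks$spacing_violation), 2)
})

test_that("wild-SNP placement is reproducible under a fixed seed", {
  set.seed(1)
  nov <- tibble::tibble(
    chromosome = "1",
    position_bp = sort(sample.int(3e6, 60)),
    is_transition = sample(c(TRUE, FALSE), 60, replace = TRUE),
    maf = round(runif(60, 0, 0.5), 1)  # heavy MAF ties
  )
  p1 <- place_wild_snps(nov, chrom_lengths = c("1" = 3e6), seed = 77)
  p2 <- place_wild_snps(nov, chrom_lengths = c("1" = 3e6), seed = 77)
  expect_identical(p1, p2)
})
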