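# small fast configuration shared across this file
small_config <- function(seed, ...) {
  sim_config(
    seed = seed,
    chromosomes = tibble::tibble(
      chromosome = c("1", "X", "Y"),
      length_bp = c(50e6, 40e6, 30e6),
      length_cM = c(30, 25, 0),
      n_markers = c(400L, 60L, 83L)
    ),
    ...
  )
}

test_that("the panel contains all founders and all 28 F1 classes", {
  panel <- simulate_panel(small_config(1))
  expect_equal(sum(panel$samples$group == "f1"), 28)
  expect_equal(sum(panel$samples$group == "classical_inbred"), 16)
  expect_equal(nrow(founder_states(8)[founder_states(8)$zygosity == "het", ]), 28)
  # structural truth completeness: every sample x marker has a diplotype,
  # every sample a sex, every VINO marker a carrier
  n_obs <- nrow(panel$samples) * nrow(panel$manifest)
  expect_equal(nrow(panel$truth$diplotypes), n_obs)
  expect_setequal(panel$truth$sexes$sample_id, panel$samples$sample_id)
  expect_true(all(!is.na(panel$truth$vino$carrier_founder)))
})

test_that("the generator is deterministic under a fixed seed", {
  p1 <- simulate_panel(small_config(7))
  p2 <- simulate_panel(small_config(7))
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$founders, p2$founders)
  s1 <- simulate_intensities(p1, sample_ids = p1$samples$sample_id[1:2])
  s2 <- simulate_intensities(p2, sample_ids = p2$samples$sample_id[1:2])
  expect_identical(s1$intensities, s2$intensities)
  expect_error(sim_config(), "seed is mandatory")
})

test_that("a zero switch rate yields pure-founder mosaic genomes", {
  panel <- simulate_panel(small_config(3, mosaic_generations = 0))
  seg <- panel$truth$mosaic_segments
  per_hap <- seg |>
    dplyr::count(.data$sample_id, .data$haplotype, .data$chromosome)
  expect_true(all(per_hap$n == 1))
})

test_that("F1 genotypes satisfy the parental predictor exactly at zero noise", {
  panel <- simulate_panel(small_config(4))
  man <- panel$manifest
  geno <- calls_matrix(panel$genotypes)
  f1s <- panel$samples[panel$samples$group == "f1", ]
  for (r in sample(nrow(f1s), 5)) {
    f1 <- geno[man$marker_id, f1s$sample_id[r]]
    p1 <- geno[man$marker_id, paste0(f1s$parent_1[r], "_rep1")]
    p2 <- geno[man$marker_id, paste0(f1s$parent_2[r], "_rep1")]
    expect_equal(f1_concordance(f1, p1, p2, chromosome = man$chromosome), 1)
  }
})

test_that("good arrays pass QC and failed arrays are flagged", {
  panel <- simulate_panel(small_config(5))
  ids <- panel$samples$sample_id[1:8]
  modes <- setNames(rep(c("good", "failed"), each = 4), ids)
  sim <- simulate_intensities(panel, modes = modes, sample_ids = ids)
  rep <- qc_report(sim$calls, sim$intensities,
                   panel$samples[panel$samples$sample_id %in% ids, ],
                   panel$manifest)
  expect_equal(rep$status[match(ids[1:4], rep$sample_id)], rep("PASS", 4))
  expect_equal(rep$status[match(ids[5:8], rep$sample_id)], rep("FAIL", 4))
  expect_true(all(rep$K[match(ids[5:8], rep$sample_id)] > 0.1))
})

test_that("diverged arrays show the near-zero intensity spike", {
  panel <- simulate_panel(small_config(6))
  sid <- panel$samples$sample_id[1]
  sim <- simulate_intensities(panel, modes = setNames("diverged", sid),
                              sample_ids = sid)
  d <- sqrt(sim$intensities$x^2 + sim$intensities$y^2)
  frac_low <- mean(d < 0.15)
  expect_gt(frac_low, 0.1)   # spike fraction 0.2 on autosomes
  expect_gt(ks_flag(d)$K, 0.1)
})

test_that("simulated females have zero good Y calls and are sexed female", {
  panel <- simulate_panel(small_config(8))
  females <- panel$samples$sample_id[panel$samples$known_sex == "F"][1:2]
  males <- panel$samples$sample_id[panel$samples$known_sex == "M"][1:2]
  ids <- c(females, males)
  sim <- simulate_intensities(panel, sample_ids = ids)
  sx <- sex_check(sim$calls, sim$intensities, panel$manifest,
                  panel$samples[panel$samples$sample_id %in% ids, ])
  expect_equal(sx$y_good_calls[match(females, sx$sample_id)], c(0L, 0L))
  expect_equal(sx$inferred_sex[match(females, sx$sample_id)], c("F", "F"))
  expect_equal(sx$inferred_sex[match(males, sx$sample_id)], c("M", "M"))
  expect_false(any(sx$sex_mismatch))
})

test_that("VINO carriers emit near-zero intensity and no-calls", {
  panel <- simulate_panel(small_config(9, vino_fraction = 0.05))
  vino <- panel$truth$vino
  expect_gt(nrow(vino), 0)
  carrier_founder <- vino$carrier_founder[1]
  mk <- vino$marker_id[1]
  sid <- paste0(carrier_founder, "_rep1")
  sim <- simulate_intensities(panel, sample_ids = sid)
  row <- sim$intensities[sim$intensities$marker_id == mk, ]
  expect_lt(sqrt(row$x^2 + row$y^2), 0.3)
  expect_equal(sim$calls$call[sim$calls$marker_id == mk], "N")
})

test_that("planted CNV regions recover mean LRR near log2(copy/2)", {
  cnv <- tibble::tibble(sample_id = c("A_rep1", "B_rep1"),
                        chromosome = "1",
                        start_bp = c(5e6, 5e6), end_bp = c(25e6, 25e6),
                        copy = c(1, 3))
  panel <- simulate_panel(small_config(10, cnv_regions = cnv))
  ids <- c(paste0(LETTERS[1:8], "_rep1"), paste0(LETTERS[1:8], "_rep2"))
  sim <- simulate_intensities(panel, sample_ids = ids)
  sig <- normalize_intensities(sim$intensities, sim$calls)
  smry <- summarize_region_lrr(sig, panel$manifest,
                               tibble::tibble(chromosome = "1",
                                              start_bp = 5e6, end_bp = 25e6))
  del <- smry$mean_LRR[smry$sample_id == "A_rep1"]
  dup <- smry$mean_LRR[smry$sample_id == "B_rep1"]
  dip <- smry$mean_LRR[smry$sample_id == "C_rep1"]
  expect_equal(del, log2(1 / 2), tolerance = 0.1)
  expect_equal(dup, log2(3 / 2), tolerance = 0.1)
  expect_equal(dip, 0, tolerance = 0.1)
  expect_equal(smry$call[smry$sample_id == "A_rep1"], "loss")
  expect_equal(smry$call[smry$sample_id == "B_rep1"], "gain")
})
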