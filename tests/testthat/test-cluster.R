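test_that("cluster detection recovers the generating allele configurations", {
  for (seed in 1:5) {
    # standard biallelic marker: two hom clusters + one het cluster
    s3 <- simulate_cluster_points(c("a", "a", "a", "a", "b", "b", "b", "b"),
                                  seed = seed)
    m3 <- cluster_multiallelic(s3$founder_points, s3$f1_points)
    expect_equal(m3$n_clusters, 3)

    # three hybridization alleles (2+1+5 founders): 3 hom + 3 het = 6
    s6 <- simulate_cluster_points(c("a", "a", "b", "c", "c", "c", "c", "c"),
                                  seed = seed)
    m6 <- cluster_multiallelic(s6$founder_points, s6$f1_points)
    expect_equal(m6$n_clusters, 6)

    # monomorphic probe: everything merges
    s1 <- simulate_cluster_points(rep("a", 8), seed = seed)
    m1 <- cluster_multiallelic(s1$founder_points, s1$f1_points)
    expect_equal(m1$n_clusters, 1)
  }
})

test_that("well-separated configurations are recovered at high rate", {
  configs <- list(c("a", "a", "a", "a", "b", "b", "b", "b"),
                  c("a", "a", "b", "c", "c", "c", "c", "c"),
                  c("a", "b", "b", "b", "b", "b", "b", "b"))
  hits <- 0; total <- 0
  for (seed in 1:10) {
    for (cfg in configs) {
      s <- simulate_cluster_points(cfg, seed = seed, noise_sd = 0.02)
      m <- cluster_multiallelic(s$founder_points, s$f1_points)
      hits <- hits + (m$n_clusters == s$truth$n_clusters)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("cluster count is invariant to relabeling and point order", {
  s <- simulate_cluster_points(c("a", "a", "b", "c", "c", "c", "c", "c"),
                               seed = 3)
  base <- cluster_multiallelic(s$founder_points, s$f1_points)$n_clusters
  perm_f <- s$founder_points[sample(nrow(s$founder_points)), ]
  perm_1 <- s$f1_points[sample(nrow(s$f1_points)), ]
  expect_equal(cluster_multiallelic(perm_f, perm_1)$n_clusters, base)
  relab <- dplyr::mutate(s$founder_points,
                         founder = chartr("ABCDEFGH", "HGFEDCBA", founder))
  relab1 <- dplyr::mutate(s$f1_points,
                          parent_1 = chartr("ABCDEFGH", "HGFEDCBA", parent_1),
                          parent_2 = chartr("ABCDEFGH", "HGFEDCBA", parent_2))
  expect_equal(cluster_multiallelic(relab, relab1)$n_clusters, base)
})

test_that("tidy and glance expose the cluster model", {
  s <- simulate_cluster_points(c("a", "a", "a", "a", "b", "b", "b", "b"),
                               seed = 1)
  m <- cluster_multiallelic(s$founder_points, s$f1_points)
  td <- tidy(m)
  expect_true(all(c("member", "cluster", "x", "y") %in% names(td)))
  expect_equal(glance(m)$n_clusters, 3)
})

test_that("construct mixture recovers planted group means", {
  sim <- simulate_construct_panel(n_samples = 200, n_targets = 1,
                                  delta_log10 = 1, sd_log10 = 0.1, seed = 11)
  calls <- call_constructs(sim$raw, sim$targets)
  merged <- dplyr::inner_join(calls, sim$truth, by = c("sample_id", "target"))
  expect_equal(mean((merged$call == "present") == merged$carrier), 1)
  fit <- attr(calls, "fits")[[1]]
  td <- tidy(fit)
  expect_equal(td$mean[td$component == "low"], 2, tolerance = 0.05)
  expect_equal(td$mean[td$component == "high"], 3, tolerance = 0.05)
  expect_true(glance(fit)$separable)
})

test_that("EM log-likelihood is nondecreasing", {
  set.seed(12)
  s <- c(rnorm(60, 2, 0.1), rnorm(40, 3, 0.1))
  fit <- fit_construct_mixture(s)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("EM agrees with an independent mixture fitter", {
  suppressPackageStartupMessages(library(mclust))
  set.seed(13)
  s <- c(rnorm(120, 2, 0.12), rnorm(80, 3.1, 0.1))
  fit <- fit_construct_mixture(s)
  mc <- mclust::Mclust(s, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("degenerate single-mode data are flagged non-separable", {
  sim <- simulate_construct_panel(n_samples = 80, n_targets = 1,
                                  carrier_fraction = 0, seed = 14)
  expect_warning(calls <- call_constructs(sim$raw, sim$targets),
                 "non-separable")
  expect_true(all(calls$non_separable))
  expect_true(all(calls$call == "absent"))
})

test_that("a single positive among many negatives is called present", {
  set.seed(15)
  n <- 100
  s_log10 <- c(rnorm(n - 1, 2, 0.08), 3.2)
  raw <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), probe_id = "p1",
                        x_raw = 10^s_log10, y_raw = 1)
  targets <- tibble::tibble(probe_id = "p1", target = "tg",
                            informative_axis = "x")
  calls <- call_constructs(raw, targets)
  expect_equal(calls$call[calls$sample_id == "S100"], "present")
  expect_equal(sum(calls$call == "present"), 1)
  # posterior agrees with the closed-form Bayes rule under the fitted fit
  fit <- attr(calls, "fits")[["tg"]]
  hi <- fit$component_high; lo <- 3 - hi
  s_obs <- calls$log10_sum[calls$sample_id == "S100"]
  p_manual <- fit$lambda[hi] * dnorm(s_obs, fit$mu[hi], fit$sigma[hi]) /
    (fit$lambda[hi] * dnorm(s_obs, fit$mu[hi], fit$sigma[hi]) +
       fit$lambda[lo] * dnorm(s_obs, fit$mu[lo], fit$sigma[lo]))
  expect_equal(calls$posterior_present[calls$sample_id == "S100"], p_manual)
})

test_that("construct calls use raw intensities only", {
  sim <- simulate_construct_panel(n_samples = 60, n_targets = 1, seed = 16)
  base <- suppressWarnings(call_constructs(sim$raw, sim$targets))
  # adding a normalized layer (or altering it) cannot change the calls
  perturbed <- dplyr::mutate(sim$raw, x = x_raw * runif(dplyr::n()),
                             y = y_raw * runif(dplyr::n()))
  again <- suppressWarnings(call_constructs(perturbed, sim$targets))
  expect_equal(again$call, base$call)
})

test_that("a target with no probes errors", {
  sim <- simulate_construct_panel(n_samples = 20, n_targets = 1, seed = 17)
  targets <- dplyr::bind_rows(sim$targets,
                              tibble::tibble(probe_id = "ghost",
                                             target = "missing",
                                             informative_axis = "x"))
  expect_error(call_constructs(sim$raw, targets), "no probes")
})
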