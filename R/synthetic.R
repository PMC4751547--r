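#' Simulation configuration
#'
#' Study conditions for the synthetic array generator. Defaults emulate a
#' desk-scale array: two autosomes plus X and Y (83 Y markers, as on the
#' full-size array), 8 founder strains with technical replicates, all 28
#' F1 combinations, and a few outbred mosaics. The intensity model is
#' anchored on the per-probe total-intensity statistic `d`: on a good
#' array `d` follows Normal(0.97, 0.42) (negative draws floored at 0); a
#' failed array draws `d` from a right-skewed Gamma with mean 0.45; a
#' genetically diverged sample mixes the good component with a spike of
#' near-zero intensities.
#'
#' @param seed integer seed (mandatory).
#' @param chromosomes tibble with `chromosome`, `length_bp`, `length_cM`,
#'   `n_markers`.
#' @param n_founders number of founder strains (default 8).
#' @param n_replicates technical replicates per founder (default 2).
#' @param n_mosaic number of outbred mosaic samples (default 4).
#' @param mosaic_generations outbreeding generations scaling the mosaic
#'   switch rate (default 10).
#' @param vino_fraction fraction of autosomal markers behaving as VINOs
#'   (off-target variation null allele) in one carrier founder (default
#'   0.01).
#' @param noise_theta sd of the angle around a cluster center (default
#'   0.02).
#' @param missing_rate sporadic no-call rate on good arrays (default
#'   0.002).
#' @param missing_rate_failed no-call rate on failed arrays (default
#'   0.35).
#' @param d_good_mean,d_good_sd reference normal for good-mode `d`
#'   (defaults 0.97, 0.42).
#' @param d_good_cv within-marker coefficient of variation of `d` across
#'   samples; the rest of the reference variance is per-marker probe
#'   affinity, fixed across samples (default 0.08).
#' @param d_failed_mean,d_failed_shape Gamma parameters for failed-mode
#'   `d` (mean 0.45, shape 4).
#' @param spike_mean,spike_sd half-normal parameters of the near-zero
#'   intensity spike (defaults 0.05, 0.03).
#' @param diverged_spike_fraction fraction of probes in the spike for
#'   diverged samples (default 0.2).
#' @param cnv_regions optional tibble `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `copy` of planted copy-number events.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       chromosomes = tibble::tibble(
                         chromosome = c("1", "2", "X", "Y"),
                         length_bp = c(100e6, 90e6, 100e6, 90e6),
                         length_cM = c(50, 45, 50, 0),
                         n_markers = c(1000L, 900L, 120L, 83L)
                       ),
                       n_founders = 8, n_replicates = 2, n_mosaic = 4,
                       mosaic_generations = 10,
                       vino_fraction = 0.01, noise_theta = 0.02,
                       missing_rate = 0.002, missing_rate_failed = 0.35,
                       d_good_mean = 0.97, d_good_sd = 0.42,
                       d_good_cv = 0.08,
                       d_failed_mean = 0.45, d_failed_shape = 4,
                       spike_mean = 0.05, spike_sd = 0.03,
                       diverged_spike_fraction = 0.2,
                       cnv_regions = NULL) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_founders >= 2, vino_fraction >= 0, vino_fraction <= 1,
            diverged_spike_fraction >= 0, diverged_spike_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# founder letters A..H etc.
.founder_names <- function(n) LETTERS[seq_len(n)]

#' Simulate a founder reference panel
#'
#' Generates a marker manifest, founder haplotypes, and genotypes for a
#' reference panel: `n_replicates` copies of each founder strain, all
#' `choose(n_founders, 2)` F1 combinations, and `n_mosaic` outbred mosaics
#' generated by Markov switching of haplotype ancestry along the genetic
#' map (switch rate scaled by `mosaic_generations`). Males are hemizygous
#' on X and Y; females have no Y calls. Ground truth (diplotypes, mosaic
#' segments, sexes, VINO markers) is recorded in full.
#'
#' @param config [sim_config()] list.
#' @return list of class `sim_panel` with `manifest`, `founders`
#'   (founders x markers allele matrix, 0/1), `samples`, `genotypes`
#'   (true calls, long tibble), `marker_params` (per-marker cluster
#'   centers), `truth`, `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fn <- .founder_names(config$n_founders)

  # manifest -----------------------------------------------------------
  chrs <- config$chromosomes
  man <- purrr::pmap_dfr(chrs, function(chromosome, length_bp, length_cM, n_markers) {
    pos <- sort(sample.int(length_bp, n_markers))
    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, n_markers, replace = TRUE)
    # transition-biased alternate alleles
    partner <- c(A = "G", G = "A", C = "T", T = "C")
    alt <- ifelse(runif(n_markers) < 0.8, partner[ref],
                  vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1)))
    tibble::tibble(
      marker_id = sprintf("%s_%09d", paste0("chr", chromosome), pos),
      chromosome = chromosome,
      position_bp = as.integer(pos),
      position_cM = length_cM * pos / length_bp,
      allele_ref = ref, allele_alt = unname(alt)
    )
  })
  n_mark <- nrow(man)

  # founder haplotypes: per-marker allele frequency, then Bernoulli
  p <- runif(n_mark, 0.1, 0.9)
  founders <- matrix(rbinom(n_mark * config$n_founders, 1,
                            rep(p, each = config$n_founders)),
                     nrow = config$n_founders,
                     dimnames = list(fn, man$marker_id))

  # marker-level intensity cluster centers (theta space) and probe affinity;
  # affinity variance chosen so the array-level marginal of
  # d = affinity * (1 + cv * noise) keeps the reference mean and sd
  sigma_a <- sqrt((config$d_good_sd^2 -
                     (config$d_good_mean * config$d_good_cv)^2) /
                    (1 + config$d_good_cv^2))
  marker_params <- tibble::tibble(
    marker_id = man$marker_id,
    theta_AA = pmin(pmax(rnorm(n_mark, 0.08, 0.02), 0.01), 0.2),
    theta_BB = pmin(pmax(rnorm(n_mark, 0.92, 0.02), 0.8), 0.99),
    affinity = pmax(rnorm(n_mark, config$d_good_mean, sigma_a), 0)
  )
  marker_params$theta_AB <- (marker_params$theta_AA + marker_params$theta_BB) / 2

  # VINO markers: autosomal subset with one carrier founder each
  auto_markers <- man$marker_id[!man$chromosome %in% c("X", "Y", "M")]
  n_vino <- round(config$vino_fraction * length(auto_markers))
  vino <- tibble::tibble(
    marker_id = sample(auto_markers, n_vino),
    carrier_founder = sample(fn, n_vino, replace = TRUE)
  )

  # samples -------------------------------------------------------------
  rep_samples <- tidyr::expand_grid(founder = fn,
                                    rep = seq_len(config$n_replicates)) |>
    dplyr::mutate(sample_id = paste0(.data$founder, "_rep", .data$rep),
                  group = "classical_inbred")
  f1_pairs <- founder_states(config$n_founders) |>
    dplyr::filter(.data$zygosity == "het")
  f1_samples <- tibble::tibble(
    sample_id = paste0("F1_", fn[f1_pairs$founder_1], "x", fn[f1_pairs$founder_2]),
    parent_1 = fn[f1_pairs$founder_1],
    parent_2 = fn[f1_pairs$founder_2],
    group = "f1"
  )
  do_samples <- tibble::tibble(
    sample_id = sprintf("DO_%03d", seq_len(config$n_mosaic)),
    group = "do"
  )
  samples <- dplyr::bind_rows(
    dplyr::select(rep_samples, "sample_id", "group") |>
      dplyr::mutate(strain = rep_samples$founder),
    dplyr::select(f1_samples, "sample_id", "group", parent_1 = "parent_1",
                  parent_2 = "parent_2"),
    do_samples
  )
  samples$known_sex <- rep(c("M", "F"), length.out = nrow(samples))

  # diplotypes -----------------------------------------------------------
  # haplotype-of-origin per sample per marker (two haplotypes)
  hap_rows <- list()
  seg_rows <- list()
  add_constant_hap <- function(sid, h1, h2) {
    hap_rows[[length(hap_rows) + 1]] <<- tibble::tibble(
      sample_id = sid, marker_id = man$marker_id, hap_1 = h1, hap_2 = h2)
  }
  for (r in seq_len(nrow(rep_samples))) {
    add_constant_hap(rep_samples$sample_id[r], rep_samples$founder[r],
                     rep_samples$founder[r])
  }
  for (r in seq_len(nrow(f1_samples))) {
    add_constant_hap(f1_samples$sample_id[r], f1_samples$parent_1[r],
                     f1_samples$parent_2[r])
  }
  # mosaics: Markov switching along the cM map per chromosome
  switch_rate <- config$mosaic_generations / 100  # expected switches per cM
  for (s in do_samples$sample_id) {
    haps <- matrix(NA_character_, n_mark, 2)
    for (hap in 1:2) {
      for (ch in chrs$chromosome) {
        idx <- which(man$chromosome == ch)
        cm <- man$position_cM[idx]
        cur <- sample(fn, 1)
        labs <- character(length(idx))
        labs[1] <- cur
        if (length(idx) > 1) {
          d_cm <- diff(cm)
          p_sw <- 1 - exp(-switch_rate * d_cm)
          sw <- runif(length(d_cm)) < p_sw
          for (i in seq_along(sw)) {
            if (sw[i]) cur <- sample(setdiff(fn, cur), 1)
            labs[i + 1] <- cur
          }
        }
        haps[idx, hap] <- labs
        runs <- rle(labs)
        ends <- cumsum(runs$lengths)
        starts <- c(1, head(ends, -1) + 1)
        seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
          sample_id = s, haplotype = hap, chromosome = ch,
          start_bp = man$position_bp[idx][starts],
          end_bp = man$position_bp[idx][ends],
          founder = runs$values
        )
      }
    }
    hap_rows[[length(hap_rows) + 1]] <- tibble::tibble(
      sample_id = s, marker_id = man$marker_id,
      hap_1 = haps[, 1], hap_2 = haps[, 2])
  }
  diplotypes <- dplyr::bind_rows(hap_rows)

  # genotypes from diplotypes -------------------------------------------
  sex_of <- setNames(samples$known_sex, samples$sample_id)
  dip <- diplotypes |>
    dplyr::left_join(dplyr::select(man, "marker_id", "chromosome"),
                     by = "marker_id")
  a1 <- founders[cbind(match(dip$hap_1, fn), match(dip$marker_id, man$marker_id))]
  a2 <- founders[cbind(match(dip$hap_2, fn), match(dip$marker_id, man$marker_id))]
  sex <- sex_of[dip$sample_id]
  # males hemizygous on X and Y (haplotype 1); females: no Y
  hemi <- (dip$chromosome == "Y") | (dip$chromosome == "X" & sex == "M")
  a2[hemi] <- a1[hemi]
  call <- dplyr::case_when(
    dip$chromosome == "Y" & sex == "F" ~ "N",
    a1 + a2 == 0 ~ "AA",
    a1 + a2 == 2 ~ "BB",
    TRUE ~ "AB"
  )
  genotypes <- tibble::tibble(sample_id = dip$sample_id,
                              marker_id = dip$marker_id, call = call)

  truth <- list(
    diplotypes = diplotypes,
    mosaic_segments = dplyr::bind_rows(seg_rows),
    sexes = dplyr::select(samples, "sample_id", sex = "known_sex"),
    vino = vino,
    cnv = config$cnv_regions
  )
  structure(
    list(manifest = man, founders = founders, samples = samples,
         genotypes = genotypes, marker_params = marker_params,
         truth = truth, config = config),
    class = "sim_panel"
  )
}

# d values for one array of n probes in a given mode; good-mode d is the
# per-marker probe affinity times small within-marker noise, so that the
# array-level marginal follows the reference normal while per-marker
# normalization can cancel the affinity component
.sim_d <- function(n, mode, cfg, affinity) {
  if (mode == "good") {
    pmax(affinity * (1 + rnorm(n, 0, cfg$d_good_cv)), 0)
  } else if (mode == "failed") {
    rgamma(n, shape = cfg$d_failed_shape,
           rate = cfg$d_failed_shape / cfg$d_failed_mean)
  } else if (mode == "diverged") {
    base <- pmax(affinity * (1 + rnorm(n, 0, cfg$d_good_cv)), 0)
    spike <- abs(rnorm(n, cfg$spike_mean, cfg$spike_sd))
    pick <- runif(n) < cfg$diverged_spike_fraction
    ifelse(pick, spike, base)
  } else {
    abort(paste0("unknown array mode: ", mode))
  }
}

#' Simulate hybridization intensities and observed calls
#'
#' For each sample, draws the per-probe total intensity `d` from the
#' distribution of its array mode (`good`, `failed`, `diverged`), places
#' the probe on the intensity arc at its genotype cluster's angle (plus
#' noise), and reconstructs the channel intensities `x = d cos`,
#' `y = d sin`. Female samples emit background intensity and no-calls at
#' Y markers; planted CNV regions multiply `d` by `copy / 2`; VINO
#' markers emit near-zero intensity and no-calls in samples carrying the
#' VINO founder haplotype. Observed calls equal the true genotypes minus
#' mode-dependent sporadic no-calls and the intensity-driven no-calls
#' above.
#'
#' @param panel [simulate_panel()] result.
#' @param modes named character vector of array modes per sample
#'   (default: all `good`).
#' @param sample_ids optional subset of samples to simulate.
#' @return list with `intensities` (tibble: `sample_id`, `marker_id`,
#'   `x_raw`, `y_raw`, `x`, `y`) and `calls` (observed calls, long
#'   tibble).
#' @export
simulate_intensities <- function(panel, modes = NULL, sample_ids = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  cfg <- panel$config
  set.seed(cfg$seed + 1L)
  if (is.null(sample_ids)) sample_ids <- panel$samples$sample_id
  if (is.null(modes)) modes <- setNames(rep("good", length(sample_ids)), sample_ids)
  bad_modes <- setdiff(unique(modes), c("good", "failed", "diverged"))
  if (length(bad_modes) > 0) abort(paste0("unknown array mode: ", bad_modes[1]))
  man <- panel$manifest
  mp <- panel$marker_params
  sex_of <- setNames(panel$samples$known_sex, panel$samples$sample_id)
  vino <- panel$truth$vino
  dip <- panel$truth$diplotypes
  cnv <- panel$truth$cnv

  out_int <- list()
  out_calls <- list()
  for (s in sample_ids) {
    mode <- if (s %in% names(modes)) modes[[s]] else "good"
    g <- panel$genotypes[panel$genotypes$sample_id == s, ]
    g <- g[match(man$marker_id, g$marker_id), ]
    call <- g$call
    n <- nrow(man)
    d <- .sim_d(n, mode, cfg, mp$affinity)

    # female Y background
    if (sex_of[[s]] == "F") {
      fy <- man$chromosome == "Y"
      d[fy] <- abs(rnorm(sum(fy), cfg$spike_mean, cfg$spike_sd))
      call[fy] <- "N"
    }
    # male X: single copy -> half intensity
    if (sex_of[[s]] == "M") {
      mx <- man$chromosome %in% c("X", "Y")
      d[mx] <- d[mx] * 0.5
    }
    # CNV regions
    if (!is.null(cnv)) {
      here <- cnv[cnv$sample_id == s, ]
      for (r in seq_len(nrow(here))) {
        in_r <- man$chromosome == here$chromosome[r] &
          man$position_bp >= here$start_bp[r] &
          man$position_bp <= here$end_bp[r]
        d[in_r] <- d[in_r] * here$copy[r] / 2
      }
    }
    # VINOs: carriers emit near-zero intensity and no-call
    if (nrow(vino) > 0) {
      dd <- dip[dip$sample_id == s, ]
      dd <- dd[match(man$marker_id, dd$marker_id), ]
      vi <- match(vino$marker_id, man$marker_id)
      carrier <- dd$hap_1[vi] == vino$carrier_founder |
        dd$hap_2[vi] == vino$carrier_founder
      hit <- vi[which(carrier)]
      if (length(hit) > 0) {
        d[hit] <- abs(rnorm(length(hit), cfg$spike_mean, cfg$spike_sd))
        call[hit] <- "N"
      }
    }
    # sporadic no-calls
    miss_rate <- if (mode == "failed") cfg$missing_rate_failed else cfg$missing_rate
    call[runif(n) < miss_rate] <- "N"

    # angle from cluster center of the observed genotype
    theta_c <- dplyr::case_when(
      call == "BB" ~ mp$theta_BB,
      call == "AB" ~ mp$theta_AB,
      TRUE ~ mp$theta_AA
    )
    theta <- pmin(pmax(theta_c + rnorm(n, 0, cfg$noise_theta), 0), 1)
    x <- d * cos(theta * pi / 2)
    y <- d * sin(theta * pi / 2)
    out_int[[s]] <- tibble::tibble(
      sample_id = s, marker_id = man$marker_id,
      x_raw = 100 * x, y_raw = 100 * y, x = x, y = y
    )
    out_calls[[s]] <- tibble::tibble(sample_id = s, marker_id = man$marker_id,
                                     call = call)
  }
  list(intensities = dplyr::bind_rows(out_int),
       calls = dplyr::bind_rows(out_calls))
}

#' Simulate intensity clusters for one probe
#'
#' Places the distinct hybridization alleles of a probe on the intensity
#' arc, builds one point cloud per founder (replicates around the
#' founder's homozygous position) and per F1 class (around the midpoint of
#' the parents' positions), and records the true number of distinct
#' clusters (distinct homozygous alleles plus distinct unordered allele
#' pairs among the F1s).
#'
#' @param founder_alleles character vector: hybridization allele of each
#'   founder (e.g. `c("a","a","b","c","c","c","c","c")`).
#' @param n_reps replicate points per founder (default 3).
#' @param f1_pairs tibble with `parent_1`, `parent_2` (founder indices);
#'   default all unordered pairs.
#' @param noise_sd isotropic noise sd around cluster centers (default
#'   0.02).
#' @param radius arc radius of the hom positions (default 1).
#' @param seed integer seed.
#' @return list with `founder_points`, `f1_points`, `truth` (list with
#'   `n_clusters`).
#' @export
simulate_cluster_points <- function(founder_alleles, n_reps = 3,
                                    f1_pairs = NULL, noise_sd = 0.02,
                                    radius = 1, seed = 1) {
  set.seed(seed)
  n_f <- length(founder_alleles)
  fn <- .founder_names(n_f)
  alleles <- sort(unique(founder_alleles))
  theta <- seq(0.1, 0.9, length.out = max(length(alleles), 2))[seq_along(alleles)]
  pos <- cbind(x = radius * cos(theta * pi / 2), y = radius * sin(theta * pi / 2))
  rownames(pos) <- alleles
  founder_points <- purrr::map_dfr(seq_len(n_f), function(i) {
    ctr <- pos[founder_alleles[i], ]
    tibble::tibble(founder = fn[i],
                   x = ctr[1] + rnorm(n_reps, 0, noise_sd),
                   y = ctr[2] + rnorm(n_reps, 0, noise_sd))
  })
  if (is.null(f1_pairs)) {
    st <- founder_states(n_f)
    f1_pairs <- st[st$zygosity == "het", c("founder_1", "founder_2")]
    names(f1_pairs) <- c("parent_1", "parent_2")
  }
  f1_points <- purrr::pmap_dfr(f1_pairs, function(parent_1, parent_2) {
    ctr <- (pos[founder_alleles[parent_1], ] + pos[founder_alleles[parent_2], ]) / 2
    tibble::tibble(parent_1 = fn[parent_1], parent_2 = fn[parent_2],
                   x = ctr[1] + rnorm(n_reps, 0, noise_sd),
                   y = ctr[2] + rnorm(n_reps, 0, noise_sd))
  })
  pair_alleles <- apply(f1_pairs, 1, function(pr) {
    paste(sort(founder_alleles[pr]), collapse = "/")
  })
  het_classes <- unique(pair_alleles[vapply(strsplit(pair_alleles, "/"),
                                            function(v) v[1] != v[2], logical(1))])
  truth <- list(n_clusters = length(alleles) + length(het_classes))
  list(founder_points = founder_points, f1_points = f1_points, truth = truth)
}

#' Simulate a congenic genome and donor panel
#'
#' Builds a panel of homozygous donor strains genotyped at uniformly
#' spaced markers on one chromosome and a test sample that is donor 1
#' throughout except for a planted block from donor 2, with per-marker
#' genotyping error. Used to exercise the ancestry-mosaic HMM with known
#' truth.
#'
#' @param n_markers markers on the chromosome (default 500).
#' @param n_donors donor strains (default 3).
#' @param length_cM chromosome genetic length (default 100).
#' @param block_cM start/end of the donor-2 block in cM (default
#'   `c(40, 60)`).
#' @param diff_rate probability two donors differ at a marker; emulates a
#'   donor panel genotyped at markers informative for the
#'   background-vs-donor comparison, with a small uninformative residue
#'   (default 0.95).
#' @param epsilon per-marker error rate applied to the sample (default
#'   0.01).
#' @param seed integer seed.
#' @return list with `sample_calls`, `donors` (long tibble), `map`,
#'   `truth` (block marker indices and bp bounds).
#' @export
simulate_congenic <- function(n_markers = 500, n_donors = 3, length_cM = 100,
                              block_cM = c(40, 60), diff_rate = 0.95,
                              epsilon = 0.01, seed = 1) {
  set.seed(seed)
  length_bp <- length_cM * 2e6
  pos <- sort(sample.int(length_bp, n_markers))
  cm <- length_cM * pos / length_bp
  mk <- sprintf("m%05d", seq_len(n_markers))
  donor_names <- paste0("donor", seq_len(n_donors))
  # donor 1 baseline; others differ at diff_rate of markers
  base <- sample(c("AA", "BB"), n_markers, replace = TRUE)
  calls <- matrix(base, n_markers, n_donors)
  for (j in seq(2, n_donors)) {
    flip <- runif(n_markers) < diff_rate
    calls[flip, j] <- ifelse(base[flip] == "AA", "BB", "AA")
  }
  colnames(calls) <- donor_names
  in_block <- cm >= block_cM[1] & cm <= block_cM[2]
  truth_idx <- range(which(in_block))
  samp <- ifelse(in_block, calls[, 2], calls[, 1])
  err <- runif(n_markers) < epsilon
  samp[err] <- ifelse(samp[err] == "AA", "BB", "AA")
  list(
    sample_calls = tibble::tibble(marker_id = mk, chromosome = "1",
                                  position_bp = pos, call = samp),
    donors = tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(marker_id = mk),
                       tibble::as_tibble(calls)),
      -"marker_id", names_to = "donor", values_to = "call"),
    map = tibble::tibble(chromosome = "1",
                         position_bp = c(1L, as.integer(length_bp)),
                         position_cM = c(0, length_cM)),
    truth = list(block_start_idx = truth_idx[1], block_end_idx = truth_idx[2],
                 block_start_bp = pos[truth_idx[1]],
                 block_end_bp = pos[truth_idx[2]],
                 in_block = in_block)
  )
}

#' Simulate construct-probe raw intensities
#'
#' Per target, carriers draw their log10 summed informative-axis intensity
#' from Normal(`mu_absent + delta_log10`, `sd_log10`) and non-carriers
#' from Normal(`mu_absent`, `sd_log10`); the total is split evenly across
#' the target's probes on the informative axis, with background on the
#' other axis.
#'
#' @param n_samples number of samples (default 100).
#' @param n_targets number of construct targets (default 2).
#' @param n_probes_per_target probes per target (default 2).
#' @param carrier_fraction fraction of carrier samples per target
#'   (default 0.3).
#' @param mu_absent mean log10 sum intensity of non-carriers (default 2).
#' @param delta_log10 carrier shift in log10 units (default 1).
#' @param sd_log10 within-group sd (default 0.1).
#' @param seed integer seed.
#' @return list with `raw` (tibble `sample_id`, `probe_id`, `x_raw`,
#'   `y_raw`), `targets` (probe map with informative axis), `truth`
#'   (carrier table and group means).
#' @export
simulate_construct_panel <- function(n_samples = 100, n_targets = 2,
                                     n_probes_per_target = 2,
                                     carrier_fraction = 0.3, mu_absent = 2,
                                     delta_log10 = 1, sd_log10 = 0.1,
                                     seed = 1) {
  set.seed(seed)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  raw <- list()
  targets <- list()
  truth <- list()
  for (t in seq_len(n_targets)) {
    tname <- paste0("construct", t)
    probes <- paste0(tname, "_p", seq_len(n_probes_per_target))
    axis <- sample(c("x", "y"), 1)
    targets[[t]] <- tibble::tibble(probe_id = probes, target = tname,
                                   informative_axis = axis)
    carrier <- runif(n_samples) < carrier_fraction
    mu <- ifelse(carrier, mu_absent + delta_log10, mu_absent)
    total <- 10^rnorm(n_samples, mu, sd_log10)
    per_probe <- total / n_probes_per_target
    for (k in seq_along(probes)) {
      sig <- per_probe
      bg <- abs(rnorm(n_samples, 5, 2))
      raw[[length(raw) + 1]] <- tibble::tibble(
        sample_id = sample_ids, probe_id = probes[k],
        x_raw = if (axis == "x") sig else bg,
        y_raw = if (axis == "y") sig else bg
      )
    }
    truth[[t]] <- tibble::tibble(sample_id = sample_ids, target = tname,
                                 carrier = carrier,
                                 mu_absent = mu_absent,
                                 mu_present = mu_absent + delta_log10)
  }
  list(raw = dplyr::bind_rows(raw), targets = dplyr::bind_rows(targets),
       truth = dplyr::bind_rows(truth))
}
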