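# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: state vectors are built as allele-pair strings, path
# scores by direct enumeration, the KS statistic via stats::ks.test.

# brute-force window score: enumerate every founder state, build its
# per-SNP unordered allele-pair string, count distinct joint vectors
oracle_window_score <- function(fa) {
  n_f <- nrow(fa)
  states <- character(0)
  for (i in seq_len(n_f)) {
    for (j in i:n_f) {
      pair <- vapply(seq_len(ncol(fa)), function(m) {
        paste(sort(c(fa[i, m], fa[j, m])), collapse = "")
      }, character(1))
      states <- c(states, paste(pair, collapse = "|"))
    }
  }
  length(unique(states))
}

# exhaustive best path score: one candidate per interval, score = sum of
# window scores over sliding windows of length w
oracle_best_path <- function(slots, fa, w) {
  grid <- do.call(expand.grid, lapply(slots, identity))
  best <- -Inf
  memo <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(grid[r, ])
    sc <- 0
    if (length(path) >= w) {
      for (s in seq_len(length(path) - w + 1)) {
        cols <- path[s:(s + w - 1)]
        key <- paste(cols, collapse = ",")
        v <- memo[[key]]
        if (is.null(v)) {
          v <- oracle_window_score(fa[, cols, drop = FALSE])
          memo[[key]] <- v
        }
        sc <- sc + v
      }
    }
    if (sc > best) best <- sc
  }
  best
}

# random selection instance: n_iv intervals with <= max_per candidates each;
# the first and last candidates sit exactly on the cM span endpoints so the
# uniform-break interval membership is unambiguous
random_beam_instance <- function(seed, n_iv = 8, max_per = 3, n_f = 8) {
  set.seed(seed)
  per <- sample.int(max_per, n_iv, replace = TRUE)
  n_c <- sum(per)
  iv <- rep(seq_len(n_iv), per)
  br <- seq(0, 10, length.out = n_iv + 1)
  cm <- unlist(lapply(seq_len(n_iv), function(i) {
    sort(runif(per[i], br[i] + 1e-3, br[i + 1] - 1e-3))
  }))
  cm[1] <- 0
  cm[n_c] <- 10
  cand <- tibble::tibble(marker_id = sprintf("m%03d", seq_len(n_c)),
                         position_cM = cm)
  fa <- matrix(rbinom(n_f * n_c, 1, 0.5), n_f, n_c,
               dimnames = list(LETTERS[seq_len(n_f)], cand$marker_id))
  slots <- split(seq_len(n_c), iv)
  list(cand = cand, fa = fa, slots = slots, n_iv = n_iv)
}

# KS statistic against a normal reference, via stats::ks.test
oracle_ks <- function(x, mean, sd) {
  unname(suppressWarnings(stats::ks.test(x, "pnorm", mean, sd)$statistic))
}

# exhaustive best-path log-likelihood for a small donor HMM
oracle_hmm_best <- function(sample_calls, donor_calls, cm, epsilon,
                            expected_segment_cM) {
  n_m <- length(sample_calls)
  n_d <- ncol(donor_calls)
  emit <- function(i, j) {
    if (sample_calls[i] == "N" || donor_calls[i, j] == "N") return(0)
    if (sample_calls[i] == donor_calls[i, j]) log(1 - epsilon) else log(epsilon)
  }
  p_sw <- 1 - exp(-pmax(diff(cm), 1e-6) / expected_segment_cM)
  paths <- do.call(expand.grid, rep(list(seq_len(n_d)), n_m))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    pth <- as.integer(paths[r, ])
    ll <- -log(n_d) + emit(1, pth[1])
    for (i in seq(2, n_m)) {
      ll <- ll + if (pth[i] == pth[i - 1]) log(1 - p_sw[i - 1]) else
        log(p_sw[i - 1] / (n_d - 1))
      ll <- ll + emit(i, pth[i])
    }
    if (ll > best) best <- ll
  }
  best
}
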