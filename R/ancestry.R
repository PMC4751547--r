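#' HMM parameters for ancestry-mosaic reconstruction
#'
#' @param epsilon per-marker genotype error/mismatch probability (default
#'   0.01).
#' @param expected_segment_cM expected donor-segment length in cM; the
#'   per-interval switch probability is
#'   `1 - exp(-d_cM / expected_segment_cM)` (default 10 cM).
#' @param margin_delta log-likelihood margin below which competing donors
#'   are collapsed into an equivalence group on a segment (default 2.0).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(epsilon = 0.01, expected_segment_cM = 10,
                       margin_delta = 2.0) {
  stopifnot(epsilon > 0, epsilon < 0.5, expected_segment_cM > 0,
            margin_delta >= 0)
  structure(list(epsilon = epsilon,
                 expected_segment_cM = expected_segment_cM,
                 margin_delta = margin_delta),
            class = "hmm_params")
}

# log emission matrix: markers x donors; obs N emits uniformly (constant 0)
.emission_loglik <- function(sample_calls, donor_calls, epsilon) {
  n_m <- length(sample_calls)
  n_d <- ncol(donor_calls)
  E <- matrix(0, n_m, n_d)
  informative <- sample_calls != "N"
  for (j in seq_len(n_d)) {
    match <- sample_calls == donor_calls[, j] & donor_calls[, j] != "N"
    E[informative, j] <- ifelse(match[informative], log(1 - epsilon), log(epsilon))
    # donor missing: uninformative
    E[donor_calls[, j] == "N", j] <- 0
  }
  E
}

# Viterbi + forward-backward on one chromosome; returns list(path, posterior, loglik)
.hmm_decode <- function(E, cm, params) {
  n_m <- nrow(E)
  n_d <- ncol(E)
  d_cm <- pmax(diff(cm), 1e-6)
  p_switch <- 1 - exp(-d_cm / params$expected_segment_cM)
  log_stay <- log(1 - p_switch)
  log_move <- log(p_switch / (n_d - 1))
  init <- rep(-log(n_d), n_m)

  # Viterbi
  V <- matrix(-Inf, n_m, n_d)
  B <- matrix(0L, n_m, n_d)
  V[1, ] <- -log(n_d) + E[1, ]
  if (n_m > 1) {
    for (i in seq(2, n_m)) {
      for (j in seq_len(n_d)) {
        cand <- V[i - 1, ] + ifelse(seq_len(n_d) == j, log_stay[i - 1], log_move[i - 1])
        b <- which.max(cand)
        V[i, j] <- cand[b] + E[i, j]
        B[i, j] <- b
      }
    }
  }
  path <- integer(n_m)
  path[n_m] <- which.max(V[n_m, ])
  if (n_m > 1) {
    for (i in seq(n_m - 1, 1)) path[i] <- B[i + 1, path[i + 1]]
  }

  # forward-backward (scaled)
  A_list <- function(i) {
    # transition matrix from marker i to i+1
    M <- matrix(exp(log_move[i]), n_d, n_d)
    diag(M) <- exp(log_stay[i])
    M
  }
  fwd <- matrix(0, n_m, n_d)
  scl <- numeric(n_m)
  f <- exp(E[1, ]) / n_d
  scl[1] <- sum(f)
  fwd[1, ] <- f / scl[1]
  if (n_m > 1) {
    for (i in seq(2, n_m)) {
      f <- as.vector(fwd[i - 1, ] %*% A_list(i - 1)) * exp(E[i, ])
      scl[i] <- sum(f)
      fwd[i, ] <- f / scl[i]
    }
  }
  bwd <- matrix(0, n_m, n_d)
  bwd[n_m, ] <- 1
  if (n_m > 1) {
    for (i in seq(n_m - 1, 1)) {
      b <- as.vector(A_list(i) %*% (exp(E[i + 1, ]) * bwd[i + 1, ]))
      bwd[i, ] <- b / scl[i + 1]
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)
  list(path = path, posterior = post, loglik = sum(log(scl)),
       viterbi_loglik = max(V[n_m, ]))
}

#' Reconstruct a genome as a mosaic of donor strains
#'
#' Hidden Markov model over candidate donor strains: hidden states are
#' donors, emissions score per-marker call match (`1 - epsilon`) vs
#' mismatch (`epsilon`; no-calls are uninformative), and transition
#' probability between adjacent markers scales with their genetic-map
#' distance. The Viterbi path is decoded into segments (boundaries placed
#' at the midpoint between the flanking markers of a state change). Per
#' segment, donors whose within-segment emission log-likelihood is within
#' `margin_delta` of the best donor are reported as an equivalence group
#' (e.g. indistinguishable substrains). Forward-backward posteriors are
#' attached as the mean posterior of the segment's donor group.
#'
#' @param sample_calls tibble with `marker_id`, `chromosome`,
#'   `position_bp`, `call` for the sample under test.
#' @param donors tibble with `donor`, `marker_id`, `call` for >= 2 donors.
#' @param map genetic map tibble (see [read_genetic_map()]).
#' @param params [hmm_params()] list.
#' @return object of class `ancestry_mosaic`: list with `segments`
#'   (tibble: chromosome, start/end bp, `donor` best label, `donor_group`
#'   collapsed label, `n_markers`, `mean_posterior`), `loglik`, and
#'   `donors` (the usable donor names).
#' @export
viterbi_mosaic <- function(sample_calls, donors, map, params = hmm_params()) {
  dmat <- tidyr::pivot_wider(donors, id_cols = "marker_id",
                             names_from = "donor", values_from = "call",
                             values_fill = "N")
  usable <- names(dmat)[-1][vapply(dmat[-1], function(v) any(v != "N"), logical(1))]
  dropped <- setdiff(names(dmat)[-1], usable)
  if (length(dropped) > 0) {
    warn(paste0("donor(s) with all-missing genotypes dropped: ",
                paste(dropped, collapse = ", ")))
  }
  if (length(usable) < 2) abort("need at least two usable donors")
  n_d <- length(usable)

  sc <- tibble::as_tibble(sample_calls) |>
    dplyr::arrange(.data$chromosome, .data$position_bp) |>
    dplyr::inner_join(dmat, by = "marker_id")
  sc$position_cM <- interpolate_cM(sc$position_bp, sc$chromosome, map)

  seg_list <- list()
  total_ll <- 0
  for (ch in unique(sc$chromosome)) {
    g <- sc[sc$chromosome == ch, ]
    E <- .emission_loglik(g$call, as.matrix(g[, usable, drop = FALSE]),
                          params$epsilon)
    dec <- .hmm_decode(E, g$position_cM, params)
    total_ll <- total_ll + dec$loglik
    # contiguous runs of one state
    runs <- rle(dec$path)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    for (r in seq_along(runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]
      start_bp <- if (i0 == 1) g$position_bp[1] else
        floor((g$position_bp[i0 - 1] + g$position_bp[i0]) / 2)
      end_bp <- if (i1 == nrow(g)) g$position_bp[nrow(g)] else
        floor((g$position_bp[i1] + g$position_bp[i1 + 1]) / 2)
      # per-donor emission loglik within the segment
      seg_ll <- colSums(E[i0:i1, , drop = FALSE])
      best <- max(seg_ll)
      group <- usable[seg_ll >= best - params$margin_delta]
      grp_post <- mean(rowSums(dec$posterior[i0:i1, usable %in% group,
                                             drop = FALSE]))
      seg_list[[length(seg_list) + 1]] <- tibble::tibble(
        chromosome = ch,
        start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
        donor = usable[runs$values[r]],
        donor_group = paste(sort(group), collapse = "|"),
        n_markers = i1 - i0 + 1L,
        mean_posterior = grp_post
      )
    }
  }
  structure(
    list(segments = dplyr::bind_rows(seg_list), loglik = total_ll,
         donors = usable, params = params),
    class = "ancestry_mosaic"
  )
}

#' @export
print.ancestry_mosaic <- function(x, ...) {
  cat("<ancestry_mosaic>", nrow(x$segments), "segment(s) over",
      length(x$donors), "donor(s)\n")
  print(x$segments)
  invisible(x)
}

#' Marker-level donor posteriors
#'
#' Forward-backward posterior probability of each donor at each marker.
#'
#' @inheritParams viterbi_mosaic
#' @return tibble: `chromosome`, `marker_id`, `position_bp`, one column
#'   per donor; rows sum to 1.
#' @export
ancestry_posteriors <- function(sample_calls, donors, map,
                                params = hmm_params()) {
  dmat <- tidyr::pivot_wider(donors, id_cols = "marker_id",
                             names_from = "donor", values_from = "call",
                             values_fill = "N")
  usable <- names(dmat)[-1][vapply(dmat[-1], function(v) any(v != "N"), logical(1))]
  if (length(usable) < 2) abort("need at least two usable donors")
  sc <- tibble::as_tibble(sample_calls) |>
    dplyr::arrange(.data$chromosome, .data$position_bp) |>
    dplyr::inner_join(dmat, by = "marker_id")
  sc$position_cM <- interpolate_cM(sc$position_bp, sc$chromosome, map)
  out <- list()
  for (ch in unique(sc$chromosome)) {
    g <- sc[sc$chromosome == ch, ]
    E <- .emission_loglik(g$call, as.matrix(g[, usable, drop = FALSE]),
                          params$epsilon)
    dec <- .hmm_decode(E, g$position_cM, params)
    p <- tibble::as_tibble(as.data.frame(dec$posterior))
    names(p) <- usable
    out[[length(out) + 1]] <- dplyr::bind_cols(
      tibble::tibble(chromosome = ch, marker_id = g$marker_id,
                     position_bp = g$position_bp), p)
  }
  dplyr::bind_rows(out)
}
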