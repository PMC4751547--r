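#' Enumerate founder genotype states
#'
#' For `n_founders` inbred founder haplotypes there are `n_founders`
#' homozygous states plus `choose(n_founders, 2)` unordered heterozygous
#' combinations (phase ignored): 36 states for 8 founders.
#'
#' @param n_founders number of founder strains (>= 2).
#' @return tibble with columns `founder_1`, `founder_2` (indices,
#'   `founder_1 <= founder_2`) and `zygosity`.
#' @export
founder_states <- function(n_founders) {
  stopifnot(n_founders >= 2)
  idx <- .state_pairs(n_founders)
  tibble::tibble(
    founder_1 = as.integer(idx[, 1]),
    founder_2 = as.integer(idx[, 2]),
    zygosity = ifelse(idx[, 1] == idx[, 2], "hom", "het")
  )
}

# memoized state-pair index matrix (hom pairs on the diagonal, het above);
# window_score is called in tight loops, so this must stay allocation-light
.state_pairs_cache <- new.env(parent = emptyenv())
.state_pairs <- function(n_f) {
  key <- as.character(n_f)
  v <- .state_pairs_cache[[key]]
  if (is.null(v)) {
    v <- which(upper.tri(diag(n_f), diag = TRUE), arr.ind = TRUE)
    .state_pairs_cache[[key]] <- v
  }
  v
}

# connected components of the wildcard-consistency graph over state vectors;
# rows of G are per-state window genotypes in {0,1,2,NA}
.consistency_components <- function(G) {
  n <- nrow(G)
  comp <- seq_len(n)
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      consistent <- all(G[a, ] == G[b, ], na.rm = TRUE)
      if (consistent) {
        old <- comp[b]
        comp[comp == old] <- comp[a]
      }
    }
  }
  length(unique(comp))
}

#' Score a window of candidate SNPs by founder-state discrimination
#'
#' The window scoring function `f` counts the number of founder genotype
#' states (homozygous founder states plus unordered heterozygous
#' combinations; 36 states for 8 founders) that can be distinguished from
#' the joint unordered genotype vector over the SNPs of the window. A
#' monomorphic window scores 1; the maximum is
#' `n_founders + choose(n_founders, 2)`.
#'
#' Missing founder alleles act as wildcards: a state vector containing a
#' wildcard collides with every vector it is consistent with (conservative
#' scoring via connected components of the consistency graph).
#'
#' @param founder_alleles matrix of founder alleles for the window,
#'   `n_founders` rows x `window_size` columns, coded 0/1 (`NA` = missing).
#' @return integer: number of distinguishable states.
#' @export
window_score <- function(founder_alleles) {
  fa <- founder_alleles
  if (!is.matrix(fa)) fa <- as.matrix(fa)
  n_f <- nrow(fa)
  w <- ncol(fa)
  stopifnot(n_f >= 2, w >= 1)
  st <- .state_pairs(n_f)
  G <- fa[st[, 1], , drop = FALSE] + fa[st[, 2], , drop = FALSE]
  if (!anyNA(G)) {
    codes <- c(G %*% 3^(seq_len(w) - 1))
    return(length(unique(codes)))
  }
  .consistency_components(G)
}

#' Filter candidate SNPs for assayability
#'
#' Retains candidates that are assayable with a single bead (not `[A/T]` or
#' `[C/G]`), have unique flanking sequence, and lie at least
#' `min_neighbor_bp` from the nearest adjacent variant. The neighbor
#' distance is taken from a `min_dist_to_neighbor_bp` column when present,
#' otherwise computed from adjacent positions within each chromosome.
#'
#' @param variants tibble of candidates sorted by position within
#'   chromosome, with `chromosome`, `position_bp`, either
#'   `is_single_bead` or `allele_ref`/`allele_alt`, and optionally
#'   `flank_unique`, `min_dist_to_neighbor_bp`.
#' @param min_neighbor_bp minimum distance to the nearest adjacent variant
#'   (default 50 bp).
#' @return tibble: the retained subset, input order preserved.
#' @export
filter_candidates <- function(variants, min_neighbor_bp = 50) {
  v <- tibble::as_tibble(variants)
  by_chr <- if ("chromosome" %in% names(v)) v$chromosome else rep("1", nrow(v))
  for (chr in unique(by_chr)) {
    if (is.unsorted(v$position_bp[by_chr == chr])) {
      abort("candidates must be sorted by position within chromosome")
    }
  }
  single <- if ("is_single_bead" %in% names(v)) {
    v$is_single_bead
  } else {
    .is_single_bead(v$allele_ref, v$allele_alt)
  }
  flank <- if ("flank_unique" %in% names(v)) v$flank_unique else rep(TRUE, nrow(v))
  if ("min_dist_to_neighbor_bp" %in% names(v)) {
    dist <- v$min_dist_to_neighbor_bp
  } else {
    dist <- rep(Inf, nrow(v))
    for (chr in unique(by_chr)) {
      i <- which(by_chr == chr)
      if (length(i) > 1) {
        gaps <- diff(v$position_bp[i])
        dist[i] <- pmin(c(Inf, gaps), c(gaps, Inf))
      }
    }
  }
  v[single & flank & dist >= min_neighbor_bp, ]
}

#' Partition a chromosome into uniform genetic-map intervals
#'
#' Divides the candidate span into `n` intervals of uniform cM size such
#' that every interval contains at least one candidate. If `n` is
#' infeasible it is decremented until feasible (intervals stay uniform in
#' cM); an error is raised if no feasible value `>= min_n` exists.
#' Intervals are half-open `[lo, hi)`; the last interval is closed.
#'
#' @param candidates tibble with a `position_cM` column.
#' @param n requested number of intervals.
#' @param min_n smallest acceptable number of intervals (typically the
#'   window size; default 1).
#' @return tibble with `interval`, `lo_cM`, `hi_cM`, `n_candidates`.
#' @export
partition_intervals <- function(candidates, n, min_n = 1) {
  cm <- candidates$position_cM
  if (length(cm) == 0) abort("no candidates")
  if (n < min_n) abort("n must be >= min_n")
  lo <- min(cm); hi <- max(cm)
  for (n_try in seq(n, min_n)) {
    br <- seq(lo, hi, length.out = n_try + 1)
    idx <- .interval_index(cm, br)
    counts <- tabulate(idx, nbins = n_try)
    if (all(counts > 0)) {
      return(tibble::tibble(
        interval = seq_len(n_try),
        lo_cM = br[-length(br)],
        hi_cM = br[-1],
        n_candidates = counts
      ))
    }
  }
  abort("no feasible interval partition with n' >= min_n")
}

# assign positions to intervals given breakpoints; [lo, hi) except last closed
.interval_index <- function(cm, br) {
  n <- length(br) - 1
  idx <- findInterval(cm, br, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), n)
}

#' Beam-search selection of one SNP per interval
#'
#' Selects one candidate SNP per genetic-map interval along a chromosome to
#' maximize the sum of the window score `f` over all complete sliding
#' windows of `window_size` consecutive chosen SNPs. A path is one chosen
#' SNP per interval; paths are extended interval by interval, the new
#' window's score is added, and the path set is pruned to the
#' `beam_width` highest-scoring paths at each step (ties kept in insertion
#' order). The reported selection is the traceback of the best final path.
#' With a beam at least as wide as the number of distinct paths the result
#' is the exhaustive optimum.
#'
#' @param candidates tibble with `marker_id`, `position_cM` (sorted by cM).
#' @param founder_alleles matrix `n_founders` x `n_candidates` of 0/1/NA
#'   founder alleles, columns aligned with (and named by) `candidates$marker_id`.
#' @param n_intervals requested number of intervals for this chromosome.
#' @param window_size sliding-window length (default 5).
#' @param beam_width number of paths retained at each step (default 1e5).
#' @param dedup_suffix if `TRUE`, keep only the best-scoring path per
#'   distinct `(window_size - 1)`-suffix before pruning (default `FALSE`).
#' @return list with `selected` (tibble of chosen candidates, one per
#'   interval, with `interval`), `score` (total path score), and
#'   `intervals` (the partition used).
#' @export
beam_select <- function(candidates, founder_alleles, n_intervals,
                        window_size = 5, beam_width = 1e5,
                        dedup_suffix = FALSE) {
  stopifnot(beam_width >= 1, window_size >= 1)
  if (is.unsorted(candidates$position_cM)) abort("candidates must be sorted by position_cM")
  fa <- as.matrix(founder_alleles)
  if (is.null(colnames(fa))) colnames(fa) <- candidates$marker_id
  fa <- fa[, candidates$marker_id, drop = FALSE]

  part <- partition_intervals(candidates, n_intervals, min_n = window_size)
  n_iv <- nrow(part)
  br <- c(part$lo_cM, part$hi_cM[n_iv])
  iv_of <- .interval_index(candidates$position_cM, br)
  slots <- split(seq_len(nrow(candidates)), iv_of)
  if (length(slots) != n_iv || any(lengths(slots) == 0)) abort("empty interval")

  memo <- new.env(parent = emptyenv())
  score_window <- function(cols) {
    key <- paste(cols, collapse = ",")
    s <- memo[[key]]
    if (is.null(s)) {
      s <- window_score(fa[, cols, drop = FALSE])
      memo[[key]] <- s
    }
    s
  }

  # beam: paths as an n_paths x i matrix of candidate row indices
  paths <- matrix(slots[[1]], ncol = 1)
  scores <- numeric(nrow(paths))
  for (i in seq(2, n_iv)) {
    cand <- slots[[i]]
    n_p <- nrow(paths)
    n_c <- length(cand)
    new_paths <- cbind(paths[rep(seq_len(n_p), each = n_c), , drop = FALSE],
                       rep(cand, times = n_p))
    new_scores <- rep(scores, each = n_c)
    if (i >= window_size) {
      win_cols <- new_paths[, seq(i - window_size + 1, i), drop = FALSE]
      keys <- apply(win_cols, 1, paste, collapse = ",")
      uk <- !duplicated(keys)
      ws <- vapply(which(uk), function(r) score_window(win_cols[r, ]), numeric(1))
      names(ws) <- keys[uk]
      new_scores <- new_scores + ws[keys]
    }
    if (dedup_suffix && i >= window_size) {
      suf <- apply(new_paths[, seq(max(1, i - window_size + 2), i), drop = FALSE],
                   1, paste, collapse = ",")
      ord <- order(-new_scores)
      keep <- ord[!duplicated(suf[ord])]
      new_paths <- new_paths[keep, , drop = FALSE]
      new_scores <- new_scores[keep]
    }
    if (nrow(new_paths) > beam_width) {
      keep <- order(-new_scores)[seq_len(beam_width)]
      keep <- sort(keep)  # ties kept in insertion order
      keep <- keep[order(-new_scores[keep])]
      new_paths <- new_paths[keep, , drop = FALSE]
      new_scores <- new_scores[keep]
    }
    paths <- new_paths
    scores <- new_scores
  }
  best <- which.max(scores)
  sel_idx <- paths[best, ]
  selected <- candidates[sel_idx, ]
  selected$interval <- seq_len(n_iv)
  list(selected = tibble::as_tibble(selected),
       score = unname(scores[best]),
       intervals = part)
}

#' Select a locally informative SNP window near a recombination hotspot
#'
#' Among all runs of `window_size` consecutive candidates whose span
#' overlaps the central region of the hotspot, returns the run maximizing
#' [window_score()]. Ties are broken by smaller bp span, then by proximity
#' of the run midpoint to the hotspot center. If no run overlaps the
#' center, the best run nearest the center is returned flagged
#' `off_center`.
#'
#' @param candidates tibble with `marker_id`, `position_bp`, sorted by
#'   position.
#' @param founder_alleles matrix `n_founders` x `n_candidates` (columns
#'   named by marker id).
#' @param center_start,center_end bp bounds of the central hotspot region
#'   (typically 100 bp wide).
#' @param window_size run length (default 4).
#' @return list with `selected` (tibble of the chosen run), `score`,
#'   `off_center` (logical).
#' @export
hotspot_select <- function(candidates, founder_alleles,
                           center_start, center_end, window_size = 4) {
  n <- nrow(candidates)
  if (n < window_size) abort("fewer candidates than window_size")
  if (is.unsorted(candidates$position_bp)) abort("candidates must be sorted by position_bp")
  fa <- as.matrix(founder_alleles)
  if (is.null(colnames(fa))) colnames(fa) <- candidates$marker_id
  center_mid <- (center_start + center_end) / 2
  runs <- tibble::tibble(start = seq_len(n - window_size + 1)) |>
    dplyr::mutate(
      end = .data$start + window_size - 1,
      span_lo = candidates$position_bp[.data$start],
      span_hi = candidates$position_bp[.data$end],
      span = .data$span_hi - .data$span_lo,
      overlaps = .data$span_lo <= center_end & .data$span_hi >= center_start,
      center_dist = abs((.data$span_lo + .data$span_hi) / 2 - center_mid)
    )
  runs$score <- vapply(seq_len(nrow(runs)), function(r) {
    cols <- candidates$marker_id[seq(runs$start[r], runs$end[r])]
    window_score(fa[, cols, drop = FALSE])
  }, numeric(1))
  pool <- if (any(runs$overlaps)) runs[runs$overlaps, ] else runs
  pool <- pool[order(-pool$score, pool$span, pool$center_dist), ]
  best <- pool[1, ]
  list(
    selected = candidates[seq(best$start, best$end), ],
    score = best$score,
    off_center = !any(runs$overlaps)
  )
}

#' Select markers to cover the genome uniformly
#'
#' Greedy gap-filling: repeatedly pick the candidate closest to the
#' midpoint of the largest uncovered gap (gaps are measured between
#' already-selected positions and the chromosome ends) until `k` markers
#' are selected. With multiple chromosomes the largest gap over all
#' chromosomes is filled at each step.
#'
#' @param candidates tibble with `chromosome`, `position_bp`.
#' @param k number of markers to select (`0 < k <= nrow(candidates)`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp);
#'   defaults to the maximum candidate position per chromosome.
#' @return tibble: selected subset, sorted by chromosome and position.
#' @export
select_uniform_spacing <- function(candidates, k, chrom_lengths = NULL) {
  if (k <= 0) abort("k must be positive")
  if (k > nrow(candidates)) abort("k exceeds the number of candidates")
  v <- tibble::as_tibble(candidates)
  if (!"chromosome" %in% names(v)) v$chromosome <- "1"
  chrs <- unique(v$chromosome)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chrs, function(ch) max(v$position_bp[v$chromosome == ch]),
                            numeric(1))
  }
  selected <- integer(0)
  avail <- rep(TRUE, nrow(v))
  for (step in seq_len(k)) {
    # find largest gap over all chromosomes
    gap_best <- NULL
    for (ch in chrs) {
      sel_pos <- sort(v$position_bp[selected][v$chromosome[selected] == ch])
      bounds <- c(0, sel_pos, chrom_lengths[[ch]])
      gaps <- diff(bounds)
      gi <- which.max(gaps)
      if (is.null(gap_best) || gaps[gi] > gap_best$len) {
        gap_best <- list(len = gaps[gi], mid = (bounds[gi] + bounds[gi + 1]) / 2,
                         chr = ch)
      }
    }
    cand_i <- which(avail & v$chromosome == gap_best$chr)
    if (length(cand_i) == 0) cand_i <- which(avail)
    pick <- cand_i[which.min(abs(v$position_bp[cand_i] - gap_best$mid))]
    selected <- c(selected, pick)
    avail[pick] <- FALSE
  }
  out <- v[sort(selected), ]
  dplyr::arrange(out, .data$chromosome, .data$position_bp)
}

#' Place novel wild-ascertained SNPs on a 1-Mb grid
#'
#' Per 1-Mb window, attempts to pick three novel SNPs: one transition from
#' each 500-kb half, and one transversion from the middle 333 kb. Within
#' each slot candidates are ranked by MAF (descending), ties broken by a
#' seeded random draw. A pick closer than `min_spacing_bp` to a previous
#' pick on the same chromosome is taken only when no compliant candidate
#' exists in its slot, and is flagged.
#'
#' @param novel tibble with `chromosome`, `position_bp`, `is_transition`,
#'   `maf` (and optionally `marker_id`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_bp tiling window size (default 1e6).
#' @param min_spacing_bp minimum spacing between picks (default 1e5).
#' @param seed integer seed for tie-breaking draws.
#' @return tibble of picks with `window`, `slot` (`transition_1`,
#'   `transversion_mid`, `transition_2`) and `spacing_violation`.
#' @export
place_wild_snps <- function(novel, chrom_lengths = NULL, window_bp = 1e6,
                            min_spacing_bp = 1e5, seed = 20151218) {
  v <- tibble::as_tibble(novel)
  if (!"chromosome" %in% names(v)) v$chromosome <- "1"
  set.seed(seed)
  v$tiebreak <- runif(nrow(v))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(unique(v$chromosome),
                            function(ch) max(v$position_bp[v$chromosome == ch]),
                            numeric(1))
  }
  picks <- list()
  for (ch in names(chrom_lengths)) {
    vc <- v[v$chromosome == ch, ]
    placed_pos <- numeric(0)
    n_win <- ceiling(chrom_lengths[[ch]] / window_bp)
    for (wi in seq_len(n_win)) {
      w0 <- (wi - 1) * window_bp
      off <- vc$position_bp - w0
      in_win <- off >= 0 & off < window_bp
      slots <- list(
        transition_1 = in_win & vc$is_transition & off < window_bp / 2,
        transversion_mid = in_win & !vc$is_transition &
          off >= window_bp / 3 & off < 2 * window_bp / 3,
        transition_2 = in_win & vc$is_transition & off >= window_bp / 2
      )
      for (slot in names(slots)) {
        pool <- vc[slots[[slot]], ]
        pool <- pool[!pool$position_bp %in% placed_pos, ]
        if (nrow(pool) == 0) next
        pool <- pool[order(-pool$maf, pool$tiebreak), ]
        compliant <- vapply(pool$position_bp, function(p) {
          length(placed_pos) == 0 || min(abs(placed_pos - p)) >= min_spacing_bp
        }, logical(1))
        if (any(compliant)) {
          hit <- pool[which(compliant)[1], ]
          viol <- FALSE
        } else {
          hit <- pool[1, ]
          viol <- TRUE
        }
        hit$window <- wi
        hit$slot <- slot
        hit$spacing_violation <- viol
        placed_pos <- c(placed_pos, hit$position_bp)
        picks[[length(picks) + 1]] <- hit
      }
    }
  }
  out <- dplyr::bind_rows(picks)
  if (nrow(out) > 0) out$tiebreak <- NULL
  out
}
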