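#' Read a marker manifest
#'
#' The manifest is a CSV with one row per array probe. Required columns:
#' `marker_id`, `chromosome`, `position_bp`, `allele_ref`, `allele_alt`.
#' Optional columns (`position_cM`, `probe_type`, `tier`, `diagnostic_for`)
#' are carried through when present. Chromosome labels are normalized with
#' [normalize_chrom()]; coordinates are 1-based.
#'
#' @param path path to a manifest CSV.
#' @return tibble with one row per marker.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(m) <- tolower(names(m))
  need <- c("marker_id", "chromosome", "position_bp", "allele_ref", "allele_alt")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) {
    abort(paste0("manifest is missing column(s): ", paste(miss, collapse = ", ")))
  }
  m <- dplyr::mutate(m,
    chromosome = normalize_chrom(.data$chromosome),
    position_bp = as.integer(.data$position_bp)
  )
  if (any(m$position_bp < 1, na.rm = TRUE)) abort("position_bp must be >= 1")
  tibble::as_tibble(m)
}

#' Write a marker manifest
#'
#' @param manifest tibble as returned by [read_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' A genetic map is a TSV with columns `chromosome`, `position_bp`,
#' `position_cM` giving anchor points per chromosome. Within a chromosome
#' base-pair positions must be strictly increasing and cM positions
#' nondecreasing.
#'
#' @param path path to the TSV.
#' @return tibble sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  gm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(gm) <- tolower(names(gm))
  names(gm)[names(gm) == "position_cm"] <- "position_cM"
  need <- c("chromosome", "position_bp", "position_cM")
  miss <- setdiff(need, names(gm))
  if (length(miss) > 0) {
    abort(paste0("genetic map is missing column(s): ", paste(miss, collapse = ", ")))
  }
  gm <- gm |>
    dplyr::mutate(chromosome = normalize_chrom(.data$chromosome)) |>
    dplyr::arrange(.data$chromosome, .data$position_bp)
  validate_genetic_map(gm)
  gm
}

#' Validate a genetic map
#'
#' @param map tibble with `chromosome`, `position_bp`, `position_cM`.
#' @return `map`, invisibly; errors on violated invariants.
#' @export
validate_genetic_map <- function(map) {
  by_chr <- split(map, map$chromosome)
  for (chr in names(by_chr)) {
    bp <- by_chr[[chr]]$position_bp
    cm <- by_chr[[chr]]$position_cM
    if (is.unsorted(bp, strictly = TRUE)) {
      abort(paste0("genetic map: position_bp not strictly increasing on chromosome ", chr))
    }
    if (is.unsorted(cm)) {
      abort(paste0("genetic map: position_cM not nondecreasing on chromosome ", chr))
    }
  }
  invisible(map)
}

#' Interpolate genetic-map position
#'
#' Linear interpolation of cM position between flanking map anchors.
#' Queries outside the anchor range are extrapolated with the slope of the
#' nearest terminal segment and floored at 0 cM.
#'
#' @param position_bp integer vector of physical positions (1-based).
#' @param chromosome chromosome label (single value or vector matching
#'   `position_bp`).
#' @param map genetic map tibble (see [read_genetic_map()]).
#' @return numeric vector of cM positions.
#' @export
interpolate_cM <- function(position_bp, chromosome, map) {
  chromosome <- normalize_chrom(chromosome)
  if (length(chromosome) == 1) chromosome <- rep(chromosome, length(position_bp))
  stopifnot(length(chromosome) == length(position_bp))
  out <- numeric(length(position_bp))
  for (chr in unique(chromosome)) {
    anchors <- map[map$chromosome == chr, ]
    if (nrow(anchors) < 2) {
      abort(paste0("chromosome ", chr, " absent from map (or has < 2 anchors)"))
    }
    idx <- which(chromosome == chr)
    bp <- anchors$position_bp
    cm <- anchors$position_cM
    n <- length(bp)
    x <- position_bp[idx]
    y <- approx(bp, cm, xout = x, rule = 1, ties = "ordered")$y
    # terminal-slope extrapolation, floored at 0
    lo <- x < bp[1]
    hi <- x > bp[n]
    if (any(lo)) {
      s <- (cm[2] - cm[1]) / (bp[2] - bp[1])
      y[lo] <- cm[1] + s * (x[lo] - bp[1])
    }
    if (any(hi)) {
      s <- (cm[n] - cm[n - 1]) / (bp[n] - bp[n - 1])
      y[hi] <- cm[n] + s * (x[hi] - bp[n])
    }
    out[idx] <- pmax(y, 0)
  }
  out
}

# recode one (a1, a2) allele pair against (ref, alt); order-insensitive
.recode_call <- function(a1, a2, ref, alt) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  missing_tok <- c("-", "N", "", NA)
  out <- rep(NA_character_, length(a1))
  is_miss <- a1 %in% missing_tok | a2 %in% missing_tok
  out[is_miss] <- "N"
  ok <- !is_miss
  hom_ref <- ok & a1 == ref & a2 == ref
  hom_alt <- ok & a1 == alt & a2 == alt
  het <- ok & ((a1 == ref & a2 == alt) | (a1 == alt & a2 == ref))
  out[hom_ref] <- "AA"
  out[hom_alt] <- "BB"
  out[het] <- "AB"
  # anything else (allele off-manifest) -> N, counted by the caller
  bad <- ok & is.na(out)
  out[bad] <- "N"
  attr(out, "n_bad_allele") <- sum(bad)
  out
}

#' Read a FinalReport-style genotype/intensity table
#'
#' Reads the tab-separated per-(sample, marker) export produced by Illumina
#' BeadStudio-style software. Column names are matched case-insensitively;
#' the reader needs at minimum a sample id, a marker id, two allele columns,
#' and `X`/`Y` normalized intensities; `X Raw`/`Y Raw` are used when present
#' (otherwise the normalized values are copied into the raw layer). A leading
#' `[Header]` block is skipped if a `[Data]` line is present.
#'
#' Calls are recoded to `AA`/`AB`/`BB`/`N` against the manifest alleles;
#' the recoding is symmetric in allele order, the tokens `-`, `N` and empty
#' map to `N`, and alleles not matching the manifest are set to `N` and
#' counted. Rows for markers absent from the manifest are dropped with a
#' warning count.
#'
#' @param path path to the TSV file.
#' @param manifest marker manifest tibble (see [read_manifest()]).
#' @return list with elements `genotypes` (tibble: `sample_id`, `marker_id`,
#'   `call`), `intensities` (tibble: `sample_id`, `marker_id`, `x_raw`,
#'   `y_raw`, `x`, `y`), `n_unknown_markers`, `n_bad_alleles`.
#' @export
read_finalreport <- function(path, manifest) {
  first <- readr::read_lines(path, n_max = 20)
  skip <- 0L
  data_line <- which(trimws(first) == "[Data]")
  if (length(data_line) > 0) skip <- data_line[1]
  raw <- readr::read_tsv(path, skip = skip, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("malformed FinalReport row at line ", prob$row[1] + skip + 1L,
                 ": ", prob$expected[1]))
  }
  nm <- tolower(names(raw))
  pick <- function(patterns, what) {
    for (p in patterns) {
      hit <- which(grepl(p, nm))
      if (length(hit) > 0) return(hit[1])
    }
    abort(paste0("FinalReport: no column matching ", what))
  }
  i_sample <- pick(c("^sample[ _]?id$", "sample"), "sample id")
  i_marker <- pick(c("^snp[ _]?name$", "^marker", "snp"), "marker id")
  i_alleles <- which(grepl("allele", nm))
  if (length(i_alleles) < 2) abort("FinalReport: need two allele columns")
  i_alleles <- i_alleles[1:2]
  i_x <- pick(c("^x$", "^x[ _]norm"), "X intensity")
  i_y <- pick(c("^y$", "^y[ _]norm"), "Y intensity")
  i_xr <- which(grepl("^x[ _]?raw$", nm))
  i_yr <- which(grepl("^y[ _]?raw$", nm))

  d <- tibble::tibble(
    sample_id = as.character(raw[[i_sample]]),
    marker_id = as.character(raw[[i_marker]]),
    a1 = as.character(raw[[i_alleles[1]]]),
    a2 = as.character(raw[[i_alleles[2]]]),
    x = as.numeric(raw[[i_x]]),
    y = as.numeric(raw[[i_y]]),
    x_raw = if (length(i_xr) > 0) as.numeric(raw[[i_xr[1]]]) else as.numeric(raw[[i_x]]),
    y_raw = if (length(i_yr) > 0) as.numeric(raw[[i_yr[1]]]) else as.numeric(raw[[i_y]])
  )

  known <- d$marker_id %in% manifest$marker_id
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " row(s) for markers absent from manifest were dropped"))
    d <- d[known, ]
  }
  d <- dplyr::left_join(
    d,
    dplyr::select(manifest, "marker_id", "allele_ref", "allele_alt"),
    by = "marker_id"
  )
  call <- .recode_call(d$a1, d$a2, toupper(d$allele_ref), toupper(d$allele_alt))
  n_bad <- attr(call, "n_bad_allele")
  if (n_bad > 0) warn(paste0(n_bad, " call(s) with alleles off the manifest set to N"))
  list(
    genotypes = tibble::tibble(sample_id = d$sample_id, marker_id = d$marker_id,
                               call = as.character(call)),
    intensities = tibble::tibble(sample_id = d$sample_id, marker_id = d$marker_id,
                                 x_raw = d$x_raw, y_raw = d$y_raw, x = d$x, y = d$y),
    n_unknown_markers = n_unknown,
    n_bad_alleles = n_bad
  )
}

#' Pivot long genotype calls to a marker x sample matrix
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @return character matrix, rows = markers, columns = samples; cells in
#'   `{AA, AB, BB, N}` (missing combinations become `N`).
#' @export
calls_matrix <- function(genotypes) {
  wide <- tidyr::pivot_wider(genotypes, id_cols = "marker_id",
                             names_from = "sample_id", values_from = "call",
                             values_fill = "N")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$marker_id
  m
}

#' Write a FinalReport-style table
#'
#' Inverse of [read_finalreport()]: one tab-separated row per
#' (sample, marker) with allele calls decoded against the manifest.
#'
#' @param genotypes tibble with `sample_id`, `marker_id`, `call`.
#' @param intensities tibble with `sample_id`, `marker_id`, `x_raw`, `y_raw`,
#'   `x`, `y` (aligned with `genotypes`).
#' @param manifest marker manifest tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_finalreport <- function(genotypes, intensities, manifest, path) {
  d <- dplyr::inner_join(genotypes, intensities, by = c("sample_id", "marker_id")) |>
    dplyr::left_join(dplyr::select(manifest, "marker_id", "allele_ref", "allele_alt"),
                     by = "marker_id")
  a1 <- dplyr::case_when(
    d$call == "AA" ~ d$allele_ref,
    d$call == "BB" ~ d$allele_alt,
    d$call == "AB" ~ d$allele_ref,
    TRUE ~ "-"
  )
  a2 <- dplyr::case_when(
    d$call == "AA" ~ d$allele_ref,
    d$call == "BB" ~ d$allele_alt,
    d$call == "AB" ~ d$allele_alt,
    TRUE ~ "-"
  )
  out <- tibble::tibble(
    `Sample ID` = d$sample_id, `SNP Name` = d$marker_id,
    `Allele1 - Forward` = a1, `Allele2 - Forward` = a2,
    `X Raw` = d$x_raw, `Y Raw` = d$y_raw, X = d$x, Y = d$y
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write regions to BED
#'
#' Input coordinates are 1-based inclusive; BED output is 0-based half-open.
#'
#' @param regions tibble with `chromosome`, `start_bp`, `end_bp` and
#'   optionally `name` (and `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chromosome", "start_bp", "end_bp") %in% names(regions)))
  lines <- paste(
    regions$chromosome,
    format(regions$start_bp - 1L, scientific = FALSE, trim = TRUE),
    format(regions$end_bp, scientific = FALSE, trim = TRUE),
    if ("name" %in% names(regions)) regions$name else ".",
    sep = "\t"
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive coordinates
#'
#' @param path BED path (0-based half-open on disk).
#' @return tibble with `chromosome`, `start_bp`, `end_bp`, `name`.
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    chromosome = normalize_chrom(b[[1]]),
    start_bp = as.integer(b[[2]]) + 1L,
    end_bp = as.integer(b[[3]]),
    name = if (ncol(b) >= 4) as.character(b[[4]]) else NA_character_
  )
}

#' Write a relaxed PHYLIP character matrix
#'
#' All sequences must be the same length over the `{A, C, G, T}` alphabet.
#' Writes the standard "n_samples n_chars" header followed by one
#' `name<whitespace>sequence` row per sample (relaxed names, no 10-character
#' limit).
#'
#' @param chars named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(chars, path) {
  if (length(chars) == 0) abort("no sequences to write")
  if (is.null(names(chars)) || any(names(chars) == "")) {
    abort("sequences must be named")
  }
  lens <- nchar(chars)
  if (length(unique(lens)) != 1) abort("ragged sequence lengths")
  if (any(grepl("[^ACGT]", chars))) abort("alphabet must be {A,C,G,T}")
  lines <- c(
    paste(length(chars), lens[1]),
    paste(format(names(chars), width = max(nchar(names(chars))) + 2), chars)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a relaxed PHYLIP character matrix
#'
#' @param path path written by [write_phylip_matrix()].
#' @return named character vector of sequences.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != hdr[1]) abort("PHYLIP body/header mismatch")
  parts <- strsplit(trimws(body), "\\s+")
  seqs <- vapply(parts, function(p) p[length(p)], character(1))
  names(seqs) <- vapply(parts, function(p) paste(p[-length(p)], collapse = " "), character(1))
  if (any(nchar(seqs) != hdr[2])) abort("PHYLIP sequence length mismatch")
  seqs
}

#' Write sequences to FASTA
#'
#' @param chars named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chars, path) {
  if (length(chars) == 0) abort("no sequences to write")
  lines <- as.vector(rbind(paste0(">", names(chars)), unname(chars)))
  readr::write_lines(lines, path)
  invisible(path)
}
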