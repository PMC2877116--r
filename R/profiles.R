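#' Build one PSSM per row of a family alignment
#'
#' Multiple-profile strategy: every sequence of the family MSA serves once
#' as the reference, which widens the search space and removes the bias a
#' single arbitrarily chosen reference would introduce.  For each row, the
#' columns gapped in that row are dropped; at each remaining column the
#' score of amino acid `a` is
#' `2 * log2((count_a + pseudocount * bg_a) / ((n + pseudocount) * bg_a))`
#' in half-bit units, where `count_a` is the number of rows carrying `a`
#' in the column, `n` the number of residues observed in the column, and
#' `bg_a` the background frequency.
#'
#' @param msa A `kin_msa` with at least 2 rows.
#' @param pseudocount Pseudocount mass added per column (default 1).
#' @param background Named background frequency vector over the 20 amino
#'   acids (defaults to standard database residue frequencies).
#' @return A list of `profile_matrix` objects, one per MSA row, each with
#'   `reference_id`, `length`, `scores` (length x 20 matrix) and
#'   `background`.
#' @export
build_pssms <- function(msa, pseudocount = 1, background = aa_background()) {
  mat <- msa_matrix(msa)
  if (nrow(mat) < 2L) stop("profile building needs at least 2 rows", call. = FALSE)
  stopifnot(pseudocount > 0)
  background <- background[AA_ALPHABET] / sum(background[AA_ALPHABET])
  # per-column residue counts over the whole alignment (X and gaps excluded)
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    as.integer(table(factor(col, levels = AA_ALPHABET)))
  }, integer(length(AA_ALPHABET)))
  rownames(counts) <- AA_ALPHABET
  nres <- colSums(counts)

  lapply(rownames(mat), function(id) {
    keep <- mat[id, ] != "-"
    if (!any(keep)) stop("row entirely gapped: ", id, call. = FALSE)
    cn <- counts[, keep, drop = FALSE]
    nn <- nres[keep]
    scores <- matrix(0, sum(keep), length(AA_ALPHABET),
                     dimnames = list(NULL, AA_ALPHABET))
    for (aa in AA_ALPHABET) {
      scores[, aa] <- 2 * log2((cn[aa, ] + pseudocount * background[[aa]]) /
                                 ((nn + pseudocount) * background[[aa]]))
    }
    structure(list(reference_id = id, length = sum(keep),
                   scores = scores, background = background),
              class = "profile_matrix")
  })
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("PSSM: reference %s, %d positions\n", x$reference_id, x$length))
  invisible(x)
}

# cell-score matrix of a query against a profile: rows = query residues,
# columns = profile positions; X residues score 0 everywhere.
profile_cells <- function(residues, profile) {
  chars <- strsplit(residues, "")[[1L]]
  S <- cbind(profile$scores, X = 0)   # length x 21
  codes <- match(chars, c(AA_ALPHABET, "X"))
  if (anyNA(codes))
    stop("query contains non-amino-acid characters", call. = FALSE)
  t(S)[codes, , drop = FALSE]         # n x length
}

# Gumbel right-tail probability with moment-fitted location and scale
gumbel_pvalue <- function(score, null_scores) {
  beta <- stats::sd(null_scores) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) beta <- 1e-6
  mu <- mean(null_scores) - 0.5772156649 * beta
  1 - exp(-exp(-(score - mu) / beta))
}

#' Preset hit criteria for the profile-search routes
#'
#' Three named presets mirror the identification routes the framework
#' supports: `mulpssm` (E-value at most 1e-4 and *more than* 70% of the
#' profile covered by the query — strictly greater), `hmm` (E-value at
#' most 0.01, no coverage requirement), and `psiblast` (E-value at most
#' 1e-4 and at least 70% coverage, inclusive).
#'
#' @return Named list of threshold lists (`max_evalue`,
#'   `min_profile_coverage`, `coverage_strict`).
#' @export
profile_presets <- function() {
  list(mulpssm = list(max_evalue = 1e-4, min_profile_coverage = 0.70,
                      coverage_strict = TRUE),
       hmm = list(max_evalue = 0.01, min_profile_coverage = 0,
                  coverage_strict = FALSE),
       psiblast = list(max_evalue = 1e-4, min_profile_coverage = 0.70,
                       coverage_strict = FALSE))
}

#' Scan a query sequence against a profile library
#'
#' Smith-Waterman local alignment of the query against each profile's
#' position scores (affine gaps), with an empirical extreme-value E-value:
#' the null distribution is built from Smith-Waterman scores of seeded
#' shuffles of the query against the same profile, and a Gumbel curve is
#' fitted by moments.  A hit passes when its E-value is at most
#' `max_evalue` *and* its profile coverage (matched profile columns /
#' profile length) clears `min_profile_coverage`; with
#' `coverage_strict = TRUE` the coverage test is strictly greater-than.
#' At most one (best) hit per profile is returned.
#'
#' @param query One row of a sequence table, or a single named residue
#'   string (at least 10 residues).
#' @param profiles List of `profile_matrix` objects from [build_pssms()].
#' @param max_evalue E-value cut-off (default 1e-4).
#' @param min_profile_coverage Profile-coverage cut-off (default 0.70).
#' @param null_samples Number of query shuffles for the null (at least 50;
#'   default 200).
#' @param seed Integer seed making the null reproducible.
#' @param coverage_strict Whether the coverage test is strict (`>`,
#'   default) or inclusive (`>=`).
#' @param gap_open,gap_extension Affine gap penalties in the profile score
#'   units.
#' @return Data frame of passing hits: `query_id`, `reference_id`,
#'   `score`, `evalue`, `profile_coverage`, `q_start`, `q_end`.
#' @export
scan_profiles <- function(query, profiles, max_evalue = 1e-4,
                          min_profile_coverage = 0.70, null_samples = 200L,
                          seed = 1L, coverage_strict = TRUE,
                          gap_open = 11, gap_extension = 1) {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    qid <- query$id
    residues <- query$residues
  } else {
    qid <- if (!is.null(names(query))) names(query)[1L] else "query"
    residues <- unname(query[1L])
  }
  if (length(profiles) == 0L) stop("profile library is empty", call. = FALSE)
  if (nchar(residues) < 10L)
    stop("query shorter than 10 residues", call. = FALSE)
  if (null_samples < 50L) stop("null_samples must be at least 50", call. = FALSE)

  n <- nchar(residues)
  perms <- with_seed(seed, replicate(null_samples, sample.int(n), simplify = FALSE))
  hits <- lapply(profiles, function(pr) {
    C <- profile_cells(residues, pr)
    aln <- sw_align_cpp(C, gap_open, gap_extension)
    nulls <- vapply(perms, function(p)
      sw_score_cpp(C[p, , drop = FALSE], gap_open, gap_extension), numeric(1))
    ev <- gumbel_pvalue(aln$score, nulls)
    cov <- aln$n_match / pr$length
    pass_cov <- if (coverage_strict) cov > min_profile_coverage
                else cov >= min_profile_coverage
    if (ev <= max_evalue && pass_cov && aln$score > 0) {
      data.frame(query_id = qid, reference_id = pr$reference_id,
                 score = aln$score, evalue = ev, profile_coverage = cov,
                 q_start = aln$q_start, q_end = aln$q_end,
                 stringsAsFactors = FALSE)
    } else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(query_id = character(), reference_id = character(),
                       score = numeric(), evalue = numeric(),
                       profile_coverage = numeric(), q_start = integer(),
                       q_end = integer(), stringsAsFactors = FALSE)
  hits[order(-hits$score), , drop = FALSE]
}

#' Detect kinase-domain sequences in a query set
#'
#' Applies [scan_profiles()] to every query; a query is retained when at
#' least one profile hit passes the thresholds.  Per-query seeds are
#' derived from `seed` so the result is deterministic.
#'
#' @param queries Sequence table (or named character vector).
#' @param profiles Profile library from [build_pssms()].
#' @param seed Base integer seed.
#' @param ... Thresholds forwarded to [scan_profiles()].
#' @return Data frame with one row per retained query: the query id and
#'   its best passing hit.
#' @export
detect_kinases <- function(queries, profiles, seed = 1L, ...) {
  v <- as_seq_vector(queries)
  rows <- lapply(seq_along(v), function(i) {
    h <- scan_profiles(v[i], profiles, seed = seed + i - 1L, ...)
    if (nrow(h) == 0L) return(NULL)
    h[1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), reference_id = character(),
                      score = numeric(), evalue = numeric(),
                      profile_coverage = numeric(), q_start = integer(),
                      q_end = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write a profile library as a TSV block format
#'
#' Each profile is a block: a `#profile` line with the reference id and
#' length, a `#background` line with the 20 background frequencies, then
#' one tab-separated row of 20 scores per profile position.
#'
#' @param profiles Profile library from [build_pssms()].
#' @param path Path to the profile file.
#' @return `read_profiles()` returns a profile library;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#alphabet", AA_ALPHABET), collapse = "\t"), con)
  for (pr in profiles) {
    writeLines(sprintf("#profile\t%s\t%d", pr$reference_id, pr$length), con)
    writeLines(paste(c("#background", sprintf("%.8g", pr$background)),
                     collapse = "\t"), con)
    apply(pr$scores, 1L, function(row)
      writeLines(paste(sprintf("%.8g", row), collapse = "\t"), con))
  }
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "#profile"))
  if (length(starts) == 0L) stop("no profiles in file", call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    head <- strsplit(lines[starts[k]], "\t")[[1L]]
    bg <- as.numeric(strsplit(lines[starts[k] + 1L], "\t")[[1L]][-1L])
    names(bg) <- AA_ALPHABET
    body <- lines[(starts[k] + 2L):ends[k]]
    scores <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
    colnames(scores) <- AA_ALPHABET
    structure(list(reference_id = head[2L], length = as.integer(head[3L]),
                   scores = scores, background = bg),
              class = "profile_matrix")
  })
}
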