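#' Alignment parameters
#'
#' Substitution table and affine gap penalties used by all pairwise and
#' progressive alignment in the package.  Defaults are BLOSUM62 with gap
#' open 11 and gap extension 1 (protein BLAST defaults); a gap of length k
#' costs `gap_open + k * gap_extension`.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`), or a numeric matrix
#'   with amino-acid dimnames.
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extension Gap extension penalty per position (positive).
#' @return A list with elements `submat`, `gap_open`, `gap_extension`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extension = 1) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  alpha <- c(AA_ALPHABET, "X")
  if (!all(alpha %in% rownames(matrix)))
    stop("substitution matrix must cover the 20 amino acids plus X", call. = FALSE)
  submat <- matrix[alpha, alpha]
  stopifnot(gap_open > 0, gap_extension > 0)
  list(submat = submat, gap_open = gap_open, gap_extension = gap_extension)
}

encode_residues <- function(x) {
  codes <- match(strsplit(x, "")[[1L]], c(AA_ALPHABET, "X"))
  if (anyNA(codes))
    stop("sequence contains non-amino-acid characters", call. = FALSE)
  codes
}

#' Global pairwise alignment
#'
#' Optimal Needleman-Wunsch alignment with affine gap penalties.  Identity
#' is the number of identical aligned residue pairs divided by the length
#' of the shorter input sequence (the convention inherited from greedy
#' identity clustering); coverage of a sequence is the fraction of its
#' residues aligned opposite non-gap positions of the other.  Traceback
#' ties are broken preferring diagonal, then up, then left, so results are
#' deterministic.
#'
#' @param a,b Residue strings (uppercase, 20-letter alphabet plus X).
#' @param params Alignment parameters from [align_params()].
#' @return An object of class `pairwise_alignment`: a list with
#'   `aligned_a`, `aligned_b` (equal-length gapped strings), `score`,
#'   `identity`, `coverage_a`, `coverage_b`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  check_residues(a, what = "sequence a")
  check_residues(b, what = "sequence b")
  ca <- encode_residues(a)
  cb <- encode_residues(b)
  C <- params$submat[ca, cb, drop = FALSE]
  res <- nw_core_cpp(C, params$gap_open, params$gap_extension)
  chars_a <- strsplit(a, "")[[1L]]
  chars_b <- strsplit(b, "")[[1L]]
  col_a <- ifelse(res$path_a == 0L, "-", chars_a[pmax(res$path_a, 1L)])
  col_b <- ifelse(res$path_b == 0L, "-", chars_b[pmax(res$path_b, 1L)])
  both <- res$path_a > 0L & res$path_b > 0L
  matches <- sum(both & col_a == col_b)
  aln <- list(aligned_a = paste(col_a, collapse = ""),
              aligned_b = paste(col_b, collapse = ""),
              score = res$score,
              identity = matches / min(length(ca), length(cb)),
              coverage_a = sum(both) / length(ca),
              coverage_b = sum(both) / length(cb))
  class(aln) <- "pairwise_alignment"
  aln
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.1f, identity %.3f, coverage %.3f/%.3f\n",
              x$score, x$identity, x$coverage_a, x$coverage_b))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Identical aligned residue pairs divided by the length of the shorter
#' de-gapped input sequence.
#'
#' @param aln A `pairwise_alignment`.
#' @return Fraction in \[0,1\].
#' @export
percent_identity <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1L]]
  cb <- strsplit(aln$aligned_b, "")[[1L]]
  matches <- sum(ca != "-" & cb != "-" & ca == cb)
  matches / min(sum(ca != "-"), sum(cb != "-"))
}

# frequency profile of a gapped character matrix: 21 x L (20 aa + X),
# columns normalized over non-gap residues (all-gap columns stay zero).
profile_freqs <- function(mat) {
  alpha <- c(AA_ALPHABET, "X")
  L <- ncol(mat)
  F <- matrix(0, length(alpha), L, dimnames = list(alpha, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) > 0L) {
      tab <- table(factor(col, levels = alpha))
      F[, j] <- as.numeric(tab) / length(col)
    }
  }
  F
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively along a neighbor-joining guide tree
#' built from pairwise p-distances (1 - pairwise identity).  Sub-alignments
#' are merged by profile-profile Needleman-Wunsch, scoring a column pair by
#' the expected substitution score between the two residue distributions.
#' No iterative refinement and no sequence weighting are applied; the
#' result is deterministic for a fixed input order.
#'
#' @param seqs Sequence table or named character vector (at least 2).
#' @param params Alignment parameters from [align_params()].
#' @return An object of class `kin_msa`: a named character vector of
#'   equal-length gapped rows in input order.
#' @export
progressive_msa <- function(seqs, params = align_params()) {
  v <- as_seq_vector(seqs)
  n <- length(v)
  if (n < 2L) stop("progressive alignment needs at least 2 sequences", call. = FALSE)
  if (n == 2L) {
    aln <- global_align(v[1L], v[2L], params)
    out <- c(aln$aligned_a, aln$aligned_b)
    names(out) <- names(v)
    return(structure(out, class = "kin_msa"))
  }
  # guide distances: 1 - pairwise identity
  D <- matrix(0, n, n, dimnames = list(names(v), names(v)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      pid <- global_align(v[i], v[j], params)$identity
      D[i, j] <- D[j, i] <- 1 - pid
    }
  }
  guide <- ape::nj(D)
  guide <- ape::root(guide, outgroup = names(v)[1L], resolve.root = TRUE)

  merge_profiles <- function(mat1, mat2) {
    F1 <- profile_freqs(mat1)
    F2 <- profile_freqs(mat2)
    S <- params$submat  # 21x21, alphabet order matches profile rows
    C <- t(F1) %*% S %*% F2
    res <- nw_core_cpp(C, params$gap_open, params$gap_extension)
    ncol_out <- length(res$path_a)
    out <- matrix("-", nrow(mat1) + nrow(mat2), ncol_out)
    rownames(out) <- c(rownames(mat1), rownames(mat2))
    sel1 <- res$path_a > 0L
    sel2 <- res$path_b > 0L
    out[seq_len(nrow(mat1)), sel1] <- mat1[, res$path_a[sel1], drop = FALSE]
    out[nrow(mat1) + seq_len(nrow(mat2)), sel2] <- mat2[, res$path_b[sel2], drop = FALSE]
    out
  }
  align_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    subs <- lapply(kids, function(k) {
      if (k <= n) {
        id <- guide$tip.label[k]
        matrix(strsplit(v[[id]], "")[[1L]], nrow = 1L,
               dimnames = list(id, NULL))
      } else {
        align_node(k)
      }
    })
    Reduce(merge_profiles, subs)
  }
  root <- n + 1L
  mat <- align_node(root)
  out <- apply(mat[names(v), , drop = FALSE], 1L, paste, collapse = "")
  structure(out, class = "kin_msa")
}

#' Convert an MSA to a character matrix
#' @param msa A `kin_msa` or named character vector of equal-length rows.
#' @return Character matrix, one row per sequence.
#' @export
msa_matrix <- function(msa) {
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    stop("MSA rows must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(mat) <- names(msa)
  mat
}

#' Read / write an MSA in aligned FASTA
#' @param path Path to the aligned FASTA file.
#' @param msa MSA to write.
#' @return `read_msa()` returns a `kin_msa`; `write_msa()` returns `path`
#'   invisibly.
#' @export
read_msa <- function(path) {
  tab <- read_fasta(path, allow_gaps = TRUE)
  v <- tab$residues
  names(v) <- tab$id
  if (length(unique(nchar(v))) > 1L)
    stop("aligned FASTA rows differ in length", call. = FALSE)
  structure(v, class = "kin_msa")
}

#' @rdname read_msa
#' @export
write_msa <- function(msa, path) {
  write_fasta(unclass(msa), path)
}

#' Pairwise dissimilarity matrix from an MSA
#'
#' Entry (i, j) is `1 - (identical columns / columns where both rows are
#' ungapped)` — the p-dissimilarity over mutually ungapped columns.
#'
#' @param msa A `kin_msa`.
#' @return Symmetric numeric matrix with zero diagonal and the row ids as
#'   dimnames.
#' @export
distance_matrix <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  gap <- mat == "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- !gap[i, ] & !gap[j, ]
      if (!any(both))
        stop(sprintf("no mutually ungapped columns between %s and %s",
                     rownames(mat)[i], rownames(mat)[j]), call. = FALSE)
      p <- 1 - sum(mat[i, both] == mat[j, both]) / sum(both)
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}
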