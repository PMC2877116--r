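# Independent oracles, kept deliberately naive: plain-R dynamic programming
# and O(n^2) enumeration, never calling the code paths they check.

# quadratic-space affine Needleman-Wunsch score (three-state recurrence);
# gap of length k costs open + k * ext, matching align_params()
oracle_nw_score <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                               X[i, j + 1L] - ext,
                               Y[i, j + 1L] - open - ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                               X[i + 1L, j] - open - ext,
                               Y[i + 1L, j] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# pairwise precision/recall by exhaustive pair enumeration
oracle_pair_scores <- function(pred, truth) {
  ids <- names(pred)
  tp <- fp <- fn <- 0L
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1L, length(ids))) {
      same_pred <- pred[[ids[i]]] == pred[[ids[j]]]
      same_true <- truth[[ids[i]]] == truth[[ids[j]]]
      if (same_pred && same_true) tp <- tp + 1L
      if (same_pred && !same_true) fp <- fp + 1L
      if (!same_pred && same_true) fn <- fn + 1L
    }
  }
  list(precision = if (tp + fp == 0L) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0L) 1 else tp / (tp + fn))
}

# canonical bipartition set of an unrooted tree, via ape's clade partitions
oracle_bipartitions <- function(tr) {
  parts <- ape::prop.part(tr)
  labels <- attr(parts, "labels")
  all <- sort(labels)
  canon <- lapply(parts, function(p) {
    side <- sort(labels[p])
    other <- setdiff(all, side)
    if (length(side) < length(other) ||
        (length(side) == length(other) && side[1L] < other[1L])) side else other
  })
  keep <- vapply(canon, function(s)
    length(s) >= 2L && length(s) <= length(all) - 2L, logical(1))
  unique(vapply(canon[keep], paste, character(1), collapse = "|"))
}

# sum-of-pairs identity of an MSA character matrix
sp_identity <- function(mat) {
  total <- 0
  ident <- 0
  n <- nrow(mat)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      total <- total + sum(both)
      ident <- ident + sum(both & mat[i, ] == mat[j, ])
    }
  }
  if (total == 0) 0 else ident / total
}
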