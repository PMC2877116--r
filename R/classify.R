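#' Assign a new catalytic-domain sequence to an established subfamily
#'
#' Aligns the query to every member of every reference subfamily (or, in
#' fast mode, prescreens representatives first).  The best hit with
#' identity at or above `min_identity` and query coverage at or above
#' `min_coverage` wins; ties are broken by higher identity, then lower
#' cluster id.  Coverage is measured on the query: the fraction of query
#' residues aligned opposite non-gap positions.
#'
#' @param query One row of a sequence table, or a single named residue
#'   string.
#' @param subfamilies A `kin_subfamilies` reference set.
#' @param ref_seqs Sequence table (or named vector) holding the reference
#'   member sequences.
#' @param min_identity Minimum identity fraction (default 0.40).
#' @param min_coverage Minimum query coverage (default 0.70).
#' @param params Alignment parameters from [align_params()].
#' @param fast If `TRUE`, align to representatives first and search full
#'   members only within clusters whose representative reaches
#'   `min_identity - 0.05`; an approximation that can miss borderline
#'   assignments.
#' @return A list with `subfamily_id`, `best_member_id`, `identity`,
#'   `coverage` and `tax_label` (possibly `NULL` when labels are not yet
#'   attached), or the string `"unclassified"` when no reference member
#'   passes both thresholds.
#' @export
assign_subfamily <- function(query, subfamilies, ref_seqs,
                             min_identity = 0.40, min_coverage = 0.70,
                             params = align_params(), fast = FALSE) {
  if (length(subfamilies) == 0L) stop("reference is empty", call. = FALSE)
  refs <- as_seq_vector(ref_seqs)
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    qres <- query$residues
  } else {
    qres <- unname(query[1L])
  }
  if (!nzchar(qres)) stop("query must be non-empty", call. = FALSE)

  search_set <- subfamilies
  if (fast) {
    keep <- vapply(subfamilies, function(sf) {
      aln <- global_align(qres, refs[[sf$representative_id]], params)
      aln$identity >= min_identity - 0.05
    }, logical(1))
    search_set <- subfamilies[keep]
    if (length(search_set) == 0L) return("unclassified")
  }
  best <- NULL
  for (sf in search_set) {
    for (mid in sf$member_ids) {
      aln <- global_align(qres, refs[[mid]], params)
      cov <- aln$coverage_a
      if (aln$identity >= min_identity && cov >= min_coverage) {
        cand <- list(subfamily_id = sf$cluster_id, best_member_id = mid,
                     identity = aln$identity, coverage = cov,
                     tax_label = sf$tax_label)
        if (is.null(best) ||
            cand$identity > best$identity ||
            (cand$identity == best$identity &&
             cand$subfamily_id < best$subfamily_id)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) "unclassified" else best
}

#' Classify a batch of query sequences
#'
#' Runs [assign_subfamily()] per query and tabulates the assignments.
#'
#' @param queries Sequence table or named character vector.
#' @param subfamilies Reference `kin_subfamilies`.
#' @param ref_seqs Reference member sequences.
#' @param ... Thresholds forwarded to [assign_subfamily()].
#' @return Data frame with one row per query (`query_id`, `subfamily_id`
#'   — `NA` for unclassified —, `best_member_id`, `identity`, `coverage`,
#'   `label`), with a `summary` attribute counting queries per subfamily
#'   and unclassified queries.
#' @export
batch_classify <- function(queries, subfamilies, ref_seqs, ...) {
  v <- as_seq_vector(queries)
  if (anyDuplicated(names(v)) > 0L)
    stop("duplicate query ids", call. = FALSE)
  rows <- lapply(seq_along(v), function(i) {
    res <- assign_subfamily(v[i], subfamilies, ref_seqs, ...)
    if (identical(res, "unclassified")) {
      data.frame(query_id = names(v)[i], subfamily_id = NA_integer_,
                 best_member_id = NA_character_, identity = NA_real_,
                 coverage = NA_real_, label = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(query_id = names(v)[i], subfamily_id = res$subfamily_id,
                 best_member_id = res$best_member_id,
                 identity = res$identity, coverage = res$coverage,
                 label = if (is.null(res$tax_label)) NA_character_
                         else format(res$tax_label),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), subfamily_id = integer(),
                      best_member_id = character(), identity = numeric(),
                      coverage = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  counts <- table(factor(ifelse(is.na(out$subfamily_id), "unclassified",
                                as.character(out$subfamily_id))))
  attr(out, "summary") <- counts
  out
}
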