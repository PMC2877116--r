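#' Greedy incremental clustering at an identity threshold
#'
#' CD-HIT-style clustering: sequences are processed in length-descending
#' order (ties broken by lexicographic id); each sequence joins the first
#' existing cluster whose *representative* aligns to it at identity greater
#' than or equal to `threshold`, otherwise it founds a new cluster with
#' itself as representative.  Because every new representative failed the
#' identity test against all earlier representatives, representatives of
#' distinct clusters are pairwise below the threshold.
#'
#' @param seqs Sequence table from [read_fasta()] or a named character
#'   vector of residues.
#' @param threshold Identity threshold in (0,1); the default 0.40 joins at
#'   40% identity or greater.
#' @param params Alignment parameters from [align_params()].
#' @param kmer_prefilter If `TRUE`, skip the alignment when the fraction of
#'   the shorter sequence's distinct 5-mers shared with the longer sequence
#'   is below 0.1.  Off by default because it can change borderline
#'   memberships.
#' @return An object of class `kin_clusters`: a list of clusters, each a
#'   list with `cluster_id` (1-based, in creation order),
#'   `representative_id` and `member_ids`.
#' @export
greedy_cluster <- function(seqs, threshold = 0.40, params = align_params(),
                           kmer_prefilter = FALSE) {
  v <- as_seq_vector(seqs)
  if (anyDuplicated(names(v)) > 0L)
    stop("duplicate sequence ids", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  if (length(v) == 0L) return(structure(list(), class = "kin_clusters"))
  ord <- order(-nchar(v), names(v), method = "radix")
  v <- v[ord]

  kmers <- NULL
  if (kmer_prefilter) {
    kmers <- lapply(v, function(s) {
      n <- nchar(s)
      if (n < 5L) return(s)
      unique(substring(s, seq_len(n - 4L), seq(5L, n)))
    })
  }
  reps <- character(0)      # representative ids in creation order
  members <- list()
  for (id in names(v)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      rid <- reps[k]
      if (kmer_prefilter) {
        short <- if (nchar(v[[id]]) <= nchar(v[[rid]])) id else rid
        long <- if (short == id) rid else id
        shared <- mean(kmers[[short]] %in% kmers[[long]])
        if (shared < 0.1) next
      }
      pid <- global_align(v[[id]], v[[rid]], params)$identity
      if (pid >= threshold) {
        members[[k]] <- c(members[[k]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  clusters <- lapply(seq_along(reps), function(k) {
    list(cluster_id = k, representative_id = reps[k], member_ids = members[[k]])
  })
  structure(clusters, class = "kin_clusters")
}

#' @export
print.kin_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$member_ids), integer(1))
  cat(sprintf("%d clusters over %d sequences (%d singletons)\n",
              length(x), sum(sizes), sum(sizes == 1L)))
  invisible(x)
}

#' Cluster sizes
#' @param clusters A `kin_clusters`.
#' @return Integer vector of member counts, named by cluster id.
#' @export
cluster_sizes <- function(clusters) {
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), integer(1))
  names(sizes) <- vapply(clusters, function(cl) as.character(cl$cluster_id),
                         character(1))
  sizes
}

#' Select prominent subfamilies
#'
#' Keeps exactly the clusters with at least `min_size` members; original
#' cluster ids are retained so subfamily numbering matches the full
#' clustering.
#'
#' @param clusters A `kin_clusters`.
#' @param min_size Minimum member count (default 4).
#' @return An object of class `kin_subfamilies`: the selected clusters,
#'   each with an unresolved `tax_label` slot (`NULL`).
#' @export
select_subfamilies <- function(clusters, min_size = 4L) {
  if (min_size < 1L) stop("min_size must be at least 1", call. = FALSE)
  keep <- Filter(function(cl) length(cl$member_ids) >= min_size, clusters)
  subs <- lapply(keep, function(cl) {
    cl$tax_label <- NULL
    cl
  })
  structure(subs, class = "kin_subfamilies", min_size = min_size)
}

#' Pairwise clustering agreement against a planted truth
#'
#' Precision and recall over co-clustered pairs plus the adjusted Rand
#' index.  Precision is the fraction of predicted co-clustered pairs that
#' are truly co-familial (1 when no pairs are predicted); recall is the
#' fraction of true co-familial pairs recovered (1 when the truth has no
#' pairs).
#'
#' @param clusters A `kin_clusters` (or `kin_subfamilies`).
#' @param truth Named vector mapping every member id to its planted family.
#' @return List with `precision`, `recall`, `ari`.
#' @export
cluster_purity <- function(clusters, truth) {
  ids <- unlist(lapply(clusters, `[[`, "member_ids"))
  missing <- setdiff(ids, names(truth))
  if (length(missing) > 0L)
    stop("id missing from truth: ", missing[1L], call. = FALSE)
  pred <- rep(vapply(clusters, `[[`, integer(1), "cluster_id"),
              vapply(clusters, function(cl) length(cl$member_ids), integer(1)))
  tru <- truth[ids]
  tab <- table(pred, tru)
  pairs <- function(x) sum(choose(x, 2))
  tp <- pairs(as.vector(tab))
  pred_pairs <- pairs(rowSums(tab))
  true_pairs <- pairs(colSums(tab))
  list(precision = if (pred_pairs == 0) 1 else tp / pred_pairs,
       recall = if (true_pairs == 0) 1 else tp / true_pairs,
       ari = mclust::adjustedRandIndex(pred, tru))
}
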