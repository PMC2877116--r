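#' Read catalytic-domain sequences from a FASTA file
#'
#' Parses a protein FASTA file into a sequence table.  The first
#' whitespace-delimited token of each header is taken as the sequence id
#' (File S1-style headers are typically a bare GI-number-like token); an
#' optional `organism=` key=value tail is honoured when present, but joins
#' against the taxonomy table remain the authoritative source of organism
#' and lineage information.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Accept the gap character `-` in residues (used when
#'   reading aligned FASTA).
#' @return A `data.frame` with columns `id`, `organism` (`NA` when the
#'   header carries none) and `residues` (uppercase), one row per record in
#'   file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  empty <- data.frame(id = character(), organism = character(),
                      residues = character(), stringsAsFactors = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) return(empty)
  if (!startsWith(lines[nonblank[1L]], ">"))
    stop(sprintf("malformed FASTA: line %d does not start a record", nonblank[1L]),
         call. = FALSE)
  hdr <- which(startsWith(lines, ">"))
  bad_hdr <- hdr[trimws(substring(lines[hdr], 2L)) == ""]
  if (length(bad_hdr) > 0L)
    stop(sprintf("malformed header at line %d: empty id", bad_hdr[1L]),
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id: ", dup[1L], call. = FALSE)
  organism <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("organism=[^[:space:]]+", h))
    if (length(m) == 1L) sub("^organism=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  residues <- toupper(as.character(set))
  if (any(nchar(residues) == 0L))
    stop("empty sequence for id: ", ids[nchar(residues) == 0L][1L], call. = FALSE)
  check_residues(residues, allow_gaps = allow_gaps)
  data.frame(id = ids, organism = organism, residues = unname(residues),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Sequence table as returned by [read_fasta()], or a named
#'   character vector of residues.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  v <- as_seq_vector(seqs)
  headers <- names(v)
  if (is.data.frame(seqs) && "organism" %in% names(seqs)) {
    has_org <- !is.na(seqs$organism)
    headers[has_org] <- paste0(seqs$id[has_org], " organism=", seqs$organism[has_org])
  }
  set <- Biostrings::BStringSet(unname(v))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a per-sequence taxonomy table
#'
#' Tab-separated file with header columns `id`, `organism`, then rank
#' columns drawn from [RANK_LADDER].  Empty cells become missing ranks.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `id`, `organism` and one column per
#'   rank of the ladder (ranks absent from the file are filled with `NA`).
#' @export
read_taxonomy_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (!all(c("id", "organism") %in% names(tab)))
    stop("taxonomy table must have 'id' and 'organism' columns", call. = FALSE)
  ranks <- setdiff(names(tab), c("id", "organism"))
  unknown <- setdiff(ranks, RANK_LADDER)
  if (length(unknown) > 0L)
    stop("unknown rank column: ", unknown[1L], call. = FALSE)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0L)
    stop("duplicate id in taxonomy table: ", dup[1L], call. = FALSE)
  for (r in setdiff(RANK_LADDER, ranks)) tab[[r]] <- NA_character_
  tab <- tab[, c("id", "organism", RANK_LADDER)]
  for (r in RANK_LADDER) {
    v <- tab[[r]]
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    tab[[r]] <- v
  }
  tab
}

#' Write a taxonomy table
#' @param tax Taxonomy `data.frame` as from [read_taxonomy_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(tax, path) {
  out <- tax[, c("id", "organism", intersect(RANK_LADDER, names(tax)))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract one lineage from a taxonomy table
#'
#' @param tax Taxonomy table.
#' @param id Sequence id.
#' @return Named character vector over the ranks present (missing ranks
#'   dropped), or an error if the id is absent.
#' @export
get_lineage <- function(tax, id) {
  i <- match(id, tax$id)
  if (is.na(i)) stop("id not in taxonomy table: ", id, call. = FALSE)
  v <- unlist(tax[i, RANK_LADDER])
  v[!is.na(v)]
}

#' Read / write cluster membership tables
#'
#' Cluster tables are TSV files with columns `cluster_id`, `member_id`,
#' `is_representative`; they always encode a partition (each member appears
#' exactly once).
#'
#' @param clusters A cluster set as returned by [greedy_cluster()].
#' @param path Path to the TSV file.
#' @return `write_cluster_table()` returns `path` invisibly;
#'   `read_cluster_table()` returns a cluster set (list of clusters, each
#'   with `cluster_id`, `representative_id`, `member_ids`).
#' @export
write_cluster_table <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               member_id = cl$member_ids,
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(cluster_id = integer(), member_id = character(),
                       is_representative = logical())
  dup <- rows$member_id[duplicated(rows$member_id)]
  if (length(dup) > 0L)
    stop("member in two clusters: ", dup[1L], call. = FALSE)
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cluster_id = "integer",
                                   member_id = "character",
                                   is_representative = "logical"))
  dup <- tab$member_id[duplicated(tab$member_id)]
  if (length(dup) > 0L)
    stop("member in two clusters: ", dup[1L], call. = FALSE)
  clusters <- lapply(split(tab, tab$cluster_id), function(g) {
    rep_id <- g$member_id[g$is_representative]
    if (length(rep_id) != 1L)
      stop("cluster ", g$cluster_id[1L], " must have exactly one representative",
           call. = FALSE)
    list(cluster_id = g$cluster_id[1L], representative_id = rep_id,
         member_ids = g$member_id)
  })
  clusters <- clusters[order(vapply(clusters, `[[`, integer(1), "cluster_id"))]
  names(clusters) <- NULL
  structure(clusters, class = "kin_clusters")
}

# serialize a lineage as a semicolon-joined rank path in ladder order
lineage_to_path <- function(lineage) {
  v <- rep("", length(RANK_LADDER))
  names(v) <- RANK_LADDER
  lineage <- lineage[!is.na(lineage)]
  v[names(lineage)] <- lineage
  paste(v, collapse = ";")
}

path_to_lineage <- function(path) {
  parts <- strsplit(path, ";", fixed = TRUE)[[1L]]
  length(parts) <- length(RANK_LADDER)
  parts[is.na(parts) | parts == ""] <- NA_character_
  names(parts) <- RANK_LADDER
  parts[!is.na(parts)]
}

#' Read / write homologue hit tables
#'
#' Tab-separated tables standing in for sequence-database search output
#' (e.g. PSI-BLAST against Uniref90).  Columns: `query_id`, `subject_id`,
#' `identity` and `query_coverage` as fractions in \[0,1\], `evalue`, and
#' `subject_lineage` as a semicolon-joined rank path in ladder order (empty
#' segments for missing ranks).  Lines starting with `#` are ignored.
#'
#' @param hits Hit `data.frame`.
#' @param path Path to the TSV file.
#' @return `read_hit_table()` returns a `data.frame` of hits;
#'   `write_hit_table()` returns `path` invisibly.
#' @export
read_hit_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = c(query_id = "character",
                                   subject_id = "character",
                                   identity = "numeric",
                                   query_coverage = "numeric",
                                   evalue = "numeric",
                                   subject_lineage = "character"))
  validate_hits(tab)
  tab
}

#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  need <- c("query_id", "subject_id", "identity", "query_coverage",
            "evalue", "subject_lineage")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L)
    stop("hit table missing column: ", miss[1L], call. = FALSE)
  if (nrow(hits) > 0L) {
    if (any(hits$identity < 0 | hits$identity > 1, na.rm = TRUE) ||
        any(hits$query_coverage < 0 | hits$query_coverage > 1, na.rm = TRUE))
      stop("identity and query_coverage must be fractions in [0,1]", call. = FALSE)
    if (any(hits$evalue < 0, na.rm = TRUE))
      stop("evalue must be non-negative", call. = FALSE)
  }
  invisible(hits)
}

#' Read / write a PHYLIP square distance matrix
#'
#' Relaxed PHYLIP format: first line the number of taxa, then one row per
#' taxon with the taxon name followed by whitespace-separated distances.
#'
#' @param d Symmetric numeric matrix with taxon ids as dimnames.
#' @param path Path to the matrix file.
#' @return `read_phylip_dist()` returns the matrix; `write_phylip_dist()`
#'   returns `path` invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])), collapse = "  "),
               con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n)) stop("malformed PHYLIP matrix: bad taxon count", call. = FALSE)
  d <- matrix(0, n, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    if (length(parts) != n + 1L)
      stop(sprintf("malformed PHYLIP matrix row %d", i), call. = FALSE)
    ids[i] <- parts[1L]
    d[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(d) <- list(ids, ids)
  d
}
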