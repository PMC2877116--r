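#' Taxonomic specificity label
#'
#' Constructor for the label attached to a subfamily: its scope
#' (`specific`, `predominant` or `organism_diverse`), the rank and taxon
#' set the label refers to, a confirmation status, and the fraction of
#' members covered by the dominant taxon.
#'
#' @param scope One of `"specific"`, `"predominant"`, `"organism_diverse"`.
#' @param rank A rank from [RANK_LADDER], or `NULL` for organism-diverse.
#' @param taxa Character vector of 1-2 taxon names at `rank` (empty for
#'   organism-diverse labels).
#' @param status One of `"tentative"`, `"confirmed"`, `"demoted"`.
#' @param dominant_fraction Fraction of members under the dominant taxon
#'   (1 for specific labels).
#' @return An object of class `tax_label`.
#' @export
tax_label <- function(scope, rank = NULL, taxa = character(),
                      status = "tentative", dominant_fraction = NA_real_) {
  scope <- match.arg(scope, c("specific", "predominant", "organism_diverse"))
  status <- match.arg(status, c("tentative", "confirmed", "demoted"))
  if (scope == "organism_diverse") {
    if (!is.null(rank) || length(taxa) > 0L)
      stop("organism_diverse labels carry no rank or taxa", call. = FALSE)
  } else {
    if (is.null(rank) || !rank %in% RANK_LADDER)
      stop("rank must be one of the rank ladder", call. = FALSE)
    if (length(taxa) < 1L || length(taxa) > 2L)
      stop("labels carry 1 or 2 taxa", call. = FALSE)
    if (scope == "specific" && !isTRUE(all.equal(dominant_fraction, 1)))
      stop("specific labels require dominant_fraction = 1", call. = FALSE)
  }
  structure(list(scope = scope, rank = rank, taxa = taxa, status = status,
                 dominant_fraction = dominant_fraction),
            class = "tax_label")
}

#' @export
format.tax_label <- function(x, ...) {
  if (x$scope == "organism_diverse") return("Organism diverse")
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  word <- if (x$scope == "specific") "specific" else "predominant"
  sprintf("%s %s %s", cap(x$rank), paste(x$taxa, collapse = " and "), word)
}

#' @export
print.tax_label <- function(x, ...) {
  cat(format(x), sprintf("[%s]", x$status), "\n")
  invisible(x)
}

# normalize lineages to a data.frame with one column per ladder rank
lineages_frame <- function(lineages) {
  if (is.data.frame(lineages)) {
    out <- lineages
    for (r in setdiff(RANK_LADDER, names(out))) out[[r]] <- NA_character_
    return(out[, RANK_LADDER, drop = FALSE])
  }
  if (is.list(lineages)) {
    rows <- lapply(lineages, function(l) {
      v <- rep(NA_character_, length(RANK_LADDER))
      names(v) <- RANK_LADDER
      l <- l[!is.na(l)]
      v[names(l)] <- l
      as.data.frame(as.list(v), stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  stop("lineages must be a data.frame or a list of named vectors", call. = FALSE)
}

#' Deepest rank shared by a set of lineages
#'
#' Returns the deepest rank of the ladder at which all lineages carry the
#' same taxon.  A lineage missing a rank neither supports nor vetoes
#' agreement at that rank, provided at least `min_rank_coverage` of the
#' lineages do carry it; below that coverage, agreement at the rank is not
#' claimed (suborder, for instance, is sparsely annotated in real
#' taxonomies).
#'
#' @param lineages Data frame with ladder-rank columns, or a list of named
#'   lineage vectors.
#' @param min_rank_coverage Minimum fraction of lineages that must carry a
#'   rank for agreement at it to be claimed (default 0.9).
#' @return A list with `rank` and `taxon`, or `NULL` when the lineages
#'   disagree even at superkingdom.
#' @export
lowest_common_rank <- function(lineages, min_rank_coverage = 0.9) {
  lf <- lineages_frame(lineages)
  if (nrow(lf) == 0L || all(is.na(unlist(lf))))
    stop("need at least one lineage with at least one rank", call. = FALSE)
  for (r in rev(RANK_LADDER)) {
    vals <- lf[[r]]
    coverage <- mean(!is.na(vals))
    if (coverage >= min_rank_coverage) {
      u <- unique(vals[!is.na(vals)])
      if (length(u) == 1L) return(list(rank = r, taxon = u))
    }
  }
  NULL
}

# ranks eligible for specificity labels: phylum through genus, matching
# the rank range used for subfamily labels
label_rank_ladder <- function() RANK_LADDER[2:7]

#' Assign a tentative taxonomic-specificity label to a subfamily
#'
#' Walks the rank ladder from genus up to phylum.  If all members share a
#' taxon at some rank the label is *specific* at the deepest such rank;
#' otherwise, if a single taxon covers at least `predominance_threshold`
#' of the members at some rank, the label is *predominant* at the deepest
#' such rank; otherwise the subfamily is *organism-diverse*.  When a
#' specific label's members span exactly two sister taxa one rank deeper
#' (and `max_taxa_per_rank >= 2`), the pair is reported at the deeper rank
#' (producing labels of the form "Genus X and Y specific").
#'
#' @param cluster_lineages Lineages of all subfamily members (data frame
#'   with rank columns, or list of named vectors).  Members with no
#'   lineage at all raise an error.
#' @param predominance_threshold Minimum member fraction under one taxon
#'   for a predominant label (default 0.75; the boundary between
#'   "predominant" and "organism-diverse" is a judgement call and is always
#'   surfaced in reports).
#' @param max_taxa_per_rank Maximum taxa in one label (1 disables pair
#'   labels; capped at 2).
#' @param min_rank_coverage Missing-rank tolerance, as in
#'   [lowest_common_rank()].
#' @return A tentative `tax_label`.
#' @export
assign_specificity <- function(cluster_lineages, predominance_threshold = 0.75,
                               max_taxa_per_rank = 2L, min_rank_coverage = 0.9) {
  lf <- lineages_frame(cluster_lineages)
  empty <- apply(is.na(lf), 1L, all)
  if (any(empty)) {
    who <- rownames(lf)[empty]
    if (is.null(who)) who <- which(empty)
    stop("members without lineage: ", paste(who, collapse = ", "), call. = FALSE)
  }
  n <- nrow(lf)
  ladder <- label_rank_ladder()

  agreement <- function(r) {
    vals <- lf[[r]]
    if (mean(!is.na(vals)) < min_rank_coverage) return(NULL)
    u <- unique(vals[!is.na(vals)])
    if (length(u) == 1L) u else NULL
  }
  # specific: deepest rank with full agreement
  for (ri in rev(seq_along(ladder))) {
    r <- ladder[ri]
    taxon <- agreement(r)
    if (!is.null(taxon)) {
      # two-sister refinement one rank deeper (still within label ranks)
      if (max_taxa_per_rank >= 2L && ri < length(ladder)) {
        r2 <- ladder[ri + 1L]
        vals2 <- lf[[r2]]
        if (mean(!is.na(vals2)) >= min_rank_coverage) {
          u2 <- unique(vals2[!is.na(vals2)])
          if (length(u2) == 2L)
            return(tax_label("specific", r2, sort(u2), dominant_fraction = 1))
        }
      }
      return(tax_label("specific", r, taxon, dominant_fraction = 1))
    }
  }
  # predominant: deepest rank where one taxon covers >= threshold of members
  for (r in rev(ladder)) {
    vals <- lf[[r]]
    if (all(is.na(vals))) next
    tab <- sort(table(vals[!is.na(vals)]), decreasing = TRUE)
    frac <- as.numeric(tab[1L]) / n
    if (frac >= predominance_threshold)
      return(tax_label("predominant", r, names(tab)[1L],
                       dominant_fraction = frac))
  }
  best <- max(vapply(ladder, function(r) {
    vals <- lf[[r]]
    if (all(is.na(vals))) return(0)
    max(table(vals[!is.na(vals)])) / n
  }, numeric(1)))
  tax_label("organism_diverse", dominant_fraction = best)
}

#' Filter homologue hits on identity, coverage and E-value
#'
#' Keeps exactly the hits with identity at or above `min_identity`,
#' query coverage at or above `min_coverage`, and E-value at or below
#' `max_evalue` (all bounds inclusive).
#'
#' @param hits Hit `data.frame` (see [read_hit_table()]).
#' @param min_identity Minimum identity fraction (default 0.40).
#' @param min_coverage Minimum query-coverage fraction (default 0.70).
#' @param max_evalue Maximum E-value (default 1e-5).
#' @return The passing subset of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 0.40, min_coverage = 0.70,
                        max_evalue = 1e-5) {
  validate_hits(hits)
  keep <- hits$identity >= min_identity &
    hits$query_coverage >= min_coverage &
    hits$evalue <= max_evalue
  hits[keep, , drop = FALSE]
}

#' Confirm or demote a tentative specificity label against homologue hits
#'
#' A tentative taxonomy label is confirmed only if every homologue hit
#' passing the close-homologue filter ([filter_hits()]) carries the
#' label's taxon at the label's rank in its subject lineage; a single
#' passing out-of-taxon hit demotes the subfamily to organism-diverse.  An
#' empty passing-hit set confirms (no counter-evidence).  Organism-diverse
#' labels have no taxon to contradict and are confirmed as they stand.
#'
#' @param label A tentative `tax_label`.
#' @param hits Hit `data.frame`; filtered internally, so raw hit tables can
#'   be passed directly.
#' @param min_identity,min_coverage,max_evalue Filter thresholds forwarded
#'   to [filter_hits()].
#' @return The resolved `tax_label` (status `confirmed` or `demoted`).
#' @export
confirm_specificity <- function(label, hits, min_identity = 0.40,
                                min_coverage = 0.70, max_evalue = 1e-5) {
  if (!inherits(label, "tax_label")) stop("label must be a tax_label", call. = FALSE)
  if (label$status != "tentative")
    stop("label already ", label$status, call. = FALSE)
  if (label$scope == "organism_diverse") {
    label$status <- "confirmed"
    return(label)
  }
  passing <- filter_hits(hits, min_identity, min_coverage, max_evalue)
  in_taxon <- vapply(passing$subject_lineage, function(p) {
    lin <- path_to_lineage(p)
    !is.na(lin[label$rank]) && lin[[label$rank]] %in% label$taxa
  }, logical(1), USE.NAMES = FALSE)
  if (all(in_taxon)) {
    label$status <- "confirmed"
    label
  } else {
    demoted <- tax_label("organism_diverse", status = "tentative",
                         dominant_fraction = label$dominant_fraction)
    demoted$status <- "demoted"
    demoted$demoted_from <- format(label)
    demoted
  }
}

#' Summarize subfamily labels
#'
#' One row per subfamily with its resolved label, plus scope and per-taxon
#' counts as attributes.
#'
#' @param subfamilies A `kin_subfamilies` whose elements carry resolved
#'   `tax_label`s (status confirmed or demoted).
#' @return Data frame with columns `cluster_id`, `size`, `scope`, `rank`,
#'   `taxa`, `dominant_fraction`, `status`, `label`; attributes
#'   `scope_counts` (named integer vector) and `taxon_counts` (data frame
#'   of labeled rank/taxon combinations with subfamily counts).
#' @export
summarize_labels <- function(subfamilies) {
  if (length(subfamilies) == 0L) {
    out <- data.frame(cluster_id = integer(), size = integer(),
                      scope = character(), rank = character(),
                      taxa = character(), dominant_fraction = numeric(),
                      status = character(), label = character(),
                      stringsAsFactors = FALSE)
    attr(out, "scope_counts") <- c(specific = 0L, predominant = 0L,
                                   organism_diverse = 0L)
    return(out)
  }
  rows <- lapply(subfamilies, function(sf) {
    l <- sf$tax_label
    if (is.null(l) || !inherits(l, "tax_label"))
      stop("subfamily ", sf$cluster_id, " has no label", call. = FALSE)
    if (l$status == "tentative")
      stop("unresolved (tentative) label for subfamily ", sf$cluster_id,
           call. = FALSE)
    data.frame(cluster_id = sf$cluster_id,
               size = length(sf$member_ids),
               scope = l$scope,
               rank = if (is.null(l$rank)) NA_character_ else l$rank,
               taxa = paste(l$taxa, collapse = " and "),
               dominant_fraction = l$dominant_fraction,
               status = l$status,
               label = format(l),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  scopes <- c("specific", "predominant", "organism_diverse")
  attr(out, "scope_counts") <- vapply(scopes, function(s) sum(out$scope == s),
                                      integer(1))
  labeled <- out[out$scope != "organism_diverse", , drop = FALSE]
  if (nrow(labeled) > 0L) {
    tc <- aggregate(list(n_subfamilies = labeled$cluster_id),
                    by = list(rank = labeled$rank, taxa = labeled$taxa,
                              scope = labeled$scope),
                    FUN = length)
    attr(out, "taxon_counts") <- tc
  }
  out
}
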