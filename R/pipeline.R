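#' Pipeline configuration
#'
#' Collects every threshold of the classification framework in one place,
#' with the defaults used throughout: clustering identity 0.40, subfamily
#' minimum size 4, close-homologue filter (identity >= 0.40, query
#' coverage >= 0.70, E-value <= 1e-5), predominance threshold 0.75, and
#' 1000 bootstrap replicates.
#'
#' @param fasta Path to the catalytic-domain FASTA file.
#' @param taxonomy Path to the taxonomy TSV.
#' @param outdir Output directory (created if needed).
#' @param hits Optional path to a homologue hit table used to confirm or
#'   demote tentative labels; with no hit table, labels confirm on the
#'   absence of counter-evidence.
#' @param cluster_threshold Clustering identity threshold.
#' @param min_size Minimum subfamily size.
#' @param predominance Predominance threshold for taxonomy labels.
#' @param min_identity,min_coverage,max_evalue Close-homologue filter.
#' @param bootstrap Bootstrap replicates for subfamily trees (0 disables
#'   tree building).
#' @param seed Integer seed funnelling all randomness in the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, taxonomy, outdir, hits = NULL,
                            cluster_threshold = 0.40, min_size = 4L,
                            predominance = 0.75, min_identity = 0.40,
                            min_coverage = 0.70, max_evalue = 1e-5,
                            bootstrap = 1000L, seed = 1L) {
  stopifnot(cluster_threshold > 0, cluster_threshold < 1,
            min_size >= 1, predominance > 0, predominance <= 1,
            min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            max_evalue >= 0, bootstrap >= 0)
  structure(list(fasta = fasta, taxonomy = taxonomy, outdir = outdir,
                 hits = hits, cluster_threshold = cluster_threshold,
                 min_size = as.integer(min_size), predominance = predominance,
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Chains the framework stages on a directory of inputs: read sequences
#' and taxonomy, cluster at the identity threshold, select subfamilies,
#' assign and resolve taxonomy labels (against the hit table when one is
#' supplied), align each subfamily, and build its NJ tree with bootstrap
#' supports.  All intermediate artifacts are written under `outdir`
#' together with a manifest recording input checksums, the configuration
#' and the package version; reruns with the same inputs and seed are
#' byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a report list: sequence/cluster/subfamily counts,
#'   the label summary, and the paths of all artifacts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "input"
  fail <- function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                   stage, conditionMessage(e)), call. = FALSE)
  tryCatch({
    seqs <- read_fasta(cfg$fasta)
    tax <- read_taxonomy_table(cfg$taxonomy)
    hits <- if (!is.null(cfg$hits)) read_hit_table(cfg$hits) else NULL
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(cfg$outdir, "trees"), showWarnings = FALSE)

    stage <- "cluster"
    clusters <- greedy_cluster(seqs, threshold = cfg$cluster_threshold)
    write_cluster_table(clusters, file.path(cfg$outdir, "clusters.tsv"))
    subfams <- select_subfamilies(clusters, min_size = cfg$min_size)

    stage <- "taxlabel"
    subfams <- structure(lapply(subfams, function(sf) {
      idx <- match(sf$member_ids, tax$id)
      if (anyNA(idx))
        stop("members missing from taxonomy table: ",
             paste(sf$member_ids[is.na(idx)], collapse = ", "))
      lineages <- tax[idx, RANK_LADDER]
      rownames(lineages) <- sf$member_ids
      label <- assign_specificity(lineages,
                                  predominance_threshold = cfg$predominance)
      sf_hits <- if (is.null(hits)) {
        data.frame(query_id = character(), subject_id = character(),
                   identity = numeric(), query_coverage = numeric(),
                   evalue = numeric(), subject_lineage = character(),
                   stringsAsFactors = FALSE)
      } else {
        hits[hits$query_id %in% sf$member_ids, , drop = FALSE]
      }
      sf$tax_label <- confirm_specificity(label, sf_hits,
                                          min_identity = cfg$min_identity,
                                          min_coverage = cfg$min_coverage,
                                          max_evalue = cfg$max_evalue)
      sf
    }), class = "kin_subfamilies")
    labels <- summarize_labels(subfams)
    write.table(labels, file.path(cfg$outdir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "tree"
    tree_files <- character(0)
    if (cfg$bootstrap > 0L) {
      for (sf in subfams) {
        members <- seqs[match(sf$member_ids, seqs$id), ]
        msa <- progressive_msa(members)
        d <- distance_matrix(msa)
        write_phylip_dist(d, file.path(cfg$outdir, "trees",
                                       sprintf("cluster_%03d.dist", sf$cluster_id)))
        tree <- bootstrap_supports(msa, replicates = cfg$bootstrap,
                                   seed = cfg$seed + sf$cluster_id)
        path <- file.path(cfg$outdir, "trees",
                          sprintf("cluster_%03d.nwk", sf$cluster_id))
        write_newick(tree, path)
        tree_files <- c(tree_files, path)
      }
    }

    stage <- "manifest"
    sizes <- cluster_sizes(clusters)
    inputs <- c(cfg$fasta, cfg$taxonomy, cfg$hits)
    outputs <- c(file.path(cfg$outdir, "clusters.tsv"),
                 file.path(cfg$outdir, "labels.tsv"), tree_files)
    manifest <- list(
      package_version = as.character(utils::packageVersion("prokclass")),
      config = unclass(cfg),
      input_md5 = as.list(tools::md5sum(inputs)),
      output_md5 = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")

    report <- list(n_sequences = nrow(seqs),
                   n_clusters = length(clusters),
                   n_singletons = sum(sizes == 1L),
                   n_subfamilies = length(subfams),
                   scope_counts = attr(labels, "scope_counts"),
                   labels = labels,
                   clusters_tsv = file.path(cfg$outdir, "clusters.tsv"),
                   labels_tsv = file.path(cfg$outdir, "labels.tsv"),
                   trees = tree_files,
                   manifest = file.path(cfg$outdir, "manifest.json"))
    invisible(report)
  }, error = fail)
}
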