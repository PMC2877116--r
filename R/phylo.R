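#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: at each stage the pair of operational
#' taxonomic units minimizing the Q-criterion (the total branch length of
#' the resulting tree) is joined, with branch lengths from the standard NJ
#' formulas.  Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with the deficit transferred to the adjacent
#' edge so that path lengths through the node are preserved; raw lengths
#' are kept in the `raw_edge_length` attribute.
#'
#' @param d Symmetric numeric matrix of dissimilarities with zero diagonal
#'   and taxon ids as dimnames (at least 2 taxa).
#' @return An unrooted `phylo` tree (ape) over the taxon ids.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix needs taxon ids", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (nrow(d) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        rownames(d)[1L], d[1L, 2L] / 2,
                                        rownames(d)[2L], d[1L, 2L] / 2))
    return(tr)
  }
  tr <- ape::nj(d)
  raw <- tr$edge.length
  # clamp negative edges, shifting the deficit onto the sibling edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    tr$edge.length[e] <- 0
    if (length(sibs) > 0L)
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "raw_edge_length") <- raw
  tr
}

# leaf bipartitions induced by the internal edges of an unrooted tree,
# as sorted character vectors of the smaller side's labels
tree_bipartitions <- function(tr) {
  n <- length(tr$tip.label)
  internal <- which(tr$edge[, 2L] > n)
  parts <- lapply(internal, function(e) {
    node <- tr$edge[e, 2L]
    tips <- unlist(node_descendant_tips(tr, node))
    side <- sort(tr$tip.label[tips])
    other <- sort(setdiff(tr$tip.label, side))
    if (length(side) < length(other) ||
        (length(side) == length(other) && side[1L] < other[1L])) side else other
  })
  parts
}

# tips below a node (iterative edge-matrix walk)
node_descendant_tips <- function(tr, node) {
  n <- length(tr$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tr$edge[tr$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Builds the full-data NJ tree from the alignment's p-dissimilarity
#' matrix, then resamples alignment columns with replacement
#' `replicates` times; each replicate yields a distance matrix and NJ
#' tree.  The support of each internal edge of the full-data tree is the
#' percentage of replicate trees containing the same leaf bipartition.
#' Supports are attached as integer node labels (the root node, which has
#' no corresponding unrooted edge, gets an empty label).
#'
#' @param msa A `kin_msa` with at least 4 rows.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the replicate column draws are fully
#'   reproducible.
#' @return The full-data `phylo` tree with `node.label` holding supports.
#' @export
bootstrap_supports <- function(msa, replicates = 1000L, seed = 1L) {
  mat <- msa_matrix(msa)
  if (nrow(mat) < 4L) stop("bootstrap needs at least 4 rows", call. = FALSE)
  if (replicates < 1L) stop("replicates must be at least 1", call. = FALSE)
  main <- nj_tree(distance_matrix(msa))
  main_parts <- tree_bipartitions(main)
  keys <- vapply(main_parts, paste, character(1), collapse = "\r")
  counts <- setNames(rep(0L, length(keys)), keys)
  ncols <- ncol(mat)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncols, replace = TRUE)
      sub <- mat[, cols, drop = FALSE]
      rows <- apply(sub, 1L, paste, collapse = "")
      rep_tree <- nj_tree(distance_matrix(structure(rows, class = "kin_msa")))
      rep_keys <- vapply(tree_bipartitions(rep_tree), paste, character(1),
                         collapse = "\r")
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  supports <- as.integer(round(100 * counts / replicates))
  # map supports onto node labels: internal edge -> child node
  n <- length(main$tip.label)
  labels <- rep("", main$Nnode)
  internal <- which(main$edge[, 2L] > n)
  for (k in seq_along(internal)) {
    node <- main$edge[internal[k], 2L]
    labels[node - n] <- as.character(supports[k])
  }
  main$node.label <- labels
  main
}

#' Write / read trees in Newick format
#'
#' Newick with branch lengths; integer bootstrap supports are serialized
#' as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Path to the Newick file.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("malformed Newick: unbalanced ')' at position %d", i),
           call. = FALSE)
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick file: ", path, call. = FALSE)
  tr
}
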