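#' Scenario configuration for the synthetic dataset generator
#'
#' Describes a planted dataset of protein-domain families with known
#' cluster structure and known taxonomic-specificity labels.  Defaults
#' emulate the statistical shape of a catalytic-domain collection: ~250
#' residue domains, families coherent at well above the 40% clustering
#' threshold, unrelated families far below it.
#'
#' @param n_families Number of planted families (default 8).
#' @param members_per_family Members per family (default 6).
#' @param domain_length Ancestor length in residues (default 250).
#' @param within_family_divergence Expected substitutions per non-motif
#'   site between a member and its family ancestor (default 0.10, i.e.
#'   members ~90% identical to the ancestor).
#' @param between_family_identity Expected identity ceiling between
#'   members of different families (independent random ancestors plus the
#'   shared motif columns give roughly 0.05-0.10); configurations where
#'   this floor reaches the within-family identity are rejected.
#' @param indel_rate Per-site probability of an indel event per member
#'   (default 0.005); indel lengths are geometric (p = 0.7) and events
#'   avoid motif columns.
#' @param scenarios Character vector, one per family, from:
#'   `"specific@<rank>"`, `"specific_pair@<rank>"` (two sister taxa),
#'   `"predominant@<rank>:<fraction>"`, `"diverse"`.  The default mix
#'   covers every label shape: phylum/order/genus-specific families, a
#'   two-sister-genera family, a phylum-predominant family, and diverse
#'   families.
#' @param seed Mandatory integer seed; the whole dataset is a pure
#'   function of the configuration.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_families = 8L, members_per_family = 6L,
                            domain_length = 250L,
                            within_family_divergence = 0.10,
                            between_family_identity = 0.15,
                            indel_rate = 0.005,
                            scenarios = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (within_family_divergence < 0 || within_family_divergence >= 1)
    stop("within_family_divergence must be in [0,1)", call. = FALSE)
  if (between_family_identity >= 1 - within_family_divergence)
    stop("infeasible config: between-family identity floor reaches ",
         "within-family identity", call. = FALSE)
  if (is.null(scenarios)) {
    base <- c("specific@phylum", "specific@phylum", "specific@order",
              "specific@genus", "specific_pair@genus",
              "predominant@phylum:0.8", "diverse", "diverse")
    scenarios <- rep_len(base, n_families)
  }
  if (length(scenarios) != n_families)
    stop("need one scenario per family", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 domain_length = as.integer(domain_length),
                 within_family_divergence = within_family_divergence,
                 between_family_identity = between_family_identity,
                 indel_rate = indel_rate,
                 scenarios = scenarios,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# --- mock taxonomy ladder -------------------------------------------------
# Three superkingdoms; 6/2/2 phyla; fan-out 3 at every deeper rank.  Taxon
# names embed the index path from the root, so two taxa are equal iff their
# whole paths agree.

mock_superkingdoms <- function() c("Bacteria", "Archaea", "Eukaryota")

mock_phyla_count <- function(sk_index) c(6L, 2L, 2L)[sk_index]

# idx: integer vector of length 8 (index at each rank; idx[1] superkingdom)
lineage_from_idx <- function(idx) {
  prefixes <- c("", "Phy", "Cla", "Ord", "Sub", "Fam", "Gen", "Spe")
  out <- character(length(RANK_LADDER))
  out[1L] <- mock_superkingdoms()[idx[1L]]
  for (k in 2:8) {
    out[k] <- paste0(prefixes[k], paste(idx[1:k], collapse = "."))
  }
  names(out) <- RANK_LADDER
  out
}

random_idx <- function(sk = NULL) {
  i1 <- if (is.null(sk)) sample.int(3L, 1L) else sk
  c(i1, sample.int(mock_phyla_count(i1), 1L), sample.int(3L, 6L, replace = TRUE))
}

parse_scenario <- function(s) {
  if (s == "diverse") return(list(kind = "diverse"))
  if (grepl("^specific_pair@", s)) {
    rank <- sub("^specific_pair@", "", s)
    stopifnot(rank %in% RANK_LADDER)
    return(list(kind = "specific_pair", rank = rank))
  }
  if (grepl("^specific@", s)) {
    rank <- sub("^specific@", "", s)
    stopifnot(rank %in% RANK_LADDER)
    return(list(kind = "specific", rank = rank))
  }
  if (grepl("^predominant@", s)) {
    body <- sub("^predominant@", "", s)
    parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
    stopifnot(parts[1L] %in% RANK_LADDER)
    return(list(kind = "predominant", rank = parts[1L],
                fraction = as.numeric(parts[2L])))
  }
  stop("unknown scenario: ", s, call. = FALSE)
}

# lineage index matrix (members x 8) realizing one family scenario
scenario_lineages <- function(sc, n) {
  ladder_pos <- function(r) match(r, RANK_LADDER)
  rows <- matrix(0L, n, 8L)
  if (sc$kind == "diverse") {
    for (m in seq_len(n)) {
      sk <- ((m - 1L) %% 3L) + 1L
      idx <- random_idx(sk)
      idx[2L] <- (((m - 1L) %/% 3L) %% mock_phyla_count(sk)) + 1L
      rows[m, ] <- idx
    }
    return(rows)
  }
  k <- ladder_pos(sc$rank)
  if (sc$kind == "specific") {
    base <- random_idx()
    for (m in seq_len(n)) {
      idx <- random_idx(base[1L])
      idx[1:k] <- base[1:k]
      if (k < 8L) idx[k + 1L] <- ((m - 1L) %% 3L) + 1L  # spread next rank
      rows[m, ] <- idx
    }
    return(rows)
  }
  if (sc$kind == "specific_pair") {
    base <- random_idx()
    for (m in seq_len(n)) {
      idx <- random_idx(base[1L])
      idx[1:(k - 1L)] <- base[1:(k - 1L)]
      idx[k] <- ((m - 1L) %% 2L) + 1L                  # two sister taxa
      rows[m, ] <- idx
    }
    return(rows)
  }
  # predominant: dominant block shares ranks 1..k; minority differs at
  # every label rank (different phylum under the same superkingdom pool)
  n_dom <- ceiling(sc$fraction * n)
  base <- random_idx()
  for (m in seq_len(n)) {
    if (m <= n_dom) {
      idx <- random_idx(base[1L])
      idx[1:k] <- base[1:k]
      if (k < 8L) idx[k + 1L] <- ((m - 1L) %% 3L) + 1L
    } else {
      repeat {
        idx <- random_idx()
        if (idx[1L] != base[1L] || idx[2L] != base[2L]) break
      }
    }
    rows[m, ] <- idx
  }
  rows
}

# intended label for a scenario (the planted truth)
scenario_truth_label <- function(sc, rows) {
  if (sc$kind == "diverse")
    return(list(scope = "organism_diverse", rank = NA_character_, taxa = ""))
  if (sc$kind == "specific") {
    lin <- lineage_from_idx(rows[1L, ])
    return(list(scope = "specific", rank = sc$rank,
                taxa = unname(lin[sc$rank])))
  }
  if (sc$kind == "specific_pair") {
    taxa <- sort(unique(apply(rows, 1L, function(r)
      lineage_from_idx(r)[[sc$rank]])))
    return(list(scope = "specific", rank = sc$rank,
                taxa = paste(taxa, collapse = " and ")))
  }
  lin <- lineage_from_idx(rows[1L, ])
  list(scope = "predominant", rank = sc$rank, taxa = unname(lin[sc$rank]))
}

# --- sequence evolution ---------------------------------------------------

kinase_motif <- function(length) {
  residues <- c("G", "G", "G", "K", "E", "H", "R", "D", "N", "D", "F", "G")
  positions <- round(seq(0.05, 0.90, length.out = length(residues)) * length)
  list(positions = positions, residues = residues)
}

sample_residues <- function(n, bg = aa_background()) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = bg)
}

mutate_member <- function(ancestor, motif_mask, divergence, indel_rate,
                          bg = aa_background()) {
  res <- ancestor
  subst <- runif(length(res)) < divergence & !motif_mask
  for (i in which(subst)) {
    alt <- AA_ALPHABET[AA_ALPHABET != res[i]]
    res[i] <- sample(alt, 1L, prob = bg[alt])
  }
  n_events <- rbinom(1L, length(res), indel_rate)
  for (e in seq_len(n_events)) {
    len <- rgeom(1L, 0.7) + 1L
    if (runif(1) < 0.5) {                        # insertion
      pos <- sample.int(length(res), 1L)
      res <- append(res, sample_residues(len, bg), after = pos)
      motif_mask <- append(motif_mask, rep(FALSE, len), after = pos)
    } else {                                     # deletion outside motifs
      free <- which(!motif_mask)
      if (length(free) == 0L) next
      start <- free[sample.int(length(free), 1L)]
      span <- start:min(start + len - 1L, length(res))
      span <- span[!motif_mask[span]]
      if (length(span) >= length(res)) next
      res <- res[-span]
      motif_mask <- motif_mask[-span]
    }
  }
  paste(res, collapse = "")
}

#' Generate a fully labeled synthetic dataset
#'
#' Per family, an ancestor domain is drawn i.i.d. from database residue
#' frequencies with 12 invariant motif columns (glycine-loop,
#' catalytic-loop and Mg-binding-like residues shared by all families);
#' members descend from the ancestor by seeded substitutions and geometric
#' indels, and carry lineages drawn from a mock rank ladder realizing the
#' family's taxonomic scenario.  The truth table records each family's
#' intended specificity label.  The output is a pure function of the
#' configuration (byte-identical across runs with the same seed).
#'
#' @param cfg A [scenario_config()].
#' @return A list: `sequences` (sequence table), `taxonomy` (taxonomy
#'   table), `truth` (per-family intended labels), `membership` (named
#'   vector id -> family).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(cfg$seed, {
    bg <- aa_background()
    motif <- kinase_motif(cfg$domain_length)
    seqs <- list()
    tax_rows <- list()
    truth_rows <- list()
    membership <- character(0)
    for (f in seq_len(cfg$n_families)) {
      family_id <- sprintf("F%02d", f)
      sc <- parse_scenario(cfg$scenarios[f])
      n <- cfg$members_per_family
      ancestor <- sample_residues(cfg$domain_length, bg)
      ancestor[motif$positions] <- motif$residues
      mask <- rep(FALSE, cfg$domain_length)
      mask[motif$positions] <- TRUE
      rows <- scenario_lineages(sc, n)
      for (m in seq_len(n)) {
        id <- sprintf("%09d", 100000000L + f * 1000L + m)
        residues <- mutate_member(ancestor, mask, cfg$within_family_divergence,
                                  cfg$indel_rate, bg)
        lin <- lineage_from_idx(rows[m, ])
        seqs[[id]] <- data.frame(id = id,
                                 organism = paste0(lin[["genus"]], "_",
                                                   lin[["species"]]),
                                 residues = residues, stringsAsFactors = FALSE)
        tax_rows[[id]] <- data.frame(id = id,
                                     organism = paste0(lin[["genus"]], "_",
                                                       lin[["species"]]),
                                     as.list(lin), stringsAsFactors = FALSE)
        membership[id] <- family_id
      }
      lab <- scenario_truth_label(sc, rows)
      truth_rows[[family_id]] <- data.frame(family = family_id,
                                            scenario = cfg$scenarios[f],
                                            scope = lab$scope, rank = lab$rank,
                                            taxa = lab$taxa,
                                            n_members = n,
                                            stringsAsFactors = FALSE)
    }
    list(sequences = do.call(rbind, c(seqs, list(make.row.names = FALSE))),
         taxonomy = do.call(rbind, c(tax_rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
         membership = membership)
  })
}

#' Generate a homologue hit table with known confirmation outcomes
#'
#' Stands in for a comprehensive-database homology search: for each planted
#' family one member is the query, and hits are sampled inside configured
#' pass/fail bands so the expected outcome of [confirm_specificity()] is
#' known.  Without contamination every hit is in-taxon and passes the
#' close-homologue filter, so every planted specific/predominant label
#' confirms; an entry in `contamination` adds out-of-taxon hits for one
#' family, either passing the filter (the family demotes) or failing it
#' (the family still confirms).
#'
#' @param dataset Output of [generate_dataset()].
#' @param n_hits_per_family In-taxon hits per family (default 5).
#' @param contamination Named list keyed by family id; each element a list
#'   with `n` (number of out-of-taxon hits) and `passing` (`TRUE` to emit
#'   them inside the filter bands, `FALSE` to emit them failing exactly one
#'   predicate).
#' @param seed Integer seed.
#' @return A hit `data.frame` (see [read_hit_table()]).
#' @export
generate_hit_table <- function(dataset, n_hits_per_family = 5L,
                               contamination = NULL, seed = 1L) {
  truth <- dataset$truth
  tax <- dataset$taxonomy
  with_seed(seed, {
    rows <- list()
    for (f in seq_len(nrow(truth))) {
      fam <- truth$family[f]
      members <- names(dataset$membership)[dataset$membership == fam]
      query <- members[1L]
      fam_tax <- tax[tax$id %in% members, , drop = FALSE]
      # homologues of a labeled family come from the labeled taxon: donor
      # lineages are restricted to in-taxon members (predominant families
      # also carry minority members whose lineages must not leak into hits)
      if (!is.na(truth$rank[f])) {
        taxa_f <- strsplit(truth$taxa[f], " and ", fixed = TRUE)[[1L]]
        fam_tax <- fam_tax[fam_tax[[truth$rank[f]]] %in% taxa_f, , drop = FALSE]
      }
      for (i in seq_len(n_hits_per_family)) {
        donor <- fam_tax[sample.int(nrow(fam_tax), 1L), , drop = FALSE]
        lin <- unlist(donor[1L, RANK_LADDER])
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query,
          subject_id = sprintf("U90_%s_%03d", fam, i),
          identity = runif(1, 0.45, 0.95),
          query_coverage = runif(1, 0.75, 1),
          evalue = 10^-runif(1, 6, 30),
          subject_lineage = lineage_to_path(lin),
          stringsAsFactors = FALSE)
      }
      cont <- contamination[[fam]]
      if (!is.null(cont)) {
        rank <- truth$rank[f]
        taxa <- strsplit(truth$taxa[f], " and ", fixed = TRUE)[[1L]]
        for (i in seq_len(cont$n)) {
          # out-of-taxon lineage: resample until the labeled rank differs
          repeat {
            idx <- random_idx()
            lin <- lineage_from_idx(idx)
            if (is.na(rank) || !lin[[rank]] %in% taxa) break
          }
          if (isTRUE(cont$passing)) {
            id_frac <- runif(1, 0.5, 0.9)
            cov <- runif(1, 0.75, 1)
            ev <- 10^-runif(1, 8, 20)
          } else {
            fail <- c("identity", "coverage", "evalue")[((i - 1L) %% 3L) + 1L]
            id_frac <- if (fail == "identity") runif(1, 0.05, 0.39)
                       else runif(1, 0.5, 0.9)
            cov <- if (fail == "coverage") runif(1, 0.2, 0.69)
                   else runif(1, 0.75, 1)
            ev <- if (fail == "evalue") 10^-runif(1, 0, 4)
                  else 10^-runif(1, 8, 20)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query,
            subject_id = sprintf("U90_%s_bad%03d", fam, i),
            identity = id_frac, query_coverage = cov, evalue = ev,
            subject_lineage = lineage_to_path(lin),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
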