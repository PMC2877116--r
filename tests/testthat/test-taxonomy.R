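# lineage fixtures echoing real prokaryotic taxa
myxo <- lin(superkingdom = "Bacteria", phylum = "Proteobacteria",
            class = "Deltaproteobacteria", order = "Myxococcales",
            suborder = "Cystobacterineae", family = "Myxococcaceae",
            genus = "Myxococcus", species = "Myxococcus_xanthus")
stig <- lin(superkingdom = "Bacteria", phylum = "Proteobacteria",
            class = "Deltaproteobacteria", order = "Myxococcales",
            suborder = "Cystobacterineae", family = "Cystobacteraceae",
            genus = "Stigmatella", species = "Stigmatella_aurantiaca")
angio <- lin(superkingdom = "Bacteria", phylum = "Proteobacteria",
             class = "Deltaproteobacteria", order = "Myxococcales",
             suborder = "Cystobacterineae", family = "Cystobacteraceae",
             genus = "Angiococcus", species = "Angiococcus_disciformis")
sulfo <- function(sp) lin(superkingdom = "Archaea", phylum = "Crenarchaeota",
                          class = "Thermoprotei", order = "Sulfolobales",
                          family = "Sulfolobaceae", genus = "Sulfolobus",
                          species = sp)
metallo <- lin(superkingdom = "Archaea", phylum = "Crenarchaeota",
               class = "Thermoprotei", order = "Sulfolobales",
               family = "Sulfolobaceae", genus = "Metallosphaera",
               species = "Metallosphaera_sedula")

test_that("lowest common rank finds the deepest shared taxon", {
  got <- lowest_common_rank(list(sulfo("Sulfolobus_solfataricus"),
                                 sulfo("Sulfolobus_tokodaii"),
                                 sulfo("Sulfolobus_acidocaldarius")))
  expect_equal(got, list(rank = "genus", taxon = "Sulfolobus"))

  got2 <- lowest_common_rank(list(myxo, stig, angio))
  expect_equal(got2, list(rank = "suborder", taxon = "Cystobacterineae"))

  expect_null(lowest_common_rank(list(myxo, sulfo("x"))))
  expect_error(lowest_common_rank(list()), "at least one lineage")
})

test_that("missing ranks in a minority do not block agreement; heavy missingness does", {
  # deepest shared rank across these three is the suborder
  partial <- angio[setdiff(names(angio), "suborder")]
  many <- c(rep(list(myxo), 5), rep(list(stig), 4), list(partial))
  expect_equal(lowest_common_rank(many),
               list(rank = "suborder", taxon = "Cystobacterineae"))
  # when half the lineages lack the suborder, the claim falls back to order
  few <- c(rep(list(myxo), 3), rep(list(stig), 2), rep(list(partial), 5))
  expect_equal(lowest_common_rank(few, min_rank_coverage = 0.9),
               list(rank = "order", taxon = "Myxococcales"))
})

test_that("specificity labels: specific, sister pairs, predominant, diverse", {
  # all members one order
  chlam <- function(g, s) lin(superkingdom = "Bacteria", phylum = "Chlamydiae",
                              class = "Chlamydiia", order = "Chlamydiales",
                              family = "Chlamydiaceae", genus = g, species = s)
  l1 <- assign_specificity(list(chlam("Chlamydia", "a"),
                                chlam("Chlamydia", "b"),
                                chlam("Chlamydophila", "c"),
                                chlam("Chlamydophila", "d")))
  # two sister genera under one family: reported as a genus pair
  expect_equal(l1$scope, "specific")
  expect_equal(l1$rank, "genus")
  expect_equal(l1$taxa, c("Chlamydia", "Chlamydophila"))
  expect_equal(format(l1), "Genus Chlamydia and Chlamydophila specific")

  l1b <- assign_specificity(list(chlam("Chlamydia", "a"),
                                 chlam("Chlamydia", "b"),
                                 chlam("Chlamydophila", "c")),
                            max_taxa_per_rank = 1)
  expect_equal(l1b$rank, "family")
  expect_equal(l1b$taxa, "Chlamydiaceae")

  l2 <- assign_specificity(list(sulfo("a"), sulfo("b"), metallo),
                           max_taxa_per_rank = 2)
  expect_equal(l2$taxa, c("Metallosphaera", "Sulfolobus"))
  expect_equal(format(l2), "Genus Metallosphaera and Sulfolobus specific")

  # 3 of 4 members one phylum, the fourth elsewhere: phylum predominant
  cyano <- function(g) lin(superkingdom = "Bacteria", phylum = "Cyanobacteria",
                           class = paste0("c", g), order = paste0("o", g),
                           family = paste0("f", g), genus = g, species = "s")
  l3 <- assign_specificity(list(cyano("Synechocystis"), cyano("Anabaena"),
                                cyano("Nostoc"), myxo))
  expect_equal(l3$scope, "predominant")
  expect_equal(l3$rank, "phylum")
  expect_equal(l3$taxa, "Cyanobacteria")
  expect_equal(l3$dominant_fraction, 0.75)
  expect_equal(format(l3), "Phylum Cyanobacteria predominant")

  # scattered members: organism diverse
  l4 <- assign_specificity(list(myxo, sulfo("a"), cyano("Nostoc"),
                                lin(superkingdom = "Bacteria",
                                    phylum = "Firmicutes", genus = "Bacillus")))
  expect_equal(l4$scope, "organism_diverse")
  expect_null(l4$rank)
  expect_equal(format(l4), "Organism diverse")

  expect_error(assign_specificity(list(myxo, lin(superkingdom = NA))),
               "without lineage")
})

test_that("predominance threshold 1.0 yields only specific or diverse labels", {
  sets <- list(
    list(myxo, stig, angio),
    list(myxo, sulfo("a"), sulfo("b"), sulfo("c")),
    list(sulfo("a"), sulfo("b"), metallo, myxo))
  for (s in sets) {
    l <- assign_specificity(s, predominance_threshold = 1.0)
    expect_true(l$scope %in% c("specific", "organism_diverse"))
  }
})

test_that("hit filtering applies the three inclusive thresholds exactly", {
  expect_equal(nrow(filter_hits(hit_row(identity = 0.39, coverage = 0.80,
                                        evalue = 1e-9))), 0L)
  expect_equal(nrow(filter_hits(hit_row(identity = 0.40, coverage = 0.70,
                                        evalue = 1e-5))), 1L)
  expect_equal(nrow(filter_hits(hit_row(identity = 0.40, coverage = 0.699,
                                        evalue = 1e-9))), 0L)
  expect_equal(nrow(filter_hits(hit_row(identity = 0.40, coverage = 0.70,
                                        evalue = 1.1e-5))), 0L)

  set.seed(44)
  hits <- do.call(rbind, lapply(1:1000, function(i)
    hit_row(subject = paste0("s", i), identity = runif(1),
            coverage = runif(1), evalue = 10^-runif(1, 0, 10))))
  got <- filter_hits(hits)
  want <- hits[hits$identity >= 0.40 & hits$query_coverage >= 0.70 &
                 hits$evalue <= 1e-5, ]
  expect_equal(got, want)
})

test_that("confirmation truth table: all passing/in-taxon combinations", {
  in_lin <- lin(superkingdom = "Bacteria", phylum = "Cyanobacteria")
  out_lin <- lin(superkingdom = "Bacteria", phylum = "Firmicutes")
  for (scope in c("specific", "predominant")) {
    for (passing in c(TRUE, FALSE)) {
      for (in_taxon in c(TRUE, FALSE)) {
        label <- tax_label(scope, "phylum", "Cyanobacteria",
                           dominant_fraction = if (scope == "specific") 1 else 0.8)
        h <- hit_row(identity = if (passing) 0.8 else 0.2,
                     coverage = 0.9, evalue = 1e-10,
                     lineage = if (in_taxon) in_lin else out_lin)
        got <- confirm_specificity(label, h)
        if (passing && !in_taxon) {
          expect_equal(got$status, "demoted")
          expect_equal(got$scope, "organism_diverse")
        } else {
          expect_equal(got$status, "confirmed")
          expect_equal(got$scope, scope)
        }
      }
    }
  }
})

test_that("confirmation edge cases: empty hits, filtered counter-evidence, reuse", {
  label <- tax_label("specific", "phylum", "Cyanobacteria", dominant_fraction = 1)
  empty <- filter_hits(hit_row())[0, ]
  expect_equal(confirm_specificity(label, empty)$status, "confirmed")

  # counter-evidence below coverage threshold is filtered out
  weak <- hit_row(identity = 0.8, coverage = 0.5, evalue = 1e-12,
                  lineage = lin(superkingdom = "Bacteria", phylum = "Firmicutes"))
  expect_equal(confirm_specificity(label, weak)$status, "confirmed")

  # a pair label accepts hits from either sister taxon
  pair <- tax_label("specific", "genus", c("Metallosphaera", "Sulfolobus"),
                    dominant_fraction = 1)
  h <- rbind(hit_row(lineage = lin(superkingdom = "Archaea", genus = "Sulfolobus")),
             hit_row(subject = "s2",
                     lineage = lin(superkingdom = "Archaea",
                                   genus = "Metallosphaera")))
  expect_equal(confirm_specificity(pair, h)$status, "confirmed")

  # subject lineage lacking the label's rank counts as counter-evidence
  norank <- hit_row(lineage = lin(superkingdom = "Bacteria"))
  expect_equal(confirm_specificity(label, norank)$status, "demoted")

  done <- confirm_specificity(label, empty)
  expect_error(confirm_specificity(done, empty), "already confirmed")

  # organism-diverse labels confirm as they stand
  div <- tax_label("organism_diverse")
  expect_equal(confirm_specificity(div, h)$status, "confirmed")
})

test_that("demotion is monotone in evidence", {
  label <- tax_label("specific", "phylum", "Cyanobacteria", dominant_fraction = 1)
  good <- hit_row(lineage = lin(superkingdom = "Bacteria",
                                phylum = "Cyanobacteria"))
  bad <- hit_row(subject = "s9",
                 lineage = lin(superkingdom = "Bacteria", phylum = "Firmicutes"))
  expect_equal(confirm_specificity(label, good)$status, "confirmed")
  expect_equal(confirm_specificity(label, rbind(good, bad))$status, "demoted")
  # once diverse, more hits never upgrade
  div <- tax_label("organism_diverse")
  expect_equal(confirm_specificity(div, rbind(good, bad))$scope,
               "organism_diverse")
})

test_that("label summaries count scopes and reject unresolved labels", {
  mk_sf <- function(id, label) list(cluster_id = id,
                                    representative_id = paste0("r", id),
                                    member_ids = paste0("m", id, 1:4),
                                    tax_label = label)
  resolved <- function(l) { l$status <- "confirmed"; l }
  subs <- structure(list(
    mk_sf(1, resolved(tax_label("specific", "phylum", "Cyanobacteria",
                                dominant_fraction = 1))),
    mk_sf(2, resolved(tax_label("predominant", "phylum", "Actinobacteria",
                                dominant_fraction = 0.8))),
    mk_sf(3, resolved(tax_label("organism_diverse")))),
    class = "kin_subfamilies")
  out <- summarize_labels(subs)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "scope_counts"),
               c(specific = 1L, predominant = 1L, organism_diverse = 1L))
  expect_equal(out$label[1], "Phylum Cyanobacteria specific")

  expect_equal(nrow(summarize_labels(structure(list(),
                                               class = "kin_subfamilies"))), 0L)

  subs[[2]]$tax_label$status <- "tentative"
  expect_error(summarize_labels(subs), "unresolved")
})
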