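---
title: "Classifying prokaryotic Ser/Thr kinase catalytic domains with prokclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying prokaryotic Ser/Thr kinase catalytic domains with prokclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prokclass)
```

## The problem

Most serine/threonine protein kinases found in archaeal and eubacterial
genomes cannot be placed in the classical eukaryotic kinase subfamilies:
prokaryotic catalytic domains are too divergent from the eukaryotic
sequences those subfamilies were defined on.  `prokclass` implements a
sequence-only classification framework for these enzymes.  Its sole unit of
comparison is the conserved catalytic kinase domain (roughly 250 residues);
everything downstream — subfamily membership, taxonomic-specificity labels,
dendrograms, assignment of new sequences — derives from pairwise and
multiple alignments of that domain.

The pipeline has five stages:

1. **Detection** (`build_pssms()`, `scan_profiles()`, `detect_kinases()`):
   find kinase catalytic domains with per-sequence position-specific
   scoring matrices built from a family alignment.
2. **Clustering** (`greedy_cluster()`, `select_subfamilies()`): greedy
   incremental clustering at a 40% identity threshold; clusters with at
   least 4 members become the named subfamilies of the classification.
3. **Taxonomy labeling** (`assign_specificity()`, `confirm_specificity()`,
   `summarize_labels()`): label each subfamily *specific*, *predominant* or
   *organism-diverse* at a rank between phylum and genus, then confirm the
   label against close homologues from a comprehensive sequence database.
4. **Trees** (`progressive_msa()`, `distance_matrix()`, `nj_tree()`,
   `bootstrap_supports()`): per-subfamily dendrograms with bootstrap
   supports.
5. **Classification of new sequences** (`assign_subfamily()`,
   `batch_classify()`): place a newly identified catalytic domain into the
   established subfamilies, or report it unclassified.

`run_pipeline()` chains stages 2-4 over a directory of inputs and writes
every artifact with a checksummed manifest.

## Alignment and identity conventions

All pairwise alignment is global (Needleman–Wunsch) with affine gaps over
BLOSUM62, gap open 11, gap extension 1; a gap of length $k$ costs
$11 + k$.  These are the standard protein-search defaults; the clustering
and homologue thresholds below inherit their meaning from tools that use
them, and all three parameters are configurable through `align_params()`.
Two conventions matter enough to state precisely:

* **Percent identity** is the number of identical aligned residue pairs
  divided by the length of the *shorter* input sequence.  This is the
  convention of greedy identity-clustering tools, and the 40% threshold
  below assumes it.  With any longer denominator, cluster granularity
  changes noticeably.
* **Query coverage** of a sequence is the fraction of its residues aligned
  opposite non-gap positions of the partner.  The 70% coverage rules below
  use this definition on the query side.

Dynamic-programming tracebacks break ties by preferring the diagonal move,
then the vertical, then the horizontal, so alignments (not just scores) are
deterministic.  The same C++ kernel serves residue-residue, profile-profile
and query-PSSM alignment; scores are verified in the test suite against an
independent plain-R dynamic program and against an external pairwise
aligner.

## Greedy clustering into subfamilies

Sequences are processed in length-descending order (ties broken by id); a
sequence joins the first cluster whose *representative* aligns at
$\ge 40\%$ identity, else founds a new cluster.  Consequences worth
knowing:

* Representatives of distinct clusters are pairwise below the threshold —
  this follows from the joining rule and is asserted property-style in the
  tests.  Non-representative members of different clusters can exceed the
  threshold; the framework's stronger informal claim holds for
  representatives only.
* The method is deterministic but order-dependent, like the original
  clustering tools; exact cluster-for-cluster agreement with any
  particular external tool release is out of scope because those tools'
  k-mer pre-filters prune different alignment candidates.  An optional
  5-mer containment pre-filter is available (`kmer_prefilter = TRUE`) and
  off by default, because it can change borderline memberships.
* The threshold is inclusive ($\ge 0.40$), consistent with the
  close-homologue rule "40% or greater".

Subfamilies are the clusters with at least `min_size = 4` members,
retaining their original cluster ids.

## Taxonomic-specificity labels

Each member carries a lineage over the fixed rank ladder
`superkingdom > phylum > class > order > suborder > family > genus >
species`.  Labels are decided per subfamily, walking ranks deepest-first
over the phylum..genus range:

* **specific** — every member carries the same taxon at the rank.  If the
  members span *exactly two* sister taxa one rank deeper, the pair is
  reported at the deeper rank ("Genus X and Y specific"); never three or
  more.
* **predominant** — no rank has full agreement, but a single taxon covers
  at least `predominance_threshold` of the members at some rank (again
  deepest-first).  The boundary between "predominant" and
  "organism-diverse" is genuinely a judgement call — a cluster that is
  98% one phylum with a couple of stray members reads as predominant,
  while 60/40 mixtures read as diverse — so the threshold is an exposed
  parameter, default 0.75 (contamination under a quarter of the membership
  still yields a predominant label), and the realized dominant fraction is
  carried in every label and report.
* **organism_diverse** — neither of the above.

Superkingdom-level agreement alone (e.g. "all bacteria") is deliberately
not a label: mixed bacterial/archaeal clusters whose members span many
phyla are organism-diverse in this scheme, which matches how such clusters
are described in practice.

Missing ranks are tolerated: a lineage lacking a rank neither supports nor
vetoes agreement there, provided at least 90% of the members do carry the
rank (suborder, in particular, is sparsely annotated in real taxonomies);
below that coverage the rank is not claimed and the label falls back to a
shallower rank.

### Confirmation against homologue hits

A label derived from cluster members alone is only **tentative**: the
member set reflects the genomes that happened to be sequenced.
`confirm_specificity()` therefore checks the label against a table of
close homologues (standing in for a comprehensive-database search).  A hit
counts only if it passes all three close-homologue criteria — identity
$\ge 0.40$, query coverage $\ge 0.70$, E-value $\le 10^{-5}$, all bounds
inclusive.  If every passing hit carries the label's taxon at the label's
rank, the label is **confirmed**; one passing out-of-taxon hit **demotes**
the subfamily to organism-diverse.  An empty passing set confirms — the
operation is a veto, not a vote, so demotion is monotone in evidence.  A
passing hit whose lineage simply lacks the label's rank also demotes: an
unplaceable close homologue cannot support a placement claim.  The
original procedure searched one randomly chosen member per cluster; the
operation accepts hits for any subset of members.

## Profile-based kinase detection

`build_pssms()` implements the multiple-profile idea: *every* row of a
family alignment becomes the reference of its own PSSM, which removes the
bias a single arbitrary reference introduces.  For reference row $r$,
columns gapped in $r$ are dropped and each remaining column scores amino
acid $a$ as

$$ s(a) = 2\log_2 \frac{c_a + \tau\,b_a}{(n + \tau)\, b_a} $$

in half-bit units, with $c_a$ the residue count in the column, $n$ the
column's residue total, $b_a$ the background frequency and $\tau$ the
pseudocount (default 1).  A column whose frequencies equal the background
scores zero, and growing $\tau$ shrinks all scores monotonically toward
zero — both covered by tests.

`scan_profiles()` runs Smith–Waterman of a query against each profile's
column scores.  Significance is assessed with an *empirical* extreme-value
null: the query is shuffled `null_samples` times (seeded), each shuffle is
scored against the profile, and a Gumbel curve is moment-fitted to the
null scores; the hit's E-value is the fitted upper-tail probability.  The
established search tools delegate this statistic to analytic parameters
whose derivation they do not expose; an explicit seeded null is
reproducible and directly testable (decoy queries of background
composition are rejected at well over 95% at the default thresholds).
Three named presets carry the hit criteria of the supported search routes:
`mulpssm` (E $\le 10^{-4}$ and *more than* 70% of the profile covered —
strictly greater, as that route specifies), `hmm` (E $\le 0.01$), and
`psiblast` (E $\le 10^{-4}$, coverage $\ge 70\%$ inclusive).  Profile
coverage is matched profile columns over profile length.

## Distances, trees and supports

Per-subfamily alignments come from `progressive_msa()`: a neighbor-joining
guide tree on pairwise p-distances, profiles merged leaf-to-root by
profile-profile Needleman–Wunsch with expected-substitution column scores.
No iterative refinement and no sequence weighting: the framework consumes
identities and distances, not fine column placement, and the simpler
procedure is deterministic.

`distance_matrix()` reports p-dissimilarity: $1 -$ (identical columns /
mutually ungapped columns) per pair, the plain observed-difference measure
(no multiple-hit correction); a pair with no mutually ungapped columns is
an error naming the pair rather than a silent `NA`.

`nj_tree()` is Saitou–Nei neighbor joining (via the ape implementation)
with two post-conditions: deterministic tie handling, and negative branch
lengths clamped to zero with the deficit moved to the adjacent edge so
path lengths through the node are preserved (raw lengths are kept in an
attribute).  On additive matrices the generating tree is recovered exactly
— topology and branch lengths — which the tests verify for up to eight
taxa against exhaustive topology enumeration.

`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and reports for each internal edge of
the full-data tree the percentage of replicates containing the same leaf
bipartition.  Supports annotate the full-data tree only (no consensus tree
is built), matching how such dendrograms are usually presented.  The
default is 1000 replicates; the bundled tests and the acceptance script
use 100, which is ample for the small, well-separated families they build.

## Classifying new sequences

`assign_subfamily()` aligns a query to every member of every reference
subfamily and returns the best hit passing identity $\ge 0.40$ and query
coverage $\ge 0.70$, with ties broken by higher identity then lower
cluster id; anything else is `unclassified` (a value, not an error).
All-members search is the default; a representatives-first fast mode
(prescreen at threshold $-$ 0.05) is available and documented as an
approximation.  Self-consistency — every reference member classifies into
its own subfamily — is asserted in the tests.

## The synthetic scenario generator

`generate_dataset()` produces fully labeled datasets exercising every
stage without any downloads: per family, an ancestor domain (default 250
residues) is drawn i.i.d. from database residue frequencies with 12
invariant motif columns mimicking the universally conserved catalytic
positions (glycine-rich loop, catalytic and Mg-binding residues); members
descend by seeded point substitutions (default 0.10 substitutions per
non-motif site) and geometric indels (length parameter 0.7, events avoid
motif columns so alignments stay well-posed).  Lineages come from a mock
ladder — three superkingdoms, ten phyla, fan-out three below — large
enough to realize every label shape, including two-sister-genera labels.
Scenario strings (`specific@rank`, `specific_pair@rank`,
`predominant@rank:fraction`, `diverse`) plant the intended label per
family, and deeper ranks are spread round-robin so no accidental deeper
agreement contradicts the plant.  The default scenario is 8 families of 6
members; at 10% divergence two members share about 82% identity
(motif fraction $+ (1-d)^2$ elsewhere), far above the 0.40 clustering
threshold, while independent ancestors keep between-family identity below
~10%.

What the generator deliberately does **not** emulate: realistic
phylogenetic site-rate heterogeneity, selection, compositional bias across
clades, fragmentary domains, or taxonomies with conflicting annotations.
Passing tests on synthetic data therefore demonstrate the *logic* of the
pipeline — threshold handling, label algebra, determinism, recovery of
planted structure under honest noise — not field performance on any real
genome collection, where domain boundaries and annotation quality dominate.

`generate_hit_table()` emits homologue hits inside configured pass/fail
bands so every confirmation outcome is known in advance; in-taxon hits for
labeled families are drawn from lineages carrying the labeled taxon
(minority members of predominant families do not leak into the hit table,
mirroring how homologues of the dominant taxon dominate a real search).

## Numerical and design notes

* All randomness (generator, nulls, bootstrap, pipeline) flows through
  explicit integer seeds; RNG state of the caller is restored afterwards.
  Same seed, same bytes — asserted for the generator and the pipeline
  manifest.
* The identity denominator (shorter sequence), the inclusive 40%/70%
  homologue bounds and the *strict* "more than 70%" profile-coverage bound
  are each implemented exactly as their respective source rules state,
  even though the asymmetry is easy to miss.
* E-value fitting uses moments (location/scale from mean and standard
  deviation of the null scores); with 50+ null samples this is stable, and
  E-value monotonicity in score is tested.
* Degenerate inputs fail fast with named offenders: empty sequences,
  rows entirely gapped, pairs with no mutually ungapped columns, members
  missing from the taxonomy, partitions with duplicated members.
* Problem sizes in the shipped tests and acceptance script (8 x 6
  sequences, 100-replicate bootstraps, 100 decoys, 50-100-sample nulls)
  were chosen as the smallest sizes at which every property is
  unambiguous; all of them scale up through ordinary arguments.

## Known limitations

* Clustering reproduces the *method*, not any specific external tool's
  bit-exact output; on the published 993-domain dataset the subfamily
  count is expected close to, but not necessarily exactly, the reported
  value (that sequence collection is not redistributed with the package;
  the dataset-scale acceptance test activates when a copy is placed under
  `inst/extdata/reference/`).
* Profile search is a single PSSM engine with empirical statistics, not a
  full profile-HMM with match/insert/delete states.
* Distances are uncorrected p-dissimilarities; no evolutionary-model
  correction is applied, which the per-cluster trees inherit.
* The taxonomy module trusts the supplied lineages; there is no name
  resolution or synonym handling.
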