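# Fixtures built in code at test time.

AA20 <- prokclass::AA_ALPHABET

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# a gap-free family MSA: one ancestor, members with point substitutions
make_family_msa <- function(n = 6L, len = 120L, divergence = 0.05, seed = 11L,
                            prefix = "m") {
  set.seed(seed)
  anc <- sample(AA20, len, TRUE)
  rows <- vapply(seq_len(n), function(i) {
    r <- anc
    mut <- runif(len) < divergence
    r[mut] <- vapply(which(mut), function(k)
      sample(setdiff(AA20, r[k]), 1L), character(1))
    paste(r, collapse = "")
  }, character(1))
  names(rows) <- sprintf("%s%02d", prefix, seq_len(n))
  structure(rows, class = "kin_msa")
}

# the default synthetic scenario used across tests (one fixed seed)
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(seed = 101L)
      cache <<- list(cfg = cfg, ds = generate_dataset(cfg))
    }
    cache
  }
})

# lineage vector helper: named character over given ranks
lin <- function(...) {
  v <- c(...)
  stopifnot(all(names(v) %in% prokclass::RANK_LADDER))
  v
}

# quick hit-row constructor
hit_row <- function(query = "q1", subject = "s1", identity = 0.8,
                    coverage = 0.9, evalue = 1e-10,
                    lineage = c(superkingdom = "Bacteria")) {
  data.frame(query_id = query, subject_id = subject, identity = identity,
             query_coverage = coverage, evalue = evalue,
             subject_lineage = prokclass:::lineage_to_path(lineage),
             stringsAsFactors = FALSE)
}

tmpfile <- function() tempfile(fileext = ".txt")
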