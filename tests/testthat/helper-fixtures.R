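# shared fixtures; heavyweight suites are built once per test run

.fixture_env <- new.env(parent = emptyenv())

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small 4-taxon suite for unit tests
tiny_suite <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- suite_config(taxa = paste0("tax", 1:4), genome_length = 6e4,
                        n_loci = 15L, core_length = 300L, flank_length = 200L,
                        divergence = 0.02, n_repeats = 2L, seed = 42L)
    .fixture_env$tiny <- generate_suite(cfg)
  }
  .fixture_env$tiny
}

# the acceptance-criterion suite: 7 taxa, 1 Mb, 300 loci (core 300, flank
# 400), 5% pairwise core divergence (2.5% per lineage), no paralogs
acceptance_suite <- function() {
  if (is.null(.fixture_env$acc)) {
    cfg <- suite_config(taxa = paste0("tax", 1:7), genome_length = 1e6,
                        n_loci = 300L, core_length = 300L, flank_length = 400L,
                        divergence = 0.025, n_repeats = 10L, seed = 20260912L)
    .fixture_env$acc <- generate_suite(cfg)
  }
  .fixture_env$acc
}

# map pipeline locus ids back to planted registry loci via base coordinates
match_planted <- function(putative, registry) {
  vapply(seq_len(nrow(putative)), function(i) {
    hit <- which(putative$start[i] < registry$loci$region_end &
                 putative$end[i] > registry$loci$region_start &
                 putative$contig[i] == registry$loci$contig)
    if (length(hit) == 1L) registry$loci$locus[hit] else NA_character_
  }, "")
}

mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
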