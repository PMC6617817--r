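test_that("suite generation is deterministic and respects zero divergence", {
  cfg <- suite_config(taxa = paste0("t", 1:3), genome_length = 3e4,
                      n_loci = 5L, divergence = 0, background_divergence = 0,
                      n_repeats = 1L, seed = 101L)
  s1 <- generate_suite(cfg)
  s2 <- generate_suite(cfg)
  for (tx in cfg$taxa)
    expect_identical(s1$assemblies[[tx]]$contigs, s2$assemblies[[tx]]$contigs)
  # zero divergence everywhere: all taxa byte-identical
  expect_identical(s1$assemblies$t1$contigs, s1$assemblies$t2$contigs)
  expect_identical(s1$assemblies$t1$contigs, s1$assemblies$t3$contigs)
  # different seed, different genomes
  s3 <- generate_suite(suite_config(taxa = paste0("t", 1:3),
                                    genome_length = 3e4, n_loci = 5L,
                                    divergence = 0, background_divergence = 0,
                                    n_repeats = 1L, seed = 102L))
  expect_false(identical(s1$assemblies$t1$contigs, s3$assemblies$t1$contigs))
})

test_that("registry coordinates are valid and regions are disjoint", {
  s <- tiny_suite()
  reg <- s$registry$loci
  G <- s$config$genome_length
  expect_true(all(reg$region_start >= 0 & reg$region_end <= G))
  expect_true(all(reg$core_start >= reg$region_start))
  expect_true(all(reg$core_end <= reg$region_end))
  expect_true(all(reg$core_end - reg$core_start == s$config$core_length))
  ord <- order(reg$region_start)
  expect_true(all(diff(reg$region_start[ord]) > 0))
  expect_true(all(reg$region_start[ord][-1] >= reg$region_end[ord][-nrow(reg)]))
  # repeats are soft-masked in every assembly
  rp <- s$registry$repeats[1, ]
  for (tx in s$config$taxa) {
    sub <- substr(s$assemblies[[tx]]$contigs[["chr1"]], rp$start + 1, rp$end)
    expect_true(grepl("^[acgt]+$", sub))
  }
})

test_that("realized core divergence tracks the configured rate", {
  cfg <- suite_config(taxa = paste0("t", 1:3), genome_length = 1.2e5,
                      n_loci = 40L, core_length = 300L, flank_length = 150L,
                      divergence = c(t1 = 0.02, t2 = 0.05, t3 = 0.1),
                      n_repeats = 0L, seed = 103L)
  s <- generate_suite(cfg)
  anc <- s$ancestor
  reg <- s$registry$loci
  for (tx in cfg$taxa) {
    diffs <- 0L; total <- 0L
    g <- s$assemblies[[tx]]$contigs[["chr1"]]
    for (i in seq_len(nrow(reg))) {
      a <- substr(anc, reg$core_start[i] + 1, reg$core_end[i])
      b <- substr(g, reg$core_start[i] + 1, reg$core_end[i])
      diffs <- diffs + sum(strsplit(a, "")[[1]] != toupper(strsplit(b, "")[[1]]))
      total <- total + nchar(a)
    }
    rate <- cfg$divergence[[tx]]
    se <- sqrt(rate * (1 - rate) / total)
    expect_gt(total, 10000)
    expect_lt(abs(diffs / total - rate), 3 * se + 1e-9)
  }
})

test_that("presence map and mapped intervals agree", {
  presence <- matrix(TRUE, 10, 3, dimnames = list(NULL, paste0("t", 1:3)))
  presence[3, "t2"] <- FALSE
  presence[7, "t3"] <- FALSE
  cfg <- suite_config(taxa = paste0("t", 1:3), genome_length = 4e4,
                      n_loci = 10L, presence = presence, n_repeats = 0L,
                      seed = 104L)
  s <- generate_suite(cfg)
  expect_equal(nrow(s$mapped$t2), 9L)
  expect_equal(nrow(s$mapped$t3), 9L)
  m2 <- suite_mapped_intervals(s, base = "t2")
  # base t2: locus absent in t2 is absent from every mapping
  absent <- s$registry$loci$locus[!s$registry$presence[, "t2"]]
  expect_false(absent %in% m2$t1$name)
  expect_false(absent %in% m2$t3$name)
})

test_that("paralog copies are planted with the requested extra divergence", {
  par <- data.frame(locus = "locus-002", taxon = "t2", divergence = 0.05,
                    stringsAsFactors = FALSE)
  cfg <- suite_config(taxa = paste0("t", 1:3), genome_length = 5e4,
                      n_loci = 8L, paralogs = par, n_repeats = 0L, seed = 105L)
  s <- generate_suite(cfg)
  pp <- s$registry$paralogs
  expect_equal(nrow(pp), 1L)
  li <- match("locus-002", s$registry$loci$locus)
  g2 <- s$assemblies$t2$contigs[["chr1"]]
  orig <- substr(g2, s$registry$loci$region_start[li] + 1,
                 s$registry$loci$region_end[li])
  copy <- substr(g2, pp$start + 1, pp$end)
  p_obs <- mean(strsplit(orig, "")[[1]] != strsplit(copy, "")[[1]])
  expect_lt(abs(p_obs - 0.05), 0.02)
  # other taxa carry no copy: the slot region stays background-diverged
  g1 <- s$assemblies$t1$contigs[["chr1"]]
  slot1 <- substr(g1, pp$start + 1, pp$end)
  expect_gt(mean(strsplit(slot1, "")[[1]] != strsplit(copy, "")[[1]]), 0.15)
})

test_that("corrupt_mapping drops and jitters reproducibly", {
  x <- intervals("c1", seq(0, 99900, by = 100), seq(50, 99950, by = 100))
  expect_equal(corrupt_mapping(x, 0, 0L, seed = 1), x)
  expect_equal(nrow(corrupt_mapping(x, 1, 0L, seed = 1)), 0L)
  set.seed(999)  # corrupt_mapping must not depend on ambient RNG state
  c1 <- corrupt_mapping(x, 0.2, 5L, seed = 7)
  c2 <- corrupt_mapping(x, 0.2, 5L, seed = 7)
  expect_identical(c1, c2)
  # binomial bound: survivors within 3 sigma of 800
  expect_lt(abs(nrow(c1) - 800), 3 * sqrt(1000 * 0.2 * 0.8) + 1)
  expect_true(all(c1$start >= 0 & c1$end > c1$start))
  expect_false(all(c1$start %% 100 == 0))   # jitter moved boundaries
})

test_that("marker alignments come from loci present everywhere", {
  s <- tiny_suite()
  mk <- suite_marker_alignments(s, n = 3)
  expect_length(mk, 3L)
  for (m in mk) {
    expect_equal(sort(names(m)), sort(s$config$taxa))
    expect_equal(unique(nchar(m)), s$config$core_length)
  }
})
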