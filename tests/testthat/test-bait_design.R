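fake_putative <- function(lens, gap = 50) {
  start <- cumsum(c(100, head(lens, -1) + gap))
  data.frame(locus = sprintf("uce-%d", seq_along(lens)), contig = "c1",
             start = start, end = start + lens, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("tile_baits covers every base with the right-aligned rule", {
  set.seed(13)
  asm <- genome_assembly("base", c(c1 = random_dna(5000)))
  cfg <- ucekit_config()

  p <- fake_putative(c(120, 180, 200, 1100))
  b <- tile_baits(p, asm, cfg)
  counts <- table(b$locus)
  expect_equal(as.integer(counts[c("uce-1", "uce-2", "uce-3", "uce-4")]),
               c(1L, 2L, 3L, ceiling((1100 - 120) / 60) + 1L))
  expect_equal(b$locus_offset[b$locus == "uce-3"], c(0, 60, 80))
  expect_equal(b$locus_offset[b$locus == "uce-2"], c(0, 60))
  # every locus base covered, no bait beyond bounds
  for (loc in unique(b$locus)) {
    len <- p$end[p$locus == loc] - p$start[p$locus == loc]
    off <- b$locus_offset[b$locus == loc]
    covered <- logical(len)
    for (s in off) covered[(s + 1):(s + 120)] <- TRUE
    expect_true(all(covered))
    expect_true(all(off + 120 <= len))
    expect_equal(unique(nchar(b$sequence[b$locus == loc])), 120L)
  }
  # sequences come from the base assembly
  i <- which(b$locus == "uce-4")[1]
  expect_equal(b$sequence[i],
               toupper(substr(asm$contigs[["c1"]], p$start[4] + 1, p$start[4] + 120)))

  expect_message(tile_baits(fake_putative(c(80, 150)), asm, cfg), "skipped 1")
})

test_that("filter_baits labels the first failing rule and preserves order", {
  cfg <- ucekit_config(max_ambiguous = 0)
  mk <- function(seqs) {
    ps <- probe_set(sprintf("uce-%d", seq_along(seqs)), 1, "b", "t", gsub("[a-z]", "N", seqs))
    ps$raw_sequence <- seqs
    ps
  }
  allA <- strrep("A", 120)
  allGC <- strrep("GC", 60)
  oneN <- paste0(strrep("AG", 55), "N", strrep("C", 9))
  masked <- paste0(strrep("a", 50), strrep("AG", 35))
  ok <- strrep("ACGT", 30)
  f <- filter_baits(mk(c(allA, allGC, oneN, ok)), cfg)
  expect_equal(f$rejected$reason, c("gc_low", "gc_high", "ambiguous"))
  expect_equal(f$kept$locus, "uce-4")
  f2 <- filter_baits(mk(c(oneN, ok)), ucekit_config(max_ambiguous = 2))
  expect_equal(nrow(f2$rejected), 0L)
  # mask filter uses the case-preserving sequence
  ps <- probe_set("uce-1", 1, "b", "t", toupper(masked))
  ps$raw_sequence <- masked
  expect_equal(filter_baits(ps, cfg)$rejected$reason, "masked")
})

test_that("candidate thresholds are monotone and paralogs are excluded", {
  s <- tiny_suite()
  run <- putative_loci(s$mapped, 1, base_assembly = s$assemblies$tax1,
                       base_taxon = "tax1")
  baits <- filter_baits(tile_baits(run, s$assemblies$tax1))$kept
  c1 <- candidate_loci(baits, s$assemblies, required_taxa = 1)
  c4 <- candidate_loci(baits, s$assemblies, required_taxa = 4)
  expect_true(all(c4$loci$locus %in% c1$loci$locus))
  expect_equal(nrow(c4$loci), 15L)   # all planted loci found everywhere

  # plant a second copy of one locus core in tax2: that locus must drop out
  reg <- s$registry$loci
  g2 <- s$assemblies$tax2$contigs[["chr1"]]
  core5 <- substr(g2, reg$core_start[5] + 1, reg$core_end[5])
  # find a background gap big enough for the copy
  occ <- rbind(reg[c("region_start", "region_end")],
               setNames(s$registry$repeats[c("start", "end")],
                        c("region_start", "region_end")))
  occ <- occ[order(occ$region_start), ]
  gap_i <- which.max(c(occ$region_start[-1], 59900) - occ$region_end)
  free_pos <- occ$region_end[gap_i] + 30
  substr(g2, free_pos, free_pos + nchar(core5) - 1) <- core5
  dup_asm <- s$assemblies
  dup_asm$tax2 <- genome_assembly("tax2", c(c1 = g2))
  c_dup <- candidate_loci(baits, dup_asm, required_taxa = 4)
  planted5 <- run$locus[match_planted(run, s$registry) == "locus-005"]
  expect_false(planted5 %in% c_dup$loci$locus)
  expect_equal(sort(setdiff(c4$loci$locus, c_dup$loci$locus)), planted5)
})

test_that("final probes are per-taxon, collapsed, and countable", {
  s <- tiny_suite()
  run <- putative_loci(s$mapped, 1, base_assembly = s$assemblies$tax1,
                       base_taxon = "tax1")
  baits <- filter_baits(tile_baits(run, s$assemblies$tax1))$kept
  cand <- candidate_loci(baits, s$assemblies, required_taxa = 4)
  probes <- design_final_probes(cand, s$assemblies)
  # counting oracle: sum over (locus, distinct sequence, tile)
  direct <- 0L
  for (i in seq_len(nrow(cand$table))) {
    len <- cand$table$end[i] - cand$table$start[i]
    if (len >= 120) direct <- direct + ceiling(max(0, len - 120) / 60) + 1L
  }
  key <- paste(probes$locus, probes$sequence)
  n_sources <- sum(lengths(strsplit(probes$source, "+", fixed = TRUE)))
  expect_equal(n_sources, direct)
  expect_false(anyDuplicated(key) > 0)
  # divergent taxa give distinct per-taxon probes under one locus id
  expect_true(any(grepl("\\+", probes$source)) ||
              all(table(probes$locus) >= max(table(baits$locus))))
  expect_true(all(nchar(probes$sequence) == 120))
})

test_that("identical loci across taxa collapse to one probe with joined provenance", {
  set.seed(14)
  core <- random_dna(300)
  asms <- lapply(setNames(paste0("t", 1:3), paste0("t", 1:3)), function(tx)
    genome_assembly(tx, c(c1 = paste0(random_dna(200), core, random_dna(200)))))
  cand <- list(table = data.frame(locus = "uce-1", taxon = paste0("t", 1:3),
                                  contig = "c1", start = 200, end = 500,
                                  strand = "+", stringsAsFactors = FALSE))
  probes <- design_final_probes(cand, asms)
  expect_equal(nrow(probes), 4L)              # one per tile position
  expect_true(all(probes$source == "t1+t2+t3"))
})
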