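make_mono <- function(loci, taxa, seqs) {
  # seqs: function(locus, taxon) -> sequence
  do.call(rbind, lapply(loci, function(l)
    do.call(rbind, lapply(taxa, function(tx)
      data.frame(locus = l, taxon = tx, sequence = seqs(l, tx),
                 stringsAsFactors = FALSE)))))
}

base_world <- function(n_loci = 6, taxa = paste0("t", 1:3), seed = 17) {
  set.seed(seed)
  anc <- setNames(lapply(seq_len(n_loci), function(i) random_dna(600)),
                  sprintf("uce-%d", seq_len(n_loci)))
  world <- list()
  for (tx in taxa)
    world[[tx]] <- vapply(anc, function(s) mutate_seq(s, 0.005), "")
  world
}

test_that("identical designs single-match everywhere and classify good", {
  w <- base_world()
  mono <- make_mono(names(w$t1), names(w), function(l, tx) w[[tx]][[l]])
  g <- cross_match(list(A = mono, B = mono), identity = 99)
  expect_true(all(g$multiplicity$n_to == 1L))
  expect_true(all(g$matches$identity == 100))
  cls <- classify_loci(g)
  expect_true(all(cls$label == "good"))
  expect_equal(length(unique(cls$cluster)), 6L)
})

test_that("disjoint designs are unshared", {
  w <- base_world()
  loci <- names(w$t1)
  monoA <- make_mono(loci[1:3], names(w), function(l, tx) w[[tx]][[l]])
  monoB <- make_mono(loci[4:6], names(w), function(l, tx) w[[tx]][[l]])
  monoB$locus <- sub("uce-([456])", "uce-10\\1", monoB$locus)
  g <- cross_match(list(A = monoA, B = monoB), identity = 95)
  cls <- classify_loci(g)
  expect_true(all(cls$label == "unshared"))
})

test_that("lineage-specific duplication labels problematic-between; split labels within", {
  w <- base_world(n_loci = 8)
  loci <- names(w$t1)
  taxa <- names(w)
  monoA <- make_mono(loci, taxa, function(l, tx) w[[tx]][[l]])
  # design B sees the duplication in taxon t2 at uce-3 as an extra locus
  set.seed(18)
  copy <- mutate_seq(w$t2[["uce-3"]], 0.02)
  monoB <- rbind(monoA,
                 data.frame(locus = "uce-900", taxon = "t2", sequence = copy,
                            stringsAsFactors = FALSE))
  # and splits uce-5 into two half-loci for every taxon
  monoB <- monoB[monoB$locus != "uce-5", ]
  halves <- do.call(rbind, lapply(taxa, function(tx) {
    s <- w[[tx]][["uce-5"]]
    data.frame(locus = c("uce-501", "uce-502"), taxon = tx,
               sequence = c(substr(s, 1, 300), substr(s, 301, 600)),
               stringsAsFactors = FALSE)
  }))
  monoB <- rbind(monoB, halves)
  g <- cross_match(list(A = monoA, B = monoB), identity = 95)
  cls <- classify_loci(g)
  lab <- function(l, d = "A") unique(cls$label[cls$locus == l & cls$design == d])
  expect_equal(lab("uce-3"), "problematic-between")
  expect_equal(lab("uce-5"), "problematic-within")
  clean <- setdiff(loci, c("uce-3", "uce-5"))
  for (l in clean) expect_equal(lab(l), "good")
  # the duplicated/split loci are exactly the problematic ones
  expect_equal(sort(unique(cls$locus[cls$label != "good" & cls$design == "A"])),
               c("uce-3", "uce-5"))
  # symmetry in design order
  g2 <- cross_match(list(B = monoB, A = monoA), identity = 95)
  cls2 <- classify_loci(g2)
  expect_equal(lab("uce-3"), unique(cls2$label[cls2$locus == "uce-3" & cls2$design == "A"]))
  expect_equal(lab("uce-5"), unique(cls2$label[cls2$locus == "uce-5" & cls2$design == "A"]))
})

test_that("score_base_genomes counts good loci and longest-sequence tallies", {
  w <- base_world()
  mono <- make_mono(names(w$t1), names(w), function(l, tx) w[[tx]][[l]])
  g <- cross_match(list(A = mono, B = mono), identity = 99)
  cls <- classify_loci(g)
  sc <- score_base_genomes(cls, g)
  expect_equal(sc$good_counts["A", ], sc$good_counts["B", ])   # tie rule
  expect_equal(unname(sc$longest_tally["A"]), unname(sc$longest_tally["B"]))
  expect_equal(unname(sc$longest_tally["A"]), 6 * 3)           # all ties awarded

  longer <- make_mono(names(w$t1), names(w),
                      function(l, tx) paste0(random_dna(50), w[[tx]][[l]], random_dna(50)))
  g2 <- cross_match(list(A = mono, B = longer), identity = 95)
  cls2 <- classify_loci(g2)
  sc2 <- score_base_genomes(cls2, g2)
  expect_equal(unname(sc2$longest_tally["B"]), 6 * 3)
  expect_equal(unname(sc2$longest_tally["A"]), 0)
})

test_that("build_optimized_subset filters, merges legacy and renumbers collisions", {
  probes <- probe_set(rep(c("uce-1", "uce-2", "uce-3"), each = 2), rep(1:2, 3),
                      "tx", "opt", replicate(6, random_dna(120)))
  out <- build_optimized_subset(probes, good_loci = c("uce-1", "uce-3"))
  expect_equal(sort(unique(out$probes$locus)), c("uce-1", "uce-3"))
  expect_equal(nrow(out$mapping), 0L)

  legacy_disjoint <- probe_set("uce-500", 1, "legacy", "v1", random_dna(120))
  out2 <- build_optimized_subset(probes, c("uce-1", "uce-3"), legacy_disjoint)
  expect_equal(nrow(out2$probes), 4L + 1L)                     # additivity
  expect_equal(out2$mapping$final, "uce-500")

  legacy_clash <- probe_set(c("uce-1", "uce-9"), 1, "legacy", "v1",
                            replicate(2, random_dna(120)))
  out3 <- build_optimized_subset(probes, c("uce-1", "uce-3"), legacy_clash)
  expect_equal(out3$mapping$final[out3$mapping$legacy == "uce-1"], "uce-4")
  expect_equal(out3$mapping$final[out3$mapping$legacy == "uce-9"], "uce-9")
  expect_true(all(grepl("^legacy:", out3$probes$design[5:6])))
  expect_false(anyDuplicated(paste(out3$probes$locus, out3$probes$design,
                                   out3$probes$probe_index)) > 0)
})
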