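test_that("p-distance and JC69 behave on simple pairs", {
  aln <- c(a = "ACGT", b = "ACGA")
  expect_equal(pairwise_distance(aln, "p")["a", "b"], 0.25)
  ident <- c(a = "ACGTACGT", b = "ACGTACGT")
  for (m in c("p", "JC69", "TN93"))
    expect_equal(unname(pairwise_distance(ident, m)["a", "b"]), 0)
  # pairwise deletion: gap/ambiguity sites dropped per pair
  gap <- c(a = "AC-TN", b = "ACGTA")
  expect_equal(pairwise_distance(gap, "p")["a", "b"], 0)
  expect_error(pairwise_distance(c(a = "----", b = "AAAA"), "p"),
               "zero comparable sites")
  expect_error(pairwise_distance(c(a = "ACG", b = "ACGT"), "p"), "equal length")
})

test_that("JC69 corrects upward and saturates gracefully", {
  set.seed(22)
  for (i in 1:20) {
    a <- random_dna(500)
    b <- mutate_seq(a, runif(1, 0.01, 0.4))
    aln <- c(a = a, b = b)
    p <- pairwise_distance(aln, "p")["a", "b"]
    jc <- pairwise_distance(aln, "JC69")["a", "b"]
    if (p > 0) expect_gt(jc, p)
  }
  sat <- c(a = strrep("A", 100), b = strrep("C", 100))
  d <- pairwise_distance(sat, "JC69")
  expect_true(is.na(d["a", "b"]))
  expect_true(attr(d, "saturated")["a", "b"])
})

test_that("TN93 agrees with the closed form and with ape", {
  # constructed pair: 100 sites, 10 transitions, 5 transversions
  a <- c(rep("A", 25), rep("C", 25), rep("G", 25), rep("T", 25))
  b <- a
  b[1:5] <- "G"; b[26:30] <- "T"     # 10 transitions (A->G, C->T)
  b[51:53] <- "C"; b[76:77] <- "A"   # 5 transversions
  aln <- c(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = ""))
  got <- pairwise_distance(aln, "TN93")["s1", "s2"]
  # independent evaluation of the closed form
  n <- 100; P1 <- 0.05; P2 <- 0.05; Q <- 0.05
  am <- rbind(a, b)
  g <- table(factor(am, c("A", "C", "G", "T"))) / length(am)
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR; k2 <- 2 * gC * gT / gY
  expected <- -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) *
      log(1 - Q / (2 * gR * gY))
  expect_equal(got, expected, tolerance = 1e-12)

  # random alignments against ape::dist.dna
  set.seed(23)
  for (i in 1:10) {
    anc <- random_dna(800)
    aln2 <- c(x = mutate_seq(anc, 0.05), y = mutate_seq(anc, 0.08),
              z = mutate_seq(anc, 0.02))
    d <- pairwise_distance(aln2, "TN93")
    bin <- ape::as.DNAbin(lapply(aln2, function(s) strsplit(tolower(s), "")[[1]]))
    ref <- as.matrix(ape::dist.dna(bin, model = "TN93",
                                   pairwise.deletion = TRUE))
    # ape estimates base frequencies marginally differently (all sites vs
    # pairwise-compared sites); agreement is to ~1e-5 absolute here
    expect_equal(unclass(d)[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4-taxon tree: ((a:1,b:2):1.5,c:3,d:4) - additive distances by path sums
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5.5
  d["a", "d"] <- d["d", "a"] <- 6.5
  d["b", "c"] <- d["c", "b"] <- 6.5
  d["b", "d"] <- d["d", "b"] <- 7.5
  d["c", "d"] <- d["d", "c"] <- 7
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  expect_equal(patristic_distances(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # 3 taxa: patristic equals input trivially
  d3 <- d[1:3, 1:3]
  expect_equal(patristic_distances(neighbor_joining(d3))[1:3, 1:3], d3,
               tolerance = 1e-9)
  # ultrametric 4-taxon matrix
  du <- matrix(c(0, 2, 6, 6, 2, 0, 6, 6, 6, 6, 0, 4, 6, 6, 4, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(patristic_distances(neighbor_joining(du))[letters[1:4], letters[1:4]],
               du, tolerance = 1e-9)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  dns <- d; dns[1, 2] <- 99
  expect_error(neighbor_joining(dns), "non-symmetric")
})

test_that("NJ and patristic agree with ape on random additive matrices", {
  set.seed(24)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:9, 1))
    tr$edge.length <- tr$edge.length + 0.05
    d <- ape::cophenetic.phylo(tr)        # additive by construction
    mine <- neighbor_joining(d)
    expect_equal(patristic_distances(mine)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    # cophenetic on my phylo object is a second, independent path-summer
    expect_equal(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    # topology matches ape's own NJ
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ape::nj(d)))), 0)
  }
})

test_that("negative branch lengths are clamped and flagged", {
  d <- matrix(c(0, 0.1, 5, 0.1, 0, 9, 5, 9, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tree <- neighbor_joining(d)   # (d_ab + d_ac - d_bc)/2 < 0 without clamping
  expect_true(all(tree$edge.length >= 0))
})

test_that("PHYLIP matrix output has the expected shape", {
  d <- matrix(c(0, 0.1, 0.2, 0.1, 0, 0.3, 0.2, 0.3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(d, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
  body <- read.table(text = lines[-1], stringsAsFactors = FALSE)
  expect_equal(body[[1]], c("a", "b", "c"))
  expect_equal(unname(as.matrix(body[, -1])), unname(d), tolerance = 1e-6)
})

test_that("taxon ranking is marker-order invariant and finds the closest taxon", {
  set.seed(25)
  anc <- lapply(1:4, function(i) random_dna(600))
  taxa <- paste0("t", 1:5)
  rates <- c(t1 = 0.01, t2 = 0.05, t3 = 0.05, t4 = 0.06, t5 = 0.05)
  markers <- lapply(anc, function(a)
    vapply(taxa, function(tx) mutate_seq(a, rates[[tx]]), ""))
  names(markers) <- paste0("m", 1:4)
  rk <- rank_base_candidates(markers)
  expect_equal(rk$taxon[1], "t1")
  expect_equal(rk$mean_rank[1], 1)
  rk2 <- rank_base_candidates(rev(markers))
  expect_equal(rk, rk2)
})
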