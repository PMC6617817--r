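aln_char_matrix <- function(alignment) {
  seqs <- toupper(unlist(alignment))
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment sequences must be equal length")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Pairwise genetic distances on an alignment
#'
#' Distances in substitutions per site under pairwise deletion: sites with a
#' gap or ambiguity in either member of a pair are excluded for that pair.
#' `p` is the raw proportion of differences; `JC69` is
#' `-(3/4) ln(1 - 4p/3)`; `TN93` is the Tamura-Nei closed form from
#' transition-class proportions and observed base composition. Undefined
#' logarithms (saturation) yield `NA` with the pair flagged in the
#' `saturated` attribute.
#'
#' @param alignment named character vector of aligned, equal-length
#'   sequences.
#' @param method one of "p", "JC69", "TN93".
#' @return symmetric distance matrix with `method` and `saturated`
#'   attributes.
#' @export
pairwise_distance <- function(alignment, method = c("p", "JC69", "TN93")) {
  method <- match.arg(method)
  mat <- aln_char_matrix(alignment)
  taxa <- rownames(mat)
  Tn <- nrow(mat)
  d <- matrix(0, Tn, Tn, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, Tn, Tn, dimnames = list(taxa, taxa))
  acgt <- c("A", "C", "G", "T")
  for (i in seq_len(Tn - 1L)) for (j in seq(i + 1L, Tn)) {
    x <- mat[i, ]; y <- mat[j, ]
    ok <- x %in% acgt & y %in% acgt
    n <- sum(ok)
    if (n == 0L) stop("zero comparable sites between ", taxa[i], " and ", taxa[j])
    x <- x[ok]; y <- y[ok]
    p <- mean(x != y)
    val <- switch(method,
      p = p,
      JC69 = {
        w <- 1 - 4 * p / 3
        if (w <= 0) { sat[i, j] <- sat[j, i] <- TRUE; NA_real_ }
        else -0.75 * log(w)
      },
      TN93 = {
        g <- (table(factor(x, acgt)) + table(factor(y, acgt))) / (2 * n)
        gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
        gR <- gA + gG; gY <- gC + gT
        diff <- x != y
        P1 <- mean(diff & ((x == "A" & y == "G") | (x == "G" & y == "A")))
        P2 <- mean(diff & ((x == "C" & y == "T") | (x == "T" & y == "C")))
        Q <- p - P1 - P2
        k1 <- 2 * gA * gG / gR
        k2 <- 2 * gC * gT / gY
        w1 <- 1 - P1 / k1 - Q / (2 * gR)
        w2 <- 1 - P2 / k2 - Q / (2 * gY)
        w3 <- 1 - Q / (2 * gR * gY)
        if (any(!is.finite(c(w1, w2, w3))) || w1 <= 0 || w2 <= 0 || w3 <= 0) {
          sat[i, j] <- sat[j, i] <- TRUE; NA_real_
        } else {
          -k1 * log(w1) - k2 * log(w2) -
            2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
        }
      })
    d[i, j] <- d[j, i] <- val
  }
  attr(d, "method") <- method
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on the Q-matrix criterion with a deterministic
#' lowest-index tie-break. Negative branch lengths are clamped to zero and
#' flagged (attribute `clamped`). Returns an unrooted `phylo` tree with a
#' basal trifurcation.
#'
#' @param d symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return an [ape::phylo] object.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-8) stop("non-symmetric distance matrix")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  D <- unname(d)
  active <- seq_len(n)
  next_id <- n + 1L
  ea <- integer(); eb <- integer(); el <- numeric()
  clamped <- FALSE
  add_edge <- function(a, b, l) {
    if (l < -1e-12) clamped <<- TRUE
    ea <<- c(ea, a); eb <<- c(eb, b); el <<- c(el, max(0, l))
  }
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q <= min(Q) + 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, active[i], vi)
    add_edge(u, active[j], vj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], u)
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  root_old <- next_id
  add_edge(root_old, active[1L], v1)
  add_edge(root_old, active[2L], v2)
  add_edge(root_old, active[3L], v3)
  # orient from the central node and renumber internals in preorder
  adj <- lapply(seq_len(root_old), function(i) integer())
  wts <- lapply(seq_len(root_old), function(i) numeric())
  for (e in seq_along(ea)) {
    adj[[ea[e]]] <- c(adj[[ea[e]]], eb[e]); wts[[ea[e]]] <- c(wts[[ea[e]]], el[e])
    adj[[eb[e]]] <- c(adj[[eb[e]]], ea[e]); wts[[eb[e]]] <- c(wts[[eb[e]]], el[e])
  }
  newid <- integer(root_old)
  newid[seq_len(n)] <- seq_len(n)
  counter <- n
  par_old <- integer(); chd_old <- integer(); elen <- numeric()
  stack <- list(list(node = root_old, parent = 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node
    if (node > n) { counter <- counter + 1L; newid[node] <- counter }
    if (fr$parent != 0L) {
      w <- wts[[fr$parent]][match(node, adj[[fr$parent]])]
      par_old <- c(par_old, fr$parent); chd_old <- c(chd_old, node)
      elen <- c(elen, w)
    }
    kids <- adj[[node]][adj[[node]] != fr$parent]
    for (kk in rev(kids)) stack[[length(stack) + 1L]] <- list(node = kk, parent = node)
  }
  edge <- cbind(newid[par_old], newid[chd_old])
  storage.mode(edge) <- "integer"
  tree <- list(edge = edge, edge.length = elen, tip.label = labels,
               Nnode = n - 2L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped
  tree
}

#' Patristic distances on a tree
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' computed by traversal (independent of the NJ construction).
#'
#' @param tree a `phylo` object.
#' @return symmetric matrix over tip labels.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- lapply(seq_len(nn), function(i) integer())
  wts <- lapply(seq_len(nn), function(i) numeric())
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], w)
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], w)
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (tip in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[tip] <- 0
    queue <- tip
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ki in seq_along(adj[[v]])) {
        u <- adj[[v]][ki]
        if (is.na(dist[u])) { dist[u] <- dist[v] + wts[[v]][ki]; queue <- c(queue, u) }
      }
    }
    out[tip, ] <- dist[seq_len(n)]
  }
  out
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(formatC(d[i, ], format = "f", digits = 6),
                           collapse = "  ")), con)
  invisible(path)
}

#' Rank base-genome candidates by genetic distance
#'
#' For every marker and method, each taxon's mean distance to all other taxa
#' is rank-ordered (ascending, ties share the mean rank); the final score is
#' the mean rank across markers and methods, rank 1 being the recommended
#' base genome. `patristic` means: TN93 distances, neighbor-joining tree,
#' path-length distances.
#'
#' @param markers named list of alignments (named character vectors) or of
#'   precomputed distance matrices.
#' @param methods subset of "p", "TN93", "JC69", "patristic" (ignored for
#'   precomputed matrices).
#' @return data.frame of class `taxon_ranking` (taxon, mean_rank,
#'   n_rankings), ordered ascending; skipped taxon/marker combinations are
#'   reported via message.
#' @export
rank_base_candidates <- function(markers,
                                 methods = c("p", "TN93", "patristic")) {
  stopifnot(length(markers) >= 1L)
  mats <- list()
  for (mk in seq_along(markers)) {
    m <- markers[[mk]]
    if (is.matrix(m)) { mats[[length(mats) + 1L]] <- m; next }
    for (meth in methods) {
      dm <- switch(meth,
        p = pairwise_distance(m, "p"),
        JC69 = pairwise_distance(m, "JC69"),
        TN93 = pairwise_distance(m, "TN93"),
        patristic = {
          base <- pairwise_distance(m, "TN93")
          if (anyNA(base) || nrow(base) < 3L) NULL
          else patristic_distances(neighbor_joining(base))
        })
      if (!is.null(dm)) mats[[length(mats) + 1L]] <- dm
    }
  }
  taxa <- sort(unique(unlist(lapply(mats, rownames))))
  ranks <- matrix(NA_real_, length(taxa), length(mats),
                  dimnames = list(taxa, NULL))
  for (k in seq_along(mats)) {
    dm <- mats[[k]]
    mean_d <- rowMeans(dm, na.rm = TRUE)
    ranks[names(mean_d), k] <- rank(mean_d, ties.method = "average")
  }
  n_rank <- rowSums(!is.na(ranks))
  if (any(n_rank < length(mats)))
    message("taxa missing from some markers: ",
            paste(taxa[n_rank < length(mats)], collapse = ","))
  out <- data.frame(taxon = taxa, mean_rank = rowMeans(ranks, na.rm = TRUE),
                    n_rankings = n_rank, stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("taxon_ranking", "data.frame")
  out
}
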