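#' Cross-design locus matching
#'
#' For every design pair and every taxon present in both, each locus sequence
#' of one design is searched against the other design's locus sequences for
#' that taxon. A hit qualifies when identity meets the threshold and the
#' aligned query span covers at least `cross_coverage` percent of the shorter
#' of the two sequences; a source locus is a single match when it matches
#' exactly one destination locus, a multi match otherwise. Both directions of
#' every pair are evaluated.
#'
#' @param monolithics named list: design id -> monolithic data.frame (locus,
#'   taxon, sequence), as produced by [insilico_test()] or
#'   [read_monolithic()].
#' @param identity percent identity threshold (95 and 99 are the
#'   conventional comparison points).
#' @param config `ucekit_config` (cross_coverage, aligner settings).
#' @return object of class `match_graph`: list with `matches` (taxon,
#'   design_from, locus_from, design_to, locus_to, identity, coverage),
#'   `multiplicity` (per source locus and destination design: number of
#'   matched loci), `presence` (design, locus, taxon, length), `designs`,
#'   `identity`.
#' @export
cross_match <- function(monolithics, identity = 99,
                        config = ucekit_config()) {
  stopifnot(length(monolithics) >= 2L, !is.null(names(monolithics)))
  designs <- names(monolithics)
  presence <- do.call(rbind, lapply(designs, function(d) {
    m <- monolithics[[d]]
    data.frame(design = d, locus = m$locus, taxon = m$taxon,
               length = nchar(m$sequence), stringsAsFactors = FALSE)
  }))
  matches <- list(); multi <- list()
  for (a in designs) for (b in designs) {
    if (a == b) next
    ma <- monolithics[[a]]; mb <- monolithics[[b]]
    common <- intersect(unique(ma$taxon), unique(mb$taxon))
    skipped <- setdiff(unique(ma$taxon), common)
    if (length(skipped))
      message(sprintf("cross_match %s->%s: taxa without counterpart skipped: %s",
                      a, b, paste(skipped, collapse = ",")))
    for (tx in common) {
      qa <- ma[ma$taxon == tx, , drop = FALSE]
      tb <- mb[mb$taxon == tx, , drop = FALSE]
      queries <- setNames(toupper(qa$sequence), qa$locus)
      target <- setNames(toupper(tb$sequence), tb$locus)
      hits <- seed_extend_search(queries, target, min_identity = identity,
                                 min_coverage = 0,
                                 seed_length = config$cross_seed_length,
                                 config = config)
      if (nrow(hits)) {
        tlen <- nchar(target)[hits$contig]
        qlen <- nchar(queries)[hits$query]
        shorter <- pmin(qlen, tlen)
        cov_short <- 100 * (hits$qend - hits$qstart) / shorter
        hits <- hits[cov_short >= config$cross_coverage, , drop = FALSE]
      }
      # distinct destination loci per source locus
      n_to <- tapply(hits$contig, hits$query,
                     function(z) length(unique(z)))
      for (lq in names(n_to))
        multi[[length(multi) + 1L]] <- data.frame(
          taxon = tx, design_from = a, locus_from = lq, design_to = b,
          n_to = as.integer(n_to[[lq]]), stringsAsFactors = FALSE)
      if (nrow(hits))
        matches[[length(matches) + 1L]] <- data.frame(
          taxon = tx, design_from = a, locus_from = hits$query,
          design_to = b, locus_to = hits$contig,
          identity = hits$identity, score = hits$score,
          stringsAsFactors = FALSE)
    }
  }
  empty_m <- data.frame(taxon = character(), design_from = character(),
                        locus_from = character(), design_to = character(),
                        locus_to = character(), identity = numeric(),
                        score = numeric(), stringsAsFactors = FALSE)
  empty_n <- data.frame(taxon = character(), design_from = character(),
                        locus_from = character(), design_to = character(),
                        n_to = integer(), stringsAsFactors = FALSE)
  matches <- if (length(matches)) unique(do.call(rbind, matches)) else empty_m
  multi <- if (length(multi)) do.call(rbind, multi) else empty_n
  rownames(matches) <- rownames(multi) <- NULL
  structure(list(matches = matches, multiplicity = multi,
                 presence = presence, designs = designs,
                 identity = identity),
            class = "match_graph")
}

#' Classify loci across designs
#'
#' Clusters loci by transitive closure of single matches, then labels each
#' cluster from per-taxon multiplicity evidence. A taxon shows multi-copy
#' evidence when any member locus matches two or more loci of that same
#' taxon in another design, or when the cluster holds two distinct loci of
#' one design for that taxon. Labels: `good` (no taxon multi),
#' `problematic-within` (every taxon with cross-design evidence is multi -
#' the split-locus signature), `problematic-between` (a mix of single- and
#' multi-copy taxa - the lineage-specific paralogy signature), `unshared`
#' (matched in fewer than two designs for every taxon).
#'
#' @param graph a `match_graph` from [cross_match()].
#' @return data.frame with one row per cluster member: cluster id, design,
#'   locus, taxa (comma list), label.
#' @export
classify_loci <- function(graph) {
  pres <- graph$presence
  nodes <- unique(pres[c("design", "locus")])
  node_id <- paste(nodes$design, nodes$locus, sep = "\r")
  parent <- seq_len(nrow(nodes)); names(parent) <- node_id
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  singles <- graph$multiplicity[graph$multiplicity$n_to == 1L, , drop = FALSE]
  m <- graph$matches
  key_multi <- paste(m$taxon, m$design_from, m$locus_from, m$design_to,
                     sep = "\r")
  key_single <- paste(singles$taxon, singles$design_from, singles$locus_from,
                      singles$design_to, sep = "\r")
  sm <- m[key_multi %in% key_single, , drop = FALSE]  # edges from single matches
  if (nrow(sm)) {
    ia <- match(paste(sm$design_from, sm$locus_from, sep = "\r"), node_id)
    ib <- match(paste(sm$design_to, sm$locus_to, sep = "\r"), node_id)
    for (e in seq_len(nrow(sm))) {
      ra <- find_root(ia[e]); rb <- find_root(ib[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nrow(nodes)), find_root, 0L)
  cluster <- match(root, sort(unique(root)))
  nodes$cluster <- cluster
  # per-taxon evidence within each cluster
  taxa_of <- split(pres$taxon, paste(pres$design, pres$locus, sep = "\r"))
  mm <- graph$multiplicity
  mm$cluster <- cluster[match(paste(mm$design_from, mm$locus_from, sep = "\r"),
                              node_id)]
  labels <- character(max(cluster))
  for (cl in seq_len(max(cluster))) {
    members <- nodes[nodes$cluster == cl, , drop = FALSE]
    ev <- mm[mm$cluster == cl, , drop = FALSE]
    if (nrow(members) < 2L && nrow(ev) == 0L) { labels[cl] <- "unshared"; next }
    taxon_multi <- tapply(ev$n_to >= 2L, ev$taxon, any)
    # two distinct loci of one design sharing a taxon also mark that taxon multi
    for (d in unique(members$design)) {
      md <- members[members$design == d, , drop = FALSE]
      if (nrow(md) >= 2L) {
        tx <- unlist(taxa_of[paste(md$design, md$locus, sep = "\r")])
        dup_tx <- unique(tx[duplicated(tx)])
        for (t2 in dup_tx) taxon_multi[t2] <- TRUE
      }
    }
    if (length(taxon_multi) == 0L) { labels[cl] <- "unshared"; next }
    if (!any(taxon_multi)) labels[cl] <- "good"
    else if (all(taxon_multi)) labels[cl] <- "problematic-within"
    else labels[cl] <- "problematic-between"
  }
  taxa_str <- vapply(paste(nodes$design, nodes$locus, sep = "\r"),
                     function(k) paste(sort(unique(taxa_of[[k]])), collapse = ","),
                     "", USE.NAMES = FALSE)
  out <- data.frame(cluster = nodes$cluster, design = nodes$design,
                    locus = nodes$locus, taxa = taxa_str,
                    label = labels[nodes$cluster], stringsAsFactors = FALSE)
  out[order(out$cluster, out$design, out$locus), , drop = FALSE]
}

#' Score base genomes from good loci
#'
#' Counts, per design and taxon, the good loci present; for every good
#' cluster found in all taxa it tallies, per design, the number of taxa in
#' which that design's extracted sequence is the longest or tied-longest.
#'
#' @param classification output of [classify_loci()].
#' @param graph the `match_graph` (supplies sequence lengths).
#' @return list with `good_counts` (design x taxon matrix),
#'   `longest_tally` (named vector per design) and `good_all_taxa`
#'   (character cluster summary of loci good in all taxa, as design:locus of
#'   members).
#' @export
score_base_genomes <- function(classification, graph) {
  pres <- graph$presence
  designs <- graph$designs
  taxa <- sort(unique(pres$taxon))
  good <- classification[classification$label == "good", , drop = FALSE]
  gc_mat <- matrix(0L, length(designs), length(taxa),
                   dimnames = list(designs, taxa))
  key <- paste(pres$design, pres$locus, sep = "\r")
  for (i in seq_len(nrow(good))) {
    tx <- pres$taxon[key == paste(good$design[i], good$locus[i], sep = "\r")]
    gc_mat[good$design[i], tx] <- gc_mat[good$design[i], tx] + 1L
  }
  tally <- setNames(numeric(length(designs)), designs)
  all_taxa_clusters <- character()
  for (cl in unique(good$cluster)) {
    members <- good[good$cluster == cl, , drop = FALSE]
    mt <- strsplit(members$taxa, ",")
    if (!setequal(Reduce(union, mt), taxa)) next
    all_taxa_clusters <- c(all_taxa_clusters,
                           paste(members$design, members$locus,
                                 sep = ":", collapse = ";"))
    for (tx in taxa) {
      lens <- setNames(rep(NA_real_, length(designs)), designs)
      for (i in seq_len(nrow(members))) {
        l <- pres$length[key == paste(members$design[i], members$locus[i],
                                      sep = "\r") & pres$taxon == tx]
        if (length(l)) lens[members$design[i]] <- max(l)
      }
      if (all(is.na(lens))) next
      mx <- max(lens, na.rm = TRUE)
      winners <- names(lens)[!is.na(lens) & lens == mx]
      tally[winners] <- tally[winners] + 1
    }
  }
  list(good_counts = gc_mat, longest_tally = tally,
       good_all_taxa = all_taxa_clusters)
}

#' Build the final optimized probe subset
#'
#' Restricts a design's probes to loci that are good in all taxa and covered
#' by that design, then merges an optional legacy probe set. Legacy locus
#' ids colliding with retained ids are renumbered deterministically above
#' the maximum retained id (ascending legacy order); provenance is kept in
#' the design tag and a mapping table is returned.
#'
#' @param probes the optimized design's `probe_set`.
#' @param good_loci character vector of locus ids (in the design's own
#'   numbering) that are good and present in all taxa.
#' @param legacy optional legacy `probe_set`.
#' @return list with `probes` (a `probe_set`) and `mapping` (legacy locus
#'   renumber table).
#' @export
build_optimized_subset <- function(probes, good_loci, legacy = NULL) {
  keep <- probes[probes$locus %in% good_loci, , drop = FALSE]
  mapping <- data.frame(legacy = character(), final = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(legacy) && nrow(legacy)) {
    new_ids <- unique(keep$locus)
    leg_ids <- unique(legacy$locus)
    nums <- as.integer(sub("uce-", "", new_ids))
    nxt <- if (length(nums)) max(nums) + 1L else 1L
    final_ids <- setNames(leg_ids, leg_ids)
    collide <- leg_ids[leg_ids %in% new_ids]
    for (l in collide[order(as.integer(sub("uce-", "", collide)))]) {
      final_ids[l] <- sprintf("uce-%d", nxt); nxt <- nxt + 1L
    }
    mapping <- data.frame(legacy = leg_ids, final = unname(final_ids),
                          stringsAsFactors = FALSE)
    leg <- legacy
    leg$design <- paste0("legacy:", leg$design)
    leg$locus <- unname(final_ids[leg$locus])
    keep <- rbind(keep[names(leg)[names(leg) %in% names(keep)]],
                  leg[names(leg)[names(leg) %in% names(keep)]])
  }
  rownames(keep) <- NULL
  class(keep) <- c("probe_set", "data.frame")
  list(probes = keep, mapping = mapping)
}
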