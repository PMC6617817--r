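tile_starts <- function(len, probe_length, offset) {
  if (len < probe_length) return(integer())
  starts <- seq.int(0L, len - probe_length, by = offset)
  if (tail(starts, 1L) + probe_length < len)
    starts <- c(starts, len - probe_length)
  starts
}

#' Tile temporary baits over putative loci
#'
#' Baits of `probe_length` bp are placed at 0, offset, 2*offset, ... with a
#' final right-aligned bait added when the last regular bait does not reach
#' the locus end, so every locus base is covered. Loci shorter than the probe
#' length are skipped (logged).
#'
#' @param putative putative-locus table from [putative_loci()].
#' @param base_assembly the base `genome_assembly` sequences are taken from.
#' @param config `ucekit_config` (probe_length, tile_offset).
#' @param design design tag recorded in the bait headers.
#' @return a `probe_set` of temporary baits (sequence case preserved from the
#'   assembly via an extra `raw_sequence` column used by masking filters).
#' @export
tile_baits <- function(putative, base_assembly, config = ucekit_config(),
                       design = "temp") {
  plen <- config$probe_length; off <- config$tile_offset
  short <- (putative$end - putative$start) < plen
  if (any(short))
    message(sprintf("tile_baits: skipped %d locus/loci shorter than %d bp",
                    sum(short), plen))
  putative <- putative[!short, , drop = FALSE]
  rows <- lapply(seq_len(nrow(putative)), function(i) {
    len <- putative$end[i] - putative$start[i]
    starts <- tile_starts(len, plen, off)
    seqfull <- substr(base_assembly$contigs[[putative$contig[i]]],
                      putative$start[i] + 1, putative$end[i])
    data.frame(locus = putative$locus[i], probe_index = seq_along(starts),
               raw_sequence = substring(seqfull, starts + 1, starts + plen),
               locus_offset = starts, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    stop("no locus long enough to tile")
  out <- probe_set(df$locus, df$probe_index, base_assembly$taxon, design,
                   df$raw_sequence)
  out$raw_sequence <- df$raw_sequence
  out$locus_offset <- df$locus_offset
  out
}

#' Filter baits on composition
#'
#' Applies, in order: ambiguous-base count, GC lower bound, GC upper bound,
#' soft-mask fraction (uses the case-preserving `raw_sequence` column when
#' present). Each rejected bait is labelled with the first failing rule;
#' input order is preserved.
#'
#' @param baits `probe_set` of temporary baits.
#' @param config `ucekit_config` (gc_min, gc_max, max_ambiguous,
#'   max_masked_fraction).
#' @return list with `kept` (a `probe_set`) and `rejected` (probe table plus
#'   a `reason` column).
#' @export
filter_baits <- function(baits, config = ucekit_config()) {
  seqs <- toupper(baits$sequence)
  raw <- if (!is.null(baits$raw_sequence)) baits$raw_sequence else baits$sequence
  n_amb <- nchar(gsub("[ACGT]", "", seqs))
  gc <- vapply(seqs, function(s) {
    bases <- nchar(gsub("[^ACGT]", "", s))
    if (bases == 0) return(NA_real_)
    100 * nchar(gsub("[^GC]", "", s)) / bases
  }, numeric(1), USE.NAMES = FALSE)
  maskf <- (nchar(raw) - nchar(gsub("[acgtnN]", "", raw))) / nchar(raw)
  reason <- rep(NA_character_, nrow(baits))
  reason[is.na(reason) & n_amb > config$max_ambiguous] <- "ambiguous"
  reason[is.na(reason) & !is.na(gc) & gc < config$gc_min] <- "gc_low"
  reason[is.na(reason) & !is.na(gc) & gc > config$gc_max] <- "gc_high"
  reason[is.na(reason) & is.na(gc)] <- "gc_low"
  reason[is.na(reason) & maskf > config$max_masked_fraction] <- "masked"
  kept <- baits[is.na(reason), , drop = FALSE]
  rej <- baits[!is.na(reason), , drop = FALSE]
  rej$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rej) <- NULL
  list(kept = kept, rejected = rej)
}

# classify every bait of every locus in one taxon; returns per-locus
# qualification and the merged best-hit interval
classify_locus_in_taxon <- function(bait_ids, bait_locus, hits, top_delta) {
  hit_by_query <- if (nrow(hits)) split(hits, hits$query) else list()
  status <- vapply(bait_ids, function(q)
    classify_multiplicity(hit_by_query[[q]], top_delta), "", USE.NAMES = FALSE)
  res <- list()
  for (loc in unique(bait_locus)) {
    st <- status[bait_locus == loc]
    ids <- bait_ids[bait_locus == loc]
    qualifies <- any(st == "unique") && !any(st == "duplicate")
    iv <- NULL
    if (qualifies) {
      best <- do.call(rbind, lapply(ids[st == "unique"], function(q)
        hit_by_query[[q]][1L, , drop = FALSE]))
      top <- best[which.max(best$score), ]
      same <- best[best$contig == top$contig, , drop = FALSE]
      merged <- merge_intervals(intervals(contig = same$contig,
                                          start = same$tstart, end = same$tend))
      pick <- merged[merged$start < top$tend & merged$end > top$tstart, ,
                     drop = FALSE][1L, ]
      iv <- data.frame(contig = pick$contig, start = pick$start,
                       end = pick$end, strand = top$strand,
                       stringsAsFactors = FALSE)
    }
    res[[loc]] <- list(qualifies = qualifies, interval = iv)
  }
  res
}

#' Determine candidate loci
#'
#' A locus qualifies in a taxon when at least one of its baits matches
#' uniquely there and none matches in duplicate. Loci qualifying in at least
#' `required_taxa` taxa are retained. Loci whose bait hits overlap another
#' locus's hits in any taxon are collapsed, keeping the lower locus id.
#'
#' @param baits kept baits (a `probe_set`).
#' @param assemblies named list of `genome_assembly` objects (the full suite,
#'   base included).
#' @param config `ucekit_config` (alignment thresholds, top_delta).
#' @param required_taxa minimum number of qualifying taxa (default: all).
#' @return list with `table` (one row per qualifying (locus, taxon) with the
#'   best-hit interval), `loci` (locus, n_taxa), and `collapsed` (mapping of
#'   dropped to kept locus ids).
#' @export
candidate_loci <- function(baits, assemblies, config = ucekit_config(),
                           required_taxa = length(assemblies)) {
  stopifnot(length(assemblies) >= 1L, nrow(baits) >= 1L)
  bait_ids <- sprintf("%s_p%d", baits$locus, baits$probe_index)
  queries <- setNames(toupper(baits$sequence), bait_ids)
  per_taxon <- list()
  for (tx in names(assemblies)) {
    hits <- seed_extend_search(queries, assemblies[[tx]], config = config)
    per_taxon[[tx]] <- classify_locus_in_taxon(bait_ids, baits$locus, hits,
                                               config$top_delta)
  }
  loci <- unique(baits$locus)
  # collapse loci whose qualified hit intervals overlap in any taxon
  parent <- setNames(seq_along(loci), loci)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (tx in names(assemblies)) {
    cls <- per_taxon[[tx]]
    ivs <- do.call(rbind, lapply(loci, function(l)
      if (!is.null(cls[[l]]) && cls[[l]]$qualifies)
        cbind(cls[[l]]$interval, locus = l) else NULL))
    if (is.null(ivs) || nrow(ivs) < 2L) next
    ord <- order(ivs$contig, ivs$start)
    ivs <- ivs[ord, ]
    for (i in seq_len(nrow(ivs) - 1L)) {
      j <- i + 1L
      while (j <= nrow(ivs) && ivs$contig[j] == ivs$contig[i] &&
             ivs$start[j] < ivs$end[i]) {
        ra <- find_root(match(ivs$locus[i], loci))
        rb <- find_root(match(ivs$locus[j], loci))
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        j <- j + 1L
      }
    }
  }
  root <- vapply(seq_along(loci), find_root, 0L)
  keep_locus <- loci[root == seq_along(loci)]
  collapsed <- data.frame(dropped = loci[root != seq_along(loci)],
                          kept = loci[root[root != seq_along(loci)]],
                          stringsAsFactors = FALSE)
  rows <- list()
  for (loc in keep_locus) {
    for (tx in names(assemblies)) {
      cl <- per_taxon[[tx]][[loc]]
      if (!is.null(cl) && cl$qualifies)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(locus = loc, taxon = tx, stringsAsFactors = FALSE),
          cl$interval)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), taxon = character(), contig = character(),
               start = numeric(), end = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  n_taxa <- table(tab$locus)
  ok <- names(n_taxa)[n_taxa >= required_taxa]
  tab <- tab[tab$locus %in% ok, , drop = FALSE]
  rownames(tab) <- NULL
  summary <- data.frame(locus = ok,
                        n_taxa = as.integer(n_taxa[ok]),
                        stringsAsFactors = FALSE)
  summary <- summary[order(as.integer(sub("uce-", "", summary$locus))), ]
  rownames(summary) <- NULL
  list(table = tab, loci = summary, collapsed = collapsed)
}

#' Design per-taxon final probes
#'
#' For every qualifying (locus, taxon), probes are re-tiled from that taxon's
#' own sequence at its best-hit interval (minus-strand intervals are
#' reverse-complemented into locus orientation first). Identical sequences
#' arising from several taxa at one locus are collapsed, with the provenance
#' list joined by `+` in the source field. Intervals shorter than the probe
#' length contribute nothing (logged).
#'
#' @param candidates result of [candidate_loci()].
#' @param assemblies named list of `genome_assembly` objects.
#' @param config `ucekit_config`.
#' @param design design tag for the probe headers.
#' @return a `probe_set`.
#' @export
design_final_probes <- function(candidates, assemblies,
                                config = ucekit_config(), design = "final") {
  tab <- candidates$table
  plen <- config$probe_length
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    len <- tab$end[i] - tab$start[i]
    if (len < plen) { skipped <- skipped + 1L; next }
    seqfull <- substr(assemblies[[tab$taxon[i]]]$contigs[[tab$contig[i]]],
                      tab$start[i] + 1, tab$end[i])
    if (tab$strand[i] == "-") seqfull <- revcomp(seqfull)
    starts <- tile_starts(len, plen, config$tile_offset)
    rows[[length(rows) + 1L]] <- data.frame(
      locus = tab$locus[i], probe_index = seq_along(starts),
      source = tab$taxon[i],
      sequence = toupper(substring(seqfull, starts + 1, starts + plen)),
      stringsAsFactors = FALSE)
  }
  if (skipped) message(sprintf(
    "design_final_probes: %d locus/taxon interval(s) shorter than %d bp skipped",
    skipped, plen))
  if (!length(rows)) stop("no probes could be designed")
  df <- do.call(rbind, rows)
  # collapse identical sequences within a locus, keeping provenance
  key <- paste(df$locus, df$sequence, sep = "\r")
  first <- !duplicated(key)
  src <- vapply(split(df$source, key), function(s)
    paste(unique(s), collapse = "+"), "")
  out <- df[first, , drop = FALSE]
  out$source <- src[paste(out$locus, out$sequence, sep = "\r")]
  ord <- order(as.integer(sub("uce-", "", out$locus)), out$probe_index,
               out$source)
  out <- out[ord, , drop = FALSE]
  probe_set(out$locus, out$probe_index, out$source, design, out$sequence)
}
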