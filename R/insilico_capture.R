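#' In silico capture test of a probe set
#'
#' Matches every probe against every assembly, merges overlapping hit spans
#' per locus, and classifies each (locus, taxon) cell: a single near-best hit
#' region is `recovered` (the merged span plus/minus `flank` bases is
#' extracted, clipped at contig ends, reverse-complemented for minus-strand
#' captures); two or more near-best disjoint regions are `duplicate-removed`;
#' no hits is `absent`.
#'
#' @param probes a `probe_set`.
#' @param assemblies named list of `genome_assembly` objects.
#' @param config `ucekit_config` (thresholds, top_delta, flank).
#' @param flank bases extracted each side of the captured span.
#' @return object of class `recovery_matrix`: list with `status` and
#'   `lengths` (taxon x locus matrices), `monolithic` (data.frame locus,
#'   taxon, sequence for every recovered cell) and `flank`.
#' @export
insilico_test <- function(probes, assemblies, config = ucekit_config(),
                          flank = config$flank) {
  if (is.null(probes) || nrow(probes) == 0L) stop("empty probe set")
  loci <- unique(probes$locus)
  taxa <- names(assemblies)
  pid <- sprintf("row%d", seq_len(nrow(probes)))
  queries <- setNames(toupper(probes$sequence), pid)
  status <- matrix("absent", nrow = length(taxa), ncol = length(loci),
                   dimnames = list(taxa, loci))
  lens <- matrix(0L, nrow = length(taxa), ncol = length(loci),
                 dimnames = list(taxa, loci))
  mono <- list()
  for (tx in taxa) {
    hits <- seed_extend_search(queries, assemblies[[tx]], config = config)
    hits$locus <- probes$locus[match(hits$query, pid)]
    hits_by_locus <- if (nrow(hits)) split(hits, hits$locus) else list()
    for (loc in names(hits_by_locus)) {
      h <- hits_by_locus[[loc]]
      # cluster hits into regions of mutually overlapping target intervals
      h <- h[order(h$contig, h$tstart), , drop = FALSE]
      region <- integer(nrow(h)); region[1L] <- 1L
      if (nrow(h) > 1L) {
        hi <- h$tend[1L]
        for (i in 2L:nrow(h)) {
          if (h$contig[i] == h$contig[i - 1L] && h$tstart[i] < hi) {
            region[i] <- region[i - 1L]
            hi <- max(hi, h$tend[i])
          } else {
            region[i] <- region[i - 1L] + 1L
            hi <- h$tend[i]
          }
        }
      }
      rscore <- tapply(h$score, region, max)
      best <- max(rscore)
      near <- sum(rscore >= best * (1 - config$top_delta / 100))
      if (near >= 2L) { status[tx, loc] <- "duplicate-removed"; next }
      rid <- as.integer(names(rscore)[which.max(rscore)])
      hr <- h[region == rid, , drop = FALSE]
      ctg <- hr$contig[1L]
      span_s <- min(hr$tstart); span_e <- max(hr$tend)
      clen <- nchar(assemblies[[tx]]$contigs[[ctg]])
      s <- max(0L, span_s - flank); e <- min(clen, span_e + flank)
      seq <- substr(assemblies[[tx]]$contigs[[ctg]], s + 1, e)
      if (hr$strand[which.max(hr$score)] == "-") seq <- revcomp(seq)
      status[tx, loc] <- "recovered"
      lens[tx, loc] <- nchar(seq)
      mono[[length(mono) + 1L]] <- data.frame(
        locus = loc, taxon = tx, sequence = toupper(seq),
        contig = ctg, start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  mono <- if (length(mono)) do.call(rbind, mono) else
    data.frame(locus = character(), taxon = character(),
               sequence = character(), contig = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  structure(list(status = status, lengths = lens, monolithic = mono,
                 flank = flank), class = "recovery_matrix")
}

#' @export
print.recovery_matrix <- function(x, ...) {
  cat(sprintf("recovery_matrix: %d taxa x %d loci; %d recovered cells, flank %d\n",
              nrow(x$status), ncol(x$status),
              sum(x$status == "recovered"), x$flank))
  invisible(x)
}

#' Completeness filter
#'
#' Keeps loci recovered in at least `ceiling(min_fraction * T)` taxa.
#'
#' @param matrix a `recovery_matrix`.
#' @param min_fraction minimum fraction of taxa (e.g. 0.75).
#' @return character vector of locus ids.
#' @export
completeness_filter <- function(matrix, min_fraction = 0.75) {
  need <- ceiling(min_fraction * nrow(matrix$status))
  counts <- colSums(matrix$status == "recovered")
  names(counts)[counts >= need]
}

#' Recovery summary
#'
#' Per-taxon recovered counts plus the union count of unique loci recovered
#' in at least one taxon.
#'
#' @param matrix a `recovery_matrix`.
#' @return list with `per_taxon` (named vector) and `union` (count).
#' @export
recovery_summary <- function(matrix) {
  per_taxon <- rowSums(matrix$status == "recovered")
  union <- sum(colSums(matrix$status == "recovered") > 0L)
  list(per_taxon = per_taxon, union = union)
}
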