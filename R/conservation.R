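#' Merge intervals into a minimal disjoint set
#'
#' Union of the input: overlapping and book-ended (half-open adjacent)
#' intervals are merged; result is sorted by (contig, start). Idempotent.
#'
#' @param x interval data.frame.
#' @return merged interval data.frame (strand collapsed to `+`).
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  if (nrow(x) == 0L) return(intervals())
  out <- lapply(split(x, x$contig), function(iv) {
    r <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1, end = iv$end))
    intervals(contig = iv$contig[1L], start = IRanges::start(r) - 1,
              end = IRanges::end(r))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

masked_fraction <- function(assembly, x) {
  x <- validate_intervals(x)
  vapply(seq_len(nrow(x)), function(i) {
    seq <- assembly$contigs[[x$contig[i]]]
    if (is.null(seq) || is.na(seq)) stop("unknown contig: ", x$contig[i])
    sub <- substr(seq, x$start[i] + 1, x$end[i])
    n <- nchar(sub)
    masked <- n - nchar(gsub("[acgtnN]", "", sub))
    masked / n
  }, numeric(1))
}

#' Remove heavily masked intervals
#'
#' Drops intervals whose soft-masked (lowercase) plus N fraction on the
#' assembly exceeds `max_masked_fraction`.
#'
#' @param x interval data.frame.
#' @param assembly `genome_assembly` the intervals live on.
#' @param max_masked_fraction maximum tolerated masked fraction.
#' @return filtered interval data.frame.
#' @export
strip_masked <- function(x, assembly, max_masked_fraction = 0.25) {
  x <- validate_intervals(x)
  if (nrow(x) == 0L) return(x)
  keep <- masked_fraction(assembly, x) <= max_masked_fraction
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect putative conserved loci
#'
#' Merges the mapped intervals of all non-base taxa on the base genome and
#' keeps merged regions of at least `min_length` bp supported by at least
#' `k` non-base taxa (a taxon supports a region when its mapped intervals
#' overlap it by at least `min_overlap` bp). Locus ids `uce-1 ...` are
#' assigned in (contig, start) order, so reruns are stable.
#'
#' @param mapped named list: taxon -> interval data.frame on base contigs.
#' @param k sharing stringency: minimum number of supporting non-base taxa
#'   (the "+k" parameter).
#' @param config `ucekit_config` supplying `min_length`, `min_overlap` and
#'   the defensive duplicate-interval collapse flag.
#' @param base_assembly optional base `genome_assembly`; when supplied,
#'   intervals on unknown contigs raise an error and heavily masked regions
#'   are removed via [strip_masked()].
#' @param base_taxon label recorded in the support list (default "base").
#' @return data.frame with columns locus, contig, start, end, strand,
#'   support (non-base supporter count) and taxa (comma list incl. base).
#' @export
putative_loci <- function(mapped, k, config = ucekit_config(),
                          base_assembly = NULL, base_taxon = "base") {
  stopifnot(is.list(mapped), length(mapped) >= 1L)
  if (is.null(names(mapped)) || any(!nzchar(names(mapped))))
    stop("mapped must be a named list (taxon -> intervals)")
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= length(mapped))
  mapped <- lapply(mapped, validate_intervals)
  if (!is.null(base_assembly)) {
    known <- names(base_assembly$contigs)
    for (tx in names(mapped)) {
      bad <- setdiff(unique(mapped[[tx]]$contig), known)
      if (length(bad)) stop("unknown contig in mapping for ", tx, ": ", bad[1L])
    }
  }
  if (config$collapse_identical_intervals)
    mapped <- lapply(mapped, function(iv)
      iv[!duplicated(iv[c("contig", "start", "end")]), , drop = FALSE])
  pooled <- do.call(rbind, lapply(mapped, function(iv)
    iv[c("contig", "start", "end", "strand")]))
  regions <- merge_intervals(pooled)
  if (nrow(regions) == 0L)
    return(data.frame(locus = character(), contig = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      support = integer(), taxa = character(),
                      stringsAsFactors = FALSE))
  support <- matrix(FALSE, nrow(regions), length(mapped),
                    dimnames = list(NULL, names(mapped)))
  for (tx in names(mapped)) {
    iv <- mapped[[tx]]
    if (nrow(iv) == 0L) next
    for (ctg in unique(regions$contig)) {
      ri <- which(regions$contig == ctg)
      qi <- which(iv$contig == ctg)
      if (!length(qi)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(regions$start[ri] + 1, regions$end[ri]),
        IRanges::IRanges(iv$start[qi] + 1, iv$end[qi]),
        minoverlap = config$min_overlap)
      support[ri[unique(S4Vectors::queryHits(hits))], tx] <- TRUE
    }
  }
  n_support <- rowSums(support)
  keep <- n_support >= k & (regions$end - regions$start) >= config$min_length
  regions <- regions[keep, , drop = FALSE]
  support <- support[keep, , drop = FALSE]
  if (!is.null(base_assembly) && nrow(regions))
    {
      mk <- masked_fraction(base_assembly, regions) <= config$max_masked_fraction
      regions <- regions[mk, , drop = FALSE]
      support <- support[mk, , drop = FALSE]
    }
  if (nrow(regions) == 0L)
    return(data.frame(locus = character(), contig = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      support = integer(), taxa = character(),
                      stringsAsFactors = FALSE))
  ord <- order(regions$contig, regions$start)
  regions <- regions[ord, , drop = FALSE]
  support <- support[ord, , drop = FALSE]
  taxa <- apply(support, 1L, function(z)
    paste(c(base_taxon, colnames(support)[z]), collapse = ","))
  out <- data.frame(locus = sprintf("uce-%d", seq_len(nrow(regions))),
                    contig = regions$contig, start = regions$start,
                    end = regions$end, strand = "+",
                    support = as.integer(rowSums(support)), taxa = taxa,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
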