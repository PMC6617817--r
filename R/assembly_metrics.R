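#' N50/L50-style contiguity statistics
#'
#' N is the length of the contig at which the cumulative sum of descending
#' contig lengths first reaches `fraction` of the total; L is that contig's
#' 1-based rank. When the threshold lands exactly on a contig boundary the
#' contig closing the boundary is reported (the bbmap/stats convention).
#'
#' @param contig_lengths positive contig lengths (bp).
#' @param fraction cumulative fraction, typically 0.5 or 0.9.
#' @return list with elements `N` and `L`.
#' @export
nl_stats <- function(contig_lengths, fraction = 0.5) {
  contig_lengths <- as.numeric(contig_lengths)
  if (length(contig_lengths) == 0L) stop("no contig lengths supplied")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  stopifnot(fraction > 0, fraction <= 1)
  len <- sort(contig_lengths, decreasing = TRUE)
  cum <- cumsum(len)
  idx <- which(cum >= fraction * sum(len))[1L]
  list(N = len[idx], L = idx)
}

#' GC percentage of an assembly or sequence
#'
#' 100 * (G+C) / (A+C+G+T), case-insensitive; N and other ambiguity codes are
#' excluded from the denominator.
#'
#' @param x a `genome_assembly` or character vector of sequences.
#' @return GC percentage.
#' @export
gc_percent <- function(x) {
  seqs <- if (inherits(x, "genome_assembly")) x$contigs else as.character(x)
  s <- toupper(paste(seqs, collapse = ""))
  counts <- table(strsplit(s, "", fixed = TRUE)[[1L]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0) stop("no unambiguous bases; GC% undefined")
  100 * gc / acgt
}

#' Assembly summary report
#'
#' Table of the standard assembly characterization metrics used when
#' screening base-genome candidates: total length, contig count, N50/L50,
#' N90/L90 and GC%.
#'
#' @param assemblies a `genome_assembly` or list of them.
#' @return data.frame, one row per taxon.
#' @export
assembly_report <- function(assemblies) {
  if (inherits(assemblies, "genome_assembly")) assemblies <- list(assemblies)
  rows <- lapply(assemblies, function(a) {
    len <- nchar(a$contigs)
    n50 <- nl_stats(len, 0.5); n90 <- nl_stats(len, 0.9)
    data.frame(taxon = a$taxon, total_length = sum(len),
               contig_count = length(len),
               N50 = n50$N, L50 = n50$L, N90 = n90$N, L90 = n90$L,
               GC_percent = gc_percent(a), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-locus read depth from intervals
#'
#' Mean depth is total aligned bases over locus length (reads-per-base);
#' covered fraction is the union of read intervals over locus length. This is
#' an interval approximation of a pileup-based depth-of-coverage estimate.
#'
#' @param reference_loci named numeric vector of locus lengths, or a
#'   data.frame with columns locus, taxon, sequence (lengths derived).
#' @param read_intervals interval data.frame whose `contig` column names loci
#'   present in `reference_loci`.
#' @return data.frame with locus, length, mean_depth, covered_fraction.
#' @export
locus_depth <- function(reference_loci, read_intervals) {
  if (is.data.frame(reference_loci)) {
    lens <- tapply(nchar(reference_loci$sequence), reference_loci$locus, max)
    lens <- setNames(as.numeric(lens), names(lens))
  } else lens <- reference_loci
  x <- validate_intervals(read_intervals)
  if (nrow(x)) {
    unknown <- setdiff(unique(x$contig), names(lens))
    if (length(unknown)) stop("intervals on unknown locus: ", unknown[1L])
    over <- x$end > lens[x$contig]
    if (any(over)) stop("interval beyond locus end for ", x$contig[which(over)[1L]])
  }
  out <- data.frame(locus = names(lens), length = as.numeric(lens),
                    mean_depth = 0, covered_fraction = 0,
                    stringsAsFactors = FALSE)
  if (nrow(x)) {
    by_locus <- split(x, x$contig)
    for (loc in names(by_locus)) {
      iv <- by_locus[[loc]]
      i <- match(loc, out$locus)
      out$mean_depth[i] <- sum(iv$end - iv$start) / out$length[i]
      merged <- merge_intervals(iv)
      out$covered_fraction[i] <- sum(merged$end - merged$start) / out$length[i]
    }
  }
  rownames(out) <- NULL
  out
}
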