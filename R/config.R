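#' Pipeline configuration
#'
#' Central container for every tunable of the design workflow. All thresholds
#' that the reports print come from here, so a run is reproducible from its
#' config alone.
#'
#' @param probe_length bait/probe length in bp (120 is the standard capture
#'   oligo length).
#' @param tile_offset spacing between successive bait start positions; 60 on
#'   120-mers gives 2x tiling density.
#' @param min_length minimum merged conserved-region length retained as a
#'   putative locus (bp).
#' @param min_overlap minimum overlap (bp) for a taxon's mapped interval to
#'   count as supporting a merged region.
#' @param max_masked_fraction regions/baits with a higher fraction of
#'   soft-masked (lowercase) plus N bases are removed.
#' @param gc_min,gc_max design-time GC%% bounds for bait filtering.
#' @param max_ambiguous maximum number of N bases tolerated in a bait.
#' @param min_identity,min_coverage percent thresholds for bait/probe to
#'   genome matching.
#' @param seed_length exact-match seed length of the local aligner.
#' @param match,mismatch,gap Smith-Waterman scoring triple (linear gap).
#' @param top_delta percent score window below the best hit within which a
#'   second non-overlapping hit flags a query as duplicate.
#' @param max_kmer_hits seeds occurring more often than this in a target are
#'   skipped (repeat guard).
#' @param cross_identity,cross_coverage identity threshold and
#'   coverage-of-the-shorter-sequence floor for cross-design locus matching
#'   (95 and 99 are the conventional comparison points).
#' @param cross_seed_length seed length for cross-design matching; longer
#'   than the bait-matching seed because monolithic sequences are long and
#'   compared at high identity.
#' @param flank bases extracted on each side of the captured span during the
#'   in silico test.
#' @param completeness minimum fraction of taxa for the completeness filter.
#' @param qc_gc_min,qc_gc_max,qc_tm_min,qc_tm_max,qc_sodium probe QC bands:
#'   GC%% limits, melting temperature limits (degrees C) and sodium molarity
#'   used by the hybrid Tm formula.
#' @param collapse_identical_intervals defensively collapse exactly duplicated
#'   mapped intervals before support counting.
#' @return an object of class `ucekit_config` (a named list).
#' @export
ucekit_config <- function(probe_length = 120L,
                          tile_offset = 60L,
                          min_length = 80L,
                          min_overlap = 1L,
                          max_masked_fraction = 0.25,
                          gc_min = 25,
                          gc_max = 70,
                          max_ambiguous = 0L,
                          min_identity = 90,
                          min_coverage = 80,
                          seed_length = 12L,
                          match = 1,
                          mismatch = -1,
                          gap = -2,
                          top_delta = 5,
                          max_kmer_hits = 200L,
                          cross_identity = 99,
                          cross_coverage = 50,
                          cross_seed_length = 16L,
                          flank = 400L,
                          completeness = 0.75,
                          qc_gc_min = 25,
                          qc_gc_max = 70,
                          qc_tm_min = 80,
                          qc_tm_max = 120,
                          qc_sodium = 0.9,
                          collapse_identical_intervals = TRUE) {
  stopifnot(tile_offset > 0, tile_offset <= probe_length,
            gc_min < gc_max, qc_tm_min < qc_tm_max, qc_sodium > 0)
  cfg <- list(probe_length = as.integer(probe_length),
              tile_offset = as.integer(tile_offset),
              min_length = as.integer(min_length),
              min_overlap = as.integer(min_overlap),
              max_masked_fraction = max_masked_fraction,
              gc_min = gc_min, gc_max = gc_max,
              max_ambiguous = as.integer(max_ambiguous),
              min_identity = min_identity, min_coverage = min_coverage,
              seed_length = as.integer(seed_length),
              match = match, mismatch = mismatch, gap = gap,
              top_delta = top_delta,
              max_kmer_hits = as.integer(max_kmer_hits),
              cross_identity = cross_identity,
              cross_coverage = cross_coverage,
              cross_seed_length = as.integer(cross_seed_length),
              flank = as.integer(flank),
              completeness = completeness,
              qc_gc_min = qc_gc_min, qc_gc_max = qc_gc_max,
              qc_tm_min = qc_tm_min, qc_tm_max = qc_tm_max,
              qc_sodium = qc_sodium,
              collapse_identical_intervals = isTRUE(collapse_identical_intervals))
  class(cfg) <- "ucekit_config"
  cfg
}

#' @export
print.ucekit_config <- function(x, ...) {
  cat("ucekit configuration\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
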