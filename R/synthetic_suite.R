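#' Synthetic suite configuration
#'
#' Describes a multi-taxon genome suite descended from a common ancestor
#' with planted conserved cores flanked by faster-evolving sequence,
#' optional lineage-specific paralog copies, tandem-repeat arrays
#' (soft-masked in the output) and locus presence/absence structure.
#' Coordinates are identical across taxa because the default mutation model
#' is substitution-only, which keeps the truth registry exact.
#'
#' @param taxa taxon labels (first is the default base genome).
#' @param genome_length genome size per taxon (bp).
#' @param n_loci number of planted conserved loci.
#' @param core_length conserved core length (bp).
#' @param flank_length flanking sequence length on each side (bp).
#' @param divergence per-taxon substitution rate from the ancestor at locus
#'   cores (scalar recycled, or named vector); rates must be in [0, 0.75).
#' @param flank_factor flank rate = core rate x this factor (capped 0.75).
#' @param background_divergence per-taxon rate outside planted loci.
#' @param presence optional logical matrix (loci x taxa); default all TRUE.
#' @param paralogs optional data.frame (locus, taxon, divergence): an extra
#'   diverged copy of the locus region planted elsewhere in that taxon.
#' @param n_repeats tandem-repeat arrays planted per genome (soft-masked).
#' @param repeat_length length of each repeat array (bp).
#' @param seed RNG seed; the whole suite is reproducible from it.
#' @return list of class `suite_config`.
#' @export
suite_config <- function(taxa = paste0("tax", 1:7),
                         genome_length = 1e6,
                         n_loci = 300L,
                         core_length = 300L,
                         flank_length = 400L,
                         divergence = 0.05,
                         flank_factor = 4,
                         background_divergence = 0.25,
                         presence = NULL,
                         paralogs = NULL,
                         n_repeats = 10L,
                         repeat_length = 500L,
                         seed = 1L) {
  stopifnot(length(taxa) >= 2L, !anyDuplicated(taxa))
  if (is.null(names(divergence)))
    divergence <- setNames(rep_len(divergence, length(taxa)), taxa)
  stopifnot(all(divergence >= 0), all(divergence < 0.75),
            background_divergence >= 0, background_divergence < 0.75)
  cfg <- list(taxa = taxa, genome_length = as.integer(genome_length),
              n_loci = as.integer(n_loci),
              core_length = as.integer(core_length),
              flank_length = as.integer(flank_length),
              divergence = divergence, flank_factor = flank_factor,
              background_divergence = background_divergence,
              presence = presence, paralogs = paralogs,
              n_repeats = as.integer(n_repeats),
              repeat_length = as.integer(repeat_length),
              seed = as.integer(seed))
  class(cfg) <- "suite_config"
  cfg
}

mutate_int <- function(v, rate) {
  hit <- which(runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- (v[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  v
}

int_to_seq <- function(v) paste(c("A", "C", "G", "T")[v + 1L], collapse = "")

#' Generate a synthetic genome suite with ground truth
#'
#' Draws an ancestor genome uniformly over ACGT, plants conserved locus
#' regions (core + flanks), paralog-copy slots and tandem-repeat arrays at
#' non-overlapping positions, then evolves each taxon independently:
#' background sequence at the background rate, locus cores at the per-taxon
#' rate, flanks at `flank_factor` times the core rate. Loci absent from a
#' taxon evolve at the background rate there. Paralog copies are taken from
#' the carrier taxon's own locus region and mutated further by the copy
#' divergence. Repeat arrays are soft-masked (lowercase) in every assembly.
#' Mapped intervals are idealized: the true core coordinates on the base
#' genome for every taxon where the locus is present.
#'
#' @param config a [suite_config()].
#' @return list of class `uce_suite`: `assemblies` (named list of
#'   `genome_assembly`), `mapped` (taxon -> interval data.frame vs the first
#'   taxon as base), `registry` (loci/presence/paralogs/repeats tables and
#'   per-taxon divergences), `ancestor` (the unmutated ancestor sequence)
#'   and `config`.
#' @export
generate_suite <- function(config = suite_config()) {
  stopifnot(inherits(config, "suite_config"))
  set.seed(config$seed)
  taxa <- config$taxa
  G <- config$genome_length
  region_len <- config$core_length + 2L * config$flank_length
  presence <- config$presence
  if (is.null(presence))
    presence <- matrix(TRUE, config$n_loci, length(taxa),
                       dimnames = list(NULL, taxa))
  stopifnot(nrow(presence) == config$n_loci)
  paralogs <- config$paralogs
  n_par <- if (is.null(paralogs)) 0L else nrow(paralogs)
  # segment plan: loci, then paralog slots, then repeat arrays
  seg_len <- c(rep(region_len, config$n_loci),
               if (n_par) rep(region_len, n_par),
               rep(config$repeat_length, config$n_repeats))
  n_seg <- length(seg_len)
  gap_min <- 100L
  free <- G - sum(seg_len) - (n_seg + 1L) * gap_min
  if (free < 0) stop("genome_length too small for requested segments")
  order_seg <- sample.int(n_seg)
  cuts <- sort(runif(n_seg))
  extra <- diff(c(0, cuts)) * free
  starts_sorted <- cumsum(gap_min + extra) +
    c(0, cumsum(seg_len[order_seg]))[seq_len(n_seg)]
  starts <- integer(n_seg)
  starts[order_seg] <- as.integer(floor(starts_sorted))
  loci_start <- starts[seq_len(config$n_loci)]
  par_start <- if (n_par) starts[config$n_loci + seq_len(n_par)] else integer()
  rep_start <- if (config$n_repeats)
    starts[config$n_loci + n_par + seq_len(config$n_repeats)] else integer()
  # registry in genome order
  ord <- order(loci_start)
  loci <- data.frame(
    locus = sprintf("locus-%03d", seq_len(config$n_loci)),
    contig = "chr1",
    region_start = loci_start[ord],
    region_end = loci_start[ord] + region_len,
    core_start = loci_start[ord] + config$flank_length,
    core_end = loci_start[ord] + config$flank_length + config$core_length,
    stringsAsFactors = FALSE)
  presence <- presence[ord, , drop = FALSE]
  rownames(presence) <- loci$locus
  ancestor <- sample.int(4L, G, replace = TRUE) - 1L
  # repeats planted in the ancestor so every taxon inherits them
  rep_df <- NULL
  if (config$n_repeats) {
    for (rs in rep_start) {
      motif <- sample.int(4L, 6L, replace = TRUE) - 1L
      fill <- rep_len(motif, config$repeat_length)
      ancestor[rs + seq_len(config$repeat_length)] <- fill
    }
    rep_df <- data.frame(contig = "chr1", start = rep_start,
                         end = rep_start + config$repeat_length,
                         stringsAsFactors = FALSE)
  }
  # per-taxon evolution
  assemblies <- list()
  par_df <- NULL
  for (tx in taxa) {
    core_rate <- config$divergence[[tx]]
    flank_rate <- min(0.75, core_rate * config$flank_factor)
    rate <- rep(config$background_divergence, G)
    for (i in seq_len(nrow(loci))) {
      if (!presence[i, tx]) next
      rate[(loci$region_start[i] + 1L):loci$region_end[i]] <- flank_rate
      rate[(loci$core_start[i] + 1L):loci$core_end[i]] <- core_rate
    }
    g <- mutate_int(ancestor, rate)
    if (n_par) for (p in seq_len(n_par)) {
      if (paralogs$taxon[p] != tx) next
      li <- match(paralogs$locus[p], loci$locus)
      if (is.na(li)) stop("paralog spec names unknown locus: ", paralogs$locus[p])
      src <- g[(loci$region_start[li] + 1L):loci$region_end[li]]
      copy <- mutate_int(src, paralogs$divergence[p])
      g[par_start[p] + seq_len(region_len)] <- copy
      par_df <- rbind(par_df, data.frame(
        locus = paralogs$locus[p], taxon = tx, contig = "chr1",
        start = par_start[p], end = par_start[p] + region_len,
        divergence = paralogs$divergence[p], stringsAsFactors = FALSE))
    }
    s <- int_to_seq(g)
    if (config$n_repeats) for (r in seq_len(nrow(rep_df))) {
      sub <- substr(s, rep_df$start[r] + 1L, rep_df$end[r])
      substr(s, rep_df$start[r] + 1L, rep_df$end[r]) <- tolower(sub)
    }
    assemblies[[tx]] <- genome_assembly(tx, c(chr1 = s))
  }
  registry <- list(loci = loci, presence = presence, paralogs = par_df,
                   repeats = rep_df, divergence = config$divergence)
  suite <- structure(list(assemblies = assemblies, registry = registry,
                          ancestor = int_to_seq(ancestor), config = config),
                     class = "uce_suite")
  suite$mapped <- suite_mapped_intervals(suite, base = taxa[1L])
  suite
}

#' @export
print.uce_suite <- function(x, ...) {
  cat(sprintf("uce_suite: %d taxa, %s bp genomes, %d planted loci, seed %d\n",
              length(x$assemblies), format(x$config$genome_length, big.mark = ","),
              nrow(x$registry$loci), x$config$seed))
  invisible(x)
}

#' Idealized mapping intervals against a chosen base
#'
#' Emits, for every non-base taxon, the true core coordinates (on the base
#' genome) of each locus present in both the base and that taxon. Because
#' the generator is substitution-only, coordinates are identical across
#' taxa, so any taxon can serve as base.
#'
#' @param suite a `uce_suite`.
#' @param base base taxon label.
#' @return named list: taxon -> interval data.frame with a `name` column.
#' @export
suite_mapped_intervals <- function(suite, base = suite$config$taxa[1L]) {
  reg <- suite$registry
  stopifnot(base %in% colnames(reg$presence))
  out <- list()
  for (tx in setdiff(suite$config$taxa, base)) {
    both <- reg$presence[, base] & reg$presence[, tx]
    li <- reg$loci[both, , drop = FALSE]
    out[[tx]] <- if (nrow(li))
      intervals(contig = li$contig, start = li$core_start, end = li$core_end,
                name = li$locus)
    else intervals()
  }
  out
}

#' Corrupt a mapping interval set
#'
#' Each interval is independently dropped with probability `dropout`;
#' surviving boundaries are shifted by an integer uniform on [-jitter,
#' jitter] (start clamped at 0, end kept > start). Reproducible from `seed`.
#'
#' @param x interval data.frame.
#' @param dropout drop probability in [0, 1].
#' @param jitter maximum boundary shift (bp).
#' @param seed RNG seed.
#' @return corrupted interval data.frame.
#' @export
corrupt_mapping <- function(x, dropout = 0, jitter = 0L, seed = 1L) {
  x <- validate_intervals(x)
  set.seed(seed)
  keep <- runif(nrow(x)) >= dropout
  out <- x[keep, , drop = FALSE]
  if (jitter > 0L && nrow(out)) {
    out$start <- pmax(0, out$start + sample(-jitter:jitter, nrow(out), TRUE))
    out$end <- out$end + sample(-jitter:jitter, nrow(out), TRUE)
    out$end <- pmax(out$end, out$start + 1)
  }
  rownames(out) <- NULL
  out
}

#' Extract planted locus sequences from a suite
#'
#' Returns the (locus, taxon) sequences of planted loci straight from the
#' truth registry: core plus `flank` bases each side (defaults to the full
#' planted flank).
#'
#' @param suite a `uce_suite`.
#' @param loci locus ids (default all).
#' @param taxa taxon labels (default all).
#' @param flank flank width (bp); `NULL` uses the planted flank length.
#' @return data.frame (locus, taxon, sequence), present cells only.
#' @export
registry_locus_sequences <- function(suite, loci = NULL, taxa = NULL,
                                     flank = NULL) {
  reg <- suite$registry
  if (is.null(loci)) loci <- reg$loci$locus
  if (is.null(taxa)) taxa <- suite$config$taxa
  if (is.null(flank)) flank <- suite$config$flank_length
  rows <- list()
  for (loc in loci) {
    i <- match(loc, reg$loci$locus)
    s <- max(0L, reg$loci$core_start[i] - flank)
    e <- min(suite$config$genome_length, reg$loci$core_end[i] + flank)
    for (tx in taxa) {
      if (!reg$presence[loc, tx]) next
      seq <- substr(suite$assemblies[[tx]]$contigs[["chr1"]], s + 1L, e)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, taxon = tx, sequence = toupper(seq),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Marker alignments from a suite
#'
#' Uses the conserved cores of loci present in every taxon as gap-free
#' marker "alignments" (exact positional homology holds because the
#' generator is substitution-only).
#'
#' @param suite a `uce_suite`.
#' @param n number of markers.
#' @return named list of alignments (named character vectors).
#' @export
suite_marker_alignments <- function(suite, n = 6L) {
  reg <- suite$registry
  everywhere <- reg$loci$locus[rowSums(reg$presence) == ncol(reg$presence)]
  stopifnot(length(everywhere) >= n)
  picked <- everywhere[seq_len(n)]
  out <- list()
  for (loc in picked) {
    i <- match(loc, reg$loci$locus)
    out[[loc]] <- vapply(suite$config$taxa, function(tx)
      toupper(substr(suite$assemblies[[tx]]$contigs[["chr1"]],
                     reg$loci$core_start[i] + 1L, reg$loci$core_end[i])), "")
  }
  out
}

#' Simulate error-free uniform reads over reference loci
#'
#' Emits read intervals (not sequences) on locus coordinates for depth
#' estimation tests.
#'
#' @param locus_lengths named vector of locus lengths.
#' @param depth target mean depth (reads-per-base).
#' @param read_length read length (bp).
#' @param seed RNG seed.
#' @return interval data.frame with `contig` naming the locus.
#' @export
simulate_locus_reads <- function(locus_lengths, depth = 10, read_length = 100L,
                                 seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (loc in names(locus_lengths)) {
    L <- locus_lengths[[loc]]
    rl <- min(read_length, L)
    n_reads <- max(0L, round(depth * L / rl))
    if (n_reads == 0L) next
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
    rows[[loc]] <- intervals(contig = loc, start = starts, end = starts + rl)
  }
  if (!length(rows)) return(intervals())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
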