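#' Exhaustive Smith-Waterman local alignment
#'
#' Full dynamic-programming local alignment under a (match, mismatch, linear
#' gap) scoring triple. Deterministic: ties in the matrix fill prefer
#' diagonal over up over left, and the traceback starts from the first
#' maximal cell in row-major order. Quadratic; intended as the reference
#' oracle and for short sequences (<= 2000 bp).
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap scoring triple; gaps are linear.
#' @return list with score, identity (% matching columns, gaps counted as
#'   mismatched columns), 0-based half-open query/target ranges, and the
#'   aligned strings. A best score <= 0 is reported as score 0 with empty
#'   alignment (no alignment).
#' @export
smith_waterman <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) > 2000L || nchar(b) > 2000L)
    stop("smith_waterman is quadratic; sequences must be <= 2000 bp")
  smith_waterman_cpp(a, b, match, mismatch, gap)
}

#' Reverse complement
#' @param x character vector of nucleotide strings (case preserved).
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) vapply(as.character(x), revcomp_cpp, "", USE.NAMES = FALSE)

#' Seeded local alignment search
#'
#' Matches queries against a genome assembly on both strands: exact
#' `seed_length`-mer matches are expanded into target windows large enough to
#' contain any positive-scoring local alignment through the seed, and each
#' window is aligned with full Smith-Waterman. Hits passing the identity and
#' query-coverage thresholds are reported sorted by score (descending) with a
#' deterministic (contig, start) tie-break. The best hit attains the
#' exhaustive Smith-Waterman optimum whenever the optimal alignment contains
#' an exact seed-length run.
#'
#' @param query named character vector of query sequences (names become the
#'   `query` column; unnamed queries are auto-named q1, q2, ...).
#' @param target `genome_assembly` (or named character vector of contigs).
#' @param min_identity,min_coverage percent thresholds; identity is matches
#'   over aligned columns (gaps count as mismatched columns), coverage is the
#'   aligned query span over query length.
#' @param seed_length exact-seed length (<= 16).
#' @param config `ucekit_config` supplying the scoring triple and repeat
#'   guard; individual arguments override it.
#' @return data.frame: query, contig, tstart, tend, qstart, qend (0-based
#'   half-open), strand, identity, coverage, score, matches, columns.
#' @export
seed_extend_search <- function(query, target,
                               min_identity = config$min_identity,
                               min_coverage = config$min_coverage,
                               seed_length = config$seed_length,
                               config = ucekit_config()) {
  contigs <- if (inherits(target, "genome_assembly")) target$contigs else target
  stopifnot(!is.null(names(contigs)))
  query <- unlist(query)
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  stopifnot(seed_length >= 4L, seed_length <= 16L)
  if (any(nchar(query) < seed_length))
    stop("query shorter than seed_length")
  informative <- nchar(gsub("[^ACGTacgt]", "", query))
  if (any(informative < seed_length))
    warning("degenerate query (insufficient unambiguous bases): ",
            paste(names(query)[informative < seed_length], collapse = ", "))
  se_search_cpp(unname(query), names(query), unname(contigs), names(contigs),
                min_identity, min_coverage, as.integer(seed_length),
                config$match, config$mismatch, config$gap,
                config$max_kmer_hits)
}

#' Classify hit multiplicity for one query
#'
#' `absent` when there is no hit; `duplicate` when at least two hits lie at
#' non-overlapping target intervals with scores within `top_delta` percent of
#' the best; otherwise `unique`.
#'
#' @param hits hit table for a single query (as from [seed_extend_search()]).
#' @param top_delta percent score window below the best hit.
#' @return one of "absent", "duplicate", "unique".
#' @export
classify_multiplicity <- function(hits, top_delta = 5) {
  if (is.null(hits) || nrow(hits) == 0L) return("absent")
  if (length(unique(hits$query)) > 1L)
    stop("classify_multiplicity expects hits of a single query")
  best <- max(hits$score)
  top <- hits[hits$score >= best * (1 - top_delta / 100), , drop = FALSE]
  if (nrow(top) >= 2L) {
    # any pair on different contigs, or same contig without interval overlap?
    for (i in seq_len(nrow(top) - 1L)) for (j in seq(i + 1L, nrow(top))) {
      disjoint <- top$contig[i] != top$contig[j] ||
        top$tend[i] <= top$tstart[j] || top$tend[j] <= top$tstart[i]
      if (disjoint) return("duplicate")
    }
  }
  "unique"
}

#' Write a BLAST outfmt-6-like hit table
#' @param hits hit table from [seed_extend_search()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(query = hits$query, target = hits$contig,
                   identity = hits$identity,
                   alnlen = hits$columns,
                   qstart = hits$qstart, qend = hits$qend,
                   tstart = hits$tstart, tend = hits$tend,
                   strand = hits$strand, score = hits$score,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
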