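#' Genome assembly container
#'
#' A named set of contig sequences for one taxon. Alphabet is restricted to
#' A, C, G, T, N with lowercase allowed for soft-masked bases; masking is
#' preserved because it drives bait filtering downstream.
#'
#' @param taxon taxon label.
#' @param contigs named character vector of contig sequences; names must be
#'   unique and sequences non-empty.
#' @return object of class `genome_assembly` with fields `taxon`, `contigs`.
#' @export
genome_assembly <- function(taxon, contigs) {
  stopifnot(is.character(taxon), length(taxon) == 1L, nzchar(taxon))
  contigs <- unlist(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs))))
    stop("contig ids must be present and unique")
  if (any(!nzchar(contigs))) stop("contig sequences must be non-empty")
  if (any(grepl("[^ACGTNacgtn]", contigs)))
    stop("assembly alphabet restricted to ACGTN (upper or lower case)")
  structure(list(taxon = taxon, contigs = contigs), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly '%s': %d contig(s), %s bp\n", x$taxon,
              length(x$contigs), format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Genomic interval set
#'
#' Coordinates are 0-based half-open throughout the package (the BED
#' convention); SAM input is converted on read.
#'
#' @param contig,start,end,strand parallel vectors; `0 <= start < end`.
#' @param ... further parallel columns (e.g. `name`, `score`, `taxon`).
#' @return a `data.frame` with columns contig, start, end, strand (+ extras).
#' @export
intervals <- function(contig = character(), start = integer(),
                      end = integer(), strand = "+", ...) {
  n <- length(contig)
  start <- as.numeric(start); end <- as.numeric(end)
  strand <- rep_len(as.character(strand), n)
  if (any(start < 0)) stop("negative coordinate")
  if (any(start >= end)) stop("start must be < end (0-based half-open)")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  data.frame(contig = as.character(contig), start = start, end = end,
             strand = strand, ..., stringsAsFactors = FALSE)
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) && (any(x$start < 0) || any(x$start >= x$end)))
    stop("invalid intervals: need 0 <= start < end")
  if (is.null(x$strand)) x$strand <- "+"
  x
}

# ---- FASTA ----------------------------------------------------------------

#' Read / write FASTA
#'
#' Backed by Biostrings with byte-preserving records (lowercase soft-masking
#' survives a round trip). `read_fasta` returns an ordered named character
#' vector; names are the full header lines without the leading `>`.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path)
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  if (any(!nzchar(out))) {
    bad <- which(!nzchar(out))[1L]
    stop("empty sequence for record '", names(out)[bad], "' in ", path)
  }
  out
}

#' @param records named character vector of sequences.
#' @param wrap line width for wrapping; 0 writes unwrapped records.
#' @rdname read_fasta
#' @return `write_fasta` returns `path` invisibly.
#' @export
write_fasta <- function(records, path, wrap = 80L) {
  stopifnot(!is.null(names(records)), all(nzchar(records)))
  width <- if (wrap <= 0) max(nchar(records)) + 1L else as.integer(wrap)
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path,
                              width = width)
  invisible(path)
}

read_assembly <- function(path, taxon) genome_assembly(taxon, read_fasta(path))

# ---- probe FASTA header grammar -------------------------------------------

#' Probe record header grammar
#'
#' Final probe headers follow the phyluce-style convention
#' `uce-<N>_p<K> |design:<tag>,probes-locus:uce-<N>,probes-probe:<K>,probes-source:<taxon>`.
#' The parser is deliberately lenient: any `uce-<N>` token in the id is
#' accepted as the locus and any unmatched tail is kept verbatim.
#'
#' @param headers character vector of FASTA headers (without `>`).
#' @return data.frame with columns locus, probe_index, source, design, tail.
#' @export
parse_probe_header <- function(headers) {
  locus <- ifelse(grepl("uce-\\d+", headers),
                  regmatches(headers, regexpr("uce-\\d+", headers)), NA_character_)
  pidx <- ifelse(grepl("probes-probe:(\\d+)", headers),
                 sub(".*probes-probe:(\\d+).*", "\\1", headers),
                 ifelse(grepl("_p(\\d+)", headers),
                        sub(".*_p(\\d+).*", "\\1", headers), NA_character_))
  src <- ifelse(grepl("probes-source:", headers),
                sub(".*probes-source:([^,| ]+).*", "\\1", headers), NA_character_)
  design <- ifelse(grepl("design:", headers),
                   sub(".*design:([^,| ]+).*", "\\1", headers), NA_character_)
  tail <- sub("^\\S+\\s*", "", headers)
  if (anyNA(locus))
    stop("unparseable probe header (no uce-<N> token): ",
         headers[which(is.na(locus))[1L]])
  data.frame(locus = locus, probe_index = as.integer(pidx), source = src,
             design = design, tail = tail, stringsAsFactors = FALSE)
}

#' Construct a probe set table
#'
#' @param locus locus ids of form `uce-<N>`.
#' @param probe_index 1-based tile index within the locus.
#' @param source taxon whose genome provided the probe sequence.
#' @param design free-text design tag.
#' @param sequence probe sequence (length must equal `probe_length` when
#'   validated downstream).
#' @return data.frame of class `probe_set`.
#' @export
probe_set <- function(locus, probe_index, source, design, sequence) {
  df <- data.frame(locus = as.character(locus),
                   probe_index = as.integer(probe_index),
                   source = as.character(source),
                   design = as.character(design),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  stopifnot(all(grepl("^uce-\\d+$", df$locus)), all(df$probe_index >= 1L))
  class(df) <- c("probe_set", "data.frame")
  df
}

probe_headers <- function(probes) {
  sprintf("%s_p%d |design:%s,probes-locus:%s,probes-probe:%d,probes-source:%s",
          probes$locus, probes$probe_index, probes$design, probes$locus,
          probes$probe_index, probes$source)
}

#' Read / write probe FASTA
#'
#' @param probes a `probe_set` table.
#' @param path file path.
#' @rdname probe_set
#' @export
write_probe_fasta <- function(probes, path) {
  write_fasta(setNames(probes$sequence, probe_headers(probes)), path, wrap = 0L)
}

#' @rdname probe_set
#' @export
read_probe_fasta <- function(path) {
  recs <- read_fasta(path)
  info <- parse_probe_header(names(recs))
  info$probe_index[is.na(info$probe_index)] <- 1L
  info$source[is.na(info$source)] <- "unknown"
  info$design[is.na(info$design)] <- "unknown"
  out <- probe_set(info$locus, info$probe_index, info$source, info$design,
                   unname(recs))
  out$tail <- info$tail
  out
}

# ---- monolithic locus FASTA -----------------------------------------------

#' Monolithic locus FASTA
#'
#' One record per (locus, taxon) with headers `uce-<N>_<taxon> |uce-<N>`.
#'
#' @param loci data.frame with columns locus, taxon, sequence.
#' @param path file path.
#' @return `read_monolithic` returns a data.frame (locus, taxon, sequence).
#' @export
write_monolithic <- function(loci, path) {
  stopifnot(all(c("locus", "taxon", "sequence") %in% names(loci)))
  if (anyDuplicated(loci[c("locus", "taxon")]))
    stop("one record per (locus, taxon) required")
  hdr <- sprintf("%s_%s |%s", loci$locus, loci$taxon, loci$locus)
  write_fasta(setNames(loci$sequence, hdr), path, wrap = 0L)
}

#' @rdname write_monolithic
#' @export
read_monolithic <- function(path) {
  recs <- read_fasta(path)
  id <- sub("\\s.*$", "", names(recs))
  locus <- regmatches(id, regexpr("^uce-\\d+", id))
  if (length(locus) != length(id)) stop("monolithic header without uce-<N> id")
  taxon <- sub("^uce-\\d+_", "", id)
  df <- data.frame(locus = locus, taxon = taxon, sequence = unname(recs),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("locus", "taxon")]))
    stop("duplicate (locus, taxon) record in ", path)
  df
}

# ---- BED ------------------------------------------------------------------

#' Read / write BED intervals
#'
#' BED3+ with 0-based half-open coordinates preserved exactly. Column 4 is
#' the name, column 5 the score, column 6 the strand when present.
#'
#' @param path file path.
#' @return data.frame interval set.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) < 3L) stop("BED needs at least 3 columns: ", path)
  out <- intervals(contig = as.character(x[[1L]]),
                   start = x[[2L]], end = x[[3L]],
                   strand = if (ncol(x) >= 6L) x[[6L]] else "+")
  if (ncol(x) >= 4L) out$name <- as.character(x[[4L]])
  if (ncol(x) >= 5L) out$score <- x[[5L]]
  out
}

#' @param x interval data.frame (columns contig, start, end and optionally
#'   name, score, strand).
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  cols <- list(x$contig, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    cols[[4L]] <- if (is.null(x$name)) "." else x$name
    cols[[5L]] <- if (is.null(x$score)) 0 else x$score
    cols[[6L]] <- x$strand
  }
  df <- do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- SAM ------------------------------------------------------------------

cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    if (length(o) == 0L) return(NA_real_)
    len <- as.numeric(sub("[MIDNSHP=X]", "", o))
    op <- sub("\\d+", "", o)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Reduce a SAM file to reference intervals
#'
#' Keeps mapped, primary, non-duplicate, non-supplementary alignments and
#' reduces each to the reference interval its CIGAR consumes. SAM's 1-based
#' POS is converted to the package's 0-based half-open convention.
#'
#' @param path SAM text file; must begin with a header.
#' @param verbose print skip counts.
#' @return data.frame interval set (one row per usable alignment).
#' @export
read_sam_intervals <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "@"))
    stop("SAM file must start with a header line: ", path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(intervals())
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6L)) stop("truncated SAM record at body line ", which(nf < 6L)[1L])
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.numeric(vapply(f, `[[`, "", 4L))
  cig <- vapply(f, `[[`, "", 6L)
  unmapped <- bitwAnd(flag, 4L) != 0L | rname == "*" | cig == "*"
  secondary <- bitwAnd(flag, 256L) != 0L
  duplicate <- bitwAnd(flag, 1024L) != 0L
  suppl <- bitwAnd(flag, 2048L) != 0L
  keep <- !(unmapped | secondary | duplicate | suppl)
  if (verbose)
    message(sprintf("SAM: kept %d, skipped %d unmapped, %d secondary, %d duplicate, %d supplementary",
                    sum(keep), sum(unmapped), sum(secondary & !unmapped),
                    sum(duplicate & !unmapped), sum(suppl & !unmapped)))
  if (!any(keep)) return(intervals())
  span <- cigar_ref_span(cig[keep])
  if (anyNA(span) || any(span <= 0))
    stop("CIGAR without reference-consuming operations in kept record")
  strand <- ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+")
  intervals(contig = rname[keep], start = pos[keep] - 1,
            end = pos[keep] - 1 + span, strand = strand)
}
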