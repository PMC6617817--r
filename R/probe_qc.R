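#' Linguistic complexity of a sequence
#'
#' Ratio of the number of distinct substrings (all lengths) to the maximum
#' possible for a sequence of that length over a 4-letter alphabet,
#' `sum_k min(4^k, L-k+1)`. Low values flag repetitive probes.
#'
#' @param x nucleotide string.
#' @return complexity in (0, 1].
#' @export
linguistic_complexity <- function(x) {
  s <- toupper(as.character(x))
  stopifnot(length(s) == 1L, nchar(s) > 0L)
  L <- nchar(s)
  observed <- 0
  maximum <- 0
  for (k in seq_len(L)) {
    observed <- observed + length(unique(substring(s, 1:(L - k + 1), k:L)))
    maximum <- maximum + min(4^k, L - k + 1)
  }
  observed / maximum
}

#' Melting temperature of an RNA-DNA hybrid probe
#'
#' Salt-adjusted hybrid formula:
#' `Tm = 79.8 + 18.5*log10(Na) + 58.4*f + 11.8*f^2 - 820/L` with `f` the GC
#' fraction and `L` the length. The constants are printed in every QC report
#' so any mismatch with other implementations is diagnosable rather than
#' silent.
#'
#' @param x nucleotide string(s).
#' @param sodium sodium molarity (default 0.9 M).
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(x, sodium = 0.9) {
  x <- toupper(as.character(x))
  L <- nchar(x)
  gcf <- nchar(gsub("[^GC]", "", x)) / pmax(1L, nchar(gsub("[^ACGT]", "", x)))
  79.8 + 18.5 * log10(sodium) + 58.4 * gcf + 11.8 * gcf^2 - 820 / L
}

#' Physical QC of probes
#'
#' Computes length, GC%, melting temperature and linguistic complexity for
#' each probe and checks them against the configured bands. Probes containing
#' N fail immediately (reason `ambiguous`).
#'
#' @param sequences character vector of probe sequences (ACGTN), optionally
#'   named; a `probe_set` is also accepted.
#' @param config `ucekit_config` supplying the QC bands
#'   (qc_gc_min/qc_gc_max, qc_tm_min/qc_tm_max, probe_length, qc_sodium).
#' @return data.frame of class `qc_report`: probe_id, length, gc, tm,
#'   complexity, pass, reasons (comma list, empty when passing).
#' @export
qc_probes <- function(sequences, config = ucekit_config()) {
  if (inherits(sequences, "probe_set"))
    sequences <- setNames(sequences$sequence,
                          sprintf("%s_p%d", sequences$locus,
                                  sequences$probe_index))
  sequences <- toupper(unlist(sequences))
  if (length(sequences) == 0L || any(!nzchar(sequences)))
    stop("empty probe sequence")
  if (any(grepl("[^ACGTN]", sequences))) stop("probes must be over ACGTN")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("probe", seq_along(sequences))
  L <- nchar(sequences)
  n_amb <- nchar(gsub("[ACGT]", "", sequences))
  gc <- 100 * nchar(gsub("[^GC]", "", sequences)) / pmax(1L, L - n_amb)
  tm <- melting_temperature(sequences, config$qc_sodium)
  lc <- vapply(sequences, linguistic_complexity, numeric(1), USE.NAMES = FALSE)
  reasons <- lapply(seq_along(sequences), function(i) {
    r <- character()
    if (n_amb[i] > 0L) return("ambiguous")
    if (L[i] != config$probe_length) r <- c(r, "length")
    if (gc[i] < config$qc_gc_min) r <- c(r, "gc_low")
    if (gc[i] > config$qc_gc_max) r <- c(r, "gc_high")
    if (tm[i] < config$qc_tm_min) r <- c(r, "tm_low")
    if (tm[i] > config$qc_tm_max) r <- c(r, "tm_high")
    r
  })
  out <- data.frame(probe_id = names(sequences), length = L, gc = gc, tm = tm,
                    complexity = lc,
                    pass = lengths(reasons) == 0L,
                    reasons = vapply(reasons, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "qc_params") <- list(sodium = config$qc_sodium,
                                 tm_formula = "79.8+18.5*log10(Na)+58.4*f+11.8*f^2-820/L",
                                 gc_band = c(config$qc_gc_min, config$qc_gc_max),
                                 tm_band = c(config$qc_tm_min, config$qc_tm_max),
                                 length = config$probe_length)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Summarize a QC report
#'
#' Min, max, mean and median for each stored metric (median uses the
#' midpoint-of-two convention for even counts) plus the pass rate.
#'
#' @param records a `qc_report` from [qc_probes()].
#' @return list of per-metric summaries and `pass_rate`.
#' @export
qc_summary <- function(records) {
  stopifnot(nrow(records) >= 1L)
  summarize <- function(v) list(min = min(v), max = max(v), mean = mean(v),
                                median = median(v))
  list(length = summarize(records$length),
       gc = summarize(records$gc),
       tm = summarize(records$tm),
       complexity = summarize(records$complexity),
       pass_rate = mean(records$pass),
       params = attr(records, "qc_params"))
}
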