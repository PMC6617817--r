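#' One full probe-design pass
#'
#' Runs detection of putative loci at stringency `k`, bait tiling and
#' filtering, candidate-locus determination and per-taxon final probe
#' design, followed (optionally) by the in silico capture test.
#'
#' @param assemblies named list of `genome_assembly` objects (suite).
#' @param mapped named list: non-base taxon -> interval data.frame on the
#'   base genome.
#' @param base base taxon label (must be in `assemblies`).
#' @param k sharing stringency ("+k"): minimum non-base taxa a putative
#'   locus must be shared with.
#' @param config `ucekit_config`.
#' @param required_taxa taxa a candidate locus must qualify in (default:
#'   all taxa of the suite -- the stringent final-design convention).
#' @param insilico run the in silico test and attach its results.
#' @param design design tag (defaults to `<base>_k<k>`).
#' @return list with putative, baits, bait_rejects, candidates, probes, and
#'   (when `insilico`) recovery plus summary.
#' @export
run_probe_design <- function(assemblies, mapped, base, k,
                             config = ucekit_config(),
                             required_taxa = length(assemblies),
                             insilico = TRUE, design = NULL) {
  stopifnot(base %in% names(assemblies))
  if (is.null(design)) design <- sprintf("%s_k%d", base, k)
  putative <- putative_loci(mapped, k, config,
                            base_assembly = assemblies[[base]],
                            base_taxon = base)
  if (nrow(putative) == 0L)
    return(list(putative = putative, baits = NULL, candidates = NULL,
                probes = NULL, recovery = NULL,
                summary = list(per_taxon = setNames(rep(0L, length(assemblies)),
                                                    names(assemblies)),
                               union = 0L),
                design = design))
  baits <- tile_baits(putative, assemblies[[base]], config, design = design)
  filt <- filter_baits(baits, config)
  cand <- candidate_loci(filt$kept, assemblies, config, required_taxa)
  out <- list(putative = putative, baits = filt$kept,
              bait_rejects = filt$rejected, candidates = cand,
              design = design)
  if (nrow(cand$table) == 0L) {
    out$probes <- NULL
    out$recovery <- NULL
    out$summary <- list(per_taxon = setNames(rep(0L, length(assemblies)),
                                             names(assemblies)), union = 0L)
    return(out)
  }
  out$probes <- design_final_probes(cand, assemblies, config, design = design)
  if (insilico) {
    out$recovery <- insilico_test(out$probes, assemblies, config)
    out$summary <- recovery_summary(out$recovery)
  }
  out
}

sweep_row <- function(base, k, run) {
  per_taxon <- run$summary$per_taxon
  data.frame(base = base, k = k,
             putative = nrow(run$putative),
             candidates = if (is.null(run$candidates)) 0L else
               nrow(run$candidates$loci),
             probes = if (is.null(run$probes)) 0L else nrow(run$probes),
             union_recovered = run$summary$union,
             t(per_taxon), stringsAsFactors = FALSE, check.names = FALSE)
}

#' Stringency sweep
#'
#' Repeats the full pipeline for each sharing stringency `k`, holding the
#' base genome and all downstream settings fixed, and tabulates candidate
#' and recovered counts against `k`.
#'
#' @param assemblies named list of `genome_assembly` objects.
#' @param mapped mapping intervals vs `base` (see [run_probe_design()]).
#' @param base fixed base taxon.
#' @param ks stringency values to test (default `1:(T-1)`).
#' @param config `ucekit_config`.
#' @param required_taxa candidate requirement (default all taxa).
#' @param keep_runs retain full per-pass artifacts (memory heavy).
#' @return list with `report` (one row per k) and optionally `runs`.
#' @export
run_stringency_sweep <- function(assemblies, mapped, base,
                                 ks = seq_len(length(assemblies) - 1L),
                                 config = ucekit_config(),
                                 required_taxa = length(assemblies),
                                 keep_runs = FALSE) {
  rows <- list(); runs <- list()
  for (k in ks) {
    run <- run_probe_design(assemblies, mapped, base, k, config,
                            required_taxa)
    message(sprintf("stringency sweep: base=%s k=%d putative=%d union=%d",
                    base, k, nrow(run$putative), run$summary$union))
    rows[[length(rows) + 1L]] <- sweep_row(base, k, run)
    if (keep_runs) runs[[as.character(k)]] <- run
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  out <- list(report = report)
  if (keep_runs) out$runs <- runs
  out
}

#' Base-genome sweep
#'
#' Repeats the full pipeline once per candidate base genome at a fixed
#' stringency, with identical downstream settings, and orders the report by
#' the union count of loci recovered in silico.
#'
#' @param assemblies named list of `genome_assembly` objects.
#' @param mapped_by_base named list: base taxon -> (taxon -> intervals on
#'   that base). Candidates without a mapping entry are skipped (logged).
#' @param k fixed sharing stringency.
#' @param config `ucekit_config`.
#' @param required_taxa candidate requirement (default all taxa).
#' @param keep_runs retain full per-pass artifacts.
#' @return list with `report` (ordered by union recovered, descending) and
#'   optionally `runs`.
#' @export
run_base_sweep <- function(assemblies, mapped_by_base, k = 1L,
                           config = ucekit_config(),
                           required_taxa = length(assemblies),
                           keep_runs = FALSE) {
  rows <- list(); runs <- list()
  for (base in names(assemblies)) {
    if (is.null(mapped_by_base[[base]])) {
      message("base sweep: no mapping for candidate ", base, "; skipped")
      next
    }
    run <- run_probe_design(assemblies, mapped_by_base[[base]], base, k,
                            config, required_taxa)
    message(sprintf("base sweep: base=%s k=%d putative=%d union=%d",
                    base, k, nrow(run$putative), run$summary$union))
    rows[[length(rows) + 1L]] <- sweep_row(base, k, run)
    if (keep_runs) runs[[base]] <- run
  }
  if (!length(rows)) stop("no base candidate had mapping intervals")
  report <- do.call(rbind, rows)
  report <- report[order(-report$union_recovered, report$base), , drop = FALSE]
  rownames(report) <- NULL
  out <- list(report = report)
  if (keep_runs) out$runs <- runs
  out
}

#' Recommend a design workflow
#'
#' Chooses the base genome from sweep results when available (the taxon with
#' the top union recovered count), falling back to the genetic-distance
#' ranking of marker alignments; recommends the least stringent temporary
#' bait design (k = 1) and the final plan: restrict to loci good in all
#' taxa, covered by the chosen design, then merge any legacy probes.
#'
#' @param sweep a [run_base_sweep()] result (optional).
#' @param markers marker alignments for [rank_base_candidates()] (optional).
#' @return list with base, basis ("sweep" or "distance"), k, and `plan`.
#' @export
recommend_workflow <- function(sweep = NULL, markers = NULL) {
  if (is.null(sweep) && is.null(markers))
    stop("need sweep results or marker alignments")
  if (!is.null(sweep)) {
    base <- sweep$report$base[1L]
    basis <- "sweep"
  } else {
    rk <- rank_base_candidates(markers)
    base <- rk$taxon[1L]
    basis <- "distance"
  }
  list(base = base, basis = basis, k = 1L,
       plan = c("design probes with the chosen base at k=1",
                "in silico test against all assemblies",
                "cross-design classification; keep loci good in all taxa",
                "restrict to loci covered by the chosen design",
                "merge legacy probes with deterministic renumbering"))
}
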