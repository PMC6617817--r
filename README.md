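# ucekit

Design and optimize target-capture probe sets for ultraconserved elements
(UCEs).

UCE phylogenomics enriches hundreds to thousands of orthologous loci across
a clade with 120-nt RNA probes targeting regions that stay nearly identical
over deep evolutionary time. Designing such a probe set from a handful of
draft genome assemblies requires two decisions that strongly shape the
outcome: which assembly serves as the **base genome** against which all
other taxa's reads are mapped to seed locus discovery, and the **sharing
stringency "+k"** — how many non-base taxa a conserved region must be shared
with before temporary baits are tiled over it. ucekit implements the full
design cycle so both can be chosen by experiment, for researchers building
clade-specific probe sets where no well-annotated genome exists.

The pipeline (all stages are ordinary R functions):

1. `putative_loci()` — merge per-taxon mapping intervals on the base genome;
   keep regions ≥ `min_length` bp supported by ≥ k non-base taxa.
2. `tile_baits()` / `filter_baits()` — 120-mers at 60-bp offsets with a
   right-aligned terminal bait (every locus base covered); GC 25–70%,
   ambiguity and soft-mask filters.
3. `candidate_loci()` — baits aligned back to every assembly by the built-in
   seeded banded Smith–Waterman engine (identity = matches/aligned columns,
   gaps count as mismatches); a locus qualifies in a taxon iff ≥ 1 bait is a
   unique match and none is a duplicate.
4. `design_final_probes()` — per-taxon probes re-tiled from each taxon's own
   sequence; identical sequences collapsed with provenance.
5. `insilico_test()` — in silico capture against all assemblies: unique
   captures extracted with ± `flank` bp (default 400), paralogous captures
   removed, yielding a taxon × locus recovery matrix and a monolithic FASTA.
6. `cross_match()` / `classify_loci()` / `score_base_genomes()` /
   `build_optimized_subset()` — cross-design comparison at 95/99% identity,
   good / problematic-within / problematic-between classification,
   base-genome scoring, and the final optimized subset with legacy-probe
   merging.

`run_base_sweep()` and `run_stringency_sweep()` orchestrate the two
experiments; `rank_base_candidates()` (p-distance, TN93, NJ patristic)
ranks base candidates by smallest average genetic distance when sweep
experiments are too expensive; `recommend_workflow()` combines them. A
synthetic multi-taxon genome generator with an exact ground-truth registry
(`generate_suite()`) makes the whole pipeline testable offline.

## Worked example

```r
library(ucekit)

cfg <- suite_config(taxa = paste0("tax", 1:5), genome_length = 2e5,
                    n_loci = 40, core_length = 300, flank_length = 400,
                    divergence = 0.025, seed = 7)
suite <- generate_suite(cfg)
suite
#> uce_suite: 5 taxa, 200,000 bp genomes, 40 planted loci, seed 7

head(assembly_report(suite$assemblies), 3)
#>      taxon total_length contig_count   N50 L50   N90 L90 GC_percent
#> tax1  tax1       200000            1 2e+05   1 2e+05   1    50.1095
#> tax2  tax2       200000            1 2e+05   1 2e+05   1    50.1640
#> tax3  tax3       200000            1 2e+05   1 2e+05   1    50.1155

run <- run_probe_design(suite$assemblies, suite$mapped, base = "tax1", k = 1)
nrow(run$putative); nrow(run$candidates$loci); nrow(run$probes)
#> [1] 40     # conserved regions shared with >= 1 other taxon
#> [1] 40     # candidate loci whose baits matched uniquely in all 5 taxa
#> [1] 793    # per-taxon final probes after identical-sequence collapse

run$summary$per_taxon; run$summary$union
#> tax1 tax2 tax3 tax4 tax5
#>   40   40   40   40   40
#> [1] 40     # every planted locus recovered in silico in every taxon

qc <- qc_summary(qc_probes(run$probes))
round(c(gc = qc$gc$median, tm = qc$tm$median, lc = qc$complexity$median,
        pass = qc$pass_rate), 3)
#>      gc      tm      lc    pass
#>  50.833 104.856   0.994   1.000
```

The per-taxon counts are loci recovered by the in silico capture test; the
union is the number of unique loci recovered in at least one taxon (the
figure of merit when comparing base genomes or stringencies). The QC line
reports median probe GC%, melting temperature of the RNA–DNA hybrid
(salt-adjusted formula, 0.9 M Na+) and linguistic complexity, plus the
fraction of probes inside all QC bands.

A thin CLI wraps the same functions
(`inst/cli/ucekit.R`: `synth`, `metrics`, `qc`, `design`, `insilico`,
`compare`, `finalize`, `distance`, `rank-base`, `sweep-stringency`,
`sweep-base`, `recommend`, `convert`, `validate`), with JSON configs
mirroring `ucekit_config()`.

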