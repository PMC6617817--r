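---
title: "Designing and optimizing UCE probe sets with ucekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and optimizing UCE probe sets with ucekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultraconserved elements (UCEs) are short genomic regions that stay nearly
identical across deeply divergent taxa while their flanks accumulate
phylogenetically informative variation. Target-capture phylogenomics rests on
probe sets — collections of 120-nt oligos — that hybridize to these conserved
cores across an entire clade. Designing such a set from a handful of draft
genome assemblies involves a chain of decisions whose consequences are not
obvious in advance: which assembly serves as the *base genome* that seeds
locus discovery, and how many taxa a conserved region must be shared with
before it is worth tiling baits over ("+k" stringency). ucekit implements the
whole design cycle so those decisions can be made by experiment:

1. **Putative loci** — merge the read-mapping intervals of every non-base
   taxon on the base genome and keep regions supported by at least *k* other
   taxa (`putative_loci()`).
2. **Temporary baits** — tile 120-mers at 60-bp offsets over each putative
   locus, with a right-aligned terminal bait so every base is covered, and
   filter on GC, ambiguity and soft-masking (`tile_baits()`,
   `filter_baits()`).
3. **Candidate loci** — align baits back to every assembly with the built-in
   seeded aligner; a locus qualifies in a taxon when at least one bait
   matches uniquely and none matches in duplicate (`candidate_loci()`).
4. **Final probes** — re-tile each candidate locus from every taxon's own
   sequence, so the set enriches the same locus across the whole suite
   (`design_final_probes()`).
5. **In silico capture** — match the probe set against all assemblies,
   remove paralogous captures, and extract each locus with flanking sequence
   into a monolithic FASTA plus a taxon-by-locus recovery matrix
   (`insilico_test()`).
6. **Cross-design comparison** — match monolithic files from alternative
   designs against each other, classify loci as good / problematic-within /
   problematic-between, score base genomes, and build an optimized final
   subset with an optional legacy-probe merge (`cross_match()`,
   `classify_loci()`, `build_optimized_subset()`).

`run_base_sweep()` and `run_stringency_sweep()` orchestrate the two
experiments; `rank_base_candidates()` offers the cheaper alternative of
choosing the base genome by smallest average genetic distance on a few
marker alignments; `recommend_workflow()` combines them.

## The alignment engine

Read mapping and BLAST/lastz-style matching are replaced by one deterministic
seeded local aligner (C++). Exact seed-length *k*-mers shared between query
and target nominate diagonal windows; each window is aligned with banded
Smith–Waterman, where the band width is the maximum number of gap columns a
reportable alignment can carry (a positive score bounds gaps by
`L·match/|gap|`; an identity floor *I* tightens that to `L·(100-I)/I`).
Because the band provably contains any qualifying alignment through the
seed, the best reported hit equals the exhaustive Smith–Waterman optimum
whenever the optimal alignment contains an exact seed-length run — the
property the test suite verifies against a full quadratic DP oracle on
random pairs.

Identity is matches over aligned columns with gaps counted as mismatched
columns; query coverage is the aligned query span over query length. Both
conventions are stated because "similarity" is otherwise ambiguous between
tools.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `probe_length` | 120 bp | capture oligo length |
| `tile_offset` | 60 bp | bait start spacing (2× tiling density) |
| `min_length` | 80 bp | minimum merged conserved region kept |
| `min_overlap` | 1 bp | overlap for a taxon to support a region |
| `min_identity` / `min_coverage` | 90 / 80 % | bait/probe-to-genome matching |
| `seed_length` | 12 | exact-seed length for bait matching |
| `cross_identity` | 99 (95 preset) | cross-design locus matching |
| `cross_seed_length` | 16 | seed for ~1 kb monolithic comparisons |
| `cross_coverage` | 50 % of shorter | floor for a cross-design match |
| `top_delta` | 5 % | score window flagging duplicate hits |
| `flank` | 400 bp | extracted flank in the in silico test |
| `gc_min`/`gc_max` | 25 / 70 % | design-time bait GC band |
| `qc_tm_min`/`qc_tm_max` | 80 / 120 °C | probe QC melting band |
| `qc_sodium` | 0.9 M | salt term of the hybrid Tm formula |

Several of these are conventions rather than published values: tiling
density, the 1-bp support overlap, the 400-bp flank, the bait-matching
thresholds and the duplicate score window are all config-exposed and printed
in report provenance blocks precisely because the design lesson of this
workflow is parameter sensitivity. Where the operational record (command
line `-n 25 -x 70`) and prose ("between 20% and 70%") disagree about the GC
lower bound, both are retained as presets; the command-line values are the
defaults.

The probe QC melting temperature uses the salt-adjusted RNA–DNA hybrid
formula `Tm = 79.8 + 18.5·log10(Na) + 58.4·f + 11.8·f² − 820/L` (f = GC
fraction). The exact variant used by existing bait-QC utilities is not
published; the constants are therefore embedded in every QC report so a
mismatch is diagnosable. Linguistic complexity is distinct substrings over
the maximum possible `Σ_k min(4^k, L−k+1)`; `LC("AAAA") = 4/10 = 0.4`.

## The synthetic world

`generate_suite()` draws an ancestor genome uniformly over ACGT, plants
non-overlapping locus regions (a conserved core with faster-evolving
flanks), then evolves each taxon independently by per-site substitution:
cores at the per-lineage rate, flanks at four times that rate, background at
25%. Tandem-repeat arrays are planted in the ancestor and soft-masked in
every assembly; lineage-specific paralog copies are written into reserved
background slots of the carrier taxon only. The mutation model is
substitution-only by default so every planted coordinate remains exact in
every assembly — the property that makes the truth registry usable for
assertions and makes any taxon usable as base without re-mapping.

**Divergence bookkeeping.** The generator's `divergence` is the per-lineage
substitution rate from the ancestor. A suite described as having "5% core
divergence" is built with per-lineage rate 0.025, because what bait matching
confronts is the *pairwise* divergence between the base and each other taxon
(≈ twice the lineage rate); at 90% matching identity a 5%-pairwise world
recovers essentially everything, while a 10%-pairwise world sits exactly on
the threshold and loses a fifth of its loci to chance. The tests encode the
pairwise reading.

What the generator does **not** emulate: indels (optional nowhere — extracted
coordinates stay exact), coverage-driven assembly fragmentation, sequencing
error, GC-biased composition, and real repeat families. The idealized
"mapper" emits true core coordinates, so a green pipeline test establishes
that detection, tiling, matching, capture and classification are correct —
not that any particular short-read mapper would have produced those
intervals. `corrupt_mapping()` reintroduces the one mapper pathology the
stringency experiments depend on: loci that are present can randomly fail to
be detected. Under 15% per-taxon dropout, requiring support from all six
non-base taxa keeps only `0.85⁶ ≈ 38%` of loci at the putative stage, while
"+1" keeps nearly all — the mechanism behind the headline recommendation to
design temporary baits at low stringency and apply the strict
all-taxa requirement later, at the candidate stage.

## Numerical and design choices

- **Determinism.** Hits are sorted by score with a (contig, start)
  tie-break; Smith–Waterman tie-breaks prefer diagonal > up > left and the
  first maximal cell in row-major order; locus ids are assigned in
  (contig, start) order; neighbor joining breaks Q-matrix ties by lowest
  index pair. Two runs from the same seed are byte-identical.
- **Half-open coordinates.** 0-based half-open everywhere internally (the
  BED convention); SAM input is converted on read; book-ended intervals
  merge.
- **Paralogy labels.** The per-taxon multiplicity evidence inside a
  cross-design cluster decides the label: no taxon multi-matching → good;
  every taxon with evidence multi-matching → problematic-within (the
  split-locus signature: one region, two ids); a mix of single and multi
  taxa → problematic-between (the lineage-specific duplication signature:
  single-copy in some taxa, two copies in another). This makes the two
  problematic categories mutually exclusive while matching both boundary
  constructions.
- **Cross-design seeds.** Monolithic sequences are ~1 kb and compared at
  95/99% identity, where exact 16-mers are guaranteed plentiful; a 16-mer
  seed removes the false-seed cost that dominates 12-mer search at that
  length without weakening the window guarantee.
- **Distances.** p-distance, JC69 and TN93 under pairwise deletion; the
  HKY-corrected variant named alongside TN93 in the original workflow has no
  recoverable closed-form recipe and is not re-implemented — TN93 (its
  generalization) and p-distance carry the ranking. Saturated pairs
  (non-positive log arguments) are flagged rather than silently clamped.
  Negative NJ branch lengths are clamped to zero and flagged.
- **Depth.** Per-locus depth is interval arithmetic (Σ read lengths / locus
  length), an approximation of base-quality-aware pileup depth; the
  covered fraction uses the interval union.
- **Degenerate inputs.** All-N queries warn and return no hits; loci shorter
  than the probe length are skipped and logged at tiling and at per-taxon
  probe design; empty probe sets error.

## Scale of the validation suites

The acceptance tests run the full pipeline on 7 × 1 Mb genomes with 300
planted loci (the stated validation world) for the recovery and stringency
criteria; the base-genome criterion uses 7 × 500 kb with 150 loci — the
criterion fixes no size, and seven full pipeline passes at the larger size
would spend runtime without changing the direction being tested. Paralogy
classification is exercised on registry-derived monolithic designs encoding
exactly a lineage-specific duplication and a split locus: an idealized
single-engine pipeline screens near-identical copies out at the candidate
stage by design, so the cross-design ambiguity that two differently-tuned
real mappers produce cannot arise end-to-end and is constructed directly
instead.

## Known limitations

- One alignment engine throughout: sensitivity asymmetries between a read
  mapper (step 2) and a bait aligner (step 4), offered in the source
  workflow as one explanation of the stringency effect, cannot be
  reproduced.
- Extracted (unaligned) sequence lengths stand in for multiple-alignment
  lengths in the longest-sequence tally; no MAFFT/gblocks re-implementation.
- No E-values or affine gaps; the linear-gap score is a design choice that
  keeps the band bound simple and the engine deterministic.
- The CLI consumes JSON (not YAML) configuration.
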