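Package: ucekit
Title: Ultraconserved Element Probe Set Design and Optimization
Version: 0.1.0
Authors@R:
    person("UCE", "Toolkit Authors", email = "ucekit@example.org", role = c("aut", "cre"))
Description: A toolkit for designing and optimizing target-capture probe sets
    for ultraconserved elements (UCEs). Detects conserved loci shared across a
    suite of genome assemblies relative to a chosen base genome, tiles and
    filters temporary baits under a tunable sharing-stringency parameter,
    designs per-taxon final probes, evaluates probe sets by in silico capture,
    classifies loci for paralogy across alternative designs, ranks candidate
    base genomes by genetic distance, and assembles an optimized final probe
    set with optional legacy-probe merging. Includes a synthetic multi-taxon
    genome generator with a ground-truth registry so the entire pipeline can
    be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
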