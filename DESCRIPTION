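Package: mitosoma
Title: Somatic Mitochondrial Mutation Burden, Spectra, Selection and
    Reversion Analysis from Duplex Sequencing Calls
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of somatic mitochondrial mutations from per-site
    duplex-sequencing variant-call tables: per-site and per-region mutation
    burden with exact Poisson intervals, sliding-window hotspot scans on the
    circular mitochondrial genome, strand-collapsed mutational spectra and
    trinucleotide contexts, a simulation-calibrated hN/hS selection test with
    a multinomial null, correction for nuclear-embedded mitochondrial segment
    (NUMT) read contamination, and tests for somatic reversion mutations at
    conplastic haplotype sites. Includes a synthetic-data generator that
    emulates duplex call tables (negative-binomial depth, region- and
    age-specific rates, hotspots, frequency-dependent selection, reversion
    enrichment and NUMT leakage) so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
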