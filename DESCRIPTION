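Package: nahrhotspot
Title: Digital-PCR Rate Estimation, Breakpoint Mapping and Selection
    Modelling for NAHR Hotspots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for non-allelic homologous recombination
    (NAHR) hotspots mediated by low-copy repeats (LCRs), modelled on the
    DPY19L2 globozoospermia locus. Implements exact hypergeometric
    quantification of rare de novo deletion and duplication events from
    limiting-dilution digital-PCR plates with exact binomial confidence
    intervals; classification of candidate variant sites into LCR-specific
    markers versus shared SNPs from control resequencing panels;
    breakpoint-interval calling, compound-heterozygote decomposition and
    founder-haplotype counting for recombined alleles; population allele
    frequency estimation and a General-Selection-Model mutation-selection
    balance analysis; degenerate PRDM9 13-mer motif scanning with 39-mer
    extended-context scoring; and a fully seeded synthetic-data generator
    emulating the paired-LCR locus, recombined cohorts and sperm
    digital-PCR plates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
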