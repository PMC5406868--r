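Package: csmarray
Title: Cross-Species Microarray Analysis with gDNA Probe Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cross-species Affymetrix-style microarray
    experiments in which RNA from a non-model species is hybridised to an
    array designed for a related species. Probe pairs that hybridise
    efficiently to genomic DNA of the target species are selected by an
    intensity threshold to build genotype-specific custom chip definitions;
    retained probes are summarized per probe set with a masked RMA-style
    procedure (log2 transform, quantile normalization, median polish).
    Downstream stages call expressed probe sets from the ranked-intensity
    curve, test differential expression (Welch t-test, Benjamini-Hochberg
    FDR, fold-change gate), classify stress-responsive versus perturbed
    genes using a recovery treatment, and build Spearman co-expression
    networks with transcription-factor degree ranking. A synthetic-data
    generator emulates the two-genotype dehydration-stress study design for
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
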