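Package: stressgrn
Title: Abiotic-Stress miRNA-TF-Gene Regulatory Networks: Construction and
    Structural Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and characterizes abiotic-stress-responsive regulatory
    networks that couple transcription factors, microRNAs, target mimics and
    their target genes, in the style of plant stress transcriptome and
    degradome meta-analyses. Provides rank-product meta-analysis of
    multi-study expression data with permutation-estimated percentage of
    false positives, reads-per-million normalization and AGO1-enrichment
    filtering of small-RNA libraries, complementarity-based miRNA target-site
    scanning with an expectation penalty score, degradome-tag mapping with
    CleaveLand-style Category 0-4 cleavage-site classification, assembly of
    the five-edge-type directed heterogeneous network, and its structural
    characterization (discrete power-law fits, small-world-ness against
    Erdos-Renyi baselines, directed assortativity, strongly connected
    components, centralities). A seeded synthetic-data generator supplies
    inputs with the statistical structure each stage assumes, so the full
    pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
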