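Package: moqtl
Title: Multi-Omics QTL Mapping and Trans-Regulatory Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for joint transcriptomics and proteomics
    quantitative trait locus (QTL) analysis in a genotyped tissue cohort:
    variant quality control and Hardy-Weinberg exact testing, cis-eQTL and
    cis-pQTL scans with latent-factor adjustment, residual- and ratio-based
    classification of loci into shared and omic-specific regulatory
    categories, approximate-Bayes-factor colocalization, polygenic-score
    guided eQTS/pQTS gene ranking, preranked gene-set enrichment with
    leading-edge candidate selection sized by F-test power analysis,
    targeted trans-QTL mapping, transcription-factor activity scoring from
    binding-site annotations, and a mediation-style filter identifying
    functional transcription-factor targets. Includes a synthetic
    multi-omics cohort generator with a machine-readable truth registry so
    every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
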