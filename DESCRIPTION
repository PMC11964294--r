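Package: heatomics
Title: Multi-Omics Integration of Transcript, Protein, and Metabolite
    Stress Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline integrating bulk transcriptome,
    stable-isotope-ratio proteome, and GC/MS metabolome responses to a
    treatment. Implements per-functional-category correlation of
    transcript and protein log2 fold changes over a hierarchical
    annotation (MapMan-bin style), cross-species ortholog-mapped
    Fisher-exact enrichment of treatment-response gene signatures,
    hypergeometric term enrichment with Benjamini-Yekutieli false
    discovery control over an expressed-gene (RPKM) background,
    replicate-level protein log2-ratio summarisation with a detection
    filter and one-sample t tests, internal-standard QC filtering and
    ratio-of-means Welch statistics for metabolite matrices, and a
    synthetic-data generator with known ground truth for every input
    the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
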