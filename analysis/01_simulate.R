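#!/usr/bin/env Rscript
# Generate the synthetic study inputs every later step consumes: paired
# transcript/protein fold changes over a category hierarchy, a count
# matrix, protein replicate ratios, a metabolite peak-area matrix with a
# planted internal-standard failure, and a signature-enrichment input set.

suppressPackageStartupMessages(library(heatomics))

seed <- 20260927L
fix_dir <- "results/fixtures"
paths <- simulate_fixtures(fix_dir, preset = "full", seed = seed)

cat("Simulated study inputs written to", fix_dir, "\n")
cat(" -", length(paths), "files:", paste(basename(unlist(paths)),
                                         collapse = ", "), "\n")
cat("Planted structure:\n")
cat(" - 8 functional categories (60 genes each) with correlations",
    "0.9, 0.93, 0.85, 0.9, -0.5, -0.47, 0.2, 0\n")
cat(" - 2,000-gene NB count matrix, 10% DE at |log2FC| = 2, 3 reps/group\n")
cat(" - 800 proteins, 5 replicate log2 ratios, mean shift -0.4 (sd 0.5),",
    "10% missing\n")
cat(" - 60 metabolites, n = 5/group, sample 2 planted as an",
    "internal-standard QC failure\n")
cat(" - 3,000-gene target universe, signature planted at odds ratio 4,",
    "orthology redundancy 1.3\n")
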