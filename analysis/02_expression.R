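#!/usr/bin/env Rscript
# Expression processing: RPKM, the expressed-gene background (mean RPKM >
# 20 in both conditions), and DE classification of the transcript table.

suppressPackageStartupMessages(library(heatomics))

fix <- "results/fixtures"; out <- "results/expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cnt <- read.delim(file.path(fix, "counts.tsv"), check.names = FALSE)
counts <- as.matrix(cnt[, -1]); rownames(counts) <- cnt[[1]]
lens <- read.delim(file.path(fix, "gene_lengths.tsv"))
des <- read.delim(file.path(fix, "design.tsv"))
mat <- expression_matrix(counts, setNames(lens$length_bp, lens$gene_id),
                         setNames(des$condition, des$sample_id))

rpkm <- compute_rpkm(mat)
bg <- expressed_background(rpkm, mat$condition, threshold = 20)
writeLines(bg$gene_ids, file.path(out, "expressed_background.txt"))
cat(sprintf("Expressed background (%s): %d of %d genes\n",
            bg$rule, length(bg$gene_ids), nrow(counts)))

tr <- read_response_table(file.path(fix, "transcripts.tsv"), "transcript",
                          col_map = list(feature_id = "feature_id",
                                         log2fc = "log2fc",
                                         p_value = "p_value",
                                         p_adj = "p_adj"))
de <- classify_de(tr, alpha = 0.05)
writeLines(de$up, file.path(out, "de_up.txt"))
writeLines(de$down, file.path(out, "de_down.txt"))
cat(sprintf("DE classification at BH-adjusted p < 0.05: %d up, %d down, %d ns\n",
            length(de$up), length(de$down), length(de$not_significant)))
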