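#!/usr/bin/env Rscript
# Transcripto-proteomic correlation: pair each protein's log2 fold change
# with its gene's transcript response and compute Pearson r / r^2 per
# functional category of the hierarchy, with one scatter HTML per term.

suppressPackageStartupMessages(library(heatomics))

fix <- "results/fixtures"; out <- "results/correlation"
dir.create(file.path(out, "scatter"), recursive = TRUE, showWarnings = FALSE)

cm <- list(feature_id = "feature_id", log2fc = "log2fc",
           p_value = "p_value", p_adj = "p_adj")
tr <- read_response_table(file.path(fix, "transcripts.tsv"), "transcript",
                          col_map = cm)
pr <- read_response_table(file.path(fix, "proteins.tsv"), "protein",
                          col_map = cm)
map <- read_orthology(file.path(fix, "protein_to_gene.tsv"))
hier <- read_annotation(file.path(fix, "annotation.tsv"))

paired <- pair_features(tr, pr, map)
cat(sprintf("paired %d protein-transcript fold changes (exclusions: %s)\n",
            nrow(paired$pairs),
            paste(names(paired$exclusions), paired$exclusions,
                  sep = "=", collapse = ", ")))

cc <- category_correlation(paired$pairs, hier, min_pairs = 5)
write.table(cc, file.path(out, "category_correlation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-category correlations (sorted by |r|):\n")
print(cc[, c("term_id", "n_pairs", "r", "r_squared", "p_value")],
      digits = 3, row.names = FALSE)

for (i in seq_len(nrow(cc))) {
  term <- cc$term_id[i]
  members <- term_members(hier, term)
  export_scatter(cc[i, ],
                 paired$pairs[paired$pairs$gene_id %in% members, ],
                 file.path(out, "scatter",
                           paste0(gsub("[^A-Za-z0-9._-]", "_", term),
                                  ".html")))
}
cat("scatter plots written to", file.path(out, "scatter"), "\n")
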