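#!/usr/bin/env Rscript
# Enrichment: (i) ortholog-mapped Fisher screen of the planted signature
# against the heat-response lists within the cross-species working set;
# (ii) hypergeometric term enrichment of the DE list over the expressed
# background with Benjamini-Yekutieli FDR.

suppressPackageStartupMessages(library(heatomics))

fix <- "results/fixtures"; out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

orth <- read_orthology(file.path(fix, "orthology.tsv"))
ws <- build_working_set(readLines(file.path(fix, "source_expressed.txt")),
                        orth,
                        readLines(file.path(fix, "target_expressed.txt")))
cat(sprintf("working set: %d target genes (%d source ids unmapped)\n",
            ws$n, ws$n_unmapped_source))

dd <- dedup_response_lists(readLines(file.path(fix, "heat_up_sources.txt")),
                           readLines(file.path(fix, "heat_down_sources.txt")),
                           orth)
sets <- read_gene_sets(file.path(fix, "signatures.gmt"))
sig <- response_signature(sets[[1]]$name, sets[[1]]$genes, character(0))
blk <- fisher_signature_block(sig, dd$up, dd$down, ws, alpha = 0.01)
write.table(blk, file.path(out, "signature_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Fisher screen (P < 0.01 significant):\n")
print(blk[, c("direction", "a", "b", "c", "d", "odds_ratio", "p_two",
              "significant")], digits = 3, row.names = FALSE)

# term enrichment of the DE-up list against the expressed background
bg <- readLines("results/expression/expressed_background.txt")
up <- readLines("results/expression/de_up.txt")
hier <- read_annotation(file.path(fix, "annotation.tsv"))
tab <- tryCatch(
  hypergeom_enrichment_table(up, bg, hier),
  error = function(e) { cat("term enrichment skipped:",
                            conditionMessage(e), "\n"); NULL })
if (!is.null(tab)) {
  write.table(tab, file.path(out, "term_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("term enrichment: %d terms tested, %d significant (p < 0.05, BY < 0.1, k >= 5)\n",
              nrow(tab), sum(tab$significant)))
}
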