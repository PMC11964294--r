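#!/usr/bin/env Rscript
# Proteomics: summarise the 5-replicate log2 ratio table with the
# <3-of-5 detection filter and one-sample t tests, then census the
# abundance changes of one annotation class.

suppressPackageStartupMessages(library(heatomics))

fix <- "results/fixtures"; out <- "results/proteomics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reps <- read.delim(file.path(fix, "protein_replicates.tsv"))
summ <- summarize_protein_table(reps, min_detected = 3)
write.table(summ, file.path(out, "protein_summaries.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d proteins: %d passed the 3-of-5 detection filter, %d excluded\n",
            nrow(summ), sum(summ$passed_detection),
            sum(!summ$passed_detection)))
cat(sprintf("significantly shifted (p < 0.05): %d\n",
            sum(summ$p_value < 0.05, na.rm = TRUE)))

# census the whole cohort as one class (fold-change bins, not significance)
hier <- annotation_hierarchy(list(all_proteins = reps$protein_id),
                             hierarchical = FALSE)
cs <- fold_change_census(summ, hier, "all_proteins")
jsonlite::write_json(unclass(cs), file.path(out, "census.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(paste0("census: %d quantified; %d (%.0f%%) decreased 20-90%%; ",
                   "%d (%.0f%%) increased >20%%\n"),
            cs$n_quantified, cs$n_down_20_90,
            100 * cs$n_down_20_90 / cs$n_quantified,
            cs$n_up_gt20, 100 * cs$n_up_gt20 / cs$n_quantified))
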