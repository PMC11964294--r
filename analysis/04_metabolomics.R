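#!/usr/bin/env Rscript
# Metabolomics: internal-standard QC (area >= 1e5, deviation < 70% of the
# batch median), normalisation, and ratio-of-means Welch statistics.

suppressPackageStartupMessages(library(heatomics))

fix <- "results/fixtures"; out <- "results/metabolomics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

met <- read.delim(file.path(fix, "metabolite_areas.tsv"),
                  check.names = FALSE)
areas <- as.matrix(met[, -1]); rownames(areas) <- met[[1]]
samp <- read.delim(file.path(fix, "metabolite_samples.tsv"))
mat <- structure(list(peak_areas = areas,
                      istd_area = setNames(samp$istd_area, samp$sample_id),
                      condition = setNames(samp$condition, samp$sample_id)),
                 class = "metabolite_matrix")

qc <- qc_filter(mat)
cat(sprintf("QC: %d of %d samples rejected (%s)\n", length(qc$rejected),
            ncol(areas), paste(qc$rejected, collapse = ", ")))

resp <- metabolite_responses(normalize_istd(qc$matrix),
                             qc$matrix$condition)
write_response_table(resp, file.path(out, "metabolite_responses.tsv"))
cat(sprintf("%d metabolites; %d significant at Welch p < 0.05; %d non-finite ratios\n",
            nrow(resp), sum(resp$p_value < 0.05, na.rm = TRUE),
            attr(resp, "n_nonfinite")))
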