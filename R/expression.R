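# Expression-level processing: RPKM, the expressed-gene background used as
# the enrichment universe, FDR adjustment, and DE-list classification.

#' Compute RPKM from a count matrix
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = 1e9 * count / (gene_length_bp * library_size)`, with library
#' size taken as the column sum of the supplied counts (self-contained;
#' aligner-reported totals may differ and are not consumed).
#'
#' @param mat an [expression_matrix()].
#' @return Numeric matrix of RPKM values, genes x samples.
#' @export
compute_rpkm <- function(mat) {
  lib <- colSums(mat$counts)
  zero <- lib == 0
  if (any(zero))
    stop_input("zero library size in sample(s): ",
               paste(colnames(mat$counts)[zero], collapse = ", "))
  rpkm <- 1e9 * sweep(mat$counts, 1, mat$gene_length_bp, "/")
  sweep(rpkm, 2, lib, "/")
}

#' Build the expressed-gene background
#'
#' A gene is expressed iff its mean RPKM is strictly greater than
#' `threshold` in the control group AND in the treatment group.  The
#' resulting set is the reference universe for term enrichment.
#'
#' @param rpkm RPKM matrix, genes x samples (from [compute_rpkm()]).
#' @param condition character vector named by sample id, values `"control"`
#'   / `"treatment"`.
#' @param threshold RPKM cutoff, default 20.
#' @return A list of class `expressed_background`: `gene_ids`, `threshold`,
#'   `rule` (textual description).
#' @export
expressed_background <- function(rpkm, condition, threshold = 20) {
  condition <- condition[colnames(rpkm)]
  for (grp in c("control", "treatment"))
    if (!any(condition == grp, na.rm = TRUE))
      stop_input("no samples in condition '", grp, "'")
  m_ctl <- rowMeans(rpkm[, condition == "control", drop = FALSE])
  m_trt <- rowMeans(rpkm[, condition == "treatment", drop = FALSE])
  keep <- m_ctl > threshold & m_trt > threshold
  structure(list(
    gene_ids = rownames(rpkm)[keep],
    threshold = threshold,
    rule = sprintf("mean RPKM > %g in both conditions", threshold)
  ), class = "expressed_background")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH via [stats::p.adjust()]: sort ascending, multiply
#' `p(i)` by `m/i`, enforce monotonicity from the largest down, cap at 1,
#' restore input order.  `NA`s pass through as `NA` and do not count
#' towards `m`.
#'
#' @param p numeric vector of probabilities in `[0, 1]` (NA allowed).
#' @return Adjusted probabilities in the input order.
#' @export
bh_adjust <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' BH step-up with the harmonic-sum correction `c(m) = sum(1/i, i=1..m)`
#' multiplied into each `p(i) * m / i` before the monotone pass; valid
#' under arbitrary dependence.  Wraps [stats::p.adjust()].
#'
#' @inheritParams bh_adjust
#' @return Adjusted probabilities in the input order; pointwise `>=`
#'   [bh_adjust()] on the same input.
#' @export
by_adjust <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BY")
}

#' Classify differential-expression lists
#'
#' Partitions a response table at an adjusted-p cutoff: `up` iff
#' `p_adj < alpha` and `log2fc > 0`; `down` iff `p_adj < alpha` and
#' `log2fc < 0`; everything else (including records with no usable
#' p-value, counted) is `not_significant`.  If `p_adj` is absent but
#' `p_value` present, `p_adj` is computed by [bh_adjust()] over the
#' supplied records.
#'
#' @param responses a response table ([feature_response_table()]).
#' @param alpha adjusted-p threshold, strict `<`; default 0.05.
#' @return A list: `up`, `down`, `not_significant` (character id vectors
#'   partitioning the input) and `n_missing_p` (records with neither
#'   p-value).
#' @export
classify_de <- function(responses, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1)
  padj <- responses$p_adj
  need <- is.na(padj) & !is.na(responses$p_value)
  if (any(need))
    padj[need] <- bh_adjust(responses$p_value)[need]
  n_missing <- sum(is.na(padj))
  if (n_missing)
    warning(n_missing, " record(s) without any p-value classified ",
            "not_significant", call. = FALSE)
  sig <- !is.na(padj) & padj < alpha & !is.na(responses$log2fc)
  up <- sig & responses$log2fc > 0
  down <- sig & responses$log2fc < 0
  list(up = responses$feature_id[up],
       down = responses$feature_id[down],
       not_significant = responses$feature_id[!(up | down)],
       n_missing_p = n_missing)
}
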