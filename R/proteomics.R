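# Proteomics: summarise per-replicate heavy/light log2 ratios into protein
# responses with a detection filter, and the abundance-change census over
# annotation classes.

#' Summarise one protein's replicate log2 ratios
#'
#' Mean over present replicate values; two-sided one-sample t test of the
#' log2 ratios against 0 with `df = n_detected - 1`.  A protein detected in
#' fewer than `min_detected` of `n_total` replicates fails the detection
#' filter: its ratio is considered unreliable, no p-value is computed, and
#' it is excluded from all downstream statistics (not imputed).  Zero
#' replicate variance with `n_detected >= 2` yields no p-value and a
#' degenerate flag.
#'
#' @param replicate_log2_ratios numeric vector, `NA` for missing replicates.
#' @param n_total nominal replicate count (default 5).
#' @param min_detected minimum detections required (default 3; must satisfy
#'   `n_total >= min_detected >= 2`).
#' @param protein_id optional identifier carried through.
#' @return A one-row data frame: `protein_id`, `n_detected`,
#'   `mean_log2_ratio`, `t_statistic`, `p_value`, `passed_detection`,
#'   `degenerate`.
#' @export
summarize_protein <- function(replicate_log2_ratios, n_total = 5L,
                              min_detected = 3L, protein_id = NA_character_) {
  if (min_detected < 2L || n_total < min_detected)
    stop_input("need n_total >= min_detected >= 2")
  v <- replicate_log2_ratios[!is.na(replicate_log2_ratios)]
  n <- length(v)
  if (n > n_total)
    stop_input("more replicate values (", n, ") than n_total (", n_total, ")")
  res <- data.frame(protein_id = protein_id, n_detected = n,
                    mean_log2_ratio = if (n) mean(v) else NA_real_,
                    t_statistic = NA_real_, p_value = NA_real_,
                    passed_detection = n >= min_detected,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  if (!res$passed_detection) return(res)
  if (sd(v) == 0) {
    res$degenerate <- TRUE
    return(res)
  }
  tt <- t.test(v, mu = 0)
  res$t_statistic <- unname(tt$statistic)
  res$p_value <- tt$p.value
  res
}

#' Summarise a replicate log2-ratio table
#'
#' Applies [summarize_protein()] row-wise to a table with a `protein_id`
#' column and one column per replicate.
#'
#' @param replicates data frame: `protein_id` plus replicate columns.
#' @param n_total,min_detected see [summarize_protein()]. `n_total`
#'   defaults to the number of replicate columns.
#' @return A data frame with one [summarize_protein()] row per protein.
#' @export
summarize_protein_table <- function(replicates, n_total = NULL,
                                    min_detected = 3L) {
  rep_cols <- setdiff(names(replicates), "protein_id")
  if (!length(rep_cols)) stop_input("no replicate columns")
  n_total <- n_total %||% length(rep_cols)
  if (min_detected < 2L || n_total < min_detected)
    stop_input("need n_total >= min_detected >= 2")
  vals <- as.matrix(replicates[, rep_cols, drop = FALSE])
  # vectorised equivalent of row-wise summarize_protein()
  n_det <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  mu[n_det == 0] <- NA_real_
  ss <- rowSums((vals - mu)^2, na.rm = TRUE)
  s2 <- ifelse(n_det > 1, ss / (n_det - 1), NA_real_)
  passed <- n_det >= min_detected
  degen <- passed & !is.na(s2) & s2 == 0
  ok <- passed & !degen
  t_stat <- ifelse(ok, mu / sqrt(s2 / n_det), NA_real_)
  p <- ifelse(ok, 2 * pt(-abs(t_stat), n_det - 1), NA_real_)
  data.frame(protein_id = replicates$protein_id, n_detected = n_det,
             mean_log2_ratio = mu, t_statistic = t_stat, p_value = p,
             passed_detection = passed, degenerate = degen,
             stringsAsFactors = FALSE)
}

#' Convert protein summaries to a feature-response table
#'
#' Keeps proteins that passed the detection filter; the log2 ratio becomes
#' `log2fc` and the one-sample t p-value becomes `p_value`.
#'
#' @param summaries output of [summarize_protein_table()].
#' @return A response table (level `"protein"`).
#' @export
protein_responses <- function(summaries) {
  keep <- summaries[summaries$passed_detection, , drop = FALSE]
  feature_response_table(keep$protein_id, "protein", keep$mean_log2_ratio,
                         p_value = keep$p_value,
                         n_control = keep$n_detected,
                         n_treatment = keep$n_detected)
}

#' Fold-change census of an annotation class
#'
#' Counts, among the detection-passing quantified proteins of one
#' annotation class, those decreased in abundance by between `down_lo` and
#' `down_hi` (linear ratio `R = 2^mean_log2_ratio` in
#' `[1 - down_hi, 1 - down_lo]`, both edges closed) and those increased by
#' more than `up_min` (`R > 1 + up_min`).  Membership is by abundance
#' change only, irrespective of significance.  Ties at bin edges are
#' reported in the result for audit.
#'
#' @param summaries output of [summarize_protein_table()].
#' @param hierarchy an [annotation_hierarchy()] over protein ids.
#' @param class_label term code of the class to census.
#' @param down_lo,down_hi decrease bin, as fractions (defaults 0.20, 0.90).
#' @param up_min minimum increase fraction (default 0.20).
#' @return A list of class `census_result`: `class_label`, `n_quantified`,
#'   `n_down_20_90`, `n_up_gt20`, `n_edge_ties`, and the bin edges used.
#' @export
fold_change_census <- function(summaries, hierarchy, class_label,
                               down_lo = 0.20, down_hi = 0.90,
                               up_min = 0.20) {
  members <- term_members(hierarchy, class_label)
  rec <- summaries[summaries$passed_detection &
                     summaries$protein_id %in% members, , drop = FALSE]
  ratio <- 2^rec$mean_log2_ratio
  lo <- 1 - down_hi; hi <- 1 - down_lo
  down <- ratio >= lo & ratio <= hi
  up <- ratio > 1 + up_min
  ties <- sum(ratio == lo | ratio == hi | ratio == 1 + up_min)
  if (ties)
    warning(ties, " protein(s) exactly at a census bin edge", call. = FALSE)
  structure(list(class_label = class_label,
                 n_quantified = nrow(rec),
                 n_down_20_90 = sum(down),
                 n_up_gt20 = sum(up),
                 n_edge_ties = ties,
                 down_ratio_range = c(lo, hi),
                 up_ratio_min = 1 + up_min),
            class = "census_result")
}
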