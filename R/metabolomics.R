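# Metabolomics: internal-standard QC filter, normalisation, and
# ratio-of-means statistics with Welch tests.

#' Internal-standard sample QC filter
#'
#' A sample is retained iff its internal-standard (e.g. ribitol) peak area
#' is at least `min_area` AND deviates from the median internal-standard
#' area of the batch by less than `max_dev` times that median.  The median
#' is computed over all samples in the batch before any rejection.
#' Retained values are never altered.
#'
#' @param mat a `metabolite_matrix` (see [generate_metabolite_matrix()]):
#'   `peak_areas` (metabolite x sample), `istd_area` (per sample),
#'   `condition` (per sample).
#' @param min_area minimum internal-standard area, default `1e5` (rule:
#'   `>=`).
#' @param max_dev maximum fractional deviation from the batch median,
#'   default 0.70 (rule: strict `<`).
#' @return A list: `matrix` (the retained `metabolite_matrix`) and
#'   `rejected` (character vector of rejected sample ids).
#' @export
qc_filter <- function(mat, min_area = 1e5, max_dev = 0.70) {
  istd <- mat$istd_area
  if (!length(istd)) stop_input("no samples")
  med <- median(istd)
  keep <- istd >= min_area & abs(istd - med) < max_dev * med
  if (!any(keep)) stop_input("all samples rejected by the QC filter")
  retained <- structure(list(
    peak_areas = mat$peak_areas[, keep, drop = FALSE],
    istd_area = istd[keep],
    condition = mat$condition[names(istd)[keep]]
  ), class = "metabolite_matrix")
  list(matrix = retained, rejected = names(istd)[!keep])
}

#' Normalise peak areas to the internal standard
#'
#' Each sample's peak areas are divided by that sample's internal-standard
#' area.  Apply after [qc_filter()]; a zero internal-standard area in a
#' retained sample is an error (impossible after QC with `min_area > 0`).
#'
#' @param mat a `metabolite_matrix`.
#' @return Numeric matrix of normalised intensities, metabolite x sample.
#' @export
normalize_istd <- function(mat) {
  if (any(mat$istd_area == 0))
    stop_input("zero internal-standard area in retained sample(s): ",
               paste(names(mat$istd_area)[mat$istd_area == 0],
                     collapse = ", "))
  sweep(mat$peak_areas, 2, mat$istd_area, "/")
}

#' Ratio of means and Welch test for one metabolite
#'
#' The treatment/control signal ratio is the mean normalised intensity in
#' the treatment group divided by the mean in the control group (a ratio of
#' means, not a mean of ratios); the p-value is a two-sided Welch t test
#' (unequal variances, Welch-Satterthwaite df).  A zero control mean gives
#' a non-finite `log2fc` (flagged, not an error); identical constant groups
#' give `p = 1` by convention, flagged degenerate.
#'
#' @param control,treatment numeric vectors of normalised intensities
#'   (length >= 2 each after `NA` removal; missing values are excluded
#'   pairwise per metabolite).
#' @return A list: `ratio`, `log2fc`, `t_statistic`, `df`, `p_value`,
#'   `mean_control`, `mean_treatment`, `nonfinite` flag, `degenerate` flag.
#' @export
ratio_and_welch <- function(control, treatment) {
  control <- control[!is.na(control)]
  treatment <- treatment[!is.na(treatment)]
  if (length(control) < 2L || length(treatment) < 2L)
    stop_input("need >= 2 values per group")
  m_c <- mean(control); m_t <- mean(treatment)
  ratio <- m_t / m_c
  log2fc <- log2(ratio)
  nonfinite <- !is.finite(log2fc)
  if (var(control) == 0 && var(treatment) == 0) {
    return(list(ratio = ratio, log2fc = log2fc, t_statistic = 0,
                df = NA_real_, p_value = if (m_c == m_t) 1 else NA_real_,
                mean_control = m_c, mean_treatment = m_t,
                nonfinite = nonfinite, degenerate = TRUE))
  }
  tt <- t.test(treatment, control, var.equal = FALSE)
  list(ratio = ratio, log2fc = log2fc,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_control = m_c, mean_treatment = m_t,
       nonfinite = nonfinite, degenerate = FALSE)
}

#' Metabolite response table from a normalised matrix
#'
#' Runs [ratio_and_welch()] per metabolite over the two condition groups
#' and assembles a feature-response table (level `"metabolite"`).
#'
#' @param normalized normalised intensity matrix (from [normalize_istd()]).
#' @param condition condition per sample (named by sample id).
#' @return A response table plus attributes `n_nonfinite` and
#'   `n_degenerate` exclusion counters.
#' @export
metabolite_responses <- function(normalized, condition) {
  condition <- condition[colnames(normalized)]
  ctl <- normalized[, condition == "control", drop = FALSE]
  trt <- normalized[, condition == "treatment", drop = FALSE]
  if (ncol(ctl) < 2L || ncol(trt) < 2L)
    stop_input("need >= 2 samples per group")
  # vectorised equivalent of per-metabolite ratio_and_welch() with
  # pairwise NA exclusion
  n_c <- rowSums(!is.na(ctl)); n_t <- rowSums(!is.na(trt))
  m_c <- rowMeans(ctl, na.rm = TRUE); m_t <- rowMeans(trt, na.rm = TRUE)
  v_c <- rowSums((ctl - m_c)^2, na.rm = TRUE) / (n_c - 1)
  v_t <- rowSums((trt - m_t)^2, na.rm = TRUE) / (n_t - 1)
  log2fc <- log2(m_t / m_c)
  se2 <- v_c / n_c + v_t / n_t
  t_stat <- (m_t - m_c) / sqrt(se2)
  df_w <- se2^2 / ((v_c / n_c)^2 / (n_c - 1) + (v_t / n_t)^2 / (n_t - 1))
  p <- 2 * pt(-abs(t_stat), df_w)
  degen <- v_c == 0 & v_t == 0
  p[degen & m_c == m_t] <- 1
  p[degen & m_c != m_t] <- NA_real_
  nonfinite <- !is.finite(log2fc)
  out <- feature_response_table(rownames(normalized), "metabolite", log2fc,
                                p_value = p,
                                mean_control = m_c, mean_treatment = m_t,
                                n_control = n_c, n_treatment = n_t)
  attr(out, "n_nonfinite") <- sum(nonfinite)
  attr(out, "n_degenerate") <- sum(degen)
  out
}
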