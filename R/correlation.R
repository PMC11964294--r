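# Transcripto-proteomic correlation analysis: pair transcript and protein
# log2 fold changes per gene and compute Pearson r, r^2 and p for every
# functional category of a hierarchical annotation.

#' Pair protein and transcript fold changes
#'
#' Joins each protein's log2 fold change to its gene's transcript log2 fold
#' change through a protein-to-gene map.  Pairing is at protein-group
#' granularity: several proteins mapping to one gene each form a pair,
#' reusing that gene's transcript value.  Pairs with a non-finite fold
#' change on either side are excluded and counted.
#'
#' @param transcripts,proteins response tables.
#' @param protein_to_gene an [orthology_map()] from protein id to gene id.
#' @param gene_level if `TRUE`, average protein fold changes per gene
#'   before pairing (one pair per gene) instead of the protein-group
#'   default.
#' @return A list: `pairs` (data frame `gene_id`, `protein_id`,
#'   `log2fc_transcript`, `log2fc_protein`) and `exclusions` (named counts:
#'   `unmapped_protein`, `no_transcript`, `nonfinite`).
#' @export
pair_features <- function(transcripts, proteins, protein_to_gene,
                          gene_level = FALSE) {
  excl <- c(unmapped_protein = 0L, no_transcript = 0L, nonfinite = 0L)
  gene <- unclass(protein_to_gene)[proteins$feature_id]
  excl[["unmapped_protein"]] <- sum(is.na(gene))
  tfc <- stats::setNames(transcripts$log2fc, transcripts$feature_id)
  df <- data.frame(gene_id = unname(gene),
                   protein_id = proteins$feature_id,
                   log2fc_protein = proteins$log2fc,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  df$log2fc_transcript <- unname(tfc[df$gene_id])
  no_t <- !df$gene_id %in% transcripts$feature_id
  excl[["no_transcript"]] <- sum(no_t)
  df <- df[!no_t, , drop = FALSE]
  bad <- !is.finite(df$log2fc_transcript) | !is.finite(df$log2fc_protein)
  excl[["nonfinite"]] <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df))
    stop_input("no transcript-protein pairs formed; check that protein ids ",
               "and gene ids use the same format")
  if (gene_level) {
    agg <- tapply(df$log2fc_protein, df$gene_id, mean)
    df <- data.frame(gene_id = names(agg),
                     protein_id = NA_character_,
                     log2fc_protein = unname(agg),
                     log2fc_transcript = unname(tfc[names(agg)]),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  list(pairs = df[, c("gene_id", "protein_id", "log2fc_transcript",
                      "log2fc_protein")],
       exclusions = excl)
}

pearson_with_p <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (n > 2 && abs(r) < 1) {
    p <- cor.test(x, y)$p.value
  } else if (abs(r) == 1) {
    p <- 0
  } else {
    p <- NA_real_
  }
  list(r = r, r_squared = r * r, p_value = p, n = n)
}

#' Per-category correlation of transcript and protein fold changes
#'
#' For every term of the hierarchy with at least `min_pairs` member pairs
#' (hierarchical membership includes descendants), computes the Pearson
#' correlation between transcript and protein log2 fold changes, its
#' square, and the two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))`.
#' Terms below `min_pairs` are omitted and counted; terms whose pairs have
#' zero variance on either axis are skipped with a degenerate counter.
#' Category p-values are reported raw, with an optional BH column.
#'
#' @param pairs the `pairs` data frame from [pair_features()] (gene-keyed
#'   membership).
#' @param hierarchy an [annotation_hierarchy()] over gene ids.
#' @param min_pairs minimum member pairs per reported term (>= 3;
#'   default 5).
#' @param add_bh add a `p_bh` column of BH-adjusted category p-values.
#' @return A data frame sorted by `abs(r)` descending: `term_id`,
#'   `term_name`, `n_pairs`, `r`, `r_squared`, `p_value`, `sign`
#'   (`positive`/`negative`/`zero`), optional `p_bh`; attributes
#'   `n_below_min` and `n_degenerate`.
#' @export
category_correlation <- function(pairs, hierarchy, min_pairs = 5L,
                                 add_bh = TRUE) {
  if (min_pairs < 3L) stop_input("min_pairs must be >= 3")
  below <- 0L; degen <- 0L
  rows <- list()
  for (term in names(hierarchy$members)) {
    idx <- pairs$gene_id %in% hierarchy$members[[term]]
    n <- sum(idx)
    if (n < min_pairs) { below <- below + 1L; next }
    x <- pairs$log2fc_transcript[idx]; y <- pairs$log2fc_protein[idx]
    if (sd(x) == 0 || sd(y) == 0) { degen <- degen + 1L; next }
    st <- pearson_with_p(x, y)
    nm <- hierarchy$terms$name[hierarchy$terms$term_id == term]
    rows[[term]] <- data.frame(
      term_id = term, term_name = nm[[1]], n_pairs = st$n, r = st$r,
      r_squared = st$r_squared, p_value = st$p_value,
      sign = if (st$r > 0) "positive" else if (st$r < 0) "negative"
             else "zero",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), term_name = character(0),
               n_pairs = integer(0), r = numeric(0), r_squared = numeric(0),
               p_value = numeric(0), sign = character(0))
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  if (add_bh && nrow(out)) out$p_bh <- bh_adjust(out$p_value)
  attr(out, "n_below_min") <- below
  attr(out, "n_degenerate") <- degen
  out
}

svg_num <- function(x) formatC(x, format = "fg", digits = 6)

#' Export a self-contained scatter plot for one category
#'
#' Writes a standalone HTML file with an inline SVG: the member pairs as
#' points (transcript log2FC on x, protein log2FC on y), the identity line,
#' the least-squares fit, and an annotation with the term name, r, r^2, n,
#' and the fitted slope.
#'
#' @param result one row of [category_correlation()] output.
#' @param pairs that term's member pairs (data frame with
#'   `log2fc_transcript`, `log2fc_protein`; must be non-empty).
#' @param path output `.html` path.
#' @return `path`, invisibly.
#' @export
export_scatter <- function(result, pairs, path) {
  if (!nrow(pairs)) stop_input("empty pair list")
  x <- pairs$log2fc_transcript; y <- pairs$log2fc_protein
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2]); icpt <- unname(fit$coefficients[1])
  w <- 520; h <- 480; pad <- 50
  rng <- range(c(x, y, 0)); span <- diff(rng); if (span == 0) span <- 1
  sx <- function(v) pad + (v - rng[1]) / span * (w - 2 * pad)
  sy <- function(v) h - pad - (v - rng[1]) / span * (h - 2 * pad)
  pts <- paste0(sprintf(
    '<circle cx="%s" cy="%s" r="3" fill="#2166ac" fill-opacity="0.6"/>',
    svg_num(sx(x)), svg_num(sy(y))), collapse = "\n")
  line_seg <- function(f, col, dash) sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"%s/>',
    svg_num(sx(rng[1])), svg_num(sy(f(rng[1]))),
    svg_num(sx(rng[2])), svg_num(sy(f(rng[2]))), col,
    if (dash) ' stroke-dasharray="5,4"' else "")
  ann <- sprintf(
    "%s: r = %.3f, r² = %.3f, n = %d, slope = %.3f",
    result$term_name, result$r, result$r_squared, result$n_pairs, slope)
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"><title>",
    result$term_name, "</title></head><body>\n<h3>", ann, "</h3>\n",
    sprintf('<svg width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            w, h),
    '\n<rect width="100%" height="100%" fill="white" stroke="#888"/>\n',
    line_seg(identity, "#999999", TRUE),
    "\n", line_seg(function(v) icpt + slope * v, "#b2182b", FALSE), "\n",
    pts, "\n</svg>\n<p>x: transcript log2FC; y: protein log2FC; dashed: ",
    "identity; red: least-squares fit (slope ", sprintf("%.4f", slope),
    ")</p>\n</body></html>\n")
  writeLines(html, path)
  invisible(path)
}
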