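# Enrichment procedures: ortholog-mapped working-set construction, Fisher
# exact signature overrepresentation, cross-study signature correlation,
# and hypergeometric term enrichment with Benjamini-Yekutieli FDR.

#' Build the cross-species working set
#'
#' The universe for contingency counting: the source study's expressed
#' genes are translated to target-species ids through the orthology map,
#' and intersected (as a set; duplicate targets collapse) with the target
#' study's expressed genes.
#'
#' @param source_expressed character vector of expressed source-species ids.
#' @param orthology an [orthology_map()] (source -> target).
#' @param target_expressed character vector of expressed target-species ids.
#' @return A list of class `working_set`: `target_ids`, `n`, plus counters
#'   `n_unmapped_source` and `n_outside_target`.
#' @export
build_working_set <- function(source_expressed, orthology, target_expressed) {
  if (!length(orthology)) stop_input("orthology map is empty")
  mapped <- unclass(orthology)[unique(source_expressed)]
  n_unmapped <- sum(is.na(mapped))
  converted <- unique(mapped[!is.na(mapped)])
  ws <- intersect(converted, unique(target_expressed))
  if (!length(ws))
    stop_input("working set is empty; check that orthology targets and ",
               "target_expressed use the same id format")
  structure(list(target_ids = ws, n = length(ws),
                 n_unmapped_source = n_unmapped,
                 n_outside_target = length(converted) - length(ws)),
            class = "working_set")
}

#' Ortholog-convert and deduplicate response gene lists
#'
#' Translates the up- and downregulated source-gene lists to target ids and
#' deduplicates each list independently, so each target gene is compared
#' only once per scenario (gene duplication would otherwise inflate the
#' counts).  A target appearing in both lists after the collapse is
#' retained in both, with a warning.  Unmapped sources are dropped and
#' counted.
#'
#' @param up_sources,down_sources character vectors of source-species ids.
#' @param orthology an [orthology_map()].
#' @return A list: `up`, `down` (unique target-id vectors), `n_unmapped`
#'   (named counts), `n_in_both`.
#' @export
dedup_response_lists <- function(up_sources, down_sources, orthology) {
  conv <- function(src) {
    t <- unclass(orthology)[unique(src)]
    list(ids = unique(t[!is.na(t)]), unmapped = sum(is.na(t)))
  }
  up <- conv(up_sources); down <- conv(down_sources)
  both <- intersect(up$ids, down$ids)
  if (length(both))
    warning(length(both), " target gene(s) in both up and down lists after ",
            "orthology collapse; retained in both", call. = FALSE)
  list(up = up$ids, down = down$ids,
       n_unmapped = c(up = up$unmapped, down = down$unmapped),
       n_in_both = length(both))
}

#' Fisher exact test of a 2x2 contingency table
#'
#' Exact hypergeometric test with fixed margins.  Two-sided: the sum of
#' probabilities of all tables (at the observed margins) no more probable
#' than the observed one; `"greater"`: the upper hypergeometric tail.
#'
#' @param tab a [contingency_2x2()].
#' @param sidedness `"two"` (default) or `"greater"`.
#' @return The exact p-value.
#' @export
fisher_exact_p <- function(tab, sidedness = c("two", "greater")) {
  sidedness <- match.arg(sidedness)
  m <- matrix(c(tab$a, tab$c, tab$b, tab$d), 2)
  alt <- if (sidedness == "two") "two.sided" else "greater"
  fisher.test(m, alternative = alt)$p.value
}

#' Fisher exact signature overrepresentation test
#'
#' Cross-classifies the working set by signature membership and response
#' membership (both sets intersected with the working set first), builds
#' the 2x2 table `a = |sig & resp|`, `b = |sig \ resp|`, `c = |resp \ sig|`,
#' `d = n - a - b - c`, and tests it with Fisher's exact test.  Significance
#' is a raw p-value threshold (no correction across signatures, matching a
#' raw screen; apply [bh_adjust()] across records if desired).
#'
#' @param signature_set,response_set character vectors of target ids.
#' @param working a [build_working_set()] result.
#' @param alpha significance threshold on the raw p (strict `<`; default
#'   0.01).
#' @param sidedness `"two"` (default) or `"greater"`; both p-values are
#'   reported, `sidedness` selects the one driving `significant`.
#' @param label record label.
#' @return A one-row data frame: `label`, `a`, `b`, `c`, `d`, `odds_ratio`
#'   (sample `ad/bc`), `p_two`, `p_greater`, `p_value` (the selected one),
#'   `significant`.
#' @export
fisher_signature_test <- function(signature_set, response_set, working,
                                  alpha = 0.01,
                                  sidedness = c("two", "greater"),
                                  label = "signature") {
  sidedness <- match.arg(sidedness)
  check_number(alpha, "alpha", 0, 1)
  ws <- working$target_ids
  sig <- intersect(unique(signature_set), ws)
  resp <- intersect(unique(response_set), ws)
  a <- length(intersect(sig, resp))
  b <- length(sig) - a
  c_ <- length(resp) - a
  d <- working$n - a - b - c_
  if (d < 0) stop("internal error: sets exceed working set")  # nocov
  tab <- contingency_2x2(a, b, c_, d)
  p2 <- fisher_exact_p(tab, "two")
  pg <- fisher_exact_p(tab, "greater")
  p <- if (sidedness == "two") p2 else pg
  data.frame(label = label, a = a, b = b, c = c_, d = d,
             odds_ratio = (a * d) / (b * c_),
             p_two = p2, p_greater = pg, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Four-direction Fisher block for one signature
#'
#' Computes the stimulated x up, stimulated x down, repressed x up and
#' repressed x down overrepresentation tests of a signature against the
#' deduplicated response lists, each within the working set.
#'
#' @param signature a [response_signature()].
#' @param up_targets,down_targets deduplicated target-id response lists
#'   (see [dedup_response_lists()]).
#' @param working a [build_working_set()] result.
#' @inheritParams fisher_signature_test
#' @return A data frame with one row per non-empty direction, columns as
#'   [fisher_signature_test()] plus `direction`.
#' @export
fisher_signature_block <- function(signature, up_targets, down_targets,
                                   working, alpha = 0.01,
                                   sidedness = c("two", "greater")) {
  sidedness <- match.arg(sidedness)
  combos <- list(
    stimulated_x_up = list(signature$stimulated, up_targets),
    stimulated_x_down = list(signature$stimulated, down_targets),
    repressed_x_up = list(signature$repressed, up_targets),
    repressed_x_down = list(signature$repressed, down_targets)
  )
  rows <- lapply(names(combos), function(nm) {
    sets <- combos[[nm]]
    if (!length(sets[[1]]) || !length(sets[[2]])) return(NULL)
    r <- fisher_signature_test(sets[[1]], sets[[2]], working, alpha = alpha,
                               sidedness = sidedness, label = signature$name)
    cbind(data.frame(direction = nm, stringsAsFactors = FALSE), r)
  })
  do.call(rbind, rows)
}

#' Cross-study signature correlation
#'
#' Pearson correlation between a source study's per-gene log2 fold changes
#' and the responses of their orthologs in the target study (e.g. a
#' published regulator-responsive transcript signature against this
#' study's fold changes).
#'
#' @param source_responses a response table in source-species ids.
#' @param target_log2fc named numeric vector: target id -> log2fc.
#' @param orthology an [orthology_map()] (source -> target).
#' @return A list: `r`, `r_squared`, `p_value`, `n` (matched finite pairs).
#' @export
signature_correlation <- function(source_responses, target_log2fc,
                                  orthology) {
  tgt <- unclass(orthology)[source_responses$feature_id]
  x <- source_responses$log2fc
  y <- unname(target_log2fc[tgt])
  keep <- !is.na(tgt) & is.finite(x) & !is.na(y) & is.finite(y)
  if (sum(keep) < 3L) stop_input("fewer than 3 matched pairs")
  pearson_with_p(x[keep], y[keep])
}

#' Hypergeometric term-enrichment upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` of the `n` query genes falling in a term of size `K` within a
#' background of size `N`.
#'
#' @param k observed query genes in the term.
#' @param K term size in the background.
#' @param n query size.
#' @param N background size.
#' @return The upper-tail probability.
#' @export
hypergeom_term_enrichment <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals)))
    stop_validation("counts must be non-negative integers")
  if (K > N || n > N || k > min(K, n) || k < max(0, K + n - N))
    stop_validation("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment over an expressed background
#'
#' Hypergeometric overrepresentation of every annotation term in a query
#' gene list against a background, with Benjamini-Yekutieli FDR across
#' terms.  A term is significant when the raw hypergeometric `p < p_max`,
#' the BY-adjusted value `< fdr_max`, and at least `min_mapped` query
#' genes map to the term.
#'
#' @param query character vector of gene ids (intersected with the
#'   background).
#' @param background character vector of background gene ids.
#' @param hierarchy an [annotation_hierarchy()].
#' @param p_max raw-p threshold (default 0.05).
#' @param fdr_max BY FDR threshold (default 0.1).
#' @param min_mapped minimum query genes mapped to the term (default 5).
#' @return A data frame: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_by`, `significant`, sorted by `p_value`.
#' @export
hypergeom_enrichment_table <- function(query, background, hierarchy,
                                       p_max = 0.05, fdr_max = 0.1,
                                       min_mapped = 5L) {
  background <- unique(background)
  query <- intersect(unique(query), background)
  N <- length(background); n <- length(query)
  if (!n) stop_input("no query genes in the background")
  rows <- lapply(names(hierarchy$members), function(term) {
    memb <- intersect(hierarchy$members[[term]], background)
    K <- length(memb)
    if (!K) return(NULL)
    k <- length(intersect(query, memb))
    data.frame(term_id = term,
               term_name = hierarchy$terms$name[
                 hierarchy$terms$term_id == term][[1]],
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_term_enrichment(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_input("no annotation terms overlap the background")
  out$p_by <- by_adjust(out$p_value)
  out$significant <- out$p_value < p_max & out$p_by < fdr_max &
    out$k >= min_mapped
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
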