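resp <- function(ids, fc, level = "transcript")
  feature_response_table(ids, level, fc)

test_that("pairing joins proteins to transcripts through the gene map", {
  tr <- resp(c("g1", "g2", "g3"), c(1, 2, 3))
  pr <- resp(c("p1", "p2", "p3"), c(0.5, 1.0, 1.5), "protein")
  map <- orthology_map(c("p1", "p2", "p3"), c("g1", "g2", "g3"))
  out <- pair_features(tr, pr, map)
  expect_equal(nrow(out$pairs), 3L)
  expect_equal(out$pairs$log2fc_transcript, c(1, 2, 3))
  expect_true(all(out$exclusions == 0))

  # non-finite protein fold change is excluded and counted
  pr2 <- resp(c("p1", "p2", "p3"), c(0.5, Inf, 1.5), "protein")
  out2 <- pair_features(tr, pr2, map)
  expect_equal(nrow(out2$pairs), 2L)
  expect_equal(unname(out2$exclusions["nonfinite"]), 1L)

  # two proteins on one gene reuse the transcript value
  map2 <- orthology_map(c("p1", "p2"), c("g1", "g1"))
  out3 <- pair_features(tr, resp(c("p1", "p2"), c(0.4, 0.6), "protein"),
                        map2)
  expect_equal(nrow(out3$pairs), 2L)
  expect_equal(out3$pairs$log2fc_transcript, c(1, 1))
  # optional gene-level averaging collapses them
  out4 <- pair_features(tr, resp(c("p1", "p2"), c(0.4, 0.6), "protein"),
                        map2, gene_level = TRUE)
  expect_equal(nrow(out4$pairs), 1L)
  expect_equal(out4$pairs$log2fc_protein, 0.5)

  # unmapped proteins and missing transcripts are counted
  pr5 <- resp(c("p1", "px"), c(1, 1), "protein")
  out5 <- pair_features(tr, pr5, orthology_map(c("p1", "px"),
                                               c("g1", "g_absent")))
  expect_equal(unname(out5$exclusions["no_transcript"]), 1L)

  expect_error(pair_features(tr, resp("py", 1, "protein"),
                             orthology_map("py", "nope")),
               "id.*format|format")
})

test_that("category correlation reproduces hand-computed Pearson values", {
  # y = 2x: r = 1 exactly; p = 0 for the collinear case
  x <- c(1, 2, 3, 4, 5)
  pairs <- data.frame(gene_id = paste0("g", 1:5), protein_id = NA,
                      log2fc_transcript = x, log2fc_protein = 2 * x)
  h <- annotation_hierarchy(list("1" = paste0("g", 1:5)))
  cc <- category_correlation(pairs, h, min_pairs = 5)
  expect_equal(cc$r, 1)
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$sign, "positive")

  # the 4-point fixture: r = 0.6 by direct covariance arithmetic
  x4 <- c(1, 2, 3, 4); y4 <- c(2, 1, 4, 3)
  pairs4 <- data.frame(gene_id = paste0("g", 1:4), protein_id = NA,
                       log2fc_transcript = x4, log2fc_protein = y4)
  h4 <- annotation_hierarchy(list("1" = paste0("g", 1:4)))
  cc4 <- category_correlation(pairs4, h4, min_pairs = 4)
  expect_equal(cc4$r, 0.6, tolerance = 1e-12)
  expect_equal(cc4$r, pearson_oracle(x4, y4), tolerance = 1e-12)
  expect_equal(cc4$r_squared, cc4$r^2, tolerance = 1e-12)
  expect_equal(cc4$p_value, cor.test(x4, y4)$p.value, tolerance = 1e-12)

  # y = -x gives r = -1
  pairsn <- data.frame(gene_id = paste0("g", 1:5), protein_id = NA,
                       log2fc_transcript = x, log2fc_protein = -x)
  ccn <- category_correlation(pairsn, h, min_pairs = 5)
  expect_equal(ccn$r, -1)
  expect_equal(ccn$sign, "negative")

  expect_error(category_correlation(pairs, h, min_pairs = 2), ">= 3")
})

test_that("r is affine-invariant and sign-flips under negation", {
  set.seed(5)
  n <- 40
  pairs <- data.frame(gene_id = paste0("g", 1:n), protein_id = NA,
                      log2fc_transcript = rnorm(n),
                      log2fc_protein = rnorm(n))
  h <- annotation_hierarchy(list("1" = pairs$gene_id))
  r0 <- category_correlation(pairs, h)$r
  aff <- pairs
  aff$log2fc_transcript <- 3 * aff$log2fc_transcript + 7
  aff$log2fc_protein <- 0.5 * aff$log2fc_protein - 2
  expect_equal(category_correlation(aff, h)$r, r0, tolerance = 1e-12)
  neg <- pairs; neg$log2fc_protein <- -neg$log2fc_protein
  expect_equal(category_correlation(neg, h)$r, -r0, tolerance = 1e-12)
})

test_that("hierarchical terms pool descendants; small terms are omitted", {
  genes <- paste0("g", 1:12)
  h <- annotation_hierarchy(list("1.1" = genes[1:5], "1.2" = genes[6:10],
                                 "2" = genes[11:12]))
  set.seed(6)
  pairs <- data.frame(gene_id = genes, protein_id = NA,
                      log2fc_transcript = rnorm(12),
                      log2fc_protein = rnorm(12))
  cc <- category_correlation(pairs, h, min_pairs = 5)
  expect_setequal(cc$term_id, c("1", "1.1", "1.2"))  # "2" has only 2 pairs
  expect_equal(attr(cc, "n_below_min"), 1L)
  # the parent pools its descendants' pairs
  parent <- cc[cc$term_id == "1", ]
  expect_equal(parent$n_pairs, 10L)
  expect_equal(parent$r,
               pearson_oracle(pairs$log2fc_transcript[1:10],
                              pairs$log2fc_protein[1:10]),
               tolerance = 1e-12)
  # a zero-variance axis skips the term with a degenerate counter
  flat <- data.frame(gene_id = genes[1:5], protein_id = NA,
                     log2fc_transcript = rep(1, 5),
                     log2fc_protein = rnorm(5))
  cc2 <- category_correlation(flat,
                              annotation_hierarchy(list("z" = genes[1:5])),
                              min_pairs = 5)
  expect_equal(nrow(cc2), 0L)
  expect_equal(attr(cc2, "n_degenerate"), 1L)
})

test_that("per-category rho is recovered inside Fisher-z intervals", {
  sizes <- c(a = 300L, b = 300L)
  g <- generate_paired_foldchanges(sizes, rho = c(0.9, -0.47), seed = 17)
  pr <- pair_features(g$transcripts, g$proteins, g$protein_to_gene)
  cc <- category_correlation(pr$pairs, g$hierarchy)
  for (term in c("a", "b")) {
    r <- cc$r[cc$term_id == term]
    rho <- g$truth$per_category_rho[[term]]
    half <- qnorm(0.975) / sqrt(300 - 3)
    expect_lt(abs(atanh(r) - atanh(rho)), half * 1.5)
  }
})

test_that("scatter export writes an annotated self-contained HTML", {
  x <- c(1, 2, 3, 4, 5)
  pairs <- data.frame(gene_id = paste0("g", 1:5), protein_id = NA,
                      log2fc_transcript = x, log2fc_protein = 2 * x)
  h <- annotation_hierarchy(list("1" = paste0("g", 1:5)),
                            term_names = c("1" = "Calvin-like"))
  cc <- category_correlation(pairs, h, min_pairs = 5)
  path <- withr::local_tempfile(fileext = ".html")
  export_scatter(cc[1, ], pairs, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  html <- paste(readLines(path), collapse = "\n")
  expect_match(html, "Calvin-like")
  # least-squares slope on the y = 2x fixture is exactly 2
  expect_match(html, "slope = 2\\.000")
  expect_match(html, "<svg")
  expect_error(export_scatter(cc[1, ], pairs[0, ], path), "empty")
})
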