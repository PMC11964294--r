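ws_of <- function(ids) structure(list(target_ids = ids, n = length(ids)),
                                 class = "working_set")

test_that("working set is the ortholog-converted intersection, as a set", {
  orth <- orthology_map(c("s1", "s2", "s3"), c("A1", "A2", "A4"))
  ws <- build_working_set(c("s1", "s2"), orth, c("A1", "A2", "A3"))
  expect_setequal(ws$target_ids, c("A1", "A2"))
  expect_equal(ws$n, 2L)

  # duplicate-target sources collapse
  orth2 <- orthology_map(c("s1", "s2"), c("A1", "A1"))
  ws2 <- build_working_set(c("s1", "s2"), orth2, c("A1", "A2"))
  expect_equal(ws2$target_ids, "A1")

  expect_error(build_working_set(c("s1"), orth, c("Z9")), "id format")
  expect_error(build_working_set("s1", orthology_map(character(0),
                                                     character(0)), "A1"),
               "empty")
})

test_that("response-list dedup keeps one target per scenario and counts drops", {
  orth <- orthology_map(c("s1", "s2", "s4"), c("A1", "A1", "A9"))
  dd <- dedup_response_lists(c("s1", "s2"), character(0), orth)
  expect_equal(dd$up, "A1")
  expect_equal(dd$down, character(0))

  # unmapped source dropped with a counter
  dd2 <- dedup_response_lists(c("s1", "s3"), "s4", orth)
  expect_equal(unname(dd2$n_unmapped["up"]), 1L)
  expect_equal(dd2$down, "A9")

  # a target landing in both lists is retained in both, with a warning
  expect_warning(dd3 <- dedup_response_lists("s1", "s2", orth), "both")
  expect_equal(dd3$up, "A1")
  expect_equal(dd3$down, "A1")
  expect_equal(dd3$n_in_both, 1L)
})

test_that("Fisher p-values match hand enumeration on the micro fixtures", {
  # margins (2,2)/(2,2): table probabilities 1/6, 4/6, 1/6
  expect_equal(fisher_exact_p(contingency_2x2(2, 0, 0, 2), "two"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(contingency_2x2(2, 0, 0, 2), "greater"), 1 / 6,
               tolerance = 1e-12)
  # odds ratio exactly 1: two-sided p = 1
  expect_equal(fisher_exact_p(contingency_2x2(5, 5, 5, 5), "two"), 1,
               tolerance = 1e-12)
})

test_that("signature test builds the table inside the working set", {
  ws <- ws_of(c("A1", "A2", "A3", "A4"))
  r <- fisher_signature_test(c("A1", "A2", "A_outside"), c("A1", "A2"), ws,
                             sidedness = "two")
  expect_equal(c(r$a, r$b, r$c, r$d), c(2, 0, 0, 2))
  expect_equal(r$p_two, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p_greater, 1 / 6, tolerance = 1e-12)
  expect_false(r$significant)

  # empty overlap with the working set: a = 0, upper tail 1
  r0 <- fisher_signature_test(character(0), c("A1"), ws,
                              sidedness = "greater")
  expect_equal(r0$a, 0L)
  expect_equal(r0$p_value, 1)
})

test_that("four-direction block covers stimulated/repressed x up/down", {
  ws <- ws_of(sprintf("A%d", 1:40))
  sig <- response_signature("hormoneX", sprintf("A%d", 1:10),
                            sprintf("A%d", 11:20))
  up <- sprintf("A%d", c(1:8, 21:24))
  down <- sprintf("A%d", c(11:16, 31:32))
  blk <- fisher_signature_block(sig, up, down, ws)
  expect_setequal(blk$direction, c("stimulated_x_up", "stimulated_x_down",
                                   "repressed_x_up", "repressed_x_down"))
  su <- blk[blk$direction == "stimulated_x_up", ]
  expect_equal(c(su$a, su$b, su$c, su$d), c(8, 2, 4, 26))
  expect_equal(su$p_two, fisher_two_oracle(8, 2, 4, 26), tolerance = 1e-9)
})

test_that("cross-study signature correlation joins through orthologs", {
  src <- feature_response_table(c("s1", "s2", "s3", "s4"), "transcript",
                                c(1, 2, 3, 4))
  orth <- orthology_map(c("s1", "s2", "s3", "s4"),
                        c("A1", "A2", "A3", "A4"))
  tgt <- setNames(c(1, 2, 3, 4), c("A1", "A2", "A3", "A4"))
  expect_equal(signature_correlation(src, tgt, orth)$r, 1)
  expect_equal(signature_correlation(src, -tgt, orth)$r, -1)

  tgt2 <- setNames(c(2, 1, 4, 3), c("A1", "A2", "A3", "A4"))
  sc <- signature_correlation(src, tgt2, orth)
  expect_equal(sc$r, 0.6, tolerance = 1e-12)
  expect_equal(sc$n, 4L)

  expect_error(signature_correlation(src[1:2, ], tgt, orth), "3 matched")
})

test_that("hypergeometric tail matches direct combinatorial summation", {
  # N = 10, K = 5, n = 4, k = 4: C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(hypergeom_term_enrichment(4, 5, 4, 10), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeom_term_enrichment(0, 5, 4, 10), 1)
  expect_equal(hypergeom_term_enrichment(6, 6, 6, 6), 1)
  expect_error(hypergeom_term_enrichment(5, 4, 4, 10), "inconsistent")

  # upper tail + strict lower tail sums to 1 across the whole support
  for (cfg in list(c(12, 5, 6), c(30, 10, 15), c(8, 8, 3))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    for (k in max(0, K + n - N):min(K, n)) {
      upper <- hypergeom_term_enrichment(k, K, n, N)
      lower <- phyper(k - 1, K, N - K, n)
      expect_equal(upper + lower, 1, tolerance = 1e-12)
      expect_equal(upper, hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
    }
  }
})

test_that("BY adjustment applies the harmonic correction", {
  # c(3) = 1 + 1/2 + 1/3 = 11/6; all three step up to 0.03 * 11/6 = 0.055
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(by_adjust(0.2), 0.2)
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(2:20, 1))
    expect_equal(by_adjust(p), by_oracle(p), tolerance = 1e-12)
    expect_true(all(by_adjust(p) >= bh_adjust(p) - 1e-15))
    perm <- sample(seq_along(p))
    expect_equal(by_adjust(p[perm]), by_adjust(p)[perm], tolerance = 1e-12)
  }
})

test_that("term enrichment applies the three-part significance rule", {
  bg <- sprintf("g%03d", 1:100)
  hier <- annotation_hierarchy(list(big = bg[1:20], small = bg[1:4]),
                               hierarchical = FALSE)
  query <- bg[1:15]  # 15 of 15 query genes in 'big' (k = 15)
  tab <- hypergeom_enrichment_table(query, bg, hier, min_mapped = 5)
  big <- tab[tab$term_id == "big", ]
  expect_equal(big$k, 15L)
  expect_equal(big$p_value, hyper_tail_oracle(15, 20, 15, 100),
               tolerance = 1e-12)
  expect_equal(tab$p_by, by_adjust(tab$p_value), tolerance = 1e-12)
  expect_true(big$significant)
  # 'small' has k = 4 < 5 mapped entries: never significant
  expect_false(tab$significant[tab$term_id == "small"])
})

test_that("type-I rate of the Fisher screen is conservative at odds 1", {
  # quick version of the simulation property (the full 1,000-draw sweep
  # runs in the acceptance suite)
  hits <- 0L
  for (s in 1:200) {
    g <- generate_signature_experiment(400L, 80L, 40L, planted_odds = 1,
                                       seed = 1000 + s)
    ws <- build_working_set(g$source_expressed, g$orthology,
                            g$target_expressed)
    dd <- dedup_response_lists(g$heat_up_sources, character(0), g$orthology)
    r <- fisher_signature_test(g$signature$stimulated, dd$up, ws)
    hits <- hits + (r$p_two < 0.01)
  }
  expect_lte(hits / 200, 0.02)
})
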