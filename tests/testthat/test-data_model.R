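test_that("response tables round-trip through TSV exactly", {
  df <- feature_response_table(
    feature_id = c("Si000001m", "Si000002m", "Si000003m"),
    level = "transcript",
    log2fc = c(1.25, -0.5, 0.333333333333),
    p_value = c(0.01, NA, 0.2),
    p_adj = c(0.03, NA, 0.3)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_response_table(df, path)
  back <- read_response_table(path, "transcript",
                              col_map = list(feature_id = "feature_id",
                                             log2fc = "log2fc",
                                             p_value = "p_value",
                                             p_adj = "p_adj"))
  expect_equal(back$feature_id, df$feature_id)
  expect_equal(back$log2fc, df$log2fc, tolerance = 1e-12)
  expect_equal(back$p_value, df$p_value, tolerance = 1e-12)
  expect_equal(back$p_adj, df$p_adj, tolerance = 1e-12)
})

test_that("malformed numeric cells become NA with a warning; NA text is silent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlog2fc\tpvalue",
               "g1\t1.0\t0.05",
               "g2\t2.0\tNA",
               "g3\tnot_a_number\t0.2"), path)
  expect_warning(df <- read_response_table(path, "transcript"),
                 "malformed")
  expect_true(is.na(df$log2fc[3]))
  expect_true(is.na(df$p_value[2]))
  expect_equal(df$p_value[1], 0.05)
})

test_that("duplicate feature ids and missing mandatory columns are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlog2fc", "g1\t1", "g1\t2"), path)
  expect_error(read_response_table(path, "transcript"), "duplicate.*g1")
  writeLines(c("id\tlog2fc", "g1\t1"), path)
  expect_error(read_response_table(path, "transcript"), "feature_id")
})

test_that("GMT reading: sizes, set semantics, errors, empty file", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg1\tg4\tg5\tg6"), path)
  sets <- read_gene_sets(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(lengths(lapply(sets, `[[`, "genes")), c(setA = 3L, setB = 4L))

  writeLines("setC\tdesc\tg1\tg2\tg1", path)
  expect_equal(length(read_gene_sets(path)$setC$genes), 2L)

  writeLines("lonely_field", path)
  expect_error(read_gene_sets(path), "line 1")

  writeLines(character(0), path)
  expect_warning(empty <- read_gene_sets(path), "empty")
  expect_length(empty, 0L)
})

test_that("GMT membership agrees with an independent reader", {
  skip_if_not_installed("fgsea")
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("s1\td\tg1\tg2\tg3", "s2\td\tg9\tg2"), path)
  ours <- lapply(read_gene_sets(path), `[[`, "genes")
  theirs <- fgsea::gmtPathways(path)
  expect_equal(ours[order(names(ours))], theirs[order(names(theirs))])
})

test_that("annotation ancestry closure follows dot-delimited codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tgene", "1.3\tg1", "2\tg2"), path)
  h <- read_annotation(path, hierarchical = TRUE)
  expect_setequal(term_members(h, "1.3"), "g1")
  expect_setequal(term_members(h, "1"), "g1")
  expect_setequal(term_members(h, "2"), "g2")

  flat <- read_annotation(path, hierarchical = FALSE)
  expect_false("1" %in% names(flat$members))
  expect_setequal(term_members(flat, "1.3"), "g1")
})

test_that("ancestry closure is idempotent and malformed codes error", {
  assignments <- list("1.2.3" = c("a", "b"), "1.2" = "c", "4" = "d")
  h1 <- annotation_hierarchy(assignments)
  # re-closing: feed the closed memberships back in as direct assignments
  h2 <- annotation_hierarchy(h1$members)
  expect_equal(h1$members[order(names(h1$members))],
               h2$members[order(names(h2$members))])
  expect_error(annotation_hierarchy(list("1..3" = "g1")), "malformed")
  expect_error(term_members(h1, "nope"), "unknown term")
})

test_that("orthology map rejects duplicates and empty ids", {
  expect_error(orthology_map(c("s1", "s1"), c("A1", "A2")),
               "mapped more than once")
  expect_error(orthology_map(c("s1", ""), c("A1", "A2")), "empty")
  m <- orthology_map(c("s1", "s2"), c("A1", "A1"))
  expect_equal(unname(m[["s2"]]), "A1")
})

test_that("response signatures reject stimulated/repressed overlap", {
  expect_error(response_signature("x", c("A1", "A2"), c("A2")),
               "both stimulated and repressed")
  s <- response_signature("x", c("A1", "A1"), "A3")
  expect_equal(s$stimulated, "A1")
})

test_that("expression matrix and contingency constructors validate", {
  counts <- matrix(c(1L, 2L, 3L, 4L), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_matrix(counts, c(g1 = 100L, g2 = -1L),
                                 c(s1 = "control", s2 = "treatment")),
               "positive length")
  expect_error(expression_matrix(counts, c(g1 = 100L, g2 = 200L),
                                 c(s1 = "control", s2 = "weird")),
               "condition")
  expect_error(contingency_2x2(1, -1, 0, 2), "non-negative")
  expect_silent(contingency_2x2(0, 0, 0, 0))
})
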