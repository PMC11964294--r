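sizes4 <- c(a = 50L, b = 50L, c = 50L, d = 50L)

test_that("paired fold changes honour rho: exact at |rho| = 1, near 0 at rho = 0", {
  g1 <- generate_paired_foldchanges(c(k = 20L), rho = 1, seed = 11)
  p1 <- pair_features(g1$transcripts, g1$proteins, g1$protein_to_gene)
  expect_equal(cor(p1$pairs$log2fc_transcript, p1$pairs$log2fc_protein), 1)

  gm <- generate_paired_foldchanges(c(k = 20L), rho = -1, seed = 11)
  pm <- pair_features(gm$transcripts, gm$proteins, gm$protein_to_gene)
  expect_equal(cor(pm$pairs$log2fc_transcript, pm$pairs$log2fc_protein), -1)

  # standard error of r is about 1/sqrt(n) under rho = 0
  g0 <- generate_paired_foldchanges(c(k = 5000L), rho = 0, seed = 11)
  p0 <- pair_features(g0$transcripts, g0$proteins, g0$protein_to_gene)
  expect_lt(abs(cor(p0$pairs$log2fc_transcript, p0$pairs$log2fc_protein)),
            0.05)
})

test_that("paired generator validates parameters and is deterministic", {
  expect_error(generate_paired_foldchanges(c(k = 10L), rho = 1.2), "rho")
  expect_error(generate_paired_foldchanges(c(k = 1L), rho = 0), ">= 2")
  expect_error(generate_paired_foldchanges(c(k = 10L), rho = 0,
                                           sd_transcript = 0), "sds")
  a <- generate_paired_foldchanges(sizes4, c(0.5, 0, -0.5, 1), seed = 3)
  b <- generate_paired_foldchanges(sizes4, c(0.5, 0, -0.5, 1), seed = 3)
  expect_identical(a, b)
})

test_that("count matrix plants DE at the requested effect size", {
  g <- generate_count_matrix(1000L, n_per_group = 6L, de_fraction = 0,
                             seed = 5)
  expect_true(all(g$truth$de_labels == "null"))

  g <- generate_count_matrix(2000L, n_per_group = 6L, de_fraction = 0.5,
                             effect_log2fc = 1, dispersion = 0.05, seed = 5)
  mat <- g$matrix
  up <- names(g$truth$de_labels)[g$truth$de_labels == "up"]
  expect_gte(length(up), 400L)
  m_t <- rowMeans(mat$counts[up, mat$condition == "treatment"])
  m_c <- rowMeans(mat$counts[up, mat$condition == "control"])
  keep <- m_c > 5  # low-count genes have unstable ratios
  expect_gt(median(m_t[keep] / m_c[keep]), 1.8)
  expect_lt(median(m_t[keep] / m_c[keep]), 2.2)
  expect_true(all(mat$gene_length_bp >= 300 & mat$gene_length_bp <= 5000))
  expect_identical(g$matrix$counts,
                   generate_count_matrix(2000L, n_per_group = 6L,
                                         de_fraction = 0.5,
                                         effect_log2fc = 1,
                                         dispersion = 0.05,
                                         seed = 5)$matrix$counts)
  expect_error(generate_count_matrix(10L, dispersion = 0), "dispersion")
})

test_that("protein replicate missingness matches the binomial tail", {
  g <- generate_protein_replicates(100L, missing_rate = 0, seed = 9)
  expect_true(all(rowSums(!is.na(g$replicates[, -1])) == 5L))

  # P(X <= 2) for X ~ Binomial(5, 0.5) is exactly 0.5
  g <- generate_protein_replicates(10000L, missing_rate = 0.5, seed = 9)
  frac_low <- mean(rowSums(!is.na(g$replicates[, -1])) < 3L)
  expect_gte(frac_low, 0.48)
  expect_lte(frac_low, 0.52)

  # CLT bound on the grand mean under zero shift
  g0 <- generate_protein_replicates(2000L, shift_mean = 0, shift_sd = 0,
                                    noise_sd = 0.3, seed = 9)
  vals <- unlist(g0$replicates[, -1])
  expect_lt(abs(mean(vals)), 3 * 0.3 / sqrt(length(vals)))
})

test_that("metabolite generator plants QC failures and unit fold changes", {
  g <- generate_metabolite_matrix(50L, istd_fail_indices = integer(0),
                                  seed = 2)
  expect_equal(length(qc_filter(g$matrix)$rejected), 0L)

  g2 <- generate_metabolite_matrix(50L, istd_fail_indices = c(2L, 7L),
                                   seed = 2)
  expect_true(all(g2$matrix$istd_area[c(2, 7)] < 1e5))
  expect_setequal(qc_filter(g2$matrix)$rejected,
                  names(g2$matrix$istd_area)[c(2, 7)])

  g3 <- generate_metabolite_matrix(200L, fc = 1, cv = 0.1, seed = 2)
  normed <- normalize_istd(g3$matrix)
  resp <- metabolite_responses(normed, g3$matrix$condition)
  ratios <- resp$mean_treatment / resp$mean_control
  expect_gt(median(ratios), 0.9)
  expect_lt(median(ratios), 1.1)
  expect_identical(
    g3$matrix$peak_areas,
    generate_metabolite_matrix(200L, fc = 1, cv = 0.1, seed = 2)$matrix$peak_areas)
})

test_that("signature experiment plants the population odds ratio", {
  g <- generate_signature_experiment(2000L, 400L, 200L, planted_odds = 1,
                                     redundancy = 1, seed = 4)
  # redundancy 1: orthology map is a bijection on its image
  expect_equal(anyDuplicated(unclass(g$orthology)), 0L)
  expect_identical(
    g$truth$in_signature,
    generate_signature_experiment(2000L, 400L, 200L, planted_odds = 1,
                                  redundancy = 1, seed = 4)$truth$in_signature)

  expect_error(generate_signature_experiment(100L, 10L, 50L,
                                             planted_odds = Inf),
               "infeasible")

  # planted OR >> 1 shows up in the realised cross-classification
  g8 <- generate_signature_experiment(5000L, 1000L, 500L, planted_odds = 8,
                                      seed = 4)
  a <- sum(g8$truth$in_signature & g8$truth$in_heat_up)
  b <- sum(g8$truth$in_signature & !g8$truth$in_heat_up)
  c_ <- sum(!g8$truth$in_signature & g8$truth$in_heat_up)
  d <- sum(!g8$truth$in_signature & !g8$truth$in_heat_up)
  expect_gt((a * d) / (b * c_), 4)
})

test_that("Plackett joint cell reproduces requested odds ratios", {
  for (or in c(0.25, 1, 2, 8)) {
    p11 <- heatomics:::plackett_p11(0.2, 0.3, or)
    p10 <- 0.2 - p11; p01 <- 0.3 - p11; p00 <- 1 - 0.2 - 0.3 + p11
    expect_equal((p11 * p00) / (p10 * p01), or, tolerance = 1e-9)
  }
  expect_equal(heatomics:::plackett_p11(0.2, 0.3, Inf), 0.2)
  expect_equal(heatomics:::plackett_p11(0.8, 0.9, 0), 0.7)
})

test_that("fixture writer emits files the readers accept, deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- simulate_fixtures(d1, "correlation", seed = 21)
  f2 <- simulate_fixtures(d2, "correlation", seed = 21)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("fixture", nm))
  tr <- read_response_table(f1$transcripts, "transcript",
                            col_map = list(feature_id = "feature_id",
                                           log2fc = "log2fc",
                                           p_value = "p_value",
                                           p_adj = "p_adj"))
  expect_gt(nrow(tr), 0)
  h <- read_annotation(f1$annotation)
  expect_true("1" %in% names(h$members))
})
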