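# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth, fully determined by a single integer seed.  Identifier
# shapes follow the deposited naming conventions (Si000001m-style source
# ids, AT1G00010-style target ids) so id-join code paths are exercised.

si_ids <- function(n, offset = 0L) sprintf("Si%06dm", seq_len(n) + offset)
at_ids <- function(n) sprintf("AT%dG%05d", (seq_len(n) - 1L) %% 5L + 1L,
                              ((seq_len(n) - 1L) %/% 5L + 1L) * 10L)

#' Simulate paired transcript/protein fold changes per functional category
#'
#' For each functional category, draws gene-wise (transcript, protein) log2
#' fold-change pairs from a bivariate normal with the stated marginal
#' standard deviations and a category-specific correlation rho.  Protein
#' identifiers map 1:1 onto gene identifiers through the returned mapping.
#' `|rho| = 1` produces exactly collinear pairs.
#'
#' @param category_sizes named integer vector: category code -> number of
#'   genes (each >= 2). Codes may be dot-delimited to exercise hierarchy.
#' @param rho numeric in `[-1, 1]`, one per category (recycled if scalar).
#' @param sd_transcript,sd_protein marginal standard deviations of the log2
#'   fold changes (> 0). Defaults 1.0 and 0.6: protein responses in
#'   ratio-proteomics data are damped relative to transcripts.
#' @param mu_transcript,mu_protein marginal means (default 0).
#' @param nonfinite_rate fraction of transcript records planted with a
#'   non-finite log2fc (one group zero), to force explicit downstream
#'   handling. Default 0.
#' @param seed integer master seed.
#' @return A list: `transcripts` and `proteins` (response tables),
#'   `hierarchy` (an [annotation_hierarchy()] over gene ids),
#'   `protein_to_gene` (an [orthology_map()]), and `truth`
#'   (`per_category_rho`, `seed`).
#' @export
generate_paired_foldchanges <- function(category_sizes, rho,
                                        sd_transcript = 1, sd_protein = 0.6,
                                        mu_transcript = 0, mu_protein = 0,
                                        nonfinite_rate = 0, seed = 1L) {
  if (is.null(names(category_sizes)) || any(!nzchar(names(category_sizes))))
    stop_input("category_sizes must be a named vector of term codes")
  if (any(category_sizes < 2L)) stop_input("category gene counts must be >= 2")
  if (sd_transcript <= 0 || sd_protein <= 0) stop_input("sds must be > 0")
  rho <- rep_len(as.numeric(rho), length(category_sizes))
  if (any(abs(rho) > 1)) stop_input("|rho| must be <= 1")
  check_number(nonfinite_rate, "nonfinite_rate", 0, 1)

  set.seed(derive_seed(seed, 1L))
  n_total <- sum(category_sizes)
  gene_id <- si_ids(n_total)
  cat_of <- rep(names(category_sizes), category_sizes)
  tfc <- numeric(n_total); pfc <- numeric(n_total)
  pos <- 1L
  for (i in seq_along(category_sizes)) {
    n <- category_sizes[[i]]; r <- rho[[i]]
    if (abs(r) == 1) {
      z <- rnorm(n)
      x <- mu_transcript + sd_transcript * z
      y <- mu_protein + sd_protein * r * z
    } else {
      xy <- MASS::mvrnorm(n, mu = c(mu_transcript, mu_protein),
                          Sigma = matrix(c(sd_transcript^2,
                                           r * sd_transcript * sd_protein,
                                           r * sd_transcript * sd_protein,
                                           sd_protein^2), 2))
      x <- xy[, 1]; y <- xy[, 2]
    }
    idx <- pos:(pos + n - 1L)
    tfc[idx] <- x; pfc[idx] <- y
    pos <- pos + n
  }
  if (nonfinite_rate > 0) {
    nf <- runif(n_total) < nonfinite_rate
    tfc[nf] <- Inf  # one group zero: ratio diverges
  }
  protein_id <- paste0(gene_id, ".p")
  transcripts <- feature_response_table(gene_id, "transcript", tfc)
  proteins <- feature_response_table(protein_id, "protein", pfc)
  hierarchy <- annotation_hierarchy(split(gene_id, cat_of),
                                    hierarchical = TRUE)
  list(transcripts = transcripts, proteins = proteins, hierarchy = hierarchy,
       protein_to_gene = orthology_map(protein_id, gene_id),
       truth = list(seed = seed,
                    per_category_rho = stats::setNames(rho,
                                                       names(category_sizes))))
}

#' Simulate a negative-binomial count matrix with planted DE genes
#'
#' Gene-wise baseline means are log-normal; counts are negative binomial
#' with common dispersion.  A `de_fraction` subset of genes is shifted by
#' `+/- effect_log2fc` (half up, half down) in the treatment group.  Gene
#' lengths are uniform on `[300, 5000]` bp.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per condition (>= 2). Default 3, a typical
#'   bulk RNA-seq design.
#' @param de_fraction fraction of genes differentially expressed, in
#'   `[0, 1]`.
#' @param effect_log2fc planted absolute log2 fold change.
#' @param dispersion NB dispersion (> 0); `size = 1/dispersion`.
#' @param lib_size target library size per sample.
#' @param seed integer master seed.
#' @return A list: `matrix` (an [expression_matrix()]) and `truth`
#'   (`de_labels`: named vector in `{up, down, null}`, plus `seed`).
#' @export
generate_count_matrix <- function(n_genes, n_per_group = 3L,
                                  de_fraction = 0.1, effect_log2fc = 2,
                                  dispersion = 0.05, lib_size = 2e7,
                                  seed = 1L) {
  if (n_per_group < 2L) stop_input("n_per_group must be >= 2")
  check_number(de_fraction, "de_fraction", 0, 1)
  if (dispersion <= 0) stop_input("dispersion must be > 0")
  set.seed(derive_seed(seed, 2L))

  gene_id <- si_ids(n_genes)
  base <- rlnorm(n_genes, meanlog = log(50), sdlog = 1.3)
  base <- base / sum(base) * lib_size
  n_de <- round(de_fraction * n_genes)
  labels <- rep("null", n_genes)
  if (n_de > 0) {
    de_idx <- sample.int(n_genes, n_de)
    up <- de_idx[seq_len(ceiling(n_de / 2))]
    down <- setdiff(de_idx, up)
    labels[up] <- "up"; labels[down] <- "down"
  }
  mult <- ifelse(labels == "up", 2^effect_log2fc,
                 ifelse(labels == "down", 2^(-effect_log2fc), 1))
  n_samp <- 2L * n_per_group
  sample_id <- sprintf("S%02d", seq_len(n_samp))
  condition <- stats::setNames(rep(c("control", "treatment"),
                                   each = n_per_group), sample_id)
  counts <- matrix(0L, n_genes, n_samp,
                   dimnames = list(gene_id, sample_id))
  for (j in seq_len(n_samp)) {
    mu <- if (condition[[j]] == "treatment") base * mult else base
    counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  lens <- stats::setNames(as.integer(round(runif(n_genes, 300, 5000))),
                          gene_id)
  list(matrix = expression_matrix(counts, lens, condition),
       truth = list(seed = seed,
                    de_labels = stats::setNames(labels, gene_id)))
}

#' Simulate per-replicate protein log2-ratio tables with missingness
#'
#' Each protein has a true mean log2 ratio (treatment channel over control
#' channel) drawn from `N(shift_mean, shift_sd)`; each of `n_reps`
#' replicate measurements adds `N(0, noise_sd)` noise and is independently
#' missing with probability `missing_rate`.
#'
#' @param n_proteins number of protein groups.
#' @param n_reps replicate count (default 5, the study design emulated).
#' @param shift_mean,shift_sd parameters of the true-shift distribution.
#' @param noise_sd replicate measurement noise sd (default 0.3).
#' @param missing_rate per-replicate missingness probability in `[0, 1)`.
#' @param seed integer master seed.
#' @return A list: `replicates` (data frame `protein_id`, `rep1..repK` with
#'   `NA` for missing) and `truth` (`protein_shift`, `seed`).
#' @export
generate_protein_replicates <- function(n_proteins, n_reps = 5L,
                                        shift_mean = 0, shift_sd = 0,
                                        noise_sd = 0.3, missing_rate = 0,
                                        seed = 1L) {
  if (n_reps < 1L) stop_input("n_reps must be >= 1")
  check_number(missing_rate, "missing_rate", 0, 1)
  if (missing_rate >= 1) stop_input("missing_rate must be < 1")
  if (noise_sd <= 0) stop_input("noise_sd must be > 0")
  set.seed(derive_seed(seed, 3L))

  protein_id <- paste0(si_ids(n_proteins), ".p")
  shift <- rnorm(n_proteins, shift_mean, shift_sd)
  vals <- matrix(rnorm(n_proteins * n_reps, mean = shift, sd = noise_sd),
                 n_proteins, n_reps)
  if (missing_rate > 0)
    vals[matrix(runif(n_proteins * n_reps) < missing_rate,
                n_proteins, n_reps)] <- NA_real_
  reps <- as.data.frame(vals)
  names(reps) <- sprintf("rep%d", seq_len(n_reps))
  reps <- cbind(data.frame(protein_id = protein_id,
                           stringsAsFactors = FALSE), reps)
  list(replicates = reps,
       truth = list(seed = seed,
                    protein_shift = stats::setNames(shift, protein_id)))
}

#' Simulate a GC/MS peak-area matrix with an internal-standard channel
#'
#' Metabolite baseline areas are log-normal; treatment samples are scaled
#' by per-metabolite linear fold changes; multiplicative log-normal noise
#' with coefficient of variation `cv` is applied.  Internal-standard areas
#' are drawn around a 2e5 nominal; samples listed in `istd_fail_indices`
#' instead get areas below 1e5 so the downstream QC filter rejects them.
#'
#' @param n_metabolites number of metabolites.
#' @param group_sizes integer vector `c(control = ..., treatment = ...)`;
#'   default 5 and 5 (the emulated study design).
#' @param fc per-metabolite linear fold change (recycled if scalar).
#' @param cv coefficient of variation of the multiplicative noise (> 0).
#' @param istd_fail_indices integer sample indices planted as QC failures.
#' @param seed integer master seed.
#' @return A list: `matrix` (class `metabolite_matrix`: `peak_areas`
#'   metabolite x sample, `istd_area` per sample, `condition` per sample)
#'   and `truth` (`metabolite_fc`, `seed`).
#' @export
generate_metabolite_matrix <- function(n_metabolites,
                                       group_sizes = c(control = 5L,
                                                       treatment = 5L),
                                       fc = 1, cv = 0.1,
                                       istd_fail_indices = integer(0),
                                       seed = 1L) {
  if (cv <= 0) stop_input("cv must be > 0")
  fc <- rep_len(as.numeric(fc), n_metabolites)
  if (any(fc < 0)) stop_input("fold changes must be >= 0")
  set.seed(derive_seed(seed, 4L))

  n_samp <- sum(group_sizes)
  metab_id <- sprintf("M%04d", seq_len(n_metabolites))
  sample_id <- sprintf("GC%02d", seq_len(n_samp))
  condition <- stats::setNames(rep(names(group_sizes), group_sizes),
                               sample_id)
  base <- rlnorm(n_metabolites, meanlog = log(5e5), sdlog = 1)
  sdlog <- sqrt(log(1 + cv^2))
  mu <- base %o% rep(1, n_samp)
  mu[, condition == "treatment"] <- mu[, condition == "treatment"] * fc
  areas <- matrix(rlnorm(n_metabolites * n_samp,
                         meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog),
                  n_metabolites, n_samp,
                  dimnames = list(metab_id, sample_id))
  istd <- rlnorm(n_samp, meanlog = log(2e5), sdlog = sqrt(log(1 + 0.05^2)))
  if (length(istd_fail_indices))
    istd[istd_fail_indices] <- runif(length(istd_fail_indices), 2e4, 9e4)
  mat <- structure(list(peak_areas = areas,
                        istd_area = stats::setNames(istd, sample_id),
                        condition = condition),
                   class = "metabolite_matrix")
  list(matrix = mat,
       truth = list(seed = seed,
                    metabolite_fc = stats::setNames(fc, metab_id)))
}

# Joint cell probability p11 of a 2x2 with marginals (p1, p2) and odds
# ratio `or` (Plackett's solution); used to plant population odds ratios.
plackett_p11 <- function(p1, p2, or) {
  if (!is.finite(or)) return(min(p1, p2))
  if (or == 1) return(p1 * p2)
  if (or == 0) return(max(0, p1 + p2 - 1))
  s <- 1 + (p1 + p2) * (or - 1)
  (s - sqrt(s^2 - 4 * or * (or - 1) * p1 * p2)) / (2 * (or - 1))
}

#' Simulate a cross-species signature-enrichment experiment
#'
#' Builds a target-species gene universe, a response signature, and
#' heat-response source-gene lists whose 2x2 cross-classification
#' (signature membership x heat-up membership) has a planted population
#' odds ratio, plus an orthology map with many-to-one redundancy.
#'
#' Membership of each target gene in the signature and in the heat-up set
#' is drawn independently across genes from the joint Bernoulli law with
#' marginals `n_sig / n_target_genes`, `n_heat_up / n_target_genes` and the
#' requested odds ratio, so set sizes are random around the requested
#' values but the population odds ratio is exact.
#'
#' @param n_target_genes size of the target-species expressed universe.
#' @param n_heat_up expected number of heat-upregulated target genes.
#' @param n_sig expected signature size.
#' @param planted_odds population odds ratio (>= 0; `Inf` nests the
#'   signature inside the heat-up set).
#' @param redundancy mean number of source genes per target gene (>= 1);
#'   the orthology map is a bijection on its image when `redundancy = 1`.
#' @param seed integer master seed.
#' @return A list: `orthology` (an [orthology_map()]), `signature` (a
#'   [response_signature()] over target ids, with the universe as its
#'   expressed background), `heat_up_sources`, `heat_down_sources`,
#'   `source_expressed`, `target_expressed`, and `truth` (`planted_odds`,
#'   memberships, `seed`).
#' @export
generate_signature_experiment <- function(n_target_genes, n_heat_up, n_sig,
                                          planted_odds = 1, redundancy = 1,
                                          seed = 1L) {
  if (n_sig > n_target_genes || n_heat_up > n_target_genes)
    stop_input("n_sig and n_heat_up must be <= n_target_genes")
  if (planted_odds < 0) stop_input("planted_odds must be >= 0")
  if (redundancy < 1) stop_input("redundancy must be >= 1")
  p1 <- n_sig / n_target_genes; p2 <- n_heat_up / n_target_genes
  if (is.infinite(planted_odds) && n_sig > n_heat_up)
    stop_input("infeasible: odds ratio Inf needs n_sig <= n_heat_up")
  p11 <- plackett_p11(p1, p2, planted_odds)
  if (p11 < max(0, p1 + p2 - 1) - 1e-12 || p11 > min(p1, p2) + 1e-12)
    stop_input("infeasible marginals for requested odds ratio")
  set.seed(derive_seed(seed, 5L))

  target <- at_ids(n_target_genes)
  # joint draw: cells (sig&up, sig only, up only, neither)
  probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  cell <- sample.int(4L, n_target_genes, replace = TRUE, prob = pmax(probs, 0))
  in_sig <- cell %in% c(1L, 2L)
  in_up <- cell %in% c(1L, 3L)

  # orthology: each target receives >= 1 source; extras give redundancy
  extra <- if (redundancy > 1)
    rpois(n_target_genes, redundancy - 1) else rep(0L, n_target_genes)
  tgt_rep <- rep(target, 1L + extra)
  src <- si_ids(length(tgt_rep))
  orth <- orthology_map(src, tgt_rep)

  up_sources <- src[tgt_rep %in% target[in_up]]
  # a disjoint down set, drawn from genes not up, for the four-direction block
  not_up <- which(!in_up)
  n_down <- min(length(not_up), max(0L, round(n_heat_up / 2)))
  down_targets <- if (n_down > 0) target[sample(not_up, n_down)] else character(0)
  down_sources <- src[tgt_rep %in% down_targets]

  sig <- response_signature("planted", stimulated = target[in_sig],
                            repressed = character(0),
                            expressed_background = target)
  list(orthology = orth,
       signature = sig,
       heat_up_sources = up_sources,
       heat_down_sources = down_sources,
       source_expressed = src,
       target_expressed = target,
       truth = list(seed = seed, planted_odds = planted_odds,
                    in_signature = stats::setNames(in_sig, target),
                    in_heat_up = stats::setNames(in_up, target)))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Materialises, in the exact TSV/GMT dialects the readers consume, one
#' coherent set of inputs for every pipeline stage: paired fold-change
#' tables with a hierarchical annotation, a count matrix with lengths and
#' design, protein replicate ratios, a metabolite peak-area matrix with
#' internal-standard channel, and a signature-enrichment input set.
#'
#' @param out_dir output directory (created if needed).
#' @param preset one of `"full"`, `"correlation"` (paired fold changes only), or
#'   `"enrichment"` (signature inputs only).
#' @param seed integer master seed.
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_fixtures <- function(out_dir, preset = c("full", "correlation",
                                                  "enrichment"),
                              seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- function(f) file.path(out_dir, f)

  if (preset %in% c("full", "correlation")) {
    sizes <- stats::setNames(rep(60L, 8L),
                             c("1", "1.1", "1.2", "2", "3", "3.1", "4", "5"))
    rho <- c(0.9, 0.93, 0.85, 0.9, -0.5, -0.47, 0.2, 0)
    pf <- generate_paired_foldchanges(sizes, rho, seed = seed)
    # give transcripts Wald-style p-values so DE classification downstream
    # has something to work with (standard error 0.4 per gene)
    pf$transcripts$p_value <- 2 * stats::pnorm(-abs(pf$transcripts$log2fc) / 0.4)
    write_response_table(pf$transcripts, p("transcripts.tsv"))
    write_response_table(pf$proteins, p("proteins.tsv"))
    write_annotation(pf$hierarchy, p("annotation.tsv"))
    write_orthology(pf$protein_to_gene, p("protein_to_gene.tsv"))
    paths <- c(paths, list(transcripts = p("transcripts.tsv"),
                           proteins = p("proteins.tsv"),
                           annotation = p("annotation.tsv"),
                           protein_to_gene = p("protein_to_gene.tsv")))
  }
  if (preset == "full") {
    cm <- generate_count_matrix(2000L, seed = seed)
    cnt <- data.frame(gene_id = rownames(cm$matrix$counts),
                      cm$matrix$counts, check.names = FALSE)
    utils::write.table(cnt, p("counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(cm$matrix$gene_length_bp),
                 length_bp = cm$matrix$gene_length_bp),
      p("gene_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(cm$matrix$condition),
                 condition = cm$matrix$condition),
      p("design.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

    pr <- generate_protein_replicates(800L, shift_mean = -0.4,
                                      shift_sd = 0.5, missing_rate = 0.1,
                                      seed = seed)
    utils::write.table(pr$replicates, p("protein_replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    mm <- generate_metabolite_matrix(60L, fc = 1, istd_fail_indices = 2L,
                                     seed = seed)
    met <- data.frame(metabolite_id = rownames(mm$matrix$peak_areas),
                      mm$matrix$peak_areas, check.names = FALSE)
    utils::write.table(met, p("metabolite_areas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(mm$matrix$istd_area),
                 istd_area = mm$matrix$istd_area,
                 condition = mm$matrix$condition),
      p("metabolite_samples.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    paths <- c(paths, list(counts = p("counts.tsv"),
                           gene_lengths = p("gene_lengths.tsv"),
                           design = p("design.tsv"),
                           protein_replicates = p("protein_replicates.tsv"),
                           metabolite_areas = p("metabolite_areas.tsv"),
                           metabolite_samples = p("metabolite_samples.tsv")))
  }
  if (preset %in% c("full", "enrichment")) {
    se <- generate_signature_experiment(3000L, 600L, 300L, planted_odds = 4,
                                        redundancy = 1.3, seed = seed)
    write_orthology(se$orthology, p("orthology.tsv"))
    write_gene_sets(list(list(name = "planted_stimulated",
                              description = "synthetic signature",
                              genes = se$signature$stimulated)),
                    p("signatures.gmt"))
    writeLines(se$heat_up_sources, p("heat_up_sources.txt"))
    writeLines(se$heat_down_sources, p("heat_down_sources.txt"))
    writeLines(se$source_expressed, p("source_expressed.txt"))
    writeLines(se$target_expressed, p("target_expressed.txt"))
    paths <- c(paths, list(orthology = p("orthology.tsv"),
                           signatures = p("signatures.gmt"),
                           heat_up_sources = p("heat_up_sources.txt"),
                           heat_down_sources = p("heat_down_sources.txt"),
                           source_expressed = p("source_expressed.txt"),
                           target_expressed = p("target_expressed.txt")))
  }
  invisible(paths)
}
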