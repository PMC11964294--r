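# End-to-end pipeline: configuration validation, stage orchestration in
# dependency order, run manifest, and the JSON + HTML summary report.

pipeline_defaults <- function() list(
  alpha_de = 0.05, rpkm_threshold = 20,
  min_detected = 3L, census_class = NULL,
  qc_min_area = 1e5, qc_max_dev = 0.70,
  min_pairs = 5L, fisher_alpha = 0.01, fisher_sidedness = "two",
  go_p_max = 0.05, go_fdr_max = 0.1, go_min_mapped = 5L,
  seed = 1L
)

known_config_keys <- function() c(
  names(pipeline_defaults()),
  "inputs", "out_dir"
)

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks parameter ranges and
#' that every referenced input path exists.
#'
#' @param config a named list (or path to a YAML file) with an `inputs`
#'   list of file paths (as written by [simulate_fixtures()]), an
#'   `out_dir`, and optional stage parameters.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), known_config_keys())
  if (length(unknown))
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$inputs) || is.null(cfg$out_dir))
    stop_input("config needs 'inputs' and 'out_dir'")
  check_number(cfg$alpha_de, "alpha_de", 0, 1)
  check_number(cfg$fisher_alpha, "fisher_alpha", 0, 1)
  check_number(cfg$go_p_max, "go_p_max", 0, 1)
  check_number(cfg$go_fdr_max, "go_fdr_max", 0, 1)
  missing <- Filter(function(p) !file.exists(p),
                    unlist(cfg$inputs, use.names = TRUE))
  if (length(missing))
    stop_input("missing input path(s): ", paste(missing, collapse = ", "))
  cfg
}

read_id_list <- function(path) unique(readLines(path, warn = FALSE))

#' Run the full pipeline on a set of input files
#'
#' Executes the stages in dependency order — expression (RPKM background +
#' DE classification), proteomics summarisation, metabolomics QC +
#' ratios, transcript-protein category correlation, signature Fisher
#' screen, term enrichment — then renders the summary report.  Stages
#' whose inputs are absent from `config$inputs` are skipped and recorded.
#' Identical config + inputs yield identical outputs.
#'
#' @param config see [validate_config()].
#' @return The run manifest (list): tool version, config hash, input
#'   checksums, per-stage record counts and exclusion counters, output
#'   paths, timestamps.  Written to `out_dir/manifest.json` alongside all
#'   stage outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ins <- cfg$inputs
  out <- function(f) file.path(cfg$out_dir, f)
  manifest <- list(
    tool = "heatomics",
    version = as.character(utils::packageVersion("heatomics")),
    started = format(Sys.time(), tz = "UTC"),
    config_hash = config_md5(cfg),
    input_md5 = as.list(tools::md5sum(unlist(ins))),
    stages = list()
  )
  results <- list()
  stage <- function(name, expr) {
    rec <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, out("manifest.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), rec$counts)
    results[[name]] <<- rec$value
  }

  # --- de: expression background + classification -----------------------
  if (!is.null(ins$counts)) stage("de", {
    cnt <- utils::read.delim(ins$counts, check.names = FALSE)
    counts <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(counts) <- cnt[[1]]
    lens <- utils::read.delim(ins$gene_lengths)
    des <- utils::read.delim(ins$design)
    mat <- expression_matrix(counts,
                             stats::setNames(lens[[2]], lens[[1]]),
                             stats::setNames(des[[2]], des[[1]]))
    rpkm <- compute_rpkm(mat)
    bg <- expressed_background(rpkm, mat$condition, cfg$rpkm_threshold)
    writeLines(bg$gene_ids, out("expressed_background.txt"))
    de <- NULL
    if (!is.null(ins$transcripts)) {
      tr <- read_response_table(ins$transcripts, "transcript",
                                col_map = list(feature_id = "feature_id",
                                               log2fc = "log2fc",
                                               p_value = "p_value",
                                               p_adj = "p_adj"))
      de <- classify_de(tr, cfg$alpha_de)
      writeLines(de$up, out("de_up.txt"))
      writeLines(de$down, out("de_down.txt"))
    }
    list(value = list(background = bg, de = de),
         counts = list(n_genes = nrow(counts),
                       n_background = length(bg$gene_ids),
                       n_up = length(de$up), n_down = length(de$down)))
  })

  # --- prot: replicate summarisation ------------------------------------
  if (!is.null(ins$protein_replicates)) stage("prot", {
    reps <- utils::read.delim(ins$protein_replicates)
    summ <- summarize_protein_table(reps, min_detected = cfg$min_detected)
    utils::write.table(summ, out("protein_summaries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    census <- NULL
    if (!is.null(cfg$census_class) && !is.null(ins$annotation)) {
      hier <- read_annotation(ins$annotation)
      census <- fold_change_census(summ, hier, cfg$census_class)
      jsonlite::write_json(unclass(census), out("census.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    list(value = list(summaries = summ, census = census),
         counts = list(n_proteins = nrow(summ),
                       n_passed = sum(summ$passed_detection),
                       n_failed_detection = sum(!summ$passed_detection)))
  })

  # --- metab: QC + normalisation + ratios -------------------------------
  if (!is.null(ins$metabolite_areas)) stage("metab", {
    met <- utils::read.delim(ins$metabolite_areas, check.names = FALSE)
    areas <- as.matrix(met[, -1, drop = FALSE])
    rownames(areas) <- met[[1]]
    samp <- utils::read.delim(ins$metabolite_samples)
    mat <- structure(list(
      peak_areas = areas,
      istd_area = stats::setNames(samp$istd_area, samp$sample_id),
      condition = stats::setNames(samp$condition, samp$sample_id)),
      class = "metabolite_matrix")
    qc <- qc_filter(mat, cfg$qc_min_area, cfg$qc_max_dev)
    normed <- normalize_istd(qc$matrix)
    resp <- metabolite_responses(normed, qc$matrix$condition)
    write_response_table(resp, out("metabolite_responses.tsv"))
    list(value = list(responses = resp, rejected = qc$rejected),
         counts = list(n_metabolites = nrow(resp),
                       n_samples_rejected = length(qc$rejected),
                       n_nonfinite = attr(resp, "n_nonfinite")))
  })

  # --- correlation: transcript-protein category correlation -------------
  if (!is.null(ins$transcripts) && !is.null(ins$proteins))
    stage("correlation", {
    cm <- list(feature_id = "feature_id", log2fc = "log2fc",
               p_value = "p_value", p_adj = "p_adj")
    tr <- read_response_table(ins$transcripts, "transcript", col_map = cm)
    pr <- read_response_table(ins$proteins, "protein", col_map = cm)
    map <- read_orthology(ins$protein_to_gene)
    hier <- read_annotation(ins$annotation)
    paired <- pair_features(tr, pr, map)
    cc <- category_correlation(paired$pairs, hier, cfg$min_pairs)
    utils::write.table(cc, out("category_correlation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = list(correlations = cc, pairs = paired$pairs),
         counts = c(list(n_pairs = nrow(paired$pairs),
                         n_terms = nrow(cc)),
                    as.list(paired$exclusions)))
  })

  # --- hormone: Fisher signature screen ---------------------------------
  if (!is.null(ins$signatures)) stage("hormone", {
    orth <- read_orthology(ins$orthology)
    ws <- build_working_set(read_id_list(ins$source_expressed), orth,
                            read_id_list(ins$target_expressed))
    dd <- dedup_response_lists(read_id_list(ins$heat_up_sources),
                               read_id_list(ins$heat_down_sources), orth)
    sets <- read_gene_sets(ins$signatures)
    rows <- lapply(sets, function(s)
      fisher_signature_test(s$genes, dd$up, ws, alpha = cfg$fisher_alpha,
                            sidedness = cfg$fisher_sidedness,
                            label = s$name))
    tab <- do.call(rbind, rows)
    utils::write.table(tab, out("signature_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = list(enrichment = tab, working_set = ws),
         counts = list(n_working = ws$n, n_signatures = nrow(tab),
                       n_significant = sum(tab$significant)))
  })

  # --- go: hypergeometric term enrichment -------------------------------
  if (!is.null(ins$annotation) && !is.null(results$de$de)) stage("go", {
    hier <- read_annotation(ins$annotation)
    bg <- results$de$background$gene_ids
    query <- intersect(results$de$de$up, bg)
    tab <- tryCatch(
      hypergeom_enrichment_table(query, bg, hier, cfg$go_p_max,
                                 cfg$go_fdr_max, cfg$go_min_mapped),
      heatomics_input_error = function(e) NULL)
    if (!is.null(tab))
      utils::write.table(tab, out("term_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    list(value = list(enrichment = tab),
         counts = list(n_terms = if (is.null(tab)) 0L else nrow(tab),
                       n_significant = if (is.null(tab)) 0L
                                       else sum(tab$significant)))
  })

  manifest$finished <- format(Sys.time(), tz = "UTC")
  report <- render_report(results, cfg$out_dir)
  manifest$outputs <- report$paths
  write_manifest(manifest, out("manifest.json"))
  invisible(c(manifest, list(results = results)))
}

config_md5 <- function(cfg) {
  # order-independent fingerprint of the effective configuration
  flat <- unlist(cfg[sort(names(cfg))])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(sprintf("%s=%s", names(flat), flat), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 15L) {
  df <- utils::head(df, max_rows)
  cells <- function(row, tag) paste0(
    "<", tag, ">",
    vapply(row, function(v) html_escape(format(v, digits = 4)), character(1)),
    "</", tag, ">", collapse = "")
  paste0("<table border='1' cellpadding='3'>\n<tr>",
         cells(names(df), "th"), "</tr>\n",
         paste(vapply(seq_len(nrow(df)), function(i)
           paste0("<tr>", cells(df[i, ], "td"), "</tr>"),
           character(1)), collapse = "\n"),
         "\n</table>")
}

#' Render the end-of-run summary report
#'
#' Produces a JSON summary and an HTML page mirroring the same numbers:
#' top categories by absolute correlation, significant signature and term
#' enrichments, the protein census, and per-stage exclusion counters.  An
#' empty enrichment stage renders an explicit "no significant terms" row.
#'
#' @param results the per-stage results list assembled by [run_pipeline()].
#' @param out_dir directory for `report.json` and `report.html`.
#' @return A list with `summary` (the JSON structure) and `paths`.
#' @export
render_report <- function(results, out_dir) {
  if (!length(results)) stop_input("no stage outputs to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  sections <- character(0)

  if (!is.null(results$correlation)) {
    top <- utils::head(results$correlation$correlations, 10)
    summary$top_categories <- top
    sections <- c(sections, "<h2>Transcript-protein correlation</h2>",
                  html_table(top))
  }
  if (!is.null(results$hormone)) {
    tab <- results$hormone$enrichment
    summary$signature_enrichment <- tab
    sections <- c(sections, "<h2>Signature enrichment (Fisher)</h2>",
                  html_table(tab))
  }
  if (!is.null(results$go)) {
    tab <- results$go$enrichment
    sig <- if (is.null(tab)) NULL else tab[tab$significant, , drop = FALSE]
    summary$term_enrichment <- sig
    sections <- c(sections, "<h2>Term enrichment (hypergeometric, BY)</h2>",
                  if (is.null(sig) || !nrow(sig))
                    "<p>no significant terms</p>" else html_table(sig))
  }
  if (!is.null(results$prot)) {
    if (!is.null(results$prot$census)) {
      summary$census <- unclass(results$prot$census)
      sections <- c(sections,
                    sprintf(paste0("<h2>Protein census</h2><p>class %s: %d ",
                                   "quantified, %d down 20-90%%, %d up ",
                                   "&gt;20%%</p>"),
                            html_escape(results$prot$census$class_label),
                            results$prot$census$n_quantified,
                            results$prot$census$n_down_20_90,
                            results$prot$census$n_up_gt20))
    }
    summary$proteins_passed <- sum(results$prot$summaries$passed_detection)
  }
  if (!is.null(results$metab)) {
    summary$metabolite_samples_rejected <- results$metab$rejected
    sections <- c(sections, sprintf(
      "<h2>Metabolomics</h2><p>%d metabolite(s); %d QC-rejected sample(s)</p>",
      nrow(results$metab$responses), length(results$metab$rejected)))
  }
  if (!is.null(results$de)) {
    summary$n_background <- length(results$de$background$gene_ids)
    summary$n_up <- length(results$de$de$up)
    summary$n_down <- length(results$de$de$down)
  }

  json_path <- file.path(out_dir, "report.json")
  html_path <- file.path(out_dir, "report.html")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               "<title>heatomics run report</title></head><body>",
               "<h1>heatomics run report</h1>", sections,
               "</body></html>"), html_path)
  list(summary = summary, paths = list(json = json_path, html = html_path))
}
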