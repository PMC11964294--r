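# Domain types and readers/writers for the tabular and gene-set formats the
# pipeline consumes.  Identifiers are opaque, case-sensitive strings
# throughout; absent values are NA, never silently zero.

#' Construct a feature-response table
#'
#' The common container for per-feature treatment-vs-control responses at
#' any molecular level: a data frame with one row per feature carrying the
#' log2 fold change (treatment over control), raw and adjusted p-values,
#' group means, and replicate counts.  Missing statistics are `NA`.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param level one of `"transcript"`, `"protein"`, `"metabolite"`.
#' @param log2fc numeric log2(treatment/control); may be `NA` or infinite
#'   when one group mean is zero (flagged, never dropped here).
#' @param p_value,p_adj probabilities in `[0, 1]` or `NA`. `p_adj` may only
#'   be present where `p_value` is present.
#' @param mean_control,mean_treatment non-negative group means in source
#'   units, or `NA`.
#' @param n_control,n_treatment replicate counts, or `NA`.
#' @return A `data.frame` with the columns above, validated.
#' @export
feature_response_table <- function(feature_id, level, log2fc,
                                   p_value = NA_real_, p_adj = NA_real_,
                                   mean_control = NA_real_,
                                   mean_treatment = NA_real_,
                                   n_control = NA_integer_,
                                   n_treatment = NA_integer_) {
  df <- data.frame(
    feature_id = as.character(feature_id),
    level = level,
    log2fc = as.numeric(log2fc),
    p_value = as.numeric(p_value),
    p_adj = as.numeric(p_adj),
    mean_control = as.numeric(mean_control),
    mean_treatment = as.numeric(mean_treatment),
    n_control = as.integer(n_control),
    n_treatment = as.integer(n_treatment),
    stringsAsFactors = FALSE
  )
  validate_response_table(df)
}

#' Validate a feature-response table
#'
#' Enforces the container's invariants: unique non-empty feature ids, a
#' known level tag, probabilities in `[0, 1]`, and `p_adj` present only
#' where `p_value` is present.
#'
#' @param df a data frame shaped as [feature_response_table()].
#' @return `df`, invisibly validated (returned unchanged).
#' @export
validate_response_table <- function(df) {
  needed <- c("feature_id", "level", "log2fc", "p_value", "p_adj")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop_input("response table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$feature_id == "" | is.na(df$feature_id)))
    stop_validation("empty feature_id")
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup))
    stop_validation("duplicate feature_id: ",
                    paste(utils::head(dup, 5L), collapse = ", "))
  if (!all(df$level %in% c("transcript", "protein", "metabolite")))
    stop_validation("level must be transcript, protein or metabolite")
  check_prob(df$p_value, "p_value")
  check_prob(df$p_adj, "p_adj")
  if (any(!is.na(df$p_adj) & is.na(df$p_value)))
    stop_validation("p_adj present where p_value is absent")
  df
}

#' Read a per-feature response table from a delimited file
#'
#' Reads a tab- (or otherwise-) separated table of per-feature statistics
#' into the standard response container.  Column names in deposited tables
#' vary, so the mapping from standard fields to file columns is
#' configurable; the defaults expect `feature_id`, `log2fc`, `pvalue`,
#' `padj`.  Malformed numeric cells become `NA` with a warning; duplicated
#' feature ids are an error.
#'
#' @param path path to the delimited text file (with header).
#' @param level level tag stamped on every record; see
#'   [feature_response_table()].
#' @param col_map named list mapping standard field names (`feature_id`,
#'   `log2fc`, `p_value`, `p_adj`, `mean_control`, `mean_treatment`) to the
#'   file's column names. Only `feature_id` and `log2fc` are mandatory.
#' @param sep field separator, default tab.
#' @return A validated response `data.frame`.
#' @export
read_response_table <- function(path, level,
                                col_map = list(feature_id = "feature_id",
                                               log2fc = "log2fc",
                                               p_value = "pvalue",
                                               p_adj = "padj"),
                                sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (fld in c("feature_id", "log2fc")) {
    col <- col_map[[fld]]
    if (is.null(col) || !col %in% names(raw))
      stop_input("mandatory column for '", fld, "' (", col %||% "<unset>",
                 ") not found in ", path)
  }
  num_field <- function(fld) {
    col <- col_map[[fld]]
    if (is.null(col) || !col %in% names(raw))
      return(rep(NA_real_, nrow(raw)))
    txt <- raw[[col]]
    out <- suppressWarnings(as.numeric(txt))
    bad <- is.na(out) & !is.na(txt) & !(trimws(txt) %in% c("", "NA", "NaN"))
    if (any(bad))
      warning(sum(bad), " malformed numeric value(s) in column '", col,
              "' set to NA", call. = FALSE)
    out
  }
  feature_response_table(
    feature_id = raw[[col_map$feature_id]],
    level = level,
    log2fc = num_field("log2fc"),
    p_value = num_field("p_value"),
    p_adj = num_field("p_adj"),
    mean_control = num_field("mean_control"),
    mean_treatment = num_field("mean_treatment")
  )
}

#' Write a feature-response table to TSV
#'
#' @param df a response table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab-separated as
#' `name <TAB> description <TAB> member1 <TAB> member2 ...`.  Members are
#' deduplicated (set semantics).  Empty sets are permitted with a warning;
#' a line with fewer than two fields is a format error naming the line.
#'
#' @param path path to the GMT file.
#' @return A named list; each element is `list(name, description, genes)`
#'   with `genes` a unique character vector.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene-set file: ", path, call. = FALSE)
    return(stats::setNames(list(), character(0)))
  }
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop_input("GMT line ", i, " has fewer than 2 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      warning("gene set '", fields[[1]], "' (line ", i, ") is empty",
              call. = FALSE)
    out[[i]] <- list(name = fields[[1]], description = fields[[2]],
                     genes = genes)
    nms[[i]] <- fields[[1]]
  }
  stats::setNames(out, nms)
}

#' Write gene sets to a GMT file
#'
#' @param sets a named list of character vectors, or the structure returned
#'   by [read_gene_sets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(name = names(sets)[[i]], description = ".",
                                   genes = s)
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a treatment-response signature
#'
#' A named pair of stimulated (up under the reference treatment) and
#' repressed gene sets in target-species identifiers, with the expressed
#' background of the reference study.  Stimulated and repressed sets must
#' be disjoint.
#'
#' @param name signature label (e.g. a hormone treatment).
#' @param stimulated,repressed character vectors of target-species ids.
#' @param expressed_background character vector of target-species ids
#'   expressed in the reference study (may be empty if supplied later).
#' @return An object of class `response_signature`.
#' @export
response_signature <- function(name, stimulated, repressed,
                               expressed_background = character(0)) {
  stimulated <- unique(as.character(stimulated))
  repressed <- unique(as.character(repressed))
  both <- intersect(stimulated, repressed)
  if (length(both))
    stop_validation("signature '", name, "': genes in both stimulated and ",
                    "repressed sets: ", paste(utils::head(both, 5L),
                                              collapse = ", "))
  structure(list(name = name, stimulated = stimulated, repressed = repressed,
                 expressed_background = unique(as.character(expressed_background))),
            class = "response_signature")
}

#' Construct an orthology map
#'
#' Many-to-one map from source-species gene ids to target-species gene ids
#' (several sources may share one target; each source appears once).
#'
#' @param source_id,target_id character vectors of equal length, no empties.
#' @return A named character vector `source -> target` of class
#'   `orthology_map`.
#' @export
orthology_map <- function(source_id, target_id) {
  source_id <- as.character(source_id); target_id <- as.character(target_id)
  if (length(source_id) != length(target_id))
    stop_input("source_id and target_id lengths differ")
  if (any(!nzchar(source_id)) || any(!nzchar(target_id)) ||
      anyNA(source_id) || anyNA(target_id))
    stop_validation("empty identifiers in orthology map")
  dup <- unique(source_id[duplicated(source_id)])
  if (length(dup))
    stop_validation("source ids mapped more than once: ",
                    paste(utils::head(dup, 5L), collapse = ", "))
  structure(stats::setNames(target_id, source_id), class = "orthology_map")
}

#' Read an orthology map from a two-column TSV
#'
#' @param path two-column tab-separated file `source_id <TAB> target_id`,
#'   no header comment lines starting with `#` are skipped.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("orthology file needs two columns: ", path)
  orthology_map(df[[1]], df[[2]])
}

#' Write an orthology map to TSV
#' @param map an [orthology_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthology <- function(map, path) {
  utils::write.table(data.frame(source_id = names(map),
                                target_id = unname(unclass(map))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- annotation hierarchy ---------------------------------------------

parse_term_code <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) == 0L || any(!nzchar(p)),
                logical(1))
  if (any(bad))
    stop_input("malformed term code(s): ",
               paste(utils::head(code[bad], 5L), collapse = ", "))
  parts
}

ancestors_of_code <- function(code) {
  parts <- parse_term_code(code)[[1]]
  if (length(parts) <= 1L) return(character(0))
  vapply(seq_len(length(parts) - 1L),
         function(k) paste(parts[1:k], collapse = "."), character(1))
}

#' Construct an annotation hierarchy
#'
#' A tree of functional terms (MapMan-bin style, dot-delimited codes encode
#' ancestry) with term-to-feature assignments.  In hierarchical mode a
#' feature assigned to a term is a member of all ancestor terms (ancestry
#' closure, applied at construction and idempotent).
#'
#' @param assignments named list: term code -> character vector of feature
#'   ids directly assigned to the term.
#' @param term_names optional named character vector of display names.
#' @param hierarchical if `TRUE`, dot-delimited codes encode ancestry and
#'   memberships are closed upward.
#' @return An object of class `annotation_hierarchy` with elements `terms`
#'   (data frame: `term_id`, `name`, `parent_id`), `members` (named list of
#'   closed memberships), `direct` (the direct assignments), and
#'   `hierarchical`.
#' @export
annotation_hierarchy <- function(assignments, term_names = NULL,
                                 hierarchical = TRUE) {
  check_flag(hierarchical, "hierarchical")
  codes <- names(assignments)
  if (is.null(codes) || any(!nzchar(codes)))
    stop_input("assignments must be a named list of term codes")
  direct <- lapply(assignments, function(x) unique(as.character(x)))
  if (hierarchical) {
    all_codes <- unique(c(codes, unlist(lapply(codes, ancestors_of_code))))
    parent <- vapply(all_codes, function(cd) {
      anc <- ancestors_of_code(cd)
      if (length(anc)) anc[[length(anc)]] else NA_character_
    }, character(1))
  } else {
    parse_term_code(codes)  # still validate code syntax
    all_codes <- codes
    parent <- rep(NA_character_, length(all_codes))
  }
  members <- stats::setNames(vector("list", length(all_codes)), all_codes)
  for (cd in all_codes) members[[cd]] <- character(0)
  for (cd in codes) {
    feats <- direct[[cd]]
    targets <- if (hierarchical) c(cd, ancestors_of_code(cd)) else cd
    for (tg in targets) members[[tg]] <- union(members[[tg]], feats)
  }
  nm <- stats::setNames(all_codes, all_codes)
  if (!is.null(term_names)) nm[names(term_names)] <- term_names
  structure(list(
    terms = data.frame(term_id = all_codes, name = unname(nm[all_codes]),
                       parent_id = unname(parent), stringsAsFactors = FALSE),
    members = members,
    direct = direct,
    hierarchical = hierarchical
  ), class = "annotation_hierarchy")
}

#' Read a term-to-feature annotation from a two-column TSV
#'
#' Expects `term_code <TAB> feature_id` rows (header required; extra
#' columns beyond the second may carry a term display name).  Dot-delimited
#' codes (`"1.3.4"`) encode ancestry when `hierarchical = TRUE`.
#'
#' @param path input path.
#' @param hierarchical close memberships over ancestors; see
#'   [annotation_hierarchy()].
#' @return An `annotation_hierarchy`.
#' @export
read_annotation <- function(path, hierarchical = TRUE) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("annotation file needs two columns: ", path)
  assignments <- split(df[[2]], df[[1]])
  term_names <- NULL
  if (ncol(df) >= 3L) {
    nm <- tapply(df[[3]], df[[1]], function(x) x[[1]])
    term_names <- stats::setNames(as.character(nm), names(nm))
  }
  annotation_hierarchy(assignments, term_names = term_names,
                       hierarchical = hierarchical)
}

#' Write an annotation's direct assignments to TSV
#' @param hierarchy an `annotation_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(hierarchy, path) {
  df <- data.frame(
    term_id = rep(names(hierarchy$direct),
                  lengths(hierarchy$direct)),
    feature_id = unlist(hierarchy$direct, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Members of a term (closure included in hierarchical mode)
#' @param hierarchy an `annotation_hierarchy`.
#' @param term_id a term code.
#' @return Character vector of feature ids.
#' @export
term_members <- function(hierarchy, term_id) {
  if (!term_id %in% names(hierarchy$members))
    stop_input("unknown term '", term_id, "'; available: ",
               paste(utils::head(names(hierarchy$members), 10L),
                     collapse = ", "))
  hierarchy$members[[term_id]]
}

#' Construct an expression count matrix with gene lengths and a design
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative integers.
#' @param gene_length_bp positive integer vector named by gene id.
#' @param condition character vector named by sample id with values
#'   `"control"` or `"treatment"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_length_bp, condition) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_input("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("counts must be non-negative integers")
  gene_length_bp <- gene_length_bp[rownames(counts)]
  if (anyNA(gene_length_bp) || any(gene_length_bp <= 0))
    stop_validation("every gene needs a positive length")
  condition <- condition[colnames(counts)]
  if (anyNA(condition) || !all(condition %in% c("control", "treatment")))
    stop_validation("every sample needs a condition in {control, treatment}")
  structure(list(counts = counts, gene_length_bp = gene_length_bp,
                 condition = condition),
            class = "expression_matrix")
}

#' Construct a 2x2 contingency table
#'
#' Cells are `a` (in both sets), `b` (first only), `c` (second only), `d`
#' (neither), over a fixed universe; margins are derived, not stored.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_validation("contingency cells must be non-negative integers")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d)), class = "contingency_2x2")
}
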