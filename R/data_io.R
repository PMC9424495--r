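#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects tab-separated text with gene/probe identifiers in the first column
#' (header `gene_id`) and one column per sample. All expression cells must be
#' numeric; values are log2 intensities unless you transform them later.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample, rows in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t2", "g2\t3\t4"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE, comment = "#"
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    abort(paste0(
      "Parse error in ", path, ": row ", p1$row, ", column ", p1$col,
      " (expected ", p1$expected, ", got ", p1$actual, ")"
    ))
  }
  if (names(x)[1] != "gene_id") {
    abort("First column of an expression TSV must be named 'gene_id'.")
  }
  validate_expression(x, allow_missing = TRUE)
  x
}

#' Write an expression matrix to TSV
#'
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expression, path) {
  validate_expression(expression, allow_missing = TRUE)
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a sample design table
#'
#' The design maps each array/sample to its culture condition (e.g. Th0, Th1,
#' Th2, Th12), measurement time in hours, and replicate (independent
#' experiment). Regression downstream needs at least 4 distinct timepoints per
#' condition.
#'
#' @param path Path to a TSV with columns `sample_id`, `condition`, `time_h`,
#'   `replicate`.
#' @return A validated tibble.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE, comment = "#")
  validate_design(x)
  grid <- dplyr::summarise(
    dplyr::group_by(x, .data$condition),
    n_times = dplyr::n_distinct(.data$time_h), .groups = "drop"
  )
  inform(paste0(
    "Design: ", nrow(x), " samples, ", nrow(grid), " condition(s); timepoints per condition: ",
    paste(paste0(grid$condition, "=", grid$n_times), collapse = ", ")
  ))
  x
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB member1 TAB ...`.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @param source_label Free-text label recorded in the `source` column
#'   (defaults to the file name).
#' @return A tibble with columns `set_name`, `description`, `source` and a
#'   list-column `genes`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("Empty GMT file: ", path))
    return(tibble::tibble(
      set_name = character(), description = character(),
      source = character(), genes = list()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    bad <- which(n_fields < 3)[1]
    abort(paste0("GMT parse error: line ", bad, " has fewer than 3 tab-separated fields."))
  }
  genes <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(genes, function(g) sum(duplicated(g)), integer(1)))
  if (n_dup > 0) {
    warn(paste0(n_dup, " duplicated member(s) within sets were dropped."))
    genes <- lapply(genes, unique)
  }
  tibble::tibble(
    set_name = vapply(fields, `[`, character(1), 1),
    description = vapply(fields, `[`, character(1), 2),
    source = source_label,
    genes = genes
  )
}

#' Collapse probe-level rows to gene level
#'
#' Microarray probes map many-to-one onto gene symbols. With
#' `rule = "max_mean"` (the common microarray convention) the probe with the
#' highest mean intensity across all samples represents the gene; with
#' `rule = "mean"` probe rows are averaged.
#'
#' @param expression Probe-level expression tibble (`gene_id` column holds
#'   probe IDs).
#' @param probe_map Data frame with columns `probe_id` and `gene_symbol`.
#' @param rule Collapse rule, `"max_mean"` (default) or `"mean"`.
#' @return Gene-level expression tibble; probes absent from `probe_map` are
#'   dropped with a message.
#' @export
collapse_probes_to_genes <- function(expression, probe_map,
                                     rule = c("max_mean", "mean")) {
  rule <- match.arg(rule)
  validate_expression(expression)
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    abort("`probe_map` needs columns probe_id and gene_symbol.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("Each probe must map to exactly one gene symbol.")
  }
  m <- expr_values(expression)
  idx <- match(rownames(m), probe_map$probe_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(paste0(dropped, " probe(s) absent from the probe map were dropped."))
  }
  keep <- !is.na(idx)
  m <- m[keep, , drop = FALSE]
  gene <- probe_map$gene_symbol[idx[keep]]
  if (rule == "max_mean") {
    means <- rowMeans(m)
    ord <- order(match(gene, unique(gene)), -means)
    first <- !duplicated(gene[ord])
    sel <- ord[first]
    out <- m[sel, , drop = FALSE]
    rownames(out) <- gene[sel]
  } else {
    groups <- split(seq_along(gene), factor(gene, levels = unique(gene)))
    out <- t(vapply(groups, function(i) colMeans(m[i, , drop = FALSE]),
                    numeric(ncol(m))))
    colnames(out) <- colnames(m)
  }
  as_expr_tbl(out)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control; a validated front end to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("All p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Write a per-gene result table with a provenance header
#'
#' Prepends `#`-commented provenance lines (analysis step, parameters, seed,
#' package version) so result files are self-describing but still parse as TSV.
#'
#' @param x Data frame of results.
#' @param path Output path.
#' @param provenance Named character/list of provenance fields.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, provenance = list()) {
  provenance <- c(
    list(written = "thkinetics", version = as.character(utils::packageVersion("thkinetics"))),
    provenance
  )
  hdr <- paste0("# ", names(provenance), ": ",
                vapply(provenance, function(v) paste(format(v), collapse = ","), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  x <- dplyr::select(as.data.frame(x), dplyr::where(~ !is.list(.x)))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
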