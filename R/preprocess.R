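#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to the same distribution: rank-wise means of
#' the sorted columns, with ties resolved by the mean of tied ranks.
#'
#' @param expression Expression tibble (`gene_id` + sample columns), complete.
#' @return Normalized expression tibble.
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(2, 4), s2 = c(6, 8))
#' quantile_normalize(m)  # both columns become (4, 6)
#' @export
quantile_normalize <- function(expression) {
  validate_expression(expression, allow_missing = TRUE)
  m <- expr_values(expression)
  if (anyNA(m)) abort("Missing values are not allowed in quantile normalization.")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  as_expr_tbl(out)
}

#' Log2-transform raw intensities
#'
#' @param expression Expression tibble of raw (linear-scale) intensities.
#' @param offset Small non-negative constant added before taking log2.
#' @return Log2-scale expression tibble.
#' @export
log2_transform <- function(expression, offset = 0) {
  validate_expression(expression, allow_missing = TRUE)
  m <- expr_values(expression)
  if (any(m + offset <= 0, na.rm = TRUE)) {
    abort("Non-positive values after adding `offset`; log2 is undefined.")
  }
  as_expr_tbl(log2(m + offset))
}

#' Filter to expressed genes
#'
#' A gene (or probe) is retained iff, for at least one condition, its mean
#' log2 expression over that condition's samples exceeds the global median of
#' the whole matrix. On a matrix whose values are all identical nothing
#' exceeds the median and zero genes survive.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @return A list with the filtered `expression` and a `report` list
#'   (`n_input`, `n_retained`, `rule`, and per-condition pass counts).
#' @export
filter_expressed <- function(expression, design) {
  validate_expression(expression)
  validate_design(design, expression)
  m <- expr_values(expression)
  med <- stats::median(m)
  conds <- unique(design$condition)
  pass <- vapply(conds, function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(m[, cols, drop = FALSE]) > med
  }, logical(nrow(m)))
  if (nrow(m) == 1L) pass <- matrix(pass, nrow = 1L)
  keep <- rowSums(pass) > 0
  report <- list(
    n_input = nrow(m),
    n_retained = sum(keep),
    rule = "per-condition mean above global median, any condition",
    global_median = med,
    per_condition = tibble::tibble(condition = conds, n_pass = colSums(pass))
  )
  list(expression = expression[keep, , drop = FALSE], report = report)
}

#' Log2 fold changes relative to a reference timepoint
#'
#' For each gene, condition and timepoint: the difference between the
#' replicate-mean log2 expression at that timepoint and at `reference_time`
#' (so the value at the reference itself is 0 and a value of 1 means
#' two-fold).
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param reference_time Reference time (hours); must exist in every condition.
#' @return Long tibble with columns `gene_id`, `condition`, `time_h`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(expression, design, reference_time = 0) {
  validate_expression(expression)
  validate_design(design, expression)
  conds <- unique(design$condition)
  out <- purrr::map(conds, function(cc) {
    prof <- profile_means(expression, design, cc)
    times <- as.numeric(colnames(prof))
    ref <- which(times == reference_time)
    if (length(ref) != 1) {
      abort(paste0("Reference time ", reference_time, " h missing in condition ", cc))
    }
    fc <- prof - prof[, ref]
    tibble::tibble(
      gene_id = rep(rownames(prof), times = length(times)),
      condition = cc,
      time_h = rep(times, each = nrow(prof)),
      log2fc = as.vector(fc)
    )
  })
  dplyr::bind_rows(out)
}
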