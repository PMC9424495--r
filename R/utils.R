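# Internal helpers shared across modules.

# Extract the numeric genes x samples matrix from an expression tibble
# (first column `gene_id`, one column per sample).
expr_values <- function(expression) {
  stopifnot(is.data.frame(expression), names(expression)[1] == "gene_id")
  m <- as.matrix(expression[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(expression$gene_id)
  m
}

as_expr_tbl <- function(values) {
  tibble::as_tibble(as.data.frame(values), rownames = "gene_id")
}

validate_expression <- function(expression, allow_missing = FALSE) {
  if (!is.data.frame(expression) || ncol(expression) < 2L) {
    abort("`expression` must be a data frame with a gene_id column and at least one sample column.")
  }
  if (names(expression)[1] != "gene_id") {
    abort("The first column of `expression` must be named 'gene_id'.")
  }
  dup <- unique(expression$gene_id[duplicated(expression$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicated gene IDs: ", paste(head(dup, 10), collapse = ", ")))
  }
  dup_s <- unique(names(expression)[-1][duplicated(names(expression)[-1])])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicated sample IDs: ", paste(head(dup_s, 10), collapse = ", ")))
  }
  m <- expr_values(expression)
  if (!allow_missing && anyNA(m)) {
    abort("`expression` contains missing values; complete matrices are required here.")
  }
  invisible(expression)
}

validate_design <- function(design, expression = NULL, min_times = 4L) {
  required <- c("sample_id", "condition", "time_h", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("`design` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(design$time_h) || anyNA(design$time_h) || any(design$time_h < 0)) {
    abort("`design$time_h` must be non-negative and numeric.")
  }
  if (anyDuplicated(design$sample_id)) {
    abort("`design$sample_id` contains duplicates.")
  }
  key <- paste(design$condition, design$time_h, design$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Each (condition, time_h, replicate) triple must be unique in `design`.")
  }
  n_times <- tapply(design$time_h, design$condition, function(x) length(unique(x)))
  if (any(n_times < min_times)) {
    bad <- names(n_times)[n_times < min_times]
    abort(paste0("Condition(s) with fewer than ", min_times, " distinct timepoints: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(expression)) {
    samples <- names(expression)[-1]
    if (!setequal(samples, design$sample_id)) {
      abort("Sample IDs in `expression` and `design` do not match.")
    }
  }
  invisible(design)
}

# Replicate-mean time profiles for one condition: genes x sorted timepoints.
profile_means <- function(expression, design, condition) {
  d <- design[design$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) abort(paste0("Condition not present in design: ", condition))
  times <- sort(unique(d$time_h))
  m <- expr_values(expression)
  out <- vapply(times, function(tt) {
    cols <- d$sample_id[d$time_h == tt]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(m), times)
  out
}

new_result <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
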