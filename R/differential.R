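# Multi-condition regression DEG calling: nested F (quantitative) plus the
# correlation-index filter (qualitative).

group_design_matrices <- function(design, degree, reference, merge = NULL) {
  cond <- as.character(design$condition)
  if (!is.null(merge)) cond[cond == merge[2]] <- merge[1]
  lev <- unique(c(reference, sort(unique(cond))))
  lev <- lev[lev %in% cond]
  f <- factor(cond, levels = lev)
  pt <- stats::poly(design$time_h, degree)
  X <- stats::model.matrix(~ f * pt)
  colnames(X) <- NULL
  X
}

rss_by_gene <- function(X, Y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("Rank-deficient design: condition/time terms are collinear.")
  }
  qty <- qr.qty(qx, Y)[seq_len(qx$rank), , drop = FALSE]
  pmax(colSums(Y^2) - colSums(qty^2), 0)
}

nested_f <- function(rss_red, rss_full, df1, df2, tot) {
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  degenerate <- (rss_red - rss_full) <= 1e-12 * pmax(tot, 1)
  f[degenerate] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[degenerate] <- 1
  list(f = f, p = p)
}

#' Overall condition-effect test (nested F over the time-only model)
#'
#' Fits, per gene, the full model (shared polynomial time trend plus
#' per-condition offsets and condition x time interactions, reference
#' condition `reference`) and the reduced time-only model, and F-tests the
#' `(G - 1) * (degree + 1)` condition-distinguishing coefficients jointly.
#' Benjamini-Hochberg correction across genes.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param genes Genes to test (default all; typically the kinetic union).
#' @param degree Polynomial degree for the time trend.
#' @param reference Reference condition for the dummy coding (cosmetic:
#'   the joint tests are reparameterization-invariant).
#' @return Tibble of class `th_group_fit` with `f_stat`, `df1`, `df2`,
#'   `p_value`, `q_value` per gene.
#' @export
fit_group_model <- function(expression, design, genes = NULL, degree = 3L,
                            reference = "Th0") {
  validate_expression(expression)
  validate_design(design, expression)
  if (!reference %in% design$condition) abort(paste0("Reference condition not in design: ", reference))
  genes <- genes %||% expression$gene_id
  sub <- expression[match(genes, expression$gene_id), , drop = FALSE]
  m <- expr_values(sub)
  Y <- t(m[, design$sample_id, drop = FALSE])
  X_full <- group_design_matrices(design, degree, reference)
  X_red <- cbind(1, stats::poly(design$time_h, degree))
  tot <- colSums(Y^2)
  rss_full <- rss_by_gene(X_full, Y)
  rss_red <- rss_by_gene(X_red, Y)
  df1 <- ncol(X_full) - ncol(X_red)
  df2 <- nrow(Y) - ncol(X_full)
  ft <- nested_f(rss_red, rss_full, df1, df2, tot)
  out <- tibble::tibble(
    gene_id = colnames(Y), f_stat = unname(ft$f), df1 = df1, df2 = df2,
    p_value = unname(ft$p), q_value = unname(benjamini_hochberg(ft$p)),
    rss_full = unname(rss_full), rss_reduced = unname(rss_red)
  )
  new_result(out, "th_group_fit", degree = degree, reference = reference)
}

#' Per-pair contrast test (quantitative DEG)
#'
#' Joint F-test that all coefficients distinguishing the two conditions of
#' `pair` (offset plus time interactions, `degree + 1` terms) are zero,
#' computed by refitting a restricted model in which the pair is merged into
#' one group. Symmetric in the pair order; BH across genes within the
#' contrast.
#'
#' @inheritParams fit_group_model
#' @param pair Length-2 character vector of condition names.
#' @return Tibble: `gene_id`, `condition_a`, `condition_b`, `f_stat`,
#'   `p_value`, `q_value`.
#' @export
contrast_test <- function(expression, design, genes = NULL, pair,
                          degree = 3L, reference = "Th0") {
  validate_expression(expression)
  validate_design(design, expression)
  if (length(pair) != 2 || !all(pair %in% design$condition)) {
    abort("`pair` must name two conditions present in the design.")
  }
  genes <- genes %||% expression$gene_id
  sub <- expression[match(genes, expression$gene_id), , drop = FALSE]
  m <- expr_values(sub)
  Y <- t(m[, design$sample_id, drop = FALSE])
  X_full <- group_design_matrices(design, degree, reference)
  X_restr <- group_design_matrices(design, degree, reference, merge = sort(pair))
  tot <- colSums(Y^2)
  rss_full <- rss_by_gene(X_full, Y)
  rss_restr <- rss_by_gene(X_restr, Y)
  df1 <- ncol(X_full) - ncol(X_restr)
  df2 <- nrow(Y) - ncol(X_full)
  ft <- nested_f(rss_restr, rss_full, df1, df2, tot)
  tibble::tibble(
    gene_id = colnames(Y), condition_a = pair[1], condition_b = pair[2],
    f_stat = unname(ft$f), p_value = unname(ft$p),
    q_value = unname(benjamini_hochberg(ft$p))
  )
}

#' Correlation index between two conditions' time profiles
#'
#' `1 - r`, with `r` the Pearson correlation between the two conditions'
#' replicate-mean profiles over shared timepoints (`mode = "means"`,
#' default) or between all matched samples (`mode = "samples"`). Identical
#' trajectories give 0; mirror-image trajectories give 2. Genes with a
#' constant profile in either condition get `NA` (undefined correlation) and
#' are excluded from qualitative calls.
#'
#' @inheritParams fit_group_model
#' @param pair Length-2 character vector of condition names.
#' @param mode Profile mode, `"means"` or `"samples"`.
#' @return Tibble: `gene_id`, `pearson_r`, `correlation_index`.
#' @export
correlation_index <- function(expression, design, pair, genes = NULL,
                              mode = c("means", "samples")) {
  mode <- match.arg(mode)
  validate_expression(expression)
  validate_design(design, expression)
  if (length(pair) != 2 || !all(pair %in% design$condition)) {
    abort("`pair` must name two conditions present in the design.")
  }
  genes <- genes %||% expression$gene_id
  sub <- expression[match(genes, expression$gene_id), , drop = FALSE]
  if (mode == "means") {
    a <- profile_means(sub, design, pair[1])
    b <- profile_means(sub, design, pair[2])
    shared <- intersect(colnames(a), colnames(b))
    a <- a[, shared, drop = FALSE]
    b <- b[, shared, drop = FALSE]
  } else {
    grab <- function(cc) {
      d <- design[design$condition == cc, , drop = FALSE]
      d <- d[order(d$time_h, d$replicate), , drop = FALSE]
      structure(expr_values(sub)[, d$sample_id, drop = FALSE],
                key = paste(d$time_h, d$replicate))
    }
    a <- grab(pair[1]); b <- grab(pair[2])
    shared <- intersect(attr(a, "key"), attr(b, "key"))
    a <- a[, match(shared, attr(a, "key")), drop = FALSE]
    b <- b[, match(shared, attr(b, "key")), drop = FALSE]
  }
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  r <- ifelse(den > 0, rowSums(ac * bc) / den, NA_real_)
  n_undef <- sum(is.na(r))
  if (n_undef > 0) {
    inform(paste0(n_undef, " gene(s) with constant profiles: correlation undefined, excluded from qualitative calls."))
  }
  tibble::tibble(gene_id = rownames(a), pearson_r = unname(r),
                 correlation_index = unname(1 - r))
}

#' Qualitative DEG filter
#'
#' A quantitative DEG is additionally qualitative when its correlation index
#' exceeds `index_threshold` (default 0.3): its trajectories differ in shape,
#' not just in level. Genes with undefined correlation are never qualitative.
#'
#' @param contrasts Tibble with columns `quantitative_deg` and
#'   `correlation_index` (see [contrast_results()]).
#' @param index_threshold Threshold on `1 - r`, in \[0, 2\].
#' @return `contrasts` with a `qualitative_deg` column.
#' @export
qualitative_deg <- function(contrasts, index_threshold = 0.3) {
  if (index_threshold < 0 || index_threshold > 2) {
    abort("`index_threshold` must lie in [0, 2].")
  }
  dplyr::mutate(
    contrasts,
    qualitative_deg = .data$quantitative_deg &
      !is.na(.data$correlation_index) &
      .data$correlation_index > index_threshold
  )
}

# Backward-stepwise per-pair coefficient selection (two-condition model):
# drop the least significant condition-linked coefficient until all remaining
# are below `alpha`; a gene is quantitative if any survives.
stepwise_pair_flag <- function(expression, design, genes, pair, degree, alpha) {
  d <- design[design$condition %in% pair, , drop = FALSE]
  f <- factor(as.character(d$condition), levels = pair)
  X <- stats::model.matrix(~ f * stats::poly(d$time_h, degree))
  cond_cols <- grep("^f", colnames(stats::model.matrix(~ f * stats::poly(d$time_h, degree))))
  m <- expr_values(expression[match(genes, expression$gene_id), , drop = FALSE])
  vapply(genes, function(g) {
    y <- m[g, d$sample_id]
    keep <- cond_cols
    repeat {
      if (length(keep) == 0) return(FALSE)
      Xk <- X[, c(setdiff(seq_len(ncol(X)), cond_cols), keep), drop = FALSE]
      fit <- stats::lm(y ~ Xk - 1)
      ps <- summary(fit)$coefficients[, 4]
      idx <- seq.int(ncol(Xk) - length(keep) + 1, ncol(Xk))
      pk <- ps[idx]
      if (all(is.finite(pk)) && max(pk) <= alpha) return(TRUE)
      worst <- which.max(ifelse(is.finite(pk), pk, Inf))
      keep <- keep[-worst]
    }
  }, logical(1))
}

#' Combined quantitative/qualitative DEG calling for one condition pair
#'
#' Runs the two-step procedure: the overall nested F-test across all
#' conditions (step 1), the per-pair contrast (step 2, joint F by default or
#' backward-stepwise coefficient selection with `stepwise = TRUE`), then the
#' correlation-index filter. `quantitative_deg` requires both steps at FDR
#' `alpha`; `qualitative_deg` additionally requires
#' `correlation_index > index_threshold`.
#'
#' @inheritParams fit_group_model
#' @param pair Length-2 character vector of condition names.
#' @param alpha FDR level for both steps.
#' @param index_threshold Correlation-index threshold for qualitative DEG.
#' @param overall Optional precomputed [fit_group_model()] result.
#' @param stepwise Use backward-stepwise coefficient selection for step 2.
#' @param mode Profile mode for the correlation index.
#' @return Tibble of class `th_contrast`, one row per gene.
#' @export
contrast_results <- function(expression, design, genes = NULL, pair,
                             alpha = 0.05, degree = 3L, index_threshold = 0.3,
                             reference = "Th0", overall = NULL,
                             stepwise = FALSE, mode = "means") {
  genes <- genes %||% expression$gene_id
  overall <- overall %||% fit_group_model(expression, design, genes, degree, reference)
  ct <- contrast_test(expression, design, genes, pair, degree, reference)
  ci <- correlation_index(expression, design, pair, genes, mode)
  x <- dplyr::left_join(ct, ci, by = "gene_id")
  x$overall_q <- overall$q_value[match(x$gene_id, overall$gene_id)]
  if (stepwise) {
    x$pair_significant <- stepwise_pair_flag(expression, design, genes, pair, degree, alpha)
  } else {
    x$pair_significant <- x$q_value < alpha
  }
  x$quantitative_deg <- x$overall_q < alpha & x$pair_significant
  x <- qualitative_deg(x, index_threshold)
  new_result(x, "th_contrast", pair = pair, alpha = alpha,
             index_threshold = index_threshold)
}

#' Correlation-volcano table
#'
#' One row per tested (kinetic-union) gene for a condition pair:
#' x = correlation index, y = -log10 contrast FDR, with the nested category
#' labels `kinetic` < `quantitative DEG` < `qualitative DEG`.
#'
#' @param contrasts Output of [contrast_results()].
#' @return Tibble of class `th_volcano`.
#' @export
build_volcano_table <- function(contrasts) {
  out <- tibble::tibble(
    gene_id = contrasts$gene_id,
    correlation_index = contrasts$correlation_index,
    neg_log10_q = -log10(pmax(contrasts$q_value, .Machine$double.xmin)),
    category = factor(
      dplyr::case_when(
        contrasts$qualitative_deg ~ "qualitative DEG",
        contrasts$quantitative_deg ~ "quantitative DEG",
        TRUE ~ "kinetic"
      ),
      levels = c("kinetic", "quantitative DEG", "qualitative DEG")
    )
  )
  new_result(out, "th_volcano", pair = attr(contrasts, "pair"))
}
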