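# Global time-course structure: PCA, cross-subset-correlated gene removal,
# divergence trajectories against the neutral condition, and the
# cytokine-quadrant co-expression arithmetic.

#' Remove genes highly correlated across all subsets
#'
#' A gene is removed when the minimum, over all condition pairs, of the
#' Pearson correlation between its replicate-mean profiles exceeds
#' `r_threshold` — i.e. its trajectory is essentially the same in every
#' subset and carries no fate information. Pairs with an undefined
#' correlation (constant profile) are treated as correlated.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table (>= 2 conditions).
#' @param r_threshold Correlation threshold (default 0.9).
#' @return List: reduced `expression`, and `removed` tibble (`gene_id`,
#'   `min_r` with `NA` where every pair was undefined).
#' @export
remove_correlated_genes <- function(expression, design, r_threshold = 0.9) {
  validate_expression(expression)
  validate_design(design, expression)
  conds <- unique(design$condition)
  if (length(conds) < 2) abort("Need at least 2 conditions.")
  profs <- lapply(conds, function(cc) profile_means(expression, design, cc))
  names(profs) <- conds
  shared <- Reduce(intersect, lapply(profs, colnames))
  profs <- lapply(profs, function(p) p[, shared, drop = FALSE])
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  min_r <- rep(Inf, nrow(expression))
  any_defined <- rep(FALSE, nrow(expression))
  for (pr in pairs) {
    a <- profs[[pr[1]]] - rowMeans(profs[[pr[1]]])
    b <- profs[[pr[2]]] - rowMeans(profs[[pr[2]]])
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    r <- ifelse(den > 0, rowSums(a * b) / den, NA_real_)
    defined <- !is.na(r)
    any_defined <- any_defined | defined
    r[!defined] <- 1  # undefined counts as correlated
    min_r <- pmin(min_r, r)
  }
  removed <- min_r > r_threshold
  n_undef <- sum(!any_defined & removed)
  if (n_undef > 0) {
    inform(paste0(n_undef, " constant gene(s) treated as correlated and removed."))
  }
  list(
    expression = expression[!removed, , drop = FALSE],
    removed = tibble::tibble(
      gene_id = expression$gene_id[removed],
      min_r = ifelse(any_defined[removed], min_r[removed], NA_real_)
    )
  )
}

#' PCA of the differentiation time course
#'
#' Gene-centered principal component analysis of the samples. Each
#' component's sign is fixed deterministically: flipped so its scores
#' correlate positively with measurement time (falling back to the first
#' non-zero loading when that correlation is zero), removing the arbitrary
#' sign ambiguity of PCA.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param n_components Number of components to keep.
#' @return List of class `th_pca`: `scores` tibble (design columns + `PC1`,
#'   ...), `explained_variance` (fractions), `loadings` (genes x components).
#' @export
pca_timecourse <- function(expression, design, n_components = 4L) {
  validate_expression(expression)
  validate_design(design, expression)
  m <- expr_values(expression)
  pc <- prcomp(t(m[, design$sample_id, drop = FALSE]), center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > 1e-10)
  if (n_components > rank_) {
    abort(paste0("`n_components` (", n_components, ") exceeds the matrix rank (", rank_, ")."))
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    r <- suppressWarnings(cor(scores[, j], design$time_h))
    flip <- if (!is.na(r) && r != 0) r < 0 else loadings[which(loadings[, j] != 0)[1], j] < 0
    if (isTRUE(flip)) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::as_tibble(design),
                              tibble::as_tibble(scores)),
    explained_variance = ev[seq_len(n_components)],
    loadings = loadings,
    n_components = n_components
  ), class = "th_pca")
}

#' Principal-component difference trajectories against a reference condition
#'
#' Per condition and timepoint, the difference between the replicate-mean
#' component score and the reference condition's score at the matched
#' timepoint. The reference's own trajectory is identically zero; timepoints
#' missing in the reference are omitted with a warning.
#'
#' @param pca A `th_pca` object from [pca_timecourse()].
#' @param reference Reference condition (default `"Th0"`).
#' @param component Component number (default 1).
#' @return Tibble of class `th_trajectories`: `condition`, `time_h`,
#'   `delta_pc`.
#' @export
pc_difference_trajectory <- function(pca, reference = "Th0", component = 1L) {
  stopifnot(inherits(pca, "th_pca"))
  if (component > pca$n_components) abort("`component` exceeds the retained components.")
  col <- paste0("PC", component)
  sc <- dplyr::summarise(
    dplyr::group_by(pca$scores, .data$condition, .data$time_h),
    score = mean(.data[[col]]), .groups = "drop"
  )
  if (!reference %in% sc$condition) abort(paste0("Reference condition not present: ", reference))
  ref <- sc[sc$condition == reference, c("time_h", "score")]
  names(ref)[2] <- "ref_score"
  x <- dplyr::inner_join(sc, ref, by = "time_h")
  dropped <- nrow(sc) - nrow(x)
  if (dropped > 0) warn(paste0(dropped, " timepoint(s) without a reference match were omitted."))
  out <- tibble::tibble(
    condition = x$condition, time_h = x$time_h,
    delta_pc = x$score - x$ref_score
  )
  out <- dplyr::arrange(out, .data$condition, .data$time_h)
  new_result(out, "th_trajectories", reference = reference, component = component)
}

#' Divergence (bifurcation) timing from PC-difference trajectories
#'
#' Per condition: the first timepoint at which `|delta PC|` exceeds
#' `fraction` of the trajectory's maximum absolute value, and the plateau
#' time (first timepoint reaching 90% of the maximum). An all-zero
#' trajectory has no divergence (`NA`). This is a parameterized heuristic
#' for reading off when cell fates start to separate.
#'
#' @param trajectories Output of [pc_difference_trajectory()].
#' @param fraction Divergence threshold as a fraction of the maximum.
#' @return Tibble: `condition`, `bifurcation_h`, `plateau_h`,
#'   `max_abs_delta`.
#' @export
bifurcation_time <- function(trajectories, fraction = 0.2) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  dplyr::summarise(
    dplyr::group_by(trajectories, .data$condition),
    {
      v <- abs(.data$delta_pc)[order(.data$time_h)]
      tt <- sort(.data$time_h)
      mx <- max(v)
      if (mx <= .Machine$double.eps^0.5) {
        tibble::tibble(bifurcation_h = NA_real_, plateau_h = NA_real_, max_abs_delta = 0)
      } else {
        tibble::tibble(
          bifurcation_h = tt[which(v > fraction * mx)[1]],
          plateau_h = tt[which(v >= 0.9 * mx)[1]],
          max_abs_delta = mx
        )
      }
    },
    .groups = "drop"
  )
}

#' Co-expression statistics from a cytokine quadrant table
#'
#' From flow-cytometry quadrant frequencies (percent) for two markers A and
#' B: the conditional frequency of B-positive cells within A-positive cells,
#' `both / (both + A_only) * 100`, and the marginal frequency of B-positive
#' cells, `both + B_only`. A conditional exceeding the marginal indicates
#' synergistic co-expression.
#'
#' @param both_pos,a_only,b_only,double_neg Quadrant frequencies in percent
#'   (the double-negative quadrant is only used for validation and may be
#'   `NULL`).
#' @param markers Length-2 character vector naming markers A and B.
#' @return Tibble: marker names, `conditional_pct` (`NA` when no A-positive
#'   cells), `marginal_pct`.
#' @examples
#' quadrant_coexpression_stats(2.43, 3.52, 29.8)
#' @export
quadrant_coexpression_stats <- function(both_pos, a_only, b_only,
                                        double_neg = NULL,
                                        markers = c("A", "B")) {
  vals <- c(both_pos, a_only, b_only, double_neg)
  if (any(vals < 0)) abort("Quadrant frequencies must be >= 0.")
  if (sum(vals) > 100.5) abort("Quadrant frequencies exceed 100% beyond rounding tolerance.")
  denom <- both_pos + a_only
  tibble::tibble(
    marker_a = markers[1], marker_b = markers[2],
    conditional_pct = if (denom > 0) both_pos / denom * 100 else NA_real_,
    marginal_pct = both_pos + b_only
  )
}
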