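# Per-gene linear decomposition of the hybrid lineage's profile into Th1 and
# Th2 contributions: Y_target = beta_Th1 * Y_Th1 + beta_Th2 * Y_Th2 + eps,
# with no intercept.

# Gene-wise sample vectors for one condition, ordered by (time, replicate).
condition_samples <- function(expression, design, condition) {
  d <- design[design$condition == condition, , drop = FALSE]
  d <- d[order(d$time_h, d$replicate), , drop = FALSE]
  structure(expr_values(expression)[, d$sample_id, drop = FALSE],
            key = paste(d$time_h, d$replicate))
}

#' Fit the hybrid two-lineage linear model per gene
#'
#' Regresses the target condition's profile on the Th1 and Th2 profiles of
#' the same gene with no intercept, as the model is stated. By default the
#' three profiles are mean-centered first (`center = TRUE`): the shared log2
#' baseline otherwise dominates the fit and forces `beta_Th1 + beta_Th2`
#' toward 1 for every gene regardless of its kinetics. Fitting uses all
#' replicate samples paired by (time, replicate) (`fit_on = "samples"`);
#' `fit_on = "means"` uses replicate-mean profiles. Coefficient t-tests use
#' `n - 2` degrees of freedom. A perfect fit (relative residual below
#' numerical tolerance, as arises in noiseless data) is resolved exactly:
#' coefficients numerically distinguishable from zero get p = 0, the rest
#' p = 1. Th1/Th2 profile pairs with |r| > 0.999 are reported as collinear
#' and not fit.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param genes Genes to fit (typically the Th1-vs-Th2 qualitative DEG).
#' @param target Target condition (`"Th12"` default, `"Th0"` supported).
#' @param center Mean-center profiles before the intercept-free fit.
#' @param fit_on `"samples"` (all replicates, default) or `"means"`.
#' @return Tibble of class `th_hybrid_fits`: per gene `beta_th1`, `beta_th2`,
#'   standard errors, t statistics, p-values, `rss`, `df`, `collinear`.
#' @export
fit_hybrid_model <- function(expression, design, genes = NULL, target = "Th12",
                             center = TRUE, fit_on = c("samples", "means")) {
  fit_on <- match.arg(fit_on)
  validate_expression(expression)
  validate_design(design, expression)
  for (cc in c(target, "Th1", "Th2")) {
    if (!cc %in% design$condition) abort(paste0("Condition not in design: ", cc))
  }
  genes <- genes %||% expression$gene_id
  sub <- expression[match(genes, expression$gene_id), , drop = FALSE]
  if (fit_on == "samples") {
    Yt <- condition_samples(sub, design, target)
    Y1 <- condition_samples(sub, design, "Th1")
    Y2 <- condition_samples(sub, design, "Th2")
    shared <- Reduce(intersect, list(attr(Yt, "key"), attr(Y1, "key"), attr(Y2, "key")))
    Yt <- Yt[, match(shared, attr(Yt, "key")), drop = FALSE]
    Y1 <- Y1[, match(shared, attr(Y1, "key")), drop = FALSE]
    Y2 <- Y2[, match(shared, attr(Y2, "key")), drop = FALSE]
  } else {
    Yt <- profile_means(sub, design, target)
    Y1 <- profile_means(sub, design, "Th1")
    Y2 <- profile_means(sub, design, "Th2")
    shared <- Reduce(intersect, list(colnames(Yt), colnames(Y1), colnames(Y2)))
    Yt <- Yt[, shared, drop = FALSE]
    Y1 <- Y1[, shared, drop = FALSE]
    Y2 <- Y2[, shared, drop = FALSE]
  }
  if (center) {
    Yt <- Yt - rowMeans(Yt); Y1 <- Y1 - rowMeans(Y1); Y2 <- Y2 - rowMeans(Y2)
  }
  n <- ncol(Yt)
  df <- n - 2L
  fit_one <- function(i) {
    x1 <- Y1[i, ]; x2 <- Y2[i, ]; y <- Yt[i, ]
    r12 <- suppressWarnings(cor(x1, x2))
    if (is.na(r12) || abs(r12) > 0.999) {
      return(c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 1))
    }
    X <- cbind(unname(x1), unname(x2))
    xtx <- crossprod(X)
    beta <- drop(solve(xtx, crossprod(X, y)))
    res <- y - drop(X %*% beta)
    rss <- sum(res^2)
    if (rss <= 1e-12 * max(sum(y^2), 1e-300)) {
      p <- ifelse(abs(beta) > 1e-8, 0, 1)
      se <- c(0, 0)
      tv <- ifelse(abs(beta) > 1e-8, sign(beta) * Inf, 0)
    } else {
      se <- sqrt(diag(solve(xtx)) * rss / df)
      tv <- beta / se
      p <- 2 * pt(-abs(tv), df)
    }
    c(beta, se, tv, p, rss, 0)
  }
  res <- t(vapply(seq_len(nrow(Yt)), fit_one, numeric(10)))
  dimnames(res) <- NULL
  out <- tibble::tibble(
    gene_id = rownames(Yt),
    beta_th1 = res[, 1], beta_th2 = res[, 2],
    se_th1 = res[, 3], se_th2 = res[, 4],
    t_th1 = res[, 5], t_th2 = res[, 6],
    p_th1 = res[, 7], p_th2 = res[, 8],
    rss = res[, 9], df = df,
    collinear = res[, 10] == 1
  )
  new_result(out, "th_hybrid_fits", target = target, center = center,
             fit_on = fit_on)
}

#' Four-way classification of hybrid-condition genes
#'
#' A coefficient counts as significant when its two-sided p-value is below
#' `alpha` AND the coefficient is positive. Both significant gives
#' `Superposition`; only `beta_Th1` gives `Th1_like`; only `beta_Th2` gives
#' `Th2_like`; neither gives `Independent`. A significant negative
#' coefficient never drives the category but raises the
#' `negative_significant` flag, since calling a gene "like" a lineage it
#' anti-correlates with would be misleading.
#'
#' @param fits Output of [fit_hybrid_model()].
#' @param alpha Per-coefficient significance level.
#' @return `fits` with `category` and `negative_significant` columns
#'   (collinear genes get `NA` category).
#' @export
classify_hybrid_genes <- function(fits, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  sig1 <- !is.na(fits$p_th1) & fits$p_th1 < alpha & fits$beta_th1 > 0
  sig2 <- !is.na(fits$p_th2) & fits$p_th2 < alpha & fits$beta_th2 > 0
  category <- dplyr::case_when(
    fits$collinear ~ NA_character_,
    sig1 & sig2 ~ "Superposition",
    sig1 ~ "Th1_like",
    sig2 ~ "Th2_like",
    TRUE ~ "Independent"
  )
  fits$category <- factor(category,
    levels = c("Th1_like", "Th2_like", "Superposition", "Independent"))
  fits$negative_significant <-
    (!is.na(fits$p_th1) & fits$p_th1 < alpha & fits$beta_th1 < 0) |
    (!is.na(fits$p_th2) & fits$p_th2 < alpha & fits$beta_th2 < 0)
  fits
}

#' Decompose a hybrid lineage's transcriptome
#'
#' Fits and classifies every gene of `genes` (the Th1-vs-Th2 qualitative DEG
#' in the intended workflow) and tabulates category fractions over the
#' successfully fit genes. Collinear/unfit genes are reported separately.
#'
#' @inheritParams fit_hybrid_model
#' @param alpha Per-coefficient significance level.
#' @return List of class `th_hybrid_result`: `fits` (classified tibble),
#'   `fractions` (category, n, fraction), `unfit` (gene IDs), `target`.
#' @export
decompose_all <- function(expression, design, genes, target = "Th12",
                          alpha = 0.05, center = TRUE,
                          fit_on = c("samples", "means")) {
  if (length(genes) == 0) abort("`genes` is empty: no qualitative DEG to decompose.")
  fits <- fit_hybrid_model(expression, design, genes, target, center, match.arg(fit_on))
  fits <- classify_hybrid_genes(fits, alpha)
  ok <- !fits$collinear
  fractions <- dplyr::count(dplyr::filter(fits, ok), .data$category,
                            .drop = FALSE, name = "n")
  fractions$fraction <- fractions$n / sum(fractions$n)
  structure(list(
    fits = fits,
    fractions = fractions,
    unfit = fits$gene_id[!ok],
    target = target, alpha = alpha
  ), class = "th_hybrid_result")
}

#' Robustness of category fractions to threshold choices
#'
#' Recomputes the four-way category fractions over a grid of coefficient
#' significance levels and correlation-index thresholds (the latter redefines
#' the qualitative-DEG input set from `contrasts`).
#'
#' @inheritParams fit_hybrid_model
#' @param contrasts Output of [contrast_results()] for the Th1-vs-Th2 pair.
#' @param alphas Coefficient significance levels to scan.
#' @param index_thresholds Correlation-index thresholds to scan.
#' @return Long tibble: `alpha`, `index_threshold`, `category`, `n`,
#'   `fraction`.
#' @export
threshold_robustness_scan <- function(expression, design, contrasts,
                                      target = "Th12",
                                      alphas = c(0.01, 0.05, 0.1),
                                      index_thresholds = 0.3,
                                      center = TRUE,
                                      fit_on = c("samples", "means")) {
  if (length(alphas) == 0 || length(index_thresholds) == 0) {
    abort("`alphas` and `index_thresholds` must be non-empty.")
  }
  fit_on <- match.arg(fit_on)
  grid <- tidyr::expand_grid(alpha = alphas, index_threshold = index_thresholds)
  purrr::pmap_dfr(grid, function(alpha, index_threshold) {
    q <- qualitative_deg(contrasts, index_threshold)
    genes <- q$gene_id[q$qualitative_deg]
    if (length(genes) == 0) {
      return(tibble::tibble(alpha = alpha, index_threshold = index_threshold,
                            category = factor(character(),
                              levels = c("Th1_like", "Th2_like", "Superposition", "Independent")),
                            n = integer(), fraction = numeric()))
    }
    res <- decompose_all(expression, design, genes, target, alpha, center, fit_on)
    dplyr::mutate(res$fractions, alpha = alpha, index_threshold = index_threshold,
                  .before = 1)
  })
}
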