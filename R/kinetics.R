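#' Per-condition polynomial regression F-test for kinetic genes
#'
#' For every gene and condition, fits expression on an orthogonal polynomial
#' time basis of the given degree (all replicate samples enter as independent
#' observations) and F-tests the full model against the intercept-only model.
#' A constant profile explains no variance and gets F = 0, p = 1.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param degree Polynomial degree (default 3: rise, peak and plateau are
#'   representable on a 10-point grid).
#' @param conditions Conditions to fit (default: all in `design`).
#' @return Tibble with one row per gene x condition: `f_stat`, `df1`, `df2`,
#'   `p_value`, residual/null sums of squares, and a `coef` list-column of
#'   fitted coefficients (orthogonal basis).
#' @export
fit_time_polynomial <- function(expression, design, degree = 3L, conditions = NULL) {
  validate_expression(expression)
  validate_design(design, expression)
  if (degree < 1) abort("`degree` must be >= 1.")
  conditions <- conditions %||% unique(design$condition)
  m <- expr_values(expression)
  out <- purrr::map(conditions, function(cc) {
    d <- design[design$condition == cc, , drop = FALSE]
    t_ <- d$time_h
    n <- length(t_)
    if (length(unique(t_)) < degree + 1 || n < degree + 2) {
      abort(paste0("Condition ", cc, ": not enough samples/timepoints for degree ", degree, "."))
    }
    X <- cbind(1, stats::poly(t_, degree))
    qx <- qr(X)
    Y <- t(m[, d$sample_id, drop = FALSE])          # n x genes
    tot <- colSums(Y^2)
    rss0 <- tot - n * colMeans(Y)^2                  # intercept-only RSS
    qty <- qr.qty(qx, Y)[seq_len(degree + 1), , drop = FALSE]
    rss <- pmax(tot - colSums(qty^2), 0)
    df1 <- degree
    df2 <- n - degree - 1
    f <- ((rss0 - rss) / df1) / (rss / df2)
    degenerate <- rss0 <= 1e-12 * pmax(tot, 1)
    f[degenerate] <- 0
    f[!is.finite(f)] <- 0
    p <- pf(f, df1, df2, lower.tail = FALSE)
    p[degenerate] <- 1
    beta <- qr.coef(qx, Y)
    tibble::tibble(
      gene_id = colnames(Y), condition = cc, degree = degree,
      f_stat = unname(f), df1 = df1, df2 = df2, p_value = unname(p),
      rss = unname(rss), rss_null = unname(rss0),
      coef = lapply(seq_len(ncol(beta)), function(j) beta[, j])
    )
  })
  dplyr::bind_rows(out)
}

#' Fold-change rescue rule for kinetic genes
#'
#' Flags a gene x condition as kinetic when its log2 fold change versus the
#' reference timepoint meets `threshold_log2` at `consecutive` or more
#' consecutive non-reference timepoints. Two-sided by default so that stably
#' downregulated genes are callable; `two_sided = FALSE` restores the strict
#' increase-only reading.
#'
#' @param fc Fold-change table from [log2_fold_change()].
#' @param threshold_log2 Absolute log2 fold-change threshold (1 = two-fold).
#' @param consecutive Required run length of consecutive hits.
#' @param two_sided Use `abs(log2fc)` (default) or signed increase only.
#' @param reference_time Reference timepoint excluded from the runs.
#' @return Tibble `gene_id`, `condition`, `foldchange_flag`.
#' @export
foldchange_rule <- function(fc, threshold_log2 = 1, consecutive = 2L,
                            two_sided = TRUE, reference_time = 0) {
  stopifnot(all(c("gene_id", "condition", "time_h", "log2fc") %in% names(fc)))
  n_times <- dplyr::n_distinct(fc$time_h)
  if (n_times < consecutive + 1) {
    abort(paste0("Need at least ", consecutive + 1, " timepoints for a run of ", consecutive, "."))
  }
  x <- fc[fc$time_h != reference_time, , drop = FALSE]
  x$hit <- if (two_sided) abs(x$log2fc) >= threshold_log2 else x$log2fc >= threshold_log2
  x <- dplyr::arrange(x, .data$condition, .data$gene_id, .data$time_h)
  dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$condition),
    foldchange_flag = {
      r <- rle(.data$hit)
      any(r$values & r$lengths >= consecutive)
    },
    .groups = "drop"
  )
}

#' Call kinetic genes per condition
#'
#' Combines the regression F-test (Benjamini-Hochberg FDR within each
#' condition, significant at `q < alpha`) with the fold-change rescue rule:
#' a gene is kinetic in a condition when either criterion holds.
#'
#' @param fits Output of [fit_time_polynomial()].
#' @param flags Output of [foldchange_rule()].
#' @param alpha FDR level for the regression test.
#' @return Tibble of class `th_kinetic_calls`: one row per gene x condition
#'   with `q_value`, `regression_significant`, `foldchange_flag`, `kinetic`.
#' @export
call_kinetic_genes <- function(fits, flags, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  x <- dplyr::left_join(
    dplyr::select(fits, "gene_id", "condition", "p_value"),
    flags, by = c("gene_id", "condition")
  )
  if (anyNA(x$foldchange_flag)) {
    abort("`fits` and `flags` must cover the same genes x conditions.")
  }
  x <- dplyr::mutate(
    dplyr::group_by(x, .data$condition),
    q_value = benjamini_hochberg(.data$p_value)
  )
  x <- dplyr::ungroup(dplyr::mutate(
    x,
    regression_significant = .data$q_value < alpha,
    kinetic = .data$regression_significant | .data$foldchange_flag
  ))
  new_result(x, "th_kinetic_calls", alpha = alpha)
}

#' Union of kinetic genes across conditions
#'
#' @param calls Output of [call_kinetic_genes()].
#' @return Character vector of genes kinetic in at least one condition,
#'   in input order.
#' @export
kinetic_union <- function(calls) {
  unique(calls$gene_id[calls$kinetic])
}

#' Cluster temporal profiles of kinetic genes
#'
#' Agglomerative clustering of replicate-mean time profiles within one
#' condition, with distance `1 - Pearson r` between gene profiles, cut to
#' exactly `k` clusters. Genes with constant profiles (undefined correlation)
#' are assigned afterwards to the centroid nearest in Euclidean distance.
#'
#' @param expression Log2-scale expression tibble.
#' @param design Sample design table.
#' @param genes Genes to cluster (e.g. the condition's kinetic set).
#' @param condition Condition whose profiles are clustered.
#' @param k Number of clusters (default 3).
#' @param linkage `"complete"` (default) or `"average"`.
#' @return List of class `th_clusters`: `assignment` tibble (`gene_id`,
#'   `cluster`), `centroids` (k x timepoints matrix of mean profiles),
#'   `condition`, `k`, `linkage`.
#' @export
cluster_profiles <- function(expression, design, genes, condition, k = 3L,
                             linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  genes <- intersect(expression$gene_id, genes)
  if (length(genes) < k) abort("`k` exceeds the number of genes to cluster.")
  sub <- expression[match(genes, expression$gene_id), , drop = FALSE]
  prof <- profile_means(sub, design, condition)
  sds <- apply(prof, 1, sd)
  constant <- sds == 0
  if (sum(!constant) < k) abort("Fewer non-constant profiles than clusters.")
  pc <- prof[!constant, , drop = FALSE]
  dd <- as.dist(1 - cor(t(pc)))
  cl <- cutree(hclust(dd, method = linkage), k = k)
  centroids <- t(vapply(seq_len(k), function(j) {
    colMeans(pc[cl == j, , drop = FALSE])
  }, numeric(ncol(pc))))
  dimnames(centroids) <- list(paste0("cluster_", seq_len(k)), colnames(prof))
  assignment <- setNames(integer(nrow(prof)), rownames(prof))
  assignment[names(cl)] <- cl
  if (any(constant)) {
    for (g in rownames(prof)[constant]) {
      d2 <- rowSums((centroids - matrix(prof[g, ], k, ncol(prof), byrow = TRUE))^2)
      assignment[g] <- which.min(d2)
    }
  }
  structure(list(
    assignment = tibble::tibble(gene_id = names(assignment), cluster = unname(assignment)),
    centroids = centroids, condition = condition, k = k, linkage = linkage
  ), class = "th_clusters")
}

# Shape features of a centroid: net change and peak prominence.
centroid_features <- function(centroids) {
  first <- centroids[, 1]
  last <- centroids[, ncol(centroids)]
  peak <- apply(centroids, 1, max)
  tibble::tibble(
    cluster = seq_len(nrow(centroids)),
    net = last - first,
    prominence = peak - pmax(first, last)
  )
}

#' Label clusters with kinetic archetypes
#'
#' Labels each cluster centroid as `C1` (fast transient upregulation), `C2`
#' (delayed stable upregulation) or `C3` (stable downregulation) from two
#' shape features: net change (final minus initial value) and peak prominence
#' (max minus the larger of initial/final). Negative net change gives C3; a
#' prominence-dominated shape gives C1; otherwise C2. With `k = 3` labels are
#' made unique (ties resolved toward the larger absolute net change).
#'
#' @param clusters A `th_clusters` object from [cluster_profiles()].
#' @return The same object with an `archetypes` tibble (`cluster`,
#'   `archetype`, shape features) and labels joined onto `assignment`.
#' @export
assign_archetype_labels <- function(clusters) {
  stopifnot(inherits(clusters, "th_clusters"))
  feats <- centroid_features(clusters$centroids)
  label_one <- function(net, prom) {
    if (net < 0) "C3" else if (prom > net) "C1" else "C2"
  }
  feats$archetype <- mapply(label_one, feats$net, feats$prominence)
  if (clusters$k == 3 && anyDuplicated(feats$archetype)) {
    # force a unique C1/C2/C3 labelling: C3 to the most negative net change,
    # C1 to the most prominence-dominated of the rest
    lab <- character(3)
    i3 <- which.min(feats$net)
    lab[i3] <- "C3"
    rest <- setdiff(1:3, i3)
    score <- feats$prominence[rest] - pmax(feats$net[rest], 0)
    tie <- order(-score, -abs(feats$net[rest]))
    lab[rest[tie[1]]] <- "C1"
    lab[rest[tie[2]]] <- "C2"
    feats$archetype <- lab
  }
  clusters$archetypes <- feats
  clusters$assignment <- dplyr::left_join(
    dplyr::select(clusters$assignment, "gene_id", "cluster"),
    dplyr::select(feats, "cluster", "archetype"), by = "cluster"
  )
  clusters
}

#' Detect kinetic-cluster switches between two conditions
#'
#' A switch is a gene kinetic in both conditions but assigned to different
#' archetypes; genes kinetic in only one condition are reported as
#' condition-specific, not as switches.
#'
#' @param labels_a,labels_b Tibbles with `gene_id` and `archetype` for the
#'   kinetic genes of each condition (see [assign_archetype_labels()]).
#' @param conditions Length-2 character vector naming the conditions.
#' @return Tibble `gene_id`, `archetype_a`, `archetype_b`, `status` in
#'   `{"switch", "stable", "only_a", "only_b"}`.
#' @export
detect_cluster_switches <- function(labels_a, labels_b, conditions = c("A", "B")) {
  a <- dplyr::select(labels_a, "gene_id", archetype_a = "archetype")
  b <- dplyr::select(labels_b, "gene_id", archetype_b = "archetype")
  x <- dplyr::full_join(a, b, by = "gene_id")
  x$status <- dplyr::case_when(
    is.na(x$archetype_b) ~ "only_a",
    is.na(x$archetype_a) ~ "only_b",
    x$archetype_a == x$archetype_b ~ "stable",
    TRUE ~ "switch"
  )
  new_result(x, "th_switches", conditions = conditions)
}
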