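test_that("polynomial F-test handles degenerate and exact profiles", {
  design <- make_design(conditions = "Th1", replicates = 2)
  t10 <- sort(unique(design$time_h))
  curves <- list(
    const = list(Th1 = rep(0, 10)),
    cubic = list(Th1 = 1e-4 * t10^3 - 0.01 * t10^2 + 0.3 * t10),
    kinetic = list(Th1 = archetype_curve(t10, "C2", 2, t0 = 24, s = 6))
  )
  expr <- make_expression(design, curves, sigma = 0)
  fits <- fit_time_polynomial(expr, design, degree = 3)

  expect_equal(fits$f_stat[fits$gene_id == "const"], 0)
  expect_equal(fits$p_value[fits$gene_id == "const"], 1)
  expect_lt(fits$rss[fits$gene_id == "cubic"], 1e-16)  # exact cubic, zero residual
  expect_lt(fits$p_value[fits$gene_id == "kinetic"], 1e-6)
  expect_true(all(fits$f_stat >= 0))

  short <- make_design(times = c(0, 6, 24, 48), conditions = "Th1", replicates = 1)
  exs <- make_expression(short, curves["const"], sigma = 0)
  expect_error(fit_time_polynomial(exs, short, degree = 3), "degree")
})

test_that("null regression p-values are uniform", {
  d <- simulate_null_dataset(n_genes = 1000, sigma = 0.25, seed = 202)
  fits <- fit_time_polynomial(d$expression, d$design, conditions = "Th1")
  ks <- suppressWarnings(stats::ks.test(fits$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fold-change rescue rule needs a consecutive run and is two-sided", {
  fc_of <- function(v) tibble::tibble(
    gene_id = "g", condition = "Th1",
    time_h = c(0, 3, 6, 12, 24), log2fc = v
  )
  expect_true(foldchange_rule(fc_of(c(0, 1.2, 1.1, 0.2, 0)))$foldchange_flag)
  expect_false(foldchange_rule(fc_of(c(0, 1.2, 0.4, 1.3, 0.1)))$foldchange_flag)
  expect_true(foldchange_rule(fc_of(c(0, -1.1, -1.4, 0, 0)))$foldchange_flag)
  expect_false(foldchange_rule(fc_of(c(0, -1.1, -1.4, 0, 0)),
                               two_sided = FALSE)$foldchange_flag)
  expect_true(foldchange_rule(fc_of(c(0, 0, 0, 1.1, 1.1)),
                              consecutive = 2)$foldchange_flag)
  expect_false(foldchange_rule(fc_of(c(0, 0, 0, 1.1, 1.1)),
                               consecutive = 3)$foldchange_flag)
  tiny <- fc_of(c(0, 1.5, 1.5, 1.5, 1.5))[1:2, ]
  expect_error(foldchange_rule(tiny, consecutive = 2), "timepoints")
})

test_that("kinetic calls OR the regression and fold-change criteria", {
  fits <- tibble::tibble(
    gene_id = c("a", "b", "c"), condition = "Th1",
    p_value = c(1e-6, 0.9, 0.8)
  )
  flags <- tibble::tibble(
    gene_id = c("a", "b", "c"), condition = "Th1",
    foldchange_flag = c(FALSE, TRUE, FALSE)
  )
  calls <- call_kinetic_genes(fits, flags, alpha = 0.05)
  expect_equal(calls$kinetic, c(TRUE, TRUE, FALSE))
  expect_equal(kinetic_union(calls), c("a", "b"))
  expect_error(call_kinetic_genes(fits, flags, alpha = 1.5), "alpha")

  # decreasing alpha never adds kinetic genes
  set.seed(31)
  fits2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:200), condition = "Th1",
                          p_value = runif(200)^2)
  flags2 <- tibble::tibble(gene_id = fits2$gene_id, condition = "Th1",
                           foldchange_flag = runif(200) < 0.1)
  prev <- NULL
  for (a in c(0.1, 0.05, 0.01, 0.001)) {
    cur <- kinetic_union(call_kinetic_genes(fits2, flags2, a))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("kinetic recovery on a mixed dataset is sensitive and specific", {
  cfg <- sim_config(n_flat = 400, n_shared = 100,
                    n_hybrid = c(Th1_like = 0, Th2_like = 0,
                                 Superposition = 0, Independent = 0),
                    sigma = 0.25, seed = 77)
  d <- simulate_dataset(cfg)
  fits <- fit_time_polynomial(d$expression, d$design)
  flags <- foldchange_rule(log2_fold_change(d$expression, d$design))
  calls <- call_kinetic_genes(fits, flags)
  got <- kinetic_union(calls)
  truth <- d$truth$gene_id[d$truth$class == "shared"]
  expect_gte(mean(truth %in% got), 0.95)
  # observed FDR over the per-condition calls, the family in which the
  # BH control is actually applied
  pos <- calls[calls$kinetic, ]
  fdr <- mean(!(pos$gene_id %in% truth))
  expect_lte(fdr, 0.10)
})

test_that("profile clustering recovers archetypes and is order/shift invariant", {
  skip_if_not_installed("mclust")
  noiseless <- make_archetype_dataset(n_per = 20, sigma = 0)
  cl <- cluster_profiles(noiseless$expression, noiseless$design,
                         noiseless$expression$gene_id, "Th1", k = 3)
  ari <- mclust::adjustedRandIndex(cl$assignment$cluster, noiseless$labels)
  expect_equal(ari, 1)

  # order invariance: shuffled gene input yields the same partition
  noisy <- make_archetype_dataset(n_per = 20, sigma = 0.25, seed = 14)
  cl1 <- cluster_profiles(noisy$expression, noisy$design,
                          noisy$expression$gene_id, "Th1", k = 3)
  perm <- sample(nrow(noisy$expression))
  cl2 <- cluster_profiles(noisy$expression[perm, ], noisy$design,
                          noisy$expression$gene_id[perm], "Th1", k = 3)
  j <- dplyr::inner_join(cl1$assignment, cl2$assignment, by = "gene_id")
  expect_equal(mclust::adjustedRandIndex(j$cluster.x, j$cluster.y), 1)

  # shift invariance of the correlation distance
  shifted <- noisy$expression
  shifted[3, -1] <- shifted[3, -1] + 5
  cl3 <- cluster_profiles(shifted, noisy$design, shifted$gene_id, "Th1", k = 3)
  j2 <- dplyr::inner_join(cl1$assignment, cl3$assignment, by = "gene_id")
  expect_equal(mclust::adjustedRandIndex(j2$cluster.x, j2$cluster.y), 1)

  expect_error(cluster_profiles(noiseless$expression[1:2, ], noiseless$design,
                                noiseless$expression$gene_id[1:2], "Th1", k = 3),
               "exceeds")
})

test_that("archetype labels follow centroid shape features", {
  d <- make_archetype_dataset(n_per = 10, sigma = 0)
  cl <- assign_archetype_labels(
    cluster_profiles(d$expression, d$design, d$expression$gene_id, "Th1", k = 3)
  )
  lab <- dplyr::inner_join(
    cl$assignment,
    tibble::tibble(gene_id = d$expression$gene_id, truth = d$labels),
    by = "gene_id"
  )
  expect_true(all(lab$archetype == lab$truth))
  expect_setequal(cl$archetypes$archetype, c("C1", "C2", "C3"))
})

test_that("cluster switches require kinetic status in both conditions", {
  a <- tibble::tibble(gene_id = c("g1", "g2", "g3"), archetype = c("C1", "C2", "C1"))
  b <- tibble::tibble(gene_id = c("g1", "g2", "g4"), archetype = c("C3", "C2", "C2"))
  sw <- detect_cluster_switches(a, b, c("Th1", "Th2"))
  expect_equal(sw$status[sw$gene_id == "g1"], "switch")
  expect_equal(sw$status[sw$gene_id == "g2"], "stable")
  expect_equal(sw$status[sw$gene_id == "g3"], "only_a")
  expect_equal(sw$status[sw$gene_id == "g4"], "only_b")
})
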