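test_that("hybrid fits are exact on noiseless copies and superpositions", {
  design <- make_design(replicates = 2)
  t10 <- sort(unique(design$time_h))
  f1 <- archetype_curve(t10, "C1", 2, tau = 6)
  f2 <- archetype_curve(t10, "C2", 2, t0 = 24, s = 6)
  curves <- list(
    copy1 = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f2, Th12 = f1),
    mix = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f2, Th12 = 0.5 * f1 + 0.5 * f2)
  )
  expr <- make_expression(design, curves, sigma = 0)
  fits <- fit_hybrid_model(expr, design)
  expect_equal(fits$beta_th1[fits$gene_id == "copy1"], 1, tolerance = 1e-8)
  expect_equal(fits$beta_th2[fits$gene_id == "copy1"], 0, tolerance = 1e-8)
  expect_lt(fits$rss[fits$gene_id == "copy1"], 1e-16)
  expect_equal(fits$beta_th1[fits$gene_id == "mix"], 0.5, tolerance = 1e-8)
  expect_equal(fits$beta_th2[fits$gene_id == "mix"], 0.5, tolerance = 1e-8)

  cls <- classify_hybrid_genes(fits)
  expect_equal(as.character(cls$category), c("Th1_like", "Superposition"))
})

test_that("scaling the target scales coefficients without changing the category", {
  design <- make_design(replicates = 2)
  t10 <- sort(unique(design$time_h))
  f1 <- archetype_curve(t10, "C1", 2, tau = 6)
  f2 <- archetype_curve(t10, "C3", 2, t0 = 24, s = 6)
  curves <- list(g = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f2,
                          Th12 = 0.6 * f1 + 0.4 * f2))
  expr <- make_expression(design, curves, sigma = 0.2, seed = 5)
  base <- classify_hybrid_genes(fit_hybrid_model(expr, design))

  th12 <- design$sample_id[design$condition == "Th12"]
  scaled <- expr
  # scale the centered target by 3 (centering makes this exact)
  v <- unlist(scaled[1, th12])
  scaled[1, th12] <- as.list(3 * (v - mean(v)) + mean(v))
  sc <- classify_hybrid_genes(fit_hybrid_model(scaled, design))
  expect_equal(sc$beta_th1, 3 * base$beta_th1, tolerance = 1e-8)
  expect_equal(sc$beta_th2, 3 * base$beta_th2, tolerance = 1e-8)
  expect_equal(sc$t_th1, base$t_th1, tolerance = 1e-8)
  expect_identical(as.character(sc$category), as.character(base$category))
})

test_that("swapping the Th1 and Th2 regressors swaps coefficients and labels", {
  design <- make_design(replicates = 2)
  t10 <- sort(unique(design$time_h))
  f1 <- archetype_curve(t10, "C1", 2.5, tau = 8)
  f2 <- archetype_curve(t10, "C3", 2.5, t0 = 30, s = 8)
  curves <- list(g = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f2, Th12 = f1))
  expr <- make_expression(design, curves, sigma = 0.2, seed = 6)
  fwd <- classify_hybrid_genes(fit_hybrid_model(expr, design))

  swapped_design <- design
  swapped_design$condition[design$condition == "Th1"] <- "Th2"
  swapped_design$condition[design$condition == "Th2"] <- "Th1"
  rev <- classify_hybrid_genes(fit_hybrid_model(expr, swapped_design))
  expect_equal(rev$beta_th1, fwd$beta_th2, tolerance = 1e-10)
  expect_equal(rev$beta_th2, fwd$beta_th1, tolerance = 1e-10)
  expect_equal(as.character(fwd$category), "Th1_like")
  expect_equal(as.character(rev$category), "Th2_like")
})

test_that("classification follows the coefficient significance pattern", {
  fits <- tibble::tibble(
    gene_id = c("t1", "t2", "sup", "ind", "negsig"),
    beta_th1 = c(1, 0.05, 0.6, 0.1, 0.8),
    beta_th2 = c(0.05, 1, 0.4, 0.1, -0.7),
    se_th1 = 0.1, se_th2 = 0.1, t_th1 = 0, t_th2 = 0,
    p_th1 = c(0.001, 0.6, 0.01, 0.4, 0.001),
    p_th2 = c(0.5, 0.002, 0.02, 0.5, 0.01),
    rss = 1, df = 18, collinear = FALSE
  )
  out <- classify_hybrid_genes(fits, alpha = 0.05)
  expect_equal(as.character(out$category),
               c("Th1_like", "Th2_like", "Superposition", "Independent", "Th1_like"))
  expect_equal(out$negative_significant,
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("collinear Th1/Th2 profiles are reported unfit, not classified", {
  design <- make_design(replicates = 2)
  t10 <- sort(unique(design$time_h))
  f <- archetype_curve(t10, "C2", 2, t0 = 24, s = 6)
  curves <- list(g = list(Th0 = rep(0, 10), Th1 = f, Th2 = f, Th12 = f))
  expr <- make_expression(design, curves, sigma = 0)
  fits <- fit_hybrid_model(expr, design)
  expect_true(fits$collinear[1])
  res <- decompose_all(expr, design, "g")
  expect_equal(res$unfit, "g")
})

test_that("decomposition tabulates fractions that sum to one", {
  cfg <- sim_config(n_flat = 0, n_shared = 0,
                    n_hybrid = c(Th1_like = 15, Th2_like = 15,
                                 Superposition = 10, Independent = 10),
                    sigma = 0.25, seed = 42)
  d <- simulate_dataset(cfg)
  res <- decompose_all(d$expression, d$design, d$truth$gene_id)
  expect_equal(sum(res$fractions$fraction), 1)
  expect_error(decompose_all(d$expression, d$design, character()), "empty")

  g <- glance(res)
  expect_equal(g$n_genes, 50)
  expect_equal(sum(unlist(g[grep("^frac_", names(g))])), 1)
  expect_equal(nrow(tidy(res)), 50)
})

test_that("threshold scan is consistent with a single decomposition", {
  cfg <- sim_config(n_flat = 50, n_shared = 0,
                    n_hybrid = c(Th1_like = 10, Th2_like = 10,
                                 Superposition = 10, Independent = 10),
                    sigma = 0.25, seed = 43)
  d <- simulate_dataset(cfg)
  u <- d$truth$gene_id[d$truth$class == "hybrid"]
  ctr <- suppressMessages(
    contrast_results(d$expression, d$design, d$truth$gene_id, c("Th1", "Th2"))
  )
  scan <- threshold_robustness_scan(d$expression, d$design, ctr,
                                    alphas = 0.05, index_thresholds = 0.3)
  qgenes <- ctr$gene_id[ctr$qualitative_deg]
  direct <- decompose_all(d$expression, d$design, qgenes, alpha = 0.05)
  expect_equal(scan$fraction, direct$fractions$fraction)
  expect_equal(scan$n, direct$fractions$n)
  expect_error(threshold_robustness_scan(d$expression, d$design, ctr,
                                         alphas = numeric()), "non-empty")
})
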