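test_that("nested F behaves at the extremes of condition separation", {
  design <- make_design(conditions = c("Th0", "Th1", "Th2"), replicates = 2)
  t10 <- sort(unique(design$time_h))
  shared <- archetype_curve(t10, "C2", 2, t0 = 24, s = 6)
  curves <- list(
    same = list(Th0 = shared, Th1 = shared, Th2 = shared),
    offset = list(Th0 = shared, Th1 = shared + 4, Th2 = shared)
  )
  expr <- make_expression(design, curves, sigma = 0)
  fit <- fit_group_model(expr, design, degree = 3)
  expect_equal(fit$f_stat[fit$gene_id == "same"], 0)
  expect_equal(fit$p_value[fit$gene_id == "same"], 1)
  expect_lt(fit$p_value[fit$gene_id == "offset"], 1e-12)
})

test_that("group-model null false-positive rate is calibrated", {
  d <- simulate_null_dataset(n_genes = 1000, sigma = 0.25, seed = 404)
  fit <- fit_group_model(d$expression, d$design)
  rate <- mean(fit$p_value < 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - ci)
  expect_lt(rate, 0.05 + ci)
})

test_that("contrast tests are symmetric and detect pairwise differences", {
  design <- make_design(replicates = 2)
  t10 <- sort(unique(design$time_h))
  f1 <- archetype_curve(t10, "C1", 2.5, tau = 6)
  f2 <- archetype_curve(t10, "C3", 2.5, t0 = 24, s = 6)
  curves <- list(
    diff12 = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f2, Th12 = f1),
    same12 = list(Th0 = rep(0, 10), Th1 = f1, Th2 = f1, Th12 = f1)
  )
  expr <- make_expression(design, curves, sigma = 0.1, seed = 9)
  ab <- contrast_test(expr, design, pair = c("Th1", "Th2"))
  ba <- contrast_test(expr, design, pair = c("Th2", "Th1"))
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-10)
  expect_lt(ab$p_value[ab$gene_id == "diff12"], 1e-8)
  expect_gt(ab$p_value[ab$gene_id == "same12"], 0.01)
  expect_error(contrast_test(expr, design, pair = c("Th1", "ThX")), "pair")
})

test_that("correlation index matches hand computation and its invariances", {
  design <- make_design(times = c(0, 6, 24, 48), conditions = c("Th1", "Th2"),
                        replicates = 1)
  curves <- list(
    hand = list(Th1 = c(0, 1, 2, 3), Th2 = c(0, 1, 0, 1)),
    ident = list(Th1 = c(0, 1, 2, 1), Th2 = c(0, 1, 2, 1)),
    anti = list(Th1 = c(0, 1, 2, 1), Th2 = c(2, 1, 0, 1))
  )
  expr <- make_expression(design, curves, sigma = 0)
  ci <- correlation_index(expr, design, c("Th1", "Th2"))
  expect_equal(ci$correlation_index[ci$gene_id == "hand"], 1 - 1 / sqrt(5),
               tolerance = 1e-10)
  expect_equal(ci$correlation_index[ci$gene_id == "ident"], 0, tolerance = 1e-12)
  expect_equal(ci$correlation_index[ci$gene_id == "anti"], 2, tolerance = 1e-12)

  # affine invariance: a * x + b with a > 0 leaves the index unchanged;
  # negation maps index -> 2 - index
  m <- as.matrix(expr[, -1])
  th1 <- design$sample_id[design$condition == "Th1"]
  scaled <- expr
  scaled[1, th1] <- as.list(2.5 * m[1, th1] + 1)
  ci2 <- correlation_index(scaled, design, c("Th1", "Th2"))
  expect_equal(ci2$correlation_index[1], ci$correlation_index[1], tolerance = 1e-10)
  negated <- expr
  negated[1, th1] <- as.list(-m[1, th1])
  ci3 <- correlation_index(negated, design, c("Th1", "Th2"))
  expect_equal(ci3$correlation_index[1], 2 - ci$correlation_index[1],
               tolerance = 1e-10)

  # constant profile: undefined, NA
  const <- expr
  const[2, th1] <- 5
  expect_message(ci4 <- correlation_index(const, design, c("Th1", "Th2")),
                 "constant")
  expect_true(is.na(ci4$correlation_index[2]))
})

test_that("qualitative DEG are nested within quantitative DEG", {
  contrasts <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    quantitative_deg = c(TRUE, TRUE, FALSE, TRUE),
    correlation_index = c(0.5, 0.1, 1.9, NA)
  )
  out <- qualitative_deg(contrasts, 0.3)
  expect_equal(out$qualitative_deg, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(qualitative_deg(contrasts, 2.5), "0, 2")
  expect_true(all(out$qualitative_deg <= out$quantitative_deg))
})

test_that("DEG calling recovers condition-specific genes on simulated data", {
  cfg <- sim_config(n_flat = 100, n_shared = 150,
                    n_hybrid = c(Th1_like = 40, Th2_like = 40,
                                 Superposition = 10, Independent = 10),
                    sigma = 0.25, seed = 55)
  d <- simulate_dataset(cfg)
  fits <- fit_time_polynomial(d$expression, d$design)
  flags <- foldchange_rule(log2_fold_change(d$expression, d$design))
  calls <- call_kinetic_genes(fits, flags)
  u <- kinetic_union(calls)
  ctr <- suppressMessages(
    contrast_results(d$expression, d$design, u, c("Th1", "Th2"))
  )
  hybrid_genes <- d$truth$gene_id[d$truth$class == "hybrid"]
  tested_hybrids <- intersect(hybrid_genes, ctr$gene_id)
  sens <- mean(ctr$quantitative_deg[match(tested_hybrids, ctr$gene_id)])
  expect_gte(sens, 0.9)
  # shared-response genes are not Th1-vs-Th2 DEG
  shared_genes <- intersect(d$truth$gene_id[d$truth$class == "shared"], ctr$gene_id)
  expect_lte(mean(ctr$quantitative_deg[match(shared_genes, ctr$gene_id)]), 0.1)

  vol <- build_volcano_table(ctr)
  expect_equal(nrow(vol), length(u))
  counts <- table(vol$category)
  expect_lte(counts[["qualitative DEG"]],
             counts[["qualitative DEG"]] + counts[["quantitative DEG"]])
  expect_true(all(ctr$qualitative_deg <= ctr$quantitative_deg))
})

test_that("stepwise coefficient selection agrees with the joint contrast on clear cases", {
  design <- make_design(conditions = c("Th0", "Th1", "Th2"), replicates = 2)
  t10 <- sort(unique(design$time_h))
  f1 <- archetype_curve(t10, "C2", 2.5, t0 = 24, s = 6)
  curves <- list(
    deg = list(Th0 = rep(0, 10), Th1 = f1, Th2 = -f1),
    null = list(Th0 = f1, Th1 = f1, Th2 = f1)
  )
  expr <- make_expression(design, curves, sigma = 0.2, seed = 21)
  ctr <- suppressMessages(contrast_results(expr, design, pair = c("Th1", "Th2"),
                                           stepwise = TRUE))
  expect_true(ctr$quantitative_deg[ctr$gene_id == "deg"])
  expect_false(ctr$quantitative_deg[ctr$gene_id == "null"])
})
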