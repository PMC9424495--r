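# Independent oracles and fixture builders used across the suite.

# Literal Benjamini-Hochberg step-up: q_i = min over j with p_(j) >= p_i of
# m * p_(j) / j. O(m^2), written straight from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  vapply(seq_len(m), function(i) {
    j <- which(ps >= p[i])
    min(pmin(m * ps[j] / j, 1))
  }, numeric(1))
}

# Exhaustive upper-tail hypergeometric p-value: enumerate every possible
# query of size n from a universe of size N and count overlaps >= k.
enumerate_hypergeom_tail <- function(k, set_idx, N, n) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% set_idx) >= k)
  mean(hits)
}

# Single-condition dataset of three fixed archetype curves (n_per genes
# each) plus Gaussian noise; used for clustering-recovery checks.
make_archetype_dataset <- function(n_per = 20, sigma = 0, seed = NULL,
                                   baseline = 7) {
  if (!is.null(seed)) set.seed(seed)
  times <- c(0, 3, 6, 12, 24, 36, 48, 72, 96, 120)
  curves <- list(
    C1 = archetype_curve(times, "C1", amplitude = 2, tau = 6),
    C2 = archetype_curve(times, "C2", amplitude = 2, t0 = 24, s = 6),
    C3 = archetype_curve(times, "C3", amplitude = 2, t0 = 24, s = 6)
  )
  design <- tidyr::expand_grid(condition = "Th1", time_h = times,
                               replicate = 1:2)
  design$sample_id <- sprintf("s_t%03d_r%d", design$time_h, design$replicate)
  design <- design[, c("sample_id", "condition", "time_h", "replicate")]
  labels <- rep(names(curves), each = n_per)
  mu <- t(vapply(labels, function(l) curves[[l]][match(design$time_h, times)],
                 numeric(nrow(design))))
  values <- baseline + mu + matrix(rnorm(length(mu), 0, sigma), nrow(mu), ncol(mu))
  rownames(values) <- sprintf("g%03d", seq_along(labels))
  colnames(values) <- design$sample_id
  expression <- tibble::as_tibble(as.data.frame(values), rownames = "gene_id")
  list(expression = expression, design = tibble::as_tibble(design),
       labels = labels, times = times, curves = curves)
}

# Small four-condition design grid used to hand-build expression fixtures.
make_design <- function(times = c(0, 3, 6, 12, 24, 36, 48, 72, 96, 120),
                        conditions = c("Th0", "Th1", "Th2", "Th12"),
                        replicates = 2) {
  d <- tidyr::expand_grid(condition = conditions, time_h = times,
                          replicate = seq_len(replicates))
  d$sample_id <- sprintf("%s_t%03d_r%d", d$condition, d$time_h, d$replicate)
  d[, c("sample_id", "condition", "time_h", "replicate")]
}

# Expression tibble from a per-gene list of per-condition curves.
make_expression <- function(design, curve_sets, sigma = 0, baseline = 7,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(unique(design$time_h))
  values <- t(vapply(curve_sets, function(cs) {
    vapply(seq_len(nrow(design)), function(i) {
      baseline + cs[[design$condition[i]]][match(design$time_h[i], times)]
    }, numeric(1))
  }, numeric(nrow(design))))
  if (sigma > 0) values <- values + matrix(rnorm(length(values), 0, sigma),
                                           nrow(values), ncol(values))
  rownames(values) <- names(curve_sets) %||%
    sprintf("g%03d", seq_along(curve_sets))
  colnames(values) <- design$sample_id
  tibble::as_tibble(as.data.frame(values), rownames = "gene_id")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
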