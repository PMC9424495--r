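#' Temporal archetype mean curves
#'
#' Smooth parametric stand-ins for the three kinetic archetypes seen in
#' polarized T helper cell time courses: `C1` fast transient upregulation
#' (gamma-type pulse, zero at t = 0, peak `amplitude` at t = `tau`),
#' `C2` delayed stable upregulation (logistic with midpoint `t0` and slope
#' scale `s`, anchored to zero at t = 0), `C3` stable downregulation (the
#' negated C2 shape), and `flat` (all zeros). Units are log2 expression
#' offsets from baseline.
#'
#' @param t Non-negative, ascending time vector (hours).
#' @param archetype One of `"C1"`, `"C2"`, `"C3"`, `"flat"`.
#' @param amplitude Positive amplitude in log2 units (sign of C3 is applied
#'   internally).
#' @param tau Peak time (h) for C1.
#' @param t0,s Midpoint and slope scale (h) for C2/C3.
#' @return Numeric vector of mean log2 offsets, same length as `t`.
#' @examples
#' archetype_curve(c(0, 6, 120), "C1", amplitude = 2, tau = 6)
#' @export
archetype_curve <- function(t, archetype = c("C1", "C2", "C3", "flat"),
                            amplitude = 2, tau = 6, t0 = 24, s = 6) {
  archetype <- match.arg(archetype)
  if (any(t < 0) || is.unsorted(t)) abort("`t` must be non-negative and ascending.")
  if (archetype == "flat") return(rep(0, length(t)))
  if (amplitude <= 0) abort("`amplitude` must be positive.")
  if (archetype == "C1") {
    if (tau <= 0) abort("`tau` must be positive.")
    return(amplitude * (t / tau) * exp(1 - t / tau))
  }
  if (s <= 0) abort("`s` must be positive.")
  v <- amplitude * plogis((t - t0) / s)
  v <- v - v[1]
  if (archetype == "C3") -v else v
}

# Localized transient bump, anchored to zero at t = 0; used only for the
# "independent" curve family, which must reach shapes orthogonal to the
# monotone/early-pulse archetypes.
bump_curve <- function(t, amplitude, t_center, width) {
  v <- amplitude * exp(-(t - t_center)^2 / (2 * width^2))
  v - v[1]
}

#' Simulation configuration
#'
#' Defines the structure of a synthetic multi-condition time-course dataset:
#' the default emulates the study design the package targets (4 conditions,
#' 10 timepoints over 120 h with 3-h initial spacing, 2 independent
#' experiments, Gaussian log2-scale noise).
#'
#' Gene classes: `flat` non-kinetic genes; `shared` genes carrying the same
#' archetype curve in every condition (shared response); and hybrid genes,
#' whose Th1 and Th2 curves are distinct (signed Pearson r within
#' `pair_cor_range`) and whose Th12 profile is a Th1 copy, a Th2 copy, a
#' convex superposition `w*Th1 + (1-w)*Th2`, or an independent pattern.
#' Independent curves are rejection-sampled until their absolute Pearson
#' correlation to both the Th1 and the Th2 curve is below `indep_r_max` and
#' the R-squared of their projection onto the span of the two curves is below
#' `indep_r2_max` (so "independent" genuinely means not attributable to
#' either program nor their combination); the Th1/Th2 pair is redrawn when a
#' pair admits no such curve.
#'
#' @param times Time grid in hours.
#' @param conditions Condition names; the generator requires the roles
#'   `Th0` (neutral), `Th1`, `Th2`, and `Th12` (hybrid).
#' @param replicates Replicates (independent experiments) per timepoint.
#' @param n_flat,n_shared Gene counts for the flat and shared-response classes.
#' @param n_hybrid Named counts for hybrid categories `Th1_like`, `Th2_like`,
#'   `Superposition`, `Independent`.
#' @param sigma Gaussian noise SD on the log2 scale.
#' @param baseline Baseline log2 intensity.
#' @param amplitude_range Range of archetype amplitudes (log2 units).
#' @param w_range Range of superposition weights.
#' @param pair_cor_range Admissible signed correlation between a hybrid
#'   gene's Th1 and Th2 mean curves.
#' @param indep_r_max Max absolute correlation of an independent curve to
#'   either parent curve.
#' @param indep_r2_max Max R-squared of an independent curve on the span of
#'   the two parent curves.
#' @param retry_cap Total candidate draws per independent gene before erroring.
#' @param seed Optional integer seed recorded in provenance.
#' @return A `sim_config` list.
#' @export
sim_config <- function(times = c(0, 3, 6, 12, 24, 36, 48, 72, 96, 120),
                       conditions = c("Th0", "Th1", "Th2", "Th12"),
                       replicates = 2L,
                       n_flat = 1400L, n_shared = 200L,
                       n_hybrid = c(Th1_like = 120L, Th2_like = 120L,
                                    Superposition = 80L, Independent = 80L),
                       sigma = 0.25, baseline = 7,
                       amplitude_range = c(1.5, 3),
                       w_range = c(0.4, 0.6),
                       pair_cor_range = c(-0.9, 0.7),
                       indep_r_max = 0.3, indep_r2_max = 0.2,
                       retry_cap = 1000L, seed = NULL) {
  if (any(times < 0) || is.unsorted(times) || length(times) < 4) {
    abort("`times` must be >= 4 non-negative ascending values.")
  }
  if (!all(c("Th0", "Th1", "Th2", "Th12") %in% conditions)) {
    abort("`conditions` must include Th0, Th1, Th2 and Th12.")
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  cats <- c("Th1_like", "Th2_like", "Superposition", "Independent")
  n_hybrid <- n_hybrid[cats]
  n_hybrid[is.na(n_hybrid)] <- 0L
  names(n_hybrid) <- cats
  if (n_flat < 0 || n_shared < 0 || any(n_hybrid < 0)) abort("Gene counts must be >= 0.")
  structure(list(
    times = times, conditions = conditions, replicates = as.integer(replicates),
    n_flat = as.integer(n_flat), n_shared = as.integer(n_shared),
    n_hybrid = setNames(as.integer(n_hybrid), cats),
    sigma = sigma, baseline = baseline,
    amplitude_range = amplitude_range, w_range = w_range,
    pair_cor_range = pair_cor_range,
    indep_r_max = indep_r_max, indep_r2_max = indep_r2_max,
    retry_cap = as.integer(retry_cap), seed = seed
  ), class = "sim_config")
}

# One random archetype curve plus its label/parameters.
draw_archetype <- function(times, amplitude_range) {
  label <- sample(c("C1", "C2", "C3"), 1)
  A <- runif(1, amplitude_range[1], amplitude_range[2])
  if (label == "C1") {
    pars <- list(amplitude = A, tau = runif(1, 3, 24))
    curve <- archetype_curve(times, "C1", A, tau = pars$tau)
  } else {
    pars <- list(amplitude = A, t0 = runif(1, 6, 60), s = runif(1, 2, 20))
    curve <- archetype_curve(times, label, A, t0 = pars$t0, s = pars$s)
  }
  list(label = label, curve = curve, pars = pars)
}

# Wider-ranged curve family (both signs, shifted pulses, localized bumps)
# for independent-category candidates.
draw_indep_candidate <- function(times, amplitude_range) {
  sgn <- sample(c(-1, 1), 1)
  A <- runif(1, amplitude_range[1], amplitude_range[2])
  type <- sample(3, 1)
  curve <- switch(type,
    sgn * archetype_curve(times, "C1", A, tau = runif(1, 3, 100)),
    sgn * archetype_curve(times, "C2", A, t0 = runif(1, 6, 110), s = runif(1, 2, 30)),
    sgn * bump_curve(times, A, runif(1, 10, 100), runif(1, 4, 30))
  )
  curve
}

# R-squared of y on the centered span of {x1, x2}.
span_r2 <- function(y, x1, x2) {
  X <- cbind(x1 - mean(x1), x2 - mean(x2))
  yc <- y - mean(y)
  fit <- lm.fit(X, yc)
  1 - sum(fit$residuals^2) / sum(yc^2)
}

#' Simulate a multi-condition time-course expression dataset
#'
#' Each sample value is `baseline + condition-specific mean curve +
#' Gaussian(0, sigma)` on the log2 scale. The returned ground truth labels
#' every gene's class, per-condition archetype and kinetic status, hybrid
#' category and generating parameters, enabling recovery tests of every
#' downstream analysis. With the same seed the output is identical.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `th_dataset` with tibbles `expression`, `design`,
#'   and `truth` (with list-column `curves` holding the per-condition mean
#'   log2 offset curves).
#' @examples
#' d <- simulate_dataset(sim_config(n_flat = 20, n_shared = 5,
#'   n_hybrid = c(Th1_like = 2, Th2_like = 2, Superposition = 2, Independent = 2),
#'   seed = 1))
#' dim(d$expression)
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  if (!is.null(config$seed)) set.seed(config$seed)
  times <- config$times
  conds <- config$conditions
  design <- tidyr::expand_grid(
    condition = conds, time_h = times, replicate = seq_len(config$replicates)
  )
  design$sample_id <- sprintf("%s_t%03d_r%d", design$condition, design$time_h, design$replicate)
  design <- dplyr::select(design, "sample_id", "condition", "time_h", "replicate")

  n_genes <- config$n_flat + config$n_shared + sum(config$n_hybrid)
  if (n_genes == 0) abort("Config declares zero genes.")
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  flat <- rep(0, length(times))
  zero_curves <- function() setNames(rep(list(flat), length(conds)), conds)

  truth_rows <- vector("list", n_genes)
  curve_list <- vector("list", n_genes)
  i <- 0L
  add_gene <- function(class, curves, archetypes, hybrid_category = NA_character_,
                       w = NA_real_) {
    i <<- i + 1L
    curve_list[[i]] <<- curves
    kinetic <- vapply(conds, function(cc) any(abs(curves[[cc]]) > 1e-12), logical(1))
    truth_rows[[i]] <<- tibble::tibble(
      gene_id = gene_ids[i], class = class, hybrid_category = hybrid_category, w = w,
      !!!setNames(as.list(archetypes[conds]), paste0("archetype_", conds)),
      !!!setNames(as.list(kinetic), paste0("kinetic_", conds))
    )
  }

  for (k in seq_len(config$n_flat)) {
    add_gene("flat", zero_curves(), setNames(rep("flat", length(conds)), conds))
  }
  for (k in seq_len(config$n_shared)) {
    a <- draw_archetype(times, config$amplitude_range)
    add_gene("shared", setNames(rep(list(a$curve), length(conds)), conds),
             setNames(rep(a$label, length(conds)), conds))
  }

  draw_pair <- function() {
    repeat {
      a1 <- draw_archetype(times, config$amplitude_range)
      a2 <- draw_archetype(times, config$amplitude_range)
      r <- cor(a1$curve, a2$curve)
      if (!is.na(r) && r > config$pair_cor_range[1] && r < config$pair_cor_range[2]) {
        return(list(a1 = a1, a2 = a2))
      }
    }
  }

  for (cat_ in names(config$n_hybrid)) {
    for (k in seq_len(config$n_hybrid[[cat_]])) {
      pair <- draw_pair()
      w <- NA_real_
      if (cat_ == "Independent") {
        found <- FALSE
        for (attempt in seq_len(config$retry_cap)) {
          cand <- draw_indep_candidate(times, config$amplitude_range)
          ok <- max(abs(cor(cand, pair$a1$curve)), abs(cor(cand, pair$a2$curve))) < config$indep_r_max &&
            span_r2(cand, pair$a1$curve, pair$a2$curve) < config$indep_r2_max
          if (isTRUE(ok)) { found <- TRUE; break }
          if (attempt %% 50L == 0L) pair <- draw_pair()  # this pair admits no candidate
        }
        if (!found) {
          abort("Could not satisfy the independent-curve correlation bound; loosen indep_r_max/indep_r2_max.")
        }
        f12 <- cand
        arch12 <- "independent"
      } else if (cat_ == "Superposition") {
        w <- runif(1, config$w_range[1], config$w_range[2])
        f12 <- w * pair$a1$curve + (1 - w) * pair$a2$curve
        arch12 <- "mixture"
      } else if (cat_ == "Th1_like") {
        f12 <- pair$a1$curve
        arch12 <- pair$a1$label
      } else {
        f12 <- pair$a2$curve
        arch12 <- pair$a2$label
      }
      curves <- zero_curves()
      curves[["Th1"]] <- pair$a1$curve
      curves[["Th2"]] <- pair$a2$curve
      curves[["Th12"]] <- f12
      arch <- setNames(rep("flat", length(conds)), conds)
      arch[["Th1"]] <- pair$a1$label
      arch[["Th2"]] <- pair$a2$label
      arch[["Th12"]] <- arch12
      add_gene("hybrid", curves, arch, hybrid_category = cat_, w = w)
    }
  }

  t_index <- match(design$time_h, times)
  values <- matrix(0, n_genes, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  for (cc in conds) {
    cols <- which(design$condition == cc)
    mu <- t(vapply(curve_list, function(cl) cl[[cc]], numeric(length(times))))
    values[, cols] <- config$baseline + mu[, t_index[cols], drop = FALSE]
  }
  if (config$sigma > 0) {
    values <- values + matrix(rnorm(length(values), 0, config$sigma),
                              nrow(values), ncol(values))
  }

  truth <- dplyr::bind_rows(truth_rows)
  truth$curves <- curve_list
  structure(list(
    expression = as_expr_tbl(values),
    design = tibble::as_tibble(design),
    truth = truth,
    config = config
  ), class = "th_dataset")
}

#' Simulate a null (all-flat) dataset
#'
#' Every gene is non-kinetic in every condition; used for type-I-error
#' calibration of the regression tests.
#'
#' @param n_genes Number of flat genes.
#' @param sigma Noise SD (log2 units).
#' @param seed Optional seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `th_dataset` list, as [simulate_dataset()].
#' @export
simulate_null_dataset <- function(n_genes = 2000L, sigma = 0.25, seed = NULL, ...) {
  cfg <- sim_config(
    n_flat = n_genes, n_shared = 0L,
    n_hybrid = c(Th1_like = 0L, Th2_like = 0L, Superposition = 0L, Independent = 0L),
    sigma = sigma, seed = seed, ...
  )
  simulate_dataset(cfg)
}
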