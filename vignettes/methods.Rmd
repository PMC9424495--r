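---
title: "Models and design choices in thkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in thkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thkinetics` analyzes dense multi-condition expression time courses from
polarized T helper cell cultures. This vignette explains the statistical
models, the parameters that matter, the synthetic-data generator used for
validation, and the places where the design was genuinely open and a choice
had to be made.

## The data model

The package works on a genes × samples matrix of log2 intensities (a tibble
with a `gene_id` column) plus a design table mapping each sample to a
condition (Th0, Th1, Th2, Th12), a time in hours, and a replicate. The
reference design is 4 conditions × 10 timepoints × 2 replicates. Replicates
are independent experiments, not technical repeats, which is why the hybrid
model pairs them explicitly (below).

Preprocessing follows the standard microarray sequence: quantile
normalization (every column forced to the rank-wise mean distribution, ties
averaged), log2 transformation for raw intensities, and an expressed-gene
filter: a gene is kept iff, in at least one condition, its mean expression
exceeds the global median of the whole matrix. We read "the median across
all groups and timepoints" as a single global median rather than
per-condition medians: it is one number, deterministic, and matches the idea
of a single expression floor. On a constant matrix this filter keeps zero
genes, a documented degenerate case. When a probe-to-gene map is supplied,
filtering happens at probe level first and probes collapse to genes by the
`max_mean` rule (the probe with the highest overall mean represents the
gene), the common microarray convention; an averaging rule is available.

## Kinetic genes

Per condition, each gene's samples are regressed on an orthogonal polynomial
time basis of degree 3 and F-tested against the intercept-only model.
Degree 3 on a 10-point grid can represent a rise, a peak and a plateau
without overfitting; the degree is exposed as a parameter. All replicate
samples enter as independent observations, preserving degrees of freedom
(`df = n − degree − 1 = 16` at the reference design). P-values are BH
corrected *within each condition* — the family in which the test is run and
reported — and significance is `q < 0.05`. The same per-family logic applies
to the per-contrast DEG tests.

A rescue rule catches genes with strong but non-polynomial responses:
|log2 fold change versus t = 0| ≥ 1 at two or more consecutive non-reference
timepoints. The rule is two-sided by default although it is often described
as an "increase" rule, because the stable-downregulation archetype (C3) must
be callable; a one-sided option exists. A gene is kinetic when either
criterion fires.

Temporal patterns come from agglomerative clustering (complete linkage by
default, average available) of replicate-mean profiles under the distance
1 − Pearson r, cut at exactly K = 3. Correlation distance makes clustering
invariant to each gene's baseline and amplitude, which is what "same shape"
should mean. Constant profiles have undefined correlation and are assigned
to the Euclidean-nearest centroid afterwards — deterministic and rare.
Centroids are labeled by two shape features: net change (final − initial)
and peak prominence (max − max(initial, final)). Negative net change ⇒ C3;
prominence dominating the net change ⇒ C1; otherwise C2. At K = 3 labels
are forced unique with ties resolved toward the larger absolute net change.

## Quantitative and qualitative DEG

Condition differences are tested on the union of kinetic genes in two
steps. Step 1 fits the full model — shared time polynomial, per-condition
offsets, and condition × time interactions, reference Th0 — against the
time-only model; the nested F tests all `(G − 1)(degree + 1)` distinguishing
coefficients jointly. Step 2 tests one condition pair by refitting with the
pair merged into one group, an exactly symmetric formulation. The default
per-pair test is this joint F — deterministic and order-independent — with a
backward-stepwise coefficient-selection mode (drop the least significant
condition-linked coefficient until all survive at α) available for users who
want per-coefficient selection semantics.

`quantitative_deg` requires both steps at FDR 0.05. The correlation index
1 − r between the two conditions' replicate-mean profiles then separates
level shifts from shape changes: `qualitative_deg` requires the index to
exceed 0.3. The index lives in [0, 2]; identical shapes give 0, mirrored
shapes give 2, and it is invariant to positive affine rescaling of either
profile. We compute r on replicate-mean profiles (10 shared timepoints) by
default because the index formalizes "similar trends over time", a
per-timepoint trajectory notion; an all-samples mode exists. Genes with a
constant profile in either condition have an undefined index and are never
called qualitative. By construction the categories nest:
qualitative ⊆ quantitative ⊆ kinetic.

## The hybrid linear model

For each gene, the Th1/2 hybrid profile is modeled as

$$Y_{Th1/2} = \beta_{Th1} Y_{Th1} + \beta_{Th2} Y_{Th2} + \epsilon$$

with no intercept. Two practical decisions matter here.

**Centering.** The model is stated on expression values, but log2 profiles
share a large common baseline (~7 log2 units against curve amplitudes of
1–3). Fit on raw levels, that baseline dominates: the least-squares solution
puts `β_Th1 + β_Th2 ≈ 1` with both coefficients highly significant for
*every* gene, and the Independent category becomes empty. The package
therefore mean-centers the three profiles before the intercept-free fit
(`center = TRUE`); this removes the baseline while keeping the model
intercept-free in the stated form. An uncentered mode is available for
comparison.

**Fit points.** By default the fit uses all replicate samples, paired by
(time, replicate) — 20 points at the reference design, `df = 18`. Replicates
are independent experiments, so pairing target and regressor samples from
the same experiment is natural and shares experiment-level effects. A
replicate-mean mode (10 points) mirrors the correlation-index convention.

A coefficient is "significant" when its two-sided t-test (at `df = n − 2`)
gives p < 0.05 *and* the coefficient is positive; positivity is a separate
condition rather than a one-sided test so standard regression output stays
interpretable. Both significant ⇒ Superposition; one ⇒ Th1-like / Th2-like;
neither ⇒ Independent. A significant *negative* coefficient never assigns a
lineage — it would call a gene "like" a program it anti-correlates with —
but raises a `negative_significant` flag. Classification uses per-gene
uncorrected coefficient p-values (this is classification of a preselected
set, not discovery); a BH-corrected variant can be applied by the user on
the returned p-value columns.

Two numerical edge cases are resolved exactly. A perfect fit (relative
residual below 1e−12, which arises in noiseless data where the target *is*
one regressor) would make t-statistics 0/0; the package instead assigns
p = 0 to coefficients numerically distinguishable from zero and p = 1 to
the rest. Th1/Th2 profile pairs with |r| > 0.999 are reported as collinear
and excluded rather than fit.

## The synthetic-data generator

`simulate_dataset()` emulates the reference design: time grid
{0, 3, 6, 12, 24, 36, 48, 72, 96, 120} h (ten points, the first three at 3-h
spacing), four conditions, two replicates, homoscedastic Gaussian noise on
the log2 scale with σ = 0.25 (typical microarray replicate noise), baseline
7 log2 units. Archetype mean curves are smooth parametric stand-ins chosen
for identifiability: C1 is a gamma-type pulse `A (t/τ) exp(1 − t/τ)` (zero
at 0, peak A at τ), C2 a logistic anchored to zero at t = 0, C3 its
negation. Amplitudes default to U(1.5, 3) log2 units — the scale of changes
that qualitative DEG calling targets.

Hybrid genes draw distinct Th1 and Th2 curves with signed correlation in
(−0.9, 0.7): the 0.7 ceiling mirrors the qualitative-DEG criterion
(index > 0.3), and the −0.9 floor excludes exactly mirrored regulation,
which is biologically implausible and makes the two regressors nearly
collinear. The Th12 profile is then a Th1 copy, a Th2 copy, a convex
superposition with weight w ~ U(0.4, 0.6), or an independent curve.
Independent curves are rejection-sampled from a wider family (shifted
pulses, logistics and localized bumps, both signs) and accepted only if
(i) their absolute correlation to both parent curves is below 0.3 and
(ii) the R² of their projection onto the span of the two parent curves is
below 0.2. The marginal bound alone does not make the category
identifiable: when the Th1 and Th2 curves are strongly anti-correlated, a
curve can correlate weakly with each yet lie almost entirely in their span.
The joint-R² bound is the literal formalization of "not attributable to
either program nor their combination". When a particular Th1/Th2 pair
admits no such curve the pair is redrawn; the total retry budget is capped
(default 1000) and exhausting it is an error suggesting looser bounds.

What the generator does **not** emulate: intensity-dependent
(heteroscedastic) noise, probe-level structure, batch effects between the
two experiments, correlated noise across genes, and count-type single-cell
data. Recovery tests passing on this generator therefore demonstrate that
the estimators are correct and calibrated under the stated model, not that
real arrays satisfy that model.

## Enrichment, PCA and bifurcation

Overrepresentation uses the exact upper-tail hypergeometric probability
(computed in log space) against the expressed-gene universe — the standard
ORA "background correction". Set sizes are filtered to [3, 1000] *after*
intersection with the universe, because the within-universe size is the `m`
that enters the test. BH runs across all tested sets pooled over sources,
significance at FDR < 0.1.

PCA is gene-centered over samples. Each component's sign is fixed by
orienting its scores to correlate positively with time (falling back to the
first non-zero loading), removing the sign ambiguity that would otherwise
break reproducibility. PC-difference trajectories subtract the reference
condition's replicate-mean score at matched timepoints; the bifurcation
read-out — first timepoint where |ΔPC| exceeds 20% of the trajectory's
maximum, plateau at 90% — is a parameterized heuristic for when fates
separate, not an inferential procedure. Genes "highly correlated across all
subsets" are removed when the *minimum* pairwise profile correlation across
condition pairs exceeds 0.9 (threshold exposed); undefined correlations
count as correlated, so constant genes are removed.

## Reproducibility and problem sizes

Every stochastic step is seeded; the pipeline orchestrator
(`run_full_analysis()`) writes per-stage TSVs with provenance headers and a
manifest of MD5 digests, and reruns with the same configuration and seed are
byte-identical. The validation suite sizes simulations to be decisive yet
quick: 2,000-gene null datasets for type-I calibration, 300 + 1,700 genes
for kinetic recovery, 200 genes per category for hybrid classification, 500
replicates for coefficient coverage, and 20 seeds × 60 genes for clustering
recovery.

## Known limitations

* The polynomial F-test assumes Gaussian, homoscedastic noise on the log2
  scale; no empirical-Bayes variance moderation is applied.
* The hybrid model regresses noisy profiles on noisy profiles; the
  resulting errors-in-variables attenuation slightly biases coefficients
  toward zero and makes nominal t-intervals mildly anticonservative at high
  noise. At the reference noise level this effect is small (the coverage
  checks in the test suite quantify it) but it grows with σ.
* Observed false-discovery proportions are controlled within each declared
  family (per condition, per contrast); unions across families — e.g. "kinetic
  in at least one condition" — inherit the usual union inflation and are not
  separately FDR-controlled.
* The bifurcation detector and the cross-subset correlation filter are
  heuristics with exposed thresholds, not tests.
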