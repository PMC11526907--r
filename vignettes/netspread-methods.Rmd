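---
title: "Modeling seeded pathology spread on the connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling seeded pathology spread on the connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When misfolded protein seeds (such as alpha-synuclein pre-formed fibrils)
are injected into one brain region, pathology appears over the following
months in a stereotyped set of distant regions. Two hypotheses compete to
explain the pattern: pathology travels along axonal projections
(connectivity), and regions differ intrinsically in their propensity to
develop pathology (vulnerability). `netspread` implements a quantitative
version of this decomposition: a linear network diffusion model captures
the connectivity component, and the model's residuals define regional
vulnerability, which can then be interrogated against regional gene
expression.

## The diffusion model

The brain is represented as a weighted directed graph: `W[i, j]` is the
projection strength from region `i` to region `j`. Spread is modeled as
linear diffusion `dx/dt = -c L x` with two directional graph Laplacians,

* anterograde (with the axon direction): `L_a = D_out - t(W)`,
  `D_out = diag(rowSums(W))`,
* retrograde (against it): `L_r = D_in - W`, `D_in = diag(colSums(W))`,

so that the propagated pathology from a one-hot seed `x0` is
`x(t) = expm(-c L t) x0`. Both Laplacians have zero column sums, so the
propagator conserves total mass, and `L_a(W) = L_r(t(W))` — anterograde
spread on a graph is retrograde spread on the transposed graph. We use
unnormalized strength Laplacians; normalization conventions (e.g. by
region volume) can be applied to `W` before construction if desired.

Observed pathology enters on the log scale. At each timepoint `t` the
across-mice mean percent area occupied per region, `y(t)`, is regressed on
the log-propagated predictors:

```
y(t) = b0(t) + b_a(t) * log10(x_a(t)) + b_r(t) * log10(x_r(t)) + eps(t)
```

with `x_a(t)` and `x_r(t)` the anterograde and retrograde propagations at
global rate constants `c_a` and `c_r`. Regions whose propagated value does
not exceed a reachability floor (default `1e-12`) are excluded from the
regression at that timepoint rather than log-transformed: an unreachable
region carries no information about spread rate, and any pseudo-count
would place it arbitrarily on the log scale. Regions with zero mean
observed pathology at a timepoint are likewise excluded there.

### Fitting

The per-timepoint coefficients are profiled out by ordinary least squares,
so the only nonlinear parameters are `(c_a, c_r)`. These are chosen to
minimize the pooled sum of squared residuals across all timepoints, with
equal weight per region-timepoint. The search is a 20x20 log-spaced grid
over `[1e-3, 1e2]` per month followed by derivative-free local refinement
(Brent in one dimension, Nelder-Mead in two) started from the best grid
cell. The objective is cheap and possibly multimodal, which is why we
refine from a global grid rather than descend from a single start; the
whole procedure is deterministic. One caveat of the pooled-SSE objective
is that the inclusion mask depends on the candidate rates, so timepoints
can contribute different region counts across candidates; on data with a
genuine diffusion signal this has negligible effect (rate constants are
recovered to well under 1% on noiseless synthetic data), but it is the
reason the fit reports per-timepoint region counts.

Rates are fit jointly across timepoints — a single pair `(c_a, c_r)` with
time-varying regression weights. This is the most parsimonious reading of
a model with "time-dependent weights" but global "diffusion rate
constants"; fitting rates per timepoint would absorb part of the
directionality signal into the rate schedule.

Single-predictor variants (`anterograde`, `retrograde`, `euclidean`) fix
the unused weight at zero. The Euclidean variant runs the same machinery
on a surrogate connectome whose symmetric weights decrease with
inter-centroid distance (default `1/d`; an exponential kernel is
available). It is the spatial-proximity null: if axonal topology matters,
the connectome models should beat it out of sample.

## Validation

**Seed specificity.** If the model merely captures generic gradients, it
should fit equally well from any seed. `alternate_seed_test()` refits the
model from randomly chosen alternate seed regions and reports, per
timepoint, the add-one permutation p-value
`p = (1 + #{r_alt >= r_actual}) / (1 + n_alt)` (never exactly zero; the
raw proportion is also stored). Alternate seeds are drawn uniformly from
the non-seed regions, without replacement unless the request exceeds the
candidate pool. The default configuration for this test disables the
local refinement stage so that hundreds of refits stay cheap; the actual
seed is always fit under exactly the same settings as the alternates, so
the comparison is fair at any setting.

**Out-of-sample model comparison.** `crossval_compare()` randomly splits
*regions* into train and held-out halves, fits each model variant on the
training regions, and scores Pearson r on the held-out regions per
timepoint. Regions are the natural resampling unit here because the
regression's observations are regional values; a mouse-level split would
mostly resample noise around the same regional means. The same splits are
used for every variant (paired comparisons), and held-out distributions
are compared pairwise with a two-sided Wilcoxon rank-sum test — a
deliberately assumption-light choice, since the distributions are bounded
and skewed. Region order in the input files does not affect the
resampling: regions are canonically sorted internally before splits are
drawn.

## Regional vulnerability

Residuals `eps(t)` measure pathology unexplained by connectivity:
positive means more pathology than connectivity predicts (vulnerable),
negative means less (resilient). The composite score averages residuals
over the late timepoints (default 1, 3, 6, 9 months) and over both
hemisphere instances of an anatomical region when the connectome carries
hemisphere structure. Early timepoints are excluded by default because
model fits there are weaker and their residual patterns cohere poorly
with the later ones — `residual_correlation_matrix()` makes that check
explicit on any fitted model. Masked region-timepoints simply contribute
nothing (no imputation): imputing zeros would bias excluded regions
toward apparent resilience. Signs follow the residual convention, so a
larger score always means more vulnerable.

## Expression association

The expression stages mirror standard spatial-transcriptomics practice:

* **Segment QC** removes profiled segments below fixed thresholds for
  trimmed (80%), stitched (80%), and aligned (75%) reads, sequencing
  saturation (50%), and percent of genes above the limit of quantification
  (3%), recording the first failing rule.
* **Gene QC** defines a per-segment LOQ as the geometric mean of the
  negative-control probes times the squared geometric SD (two geometric
  SDs above background, the platform convention; the multiplier is
  configurable), removes genes detected in fewer than 1% of segments,
  then removes global and local outliers by one-pass two-sided Grubbs
  tests at alpha 0.01 ("global" = per-gene pooled values across the
  dataset, "local" = across genes within one segment). A keep-list
  exempts a priori genes. The Grubbs critical value uses the standard
  t-quantile formula, implemented directly and tested against it.
* **Association.** Each gene's regional profile is normalized with a
  scaled sigmoid — z-score, logistic, then min-max to span [0, 1] — and
  both the gene profile and the vulnerability map are rank inverse normal
  transformed (Blom offset 3/8, average ranks for ties) before computing
  Pearson correlations with two-sided p-values and Benjamini-Hochberg
  q-values. For tie-free input the sigmoid is order-preserving and
  therefore mathematically redundant before a rank transform (a property
  the test suite asserts); both steps are kept because together they
  define the normalization contract, and the sigmoid is what makes the
  stored atlas scale comparable across genes.
* **Enrichment.** `preranked_gsea()` is the classic weighted
  Kolmogorov-Smirnov running sum on the correlation-ranked gene list, with
  a gene-label permutation null (the phenotype here is a single regional
  vector, so phenotype permutation is unavailable), normalized enrichment
  scores per sign, and per-sign FDR. The enrichment score is tested
  against brute-force enumeration and against an independent reference
  implementation.
* **Kinase filtering** intersects significant positively correlated genes
  with a kinase class list and an externally derived differential
  expression list, ordered by correlation strength.

## Synthetic data and what passing tests mean

`synth_connectome()` generates sparse directed graphs with log-normal
weights, random 3-D centroids, guaranteed weak connectivity from the seed
candidate, and optional mirrored hemispheres with weak commissural links.
`synth_pathology()` evaluates the diffusion equation at known rates and
weights, adds planted per-region offsets in log10 space (optionally only
at late timepoints), and draws per-mouse log-normal noise — noise is
normal in log10 space to match the model's additive error term.
`synth_expression()` plants genes whose regional profiles correlate with
the planted vulnerability at a chosen effect size among pure-noise genes.

The shipped reference scenario uses 40 regions at density 0.2, the
study-style design of 8 timepoints (0.1-9 months) with 5 mice per
timepoint, log10 noise SD 0.1, planted offsets of SD 0.5, and a
1,000-gene atlas with 50 genes planted at correlation 0.6. Forty regions
keep a full fit under a second so that permutation and cross-validation
distributions with hundreds of refits remain routine; the planted effect
sizes are comfortably inside what the corresponding real assays resolve.

Synthetic data are generated *from the fitted model's own family*, so
parameter-recovery and discrimination results demonstrate the estimator's
correctness and power, not the biological adequacy of linear diffusion.
Real pathology data add model misspecification (nonlinear aggregation,
clearance, neuron death), spatially correlated measurement error from
registration and segmentation, and a connectome that is itself estimated
— none of which the generator emulates. Conclusions about real data rest
on the validation machinery (seed nulls, out-of-sample comparison), not
on the synthetic benchmarks.

## Numerical choices and edge cases

* Matrix exponentials are computed densely (`Matrix::expm`); graphs of a
  few hundred regions are well within range.
* Propagated values get tiny negative entries from roundoff; they are
  clipped to zero. Mass conservation holds to 1e-10 relative, the
  semigroup property to 1e-10, and agreement with brute-force RK4
  integration to 1e-6 — all asserted in the test suite.
* Pearson statistics require at least 3 included regions and nonzero
  variance; otherwise they are returned as `NA` flagged undefined, never
  silently as a number.
* Peak-timepoint ties break toward the earliest timepoint; all-zero
  series are flagged `"none"`.
* Degenerate inputs to the normalizations (constant vectors) return
  flagged neutral values (0.5 after the sigmoid, 0 after the rank
  transform) rather than errors, so single pathological genes cannot
  abort an atlas-wide scan.
* All randomness flows through explicit integer seeds; rerunning any
  stochastic routine, or the whole pipeline, with the same seed is
  bit-reproducible, which the pipeline manifest makes checkable via
  output hashes.

## Known limitations

* Linear diffusion has no aggregation, clearance, or cell-death terms;
  time-varying regression weights absorb some, but not all, of that
  nonlinearity.
* The pooled-SSE objective weights region-timepoints equally, so
  timepoints with many included regions dominate rate estimation.
* Hemisphere pooling assumes residuals are conserved across hemispheres;
  the flag to keep hemispheres separate exists precisely so that this
  assumption can be checked per dataset.
* The enrichment FDR follows the classic per-sign permutation recipe,
  which is conservative for small collections of sets.
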