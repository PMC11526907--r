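# netspread

Network diffusion modeling of seeded protein pathology spread, residual
regional vulnerability, and its association with regional gene expression.

## What it does

After misfolded protein seeds (e.g. alpha-synuclein pre-formed fibrils)
are injected into one brain region, pathology spreads over months to a
stereotyped set of regions. `netspread` decomposes that pattern into a
connectivity component and an intrinsic-vulnerability component:

1. **Diffusion model.** Pathology is propagated from the seed along a
   weighted directed connectome with anterograde and retrograde graph
   Laplacian propagators, `x(t) = expm(-c L t) x0`, and observed regional
   log pathology is regressed on the log-propagated predictors:

   `y(t) = b0(t) + b_a(t) log10(x_a(t)) + b_r(t) log10(x_r(t)) + eps(t)`

   Global rate constants `(c_a, c_r)` minimize pooled squared error over
   all timepoints (grid search plus local refinement); per-timepoint
   weights come from ordinary least squares.
2. **Validation.** A seed-specificity permutation test (refit from random
   alternate seeds, add-one p-values) and cross-validated comparison of
   the bidirectional, anterograde-only, retrograde-only and Euclidean
   distance models on held-out regions (Wilcoxon rank-sum on held-out
   Pearson r).
3. **Vulnerability.** Residuals `eps(t)` averaged over late timepoints
   (and hemispheres) give a composite per-region vulnerability score;
   positive = more pathology than connectivity predicts.
4. **Expression association.** Segment and gene QC (LOQ from negative
   probes, Grubbs outlier tests), sigmoid + rank inverse normal
   normalization, per-gene Pearson correlation with vulnerability under
   Benjamini-Hochberg FDR, preranked gene set enrichment, and kinase
   candidate filtering.
5. **Synthetic data.** Generators for connectomes, pathology time courses
   and expression atlases with known ground truth, so every stage is
   testable end to end without external downloads.

See the methods vignette (`vignettes/netspread-methods.Rmd`) for the
model's assumptions, parameter meanings and design decisions.

## Worked example

```r
library(netspread)

sim  <- simulate_scenario(rng_seed = 42)   # 40 regions, 8 timepoints
fit  <- fit_model(sim$pathology, sim$conn, sim$truth$seed_region)
fit
#> spread_fit: mode bidirectional, 40 regions, 8 timepoints
#>   rates: c_a = 99.99, c_r = 1.698
#>   per-timepoint Pearson r: 0.734 0.690 0.673 0.629 0.640 0.632 0.628 0.624
```

The per-timepoint r is the correlation between predicted and observed log
pathology over included regions. This scenario plants large per-region
vulnerability offsets (SD 0.5 log10 units), so connectivity explains only
part of the pattern, and the weakly contributing anterograde rate drifts
to the search bound where its predictor is nearly flat — with offsets
removed the true rates (0.5, 2.0) are recovered to well under 1%.

```r
vuln <- composite_vulnerability(fit)       # mean residual over 1,3,6,9 MPI
head(vuln, 3)
#>   region_id       score n_contributing
#> 1      R001 -1.19739959              4
#> 2      R002  0.12950914              4
#> 3      R003  0.02393823              4
s <- vulnerability_scores(vuln)
cor(s, sim$truth$delta[names(s)])          # recovery of planted offsets
#> [1] 0.9138123

assoc <- gene_vulnerability_correlation(sim$atlas, vuln)
hits  <- subset(assoc, !is.na(q) & q < 0.05)
nrow(hits); sum(hits$gene %in% sim$truth$planted)
#> [1] 40
#> [1] 39
head(assoc[order(assoc$p), c("gene", "r", "p", "q")], 3)
#>    gene         r            p            q
#>  g00056 0.7076348 3.290221e-07 0.0003290221
#>  g00932 0.6799053 1.398251e-06 0.0003473687
#>  g00766 0.6794619 1.429176e-06 0.0003473687
```

Of the 40 genes passing FDR, 39 are among the 50 planted at true
correlation 0.6 — one false positive, in line with the nominal 5% FDR.

A thin command-line wrapper is installed as `exec/netspread`
(subcommands `validate`, `simulate`, `fit`, `run`); `run_pipeline()`
executes every configured stage and writes a manifest with input/output
hashes so reruns can be verified byte-for-byte.

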