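---
title: "Predicting yield heterosis from parental metabolomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting yield heterosis from parental metabolomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Field evaluation of candidate rice hybrids is the bottleneck of heterosis
breeding: a cross must be made, grown and harvested before its yield
advantage over its parents is known. `metaheterosis` implements a
metabolome-based shortcut. Untargeted LC-MS profiles of *parental seedlings*
are combined per candidate cross into predictive variables, a partial least
squares (PLS) model links them to better-parent heterosis for yield per
plant (BPH-YPP) measured on a deliberately chosen training subset, and the
model then ranks the untested crosses.

The trait is
$$\mathrm{BPH\text{-}YPP} = \frac{F_1 - P_H}{P_H},$$
where $F_1$ is the hybrid's replicate-mean yield per plant and $P_H$ the
larger of the two parental replicate means. It is dimensionless, invariant
to a common rescaling of all yields, and symmetric in the parents.

## Normalization chain

Metabolite tables move through four explicit states, and every operation
checks the state of its input:

1. **raw** — relative abundances, one row per sample (replicates separate);
2. **replicate_averaged** — arithmetic mean per genotype;
3. **sum_normalized** — each row rescaled to a common total (default 1; only
   relative structure survives the next step, so the constant is arbitrary);
4. **autoscaled** — each analyte centered to mean 0 and scaled to unit
   sample ($n-1$) standard deviation. All-constant analytes are dropped with
   a warning rather than divided by zero.

This mirrors the standard untargeted-metabolomics recipe (normalization by
sum, no transformation, autoscaling). QC injections are excluded before
normalization of the analysis matrix via `filter_samples()`; roles are part
of the sample metadata precisely so that this is a filter, not a convention.

## Predictive variables

For a cross with female parent $P_1$ and male parent $P_2$, three per-analyte
combinations are supported: means $(P_1+P_2)/2$, differences $P_1-P_2$ and
ratios $P_1/P_2$. Ratios are only defined on positive abundances and are
therefore computed from the `sum_normalized` state; means and differences
default to the autoscaled matrix used for modeling. Measured profiles of
reciprocal hybrids correlate far better with parental means than with
differences or ratios (`compare_hybrid_to_transforms()`), which is why the
means are the predictive variables everywhere downstream. Reciprocal crosses
receive identical mean rows by construction.

## The PLS engine

`fit_pls()` is NIPALS PLS1 with X-deflation only (deflating a univariate y
is redundant). X and y are re-centered and scaled from the training rows
even if X is already autoscaled — harmless, and it makes subsetting rows or
columns safe. Per component $a$: $w_a \propto X_a^\top y$, $t_a = X_a w_a$,
$p_a = X_a^\top t_a / t_a^\top t_a$, $q_a = y^\top t_a / t_a^\top t_a$,
then $X_{a+1} = X_a - t_a p_a^\top$. The coefficient form
$b = W(P^\top W)^{-1} q$ is back-transformed to the input scale, so a frozen
model is just $(b, b_0)$ plus analyte ids — serializable to JSON and
applicable seasons later without refitting (`validate_holdout()`).

The inner NIPALS loop converges in one pass for a univariate response; the
iteration (tolerance $10^{-12}$, 500 iterations) is kept for generality.
Components are truncated with a warning when the residual covariance with y
is numerically exhausted, so requesting more factors than the rank supports
is safe.

**Latent-factor count.** Factors are added while the adjusted R-square of
cumulative Y variance,
$1 - (1 - R^2_a)\,(n-1)/(n-a-1)$, increases; the argmax over $a \le 17$ is
selected. The originating software environment for this class of analyses
does not print its adjusted-R² formula; we use the standard regression
definition and document it so third-decimal differences are traceable.

**VIP.** For a component subset $S$,
$$\mathrm{VIP}_j(S) = \sqrt{p \cdot \frac{\sum_{a\in S} SS_a\,(w_{ja}/\lVert w_a\rVert)^2}{\sum_{a\in S} SS_a}},
\qquad SS_a = q_a^2\, t_a^\top t_a .$$
Every single-component VIP vector satisfies $\sum_j \mathrm{VIP}_{ja}^2 = p$,
which the test suite asserts on every fitted model.

### Which "VIP over all latent factors"?

The phrase "mean VIP of all latent factors" admits two readings: the
unweighted arithmetic mean of per-component VIPs, or the multi-component
VIP above with $S$ = all factors (each factor weighted by the Y variance
$SS_a$ it explains). Both are implemented (`vip(mode = "mean")` vs the
default cumulative form), but the sweep default is the **weighted** form,
for a reason the synthetic generator makes vivid: when the heterosis signal
is concentrated in few latent directions, the informative analytes' variance
is captured — and deflated away — by the early components, so their weights
in the later, noise-chasing components are near zero. An unweighted average
over ~10 extracted factors then ranks exactly the informative analytes
*below* the background, inverting the selection; the weighted form is immune
because the noise components carry negligible $SS_a$. The arithmetic mean
remains available (`vip_mode = "mean_all"`) for comparison, alongside
`component1` and `mean_first_m`.

## Population structure and core hybrids

PCA (`run_pca()`, column-centered SVD) is computed per population on the
hybrids' predictive variables. SVD leaves component signs arbitrary, so each
loading vector is oriented to make its largest-magnitude entry positive;
without this, the PC1 ordering — and hence the core selection — could
silently reverse between platforms. Hybrids are ranked by PC1 score from
high to low (ties broken by id) and every $k$-th hybrid, starting at offset
0, becomes a core hybrid: $k=3$ on the first population and $k=2$ on the
second give the 1/3N + 1/2N mixed training set, whose complement forms the
per-population evaluation sets. The starting offset is not dictated by
anything in the procedure; 0 (begin at the top score) is the default and the
parameter is exposed and recorded.

Parent relatedness is summarized by Ward clustering (`hclust` method
`ward.D2`, i.e. proper Ward on unsquared Euclidean distances) with Newick
export through `ape`.

## The feature sweep and the full workflow

`feature_sweep()` ranks analytes once from the all-variable training model,
freezes the ranking, and refits at each count of the grid (default 100 to
$p$ in steps of 100), re-selecting the latent-factor count each time since
the optimum changes with dimension. The best count maximizes the mean
predictability across evaluation sets; per-set curves are returned so the
per-population behaviour (which can differ substantially) stays visible.
`redundancy_filter()` prunes, pair by pair, the higher-correlated/lower-VIP
members among the selected analytes (|r| > 0.9 by default) — selected
variables are heavily intercorrelated pathway members, and a few hundred can
usually go without hurting prediction.

`run_workflow()` chains everything — filtering, averaging, normalization,
predictive variables, BPH, per-population PCA, core selection, training,
sweep — and emits TSV result tables plus a JSON manifest. With a fixed
generator seed the entire output is byte-identical across runs, which the
acceptance tests check literally.

**Predictability** is the two-tailed Pearson correlation between observed
and predicted BPH-YPP on an evaluation set, with
$t = r\sqrt{(n-2)/(1-r^2)}$. When one number is needed for the whole
workflow we report it over the pooled noncore hybrids of both populations,
with per-population values alongside — the second, test-cross population is
intrinsically the fragile one (half of each of its predictive-variable rows
is the constant CMS-line profile) and its predictability varies
considerably between realizations.

## The synthetic generator

`generate_synthetic()` exists so that every stage is testable with known
ground truth and no external data. Its defaults are fixed study conditions,
not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| populations | 18-parent diallel (306 hybrids) + 107 testcrosses | field design shape |
| `p`, `s` | 2000, 200 | analytes, planted informative analytes |
| `d` | 10 | background latent dimension of parent metabolomes |
| `delta` | 1 | population divergence (SD units along a fixed direction) |
| `beta_sd`, `module_loading_sd` | 2, 0.3 | planted module loading scale and spread |
| `signal_r2` | 0.5 | BPH variance explained by the planted signal |
| `sigma_rep` | 0.3 | log-scale replicate (measurement) noise |
| `sigma_analyte` | 1 | per-analyte biological noise beyond the latent factors |
| `bph_mean`, `bph_signal_sd` | 0.1, 0.15 | location/spread of BPH-YPP (typical published rice values) |
| `base_ypp` | 50 g/plant | parental yield level |

Parent log-profiles follow a latent-factor model
($x_i = L u_i + \text{module} + \text{shift} + \varepsilon_i$), are
exponentiated into log-normal raw abundances with per-analyte baselines
spanning decades, and acquire multiplicative replicate noise — the gross
statistical shape of untargeted LC-MS data. Three deliberate design choices
deserve explanation:

* **The population shift is a direction, not a constant.** A uniform
  per-analyte offset for the second population would be annihilated exactly
  by sum normalization (it rescales row totals away). The divergence is
  therefore a fixed random direction per analyte, drawn on the non-planted
  analytes, so that population identity separates parents on PC1 without
  mimicking the heterosis signal.
* **The planted analytes form a correlated module.** Each planted analyte
  loads on a latent "heterosis program" factor, and the same loadings are
  the effect vector of the hybrid signal. This is both the realistic shape —
  heterosis-associated metabolites are coherent pathway members, and
  selected variables are intercorrelated enough that a redundancy filter
  can prune hundreds — and a mathematical necessity: with independent
  per-analyte effects, a 200-analyte signal spread over a training set whose
  rows share ~130 distinct parents puts every per-analyte correlation below
  the sampling noise floor, and *no* method could recover the planted set.
* **The truth is planted on the normalized scale.** The hybrid signal is
  linear in the planted analytes of the noise-free, sum-normalized,
  autoscaled parental means — exactly the quantity the modeling path sees —
  so with all noise at zero the pipeline must recover the signal essentially
  perfectly (the suite checks $r > 0.9$ held-out; at study scale the
  acceptance run achieves $r \approx 1$), and replicate noise degrades it
  realistically rather than by construction artifact.

Phenotypes are built so `compute_bph()` recovers the planted BPH-YPP
exactly: all parents yield `base_ypp` in every replicate and each hybrid
yields `base_ypp (1 + \mathrm{BPH})`; draws that would imply non-positive
yields are resampled with a warning, boundedly. What the generator does
*not* emulate: retention-time drift, batch effects, missing peaks,
heteroscedastic intensity-dependent noise, genotype-by-environment
interaction within a season. Passing tests therefore certify the
statistical machinery under a clean linear-module world, not performance on
any real study.

## Problem sizes in the test and acceptance runs

The suite exercises the full study scale (306 + 107 hybrids, 2,000
analytes) once and memoises it; structural tests run on a reduced study
(8 + 20 parents, 120 analytes), chosen to exercise every code path in
seconds. The signal-free null is evaluated over 50 seeds at a reduced size
(10 + 40 parents, 400 analytes, 80 evaluation hybrids per seed), where the
pipeline's evaluation predictability must stay centered at zero
(mean $|r| < 2/\sqrt{n_\mathrm{eval}}$). `scripts/acceptance.R` recomputes
the headline quantities — pooled and per-population held-out
predictability, planted-analyte recovery, selected factor count, sweep
optimum, null mean $|r|$, differential-analyte count and its overlap with
the PLS selection — from scratch at the study scale for any seed.

## Reproducing the original two-population study

`reproduce_published_stats()` runs the complete published analysis —
all-variable model, PLS-DA screening cutoffs, core-set predictions,
weighted-VIP sweep, differential counts, across-year validation — once the
original supplementary phenotype/metabolite tables are placed under
`inst/extdata/published/` (they are too large to ship; the raw spectra live
in MetaboLights study MTBLS742). The corresponding acceptance test states
the expected printed statistics and fails informatively when the tables are
absent.

## Known limitations

* PLS1 only: one response at a time; no multi-trait or PLS2 support.
* The adjusted-R² factor rule is greedy and, at $p \gg n$, tends to select
  around ten factors; cross-validated factor selection is not implemented.
* The permutation statistic for PLS-DA (between/within separation of
  component-1 scores) and the CV accuracy/Q² measures are documented
  choices; other software computes close but not identical variants.
* Ratio predictive variables are exposed for comparison but deliberately
  blocked on autoscaled input, where they are undefined.
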