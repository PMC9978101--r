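---
title: "Methods: degree centrality of resting-state brain networks across diagnostic groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: degree centrality of resting-state brain networks across diagnostic groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

dcnet implements a graph-theoretical analysis of resting-state fMRI used
to compare three diagnostic groups — healthy controls (HC), subclinical
depression (SD) and major depressive disorder (MDD) — through nodal
degree centrality (DC) of functional connectivity networks, and to
evaluate DC values as diagnostic indexes.

The pipeline starts from per-subject ROI time series (a T × g matrix on
a g-region parcellation, by default the 246-node Brainnetome scheme) and
the six rigid-body realignment parameters, and proceeds in four stages:

1. **Time-series preprocessing.** Discard the first 10 volumes;
   compute framewise displacement (FD); exclude subjects with less than
   3 minutes of scan surviving FD > 0.2 mm scrubbing, or with any
   translation > 2 mm or rotation > 2°; scrub flagged volumes; regress
   out the Friston-24 motion set plus a global (gray-matter stand-in)
   signal; bandpass 0.01–0.08 Hz.
2. **Network construction.** Pearson correlation between every pair of
   ROI series gives the g × g connectivity matrix; it is binarized at a
   sparsity threshold S by keeping the K = round(S·g(g−1)/2) strongest
   edges. The sweep S = 0.05–0.40 in steps of 0.01 (36 networks) supports
   threshold diagnostics; results are reported at S = 0.30. DC of node i
   is its number of edges, so every subject's DC row sums to 2K.
3. **Group inference.** Per node, an ANCOVA-style linear model
   `DC ~ group + age + sex + education + mean_fd` with the partial F
   test of the group factor, Bonferroni-corrected across the g nodes;
   pairwise post-hoc covariate-adjusted t tests (MDD–HC, SD–HC, MDD–SD)
   over the ANOVA-significant node set, again Bonferroni-corrected, with
   the adjusted direction of the difference recorded.
4. **Discrimination.** For each flagged region, ROC analysis of the DC
   index (AUC, DeLong 95% CI and p against AUC = 0.5, Youden-optimal
   cut-off with sensitivity/specificity in percent); all flagged regions
   of a comparison are also combined into a composite index by unpenalized
   maximum-likelihood logistic regression, z = a₀ + Σ aⱼXⱼ,
   P = 1/(1+e^(−z)), whose predicted probability is scored with the same
   ROC machinery.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_discard` | 10 | volumes | scanner equilibration / habituation |
| `fd_threshold` | 0.2 | mm | scrubbing cut-off (Power's FD) |
| `min_minutes` | 3 | min | minimum surviving scan time |
| `trans_limit_mm`, `rot_limit_deg` | 2, 2 | mm, ° | gross-motion exclusion |
| `low_hz`, `high_hz` | 0.01, 0.08 | Hz | resting-state BOLD band |
| sparsity sweep | 0.05–0.40 by 0.01 | – | 36 networks, integrity/small-world diagnostics |
| `report_sparsity` | 0.30 | – | reporting threshold |
| `alpha` | 0.05 | – | significance after Bonferroni |

FD at volume t is Σ|Δparamₚ| over the six parameters with rotational
differences converted to arc length on a 50 mm sphere (Power's
convention); the first volume has FD 0. The head-motion covariate
`mean_fd` is the mean FD over post-discard, pre-censor volumes, so it
reflects the subject's full motion burden rather than the already-cleaned
remainder.

## The synthetic cohort: a stated world

Clinical resting-state data for this design are not freely available, so
the package ships a generator whose output feeds every stage and whose
ground truth makes recovery testable.

* **Connectivity.** A base correlation matrix shared by all groups comes
  from a 10-factor model: one global factor with positive loadings
  (N(0.5, 0.15)) — giving the positive-dominant mean correlation (~0.1)
  typical of ROI-level FC — plus nine zero-mean factors (loadings
  N(0, 0.3)) and unit idiosyncratic noise, rescaled to a correlation
  matrix. Group effects add `delta_r` to the correlations between a hub
  node and its `partner_count` partners (partners are the nodes following
  the hub in index order, so the ground truth is deterministic).
* **Positive-definiteness repair.** After perturbation the matrix is
  projected to the *nearest correlation matrix* by Higham's alternating
  projections (PSD projection alternating with unit-diagonal restoration,
  with Dykstra correction). We first used the simpler eigenvalue-clip +
  re-standardize repair and found it inflates the hub's variance, which
  deflates all its remaining correlations: at g = 246 the planted hub's
  degree signature is *inverted* by the repair. Higham's projection
  modifies entries minimally and preserves the planted structure; this is
  the package's deliberate numerical choice.
* **Dynamics.** Each subject's series is a stationary AR(1) process with
  the group correlation as spatial covariance; the default autocorrelation
  0.3 matches typical BOLD at TR = 2.5 s. Innovations are scaled by
  √(1−φ²) so the marginal covariance equals the target; a 50-volume
  burn-in removes initialization transients.
* **Motion.** Realignment traces are random walks (translations: step SD
  `drift_scale` = 0.02 mm; rotations scaled 1/50 so their FD contribution
  matches) with Poisson-placed single-volume spikes (rate 0.01/volume,
  amplitude 0.5 mm), producing realistic FD distributions and occasional
  exclusions.
* **Phenotypes.** Age, education, sex proportions, BDI-II (HC/SD) and
  HAMD (MDD) are drawn per group from the demographics the generator
  emulates (a university-age cohort; default enrolled sizes
  HC/SD/MDD = 40/34/40). The generator makes no claim of clinical realism
  for the score distributions beyond group-dependent means.
* **Reproducibility.** Per-subject RNG streams are derived from the
  master seed by fixed (group, index) offsets, so a subject's data do not
  change when another group's size changes.

What the generator does **not** emulate: hemodynamic response shape,
physiological noise structure beyond AR(1), spatial autocorrelation of
motion artifacts with signal, scanner drift nonstationarity, and any
voxel-level phenomenon (the pipeline starts at ROI series by design). A
green recovery test therefore establishes that the pipeline recovers
effects *of the planted kind* — block increments to a hub's
correlations — not that it would detect every physiologically plausible
alteration.

## Numerical choices

* **Bandpass realization.** Zero-phase ideal rectangular filter in the
  Fourier domain (bins outside [0.01, 0.08] Hz zeroed, DC removed). This
  matches the convention of the standard rs-fMRI preprocessing
  toolchains, is exactly zero-phase, and avoids hand-rolled IIR design;
  filtering is applied to the concatenated retained frames after
  scrubbing, treated as contiguous — a documented simplification.
* **Edge budget and ties.** K = round(S·g(g−1)/2); boundary ties among
  equal correlations are broken by ascending (i, j) order. One fixed
  total order makes K exact, runs deterministic, and edge sets nested
  across the sweep. Edges are ranked by signed correlation (the positive
  end is retained), not absolute value.
* **Small-world nulls.** σ = (C/C_rand)/(L/L_rand) against 20
  Maslov–Sneppen degree-preserving rewirings (10·|E| swap attempts,
  seeded); C is the mean local clustering coefficient, L the mean
  shortest path on the largest component (disconnected thresholds report
  their component count rather than being forced connected).
* **Logistic fit.** IRLS on internally standardized columns (coefficients
  reported on the original scale), convergence at max |score| < 1e−8 or
  100 iterations; separation (any standardized coefficient beyond ~30, or
  divergence) raises an error rather than returning a silent non-MLE. The
  composite index is evaluated in-sample — no cross-validation — matching
  the convention of clinical ROC biomarker reports.
* **ROC.** Criterion "positive if value > c" with orientation
  auto-selected so AUC ≥ 0.5 (recorded and reported); ties contribute ½;
  CI and p from the DeLong variance of placement values; the Youden
  maximizer breaks ties by higher sensitivity, then lower cut-off.
* **Degenerate inputs.** Constant ROI series abort FC with the node
  named; constant DC columns yield F = 0, p = 1; constant covariates are
  dropped with a warning; a fully scrubbed subject is an upstream
  exclusion, not a silent empty matrix.

## A known limitation: mean-signal regression vs hub effects

The "gray-matter signal" nuisance regressor must be approximated at ROI
level by the mean over all g ROI series. This stand-in behaves like
global-signal regression, whose group-difference distortions are well
documented: a planted hub effect (a hub comoving more strongly with a
sizable partner set) loads on the mean signal, so regressing the mean
out removes part of the effect *and* lowers the hub's remaining
correlations by roughly `partner_count · delta_r_effective / g` each.
Under rank-based sparsity thresholding the partner-edge gain is then
largely offset by non-partner-edge loss, so the hub's *degree* shift
shrinks far more than its partner correlations do. The attenuation grows
as `partner_count/g` grows — it is most severe exactly in the scaled-down
test worlds (g = 60, 20 partners) used for fast verification — and it is
a property of the analysis design, not of any generator setting. The
package's parameter-recovery suite measures detection rates under this
stated world and reports them as they are; users planting effects for
power analyses should be aware that mean-signal regression makes
DC-based recovery conservative for effects coupled to the global mean.

## Open design points, decided

* Post-hoc Bonferroni families: ANOVA across all g nodes; post-hoc
  across the ANOVA-significant set per pair (post-hoc tests are run
  "based on the ANOVA results").
* Covariates enter the model (ANCOVA-style GLM) rather than
  residualize-then-test; the two differ only in degrees-of-freedom
  bookkeeping.
* Nuisance regression runs after scrubbing, on the retained frames; the
  Friston-24 lagged terms are built within the retained series.
* Negative correlations are eligible edge candidates but in practice are
  never selected at the default sweep (signed ranking retains the
  positive end first).
* The positive class of each ROC comparison is the first-named (more
  affected) group; the orientation actually used is logged in the result.
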