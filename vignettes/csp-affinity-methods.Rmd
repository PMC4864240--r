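---
title: "Models and methods behind cspAffinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cspAffinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspAffinity)
```

cspAffinity quantifies how insect chemosensory proteins (CSPs) bind
ligands, from two independent directions — a competitive fluorescence
assay and ensemble docking — plus a relative-expression stage for the
qPCR profiling that motivates which proteins and ligands to test. This
vignette explains each model, its assumptions, the tunable parameters,
and the design choices made where the methodology was genuinely open.

## Competitive fluorescence binding

### One-site saturation

The fluorescent reporter 1-NPN binds a single hydrophobic site; observed
intensity follows the one-site isotherm

$$ I(c) = \frac{B_{max}\,c}{K_{probe} + c}, $$

where $c$ is the probe concentration (µM), $K_{probe}$ the dissociation
constant of the probe–protein complex and $B_{max}$ the saturating
intensity. `fitSaturation()` offers two routes:

* **nonlinear** (default): Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`, positivity bounds, convergence tolerances
  `ftol = ptol = 1e-15` so noiseless data are recovered to machine
  precision), seeded by the Scatchard estimate;
* **scatchard**: the classical linearisation $I/c$ vs $I$, whose slope is
  $-1/K_{probe}$ — kept because saturation analyses are traditionally
  reported with Scatchard insets, and it provides an independent check on
  the nonlinear route (the two must agree within 1% on clean data).

A titration whose intensity does not vary, or whose Scatchard slope is
non-negative, cannot identify $K_{probe}$ and raises an error rather than
returning a boundary estimate.

The model assumes one binding site, no probe depletion, no inner-filter
or quencher corrections, and intensities already reduced from emission
spectra to one number per concentration. Multi-site binding and spectral
processing are out of scope.

### Displacement and the IC50 → Ki conversion

A competitor at concentration $L$ displaces the probe. For fitting and
simulation the package uses the competitive one-site displacement model

$$ \mathrm{percent}(L) = 100\,\frac{P + K}{P + K\,(1 + L/K_i)}, $$

with $P$ the probe concentration and $K = K_{probe}$. This form was
chosen because its half-displacement point is analytically
$L_{50} = K_i\,(1 + P/K)$, so the standard conversion

$$ K_i = \frac{IC_{50}}{1 + [\mathrm{1\text{-}NPN}]/K_{probe}} $$

inverts it *exactly*: the generator and the analysis are mutually
consistent by construction, which is what makes zero-noise round-trip
recovery a meaningful test.

`fitCompetition()` fits a four-parameter logistic in log-concentration
with:

* **top fixed at 100** by default. Percent fluorescence is defined as
  percent of the zero-competitor reading, so the upper plateau is 100 by
  construction. Fixing the plateau to the observed low-concentration
  points instead (`top = "data"`) is available for data normalized
  against an unreliable blank, but it biases the midpoint whenever the
  lowest measured concentration already displaces some probe (at
  IC50 ≈ 6.7 µM the curve is at ~77% by 2 µM), so it is not the default.
* **bottom bounded in [0, 50]** and **Hill slope initialised at 1**
  (bounded [0.1, 10]): displacement of a single site gives a Hill slope
  of 1, and bounding the lower plateau stabilises fits on the short 5–8
  point curves typical of these assays.
* the **undetermined rule**: a fitted IC50 above 100 µM (configurable via
  `undeterminedThreshold`), or a curve that never crosses 50%, is
  reported as status `"undetermined"` ("u.d." in tables) rather than as a
  number — weak binders beyond the measured range should not be
  quantified. A curve that never decreases at all is `"failed"`.
* a **fallback**: when the sigmoid does not converge but the observed
  points bracket 50%, log-linear interpolation between the bracketing
  points supplies the IC50 (ties at exactly 50% take the lower
  concentration). Whether the original assays were analysed by sigmoid
  fit or interpolation is not documented; both are exposed via
  `method =`, and on clean data they agree closely.

**Free vs total probe.** The conversion formula calls for the *free*
1-NPN concentration, which is never reported and cannot be recovered from
percent-normalized curves. The package uses the total reporter
concentration (2 µM). Back-calculation shows this leaves a 1–3% residual
against constants derived with the free concentration (implied free
values ~1.7–1.9 µM); the acceptance tolerance accounts for that residual,
and no attempt is made to guess the free concentration.

## Ensemble-docking consensus

Docking one ligand against $N$ homology models of the same receptor
(typically $N = 100$) emulates receptor flexibility. Each pose carries a
predicted binding free energy $\Delta G$ (kcal/mol) and ligand heavy-atom
coordinates in the shared receptor frame, so poses are compared by RMSD
**without superposition** — superposing ligand coordinates would erase
exactly the binding-site placement differences the clustering must see.

`clusterPoses()` uses greedy, energy-ordered leader clustering: poses are
visited by ascending energy (ties by model id, then pose index); each
unassigned pose seeds a cluster and absorbs every unassigned pose within
`rmsdCutoff` of it. This algorithm was chosen for determinism and
transparency at small $N$: it guarantees every pose is assigned once,
members lie within the cutoff of their seed, and seeds are pairwise
separated by more than the cutoff — properties the test suite verifies
against exhaustive pairwise distances. The default cutoff of **2.0 Å** is
the common docking-pose clustering convention; the original analysis does
not state one, so it is a parameter, not a constant.

The consensus mode is the **most populated cluster**, where population is
counted in *distinct receptor models*, because the downstream free/bound
bookkeeping counts models, not poses ("the amount of models among 100").
Counting raw poses is available via `countBy = "poses"`. Ties break to
the lower mean member energy, then the lower seed energy, making
selection invariant to input order.

Energy aggregation takes the **best pose per represented model** before
averaging — a model contributing five near-duplicate poses should not
count five times. The mean converts to a dissociation constant

$$ K_d = \exp(\Delta G / RT), \qquad R = 1.9872\times10^{-3}
   \ \mathrm{kcal\,mol^{-1}K^{-1}},\ T = 300\ \mathrm{K}, $$

computed in mol/L and reported in µM, then weighted by the model-count
ratio $free/bound$: a mode seen in 60 of 100 models with 40 free gets
$K_d^{w} = K_d \times 40/60$. When *every* model exhibits the mode
($free = 0$) the literal weight would give an unphysical zero, so the
weight is taken as 1 and the result flagged `degenerate`. The weighting
direction follows the stated free/bound fraction literally; a reading
normalised as $(free+bound)/bound$ would differ by a constant factor and
is not implemented.

Predicted $K_d$ values from the original docking study are not
reproducible without its Modeller model ensembles and docking engine; the
package validates the consensus arithmetic by construction instead —
planted-cluster recovery, closed-form $K_d$ checks, and the exactness of
the weighting identity.

## Relative expression (2^−ΔΔCt)

`ddCtFoldChange()` follows the Livak convention: replicate Ct values are
averaged per sample × gene before differencing,
$\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{ref}$,
$\Delta\Delta Ct = \Delta Ct_s - \Delta Ct_{cal}$, fold
$= 2^{-\Delta\Delta Ct}$. The calibrator's fold is exactly 1 by
construction. Replicate scatter propagates as
$s_{\Delta Ct} = \sqrt{s_{target}^2 + s_{ref}^2}$ and maps through the
exponential to the asymmetric range
$[2^{-(\Delta\Delta Ct + s)}, 2^{-(\Delta\Delta Ct - s)}]$; the reported
`sd` is the half-width of that range. Technical and biological replicates
are treated as exchangeable — how the original ±sd (n = 9) combined the
two levels is not documented. Per-replicate pairing, primer-efficiency
correction and significance grouping are out of scope;
`summarizeReplicates()` (per-group mean/sd/n) is the hand-off point for
standard ANOVA tooling.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* `simulateSaturation()`: 15 points, 2–30 µM (the titration protocol
  range), multiplicative Gaussian noise (default 2% — relative error is
  how fluorescence intensity misbehaves), $K_{probe}$ defaults to the
  CSP1 constant 11.66 µM.
* `simulateCompetition()`: 8 log-spaced points over 2–50 µM (the
  competitor range; widen `concRange` to bracket a large IC50), same
  multiplicative noise model, generated from the displacement model
  above so round trips are exact at zero noise.
* `simulatePoseEnsemble()`: 100 models, planted occupancy 0.6, planted
  energies $N(-6.8635, 0.25)$ kcal/mol (mean chosen so the closed-form
  $K_d$ is exactly 10 µM, a mid-range docking affinity), decoys displaced
  ≥ 3× the cluster cutoff with energies 2 kcal/mol weaker. The 3× spacing
  makes planted-cluster recovery well-defined at small $N$; planted
  jitter ≤ cutoff/2 guarantees (by the triangle inequality) that the
  planted poses form a single cluster. The generator records which models
  received the planted pose so recovery can be scored.
* `simulateCtTable()`: additive cycle noise (default sd 0.2 cycles,
  instrument-typical) on the target-gene draws, reference gene at its
  baseline; since ΔCt depends only on the difference of gene means,
  reference scatter is absorbed into the same noise term. Default
  contrast control = 1 vs treated = 10, the induction scale seen for
  insecticide-responsive CSP transcripts.

Every generator takes a `seed` and is a bit-exact function of its
arguments, restoring the caller's RNG state.

What passing these tests shows: the estimators are consistent with their
own generating models at realistic noise, the clustering and conversions
are arithmetically correct, and the pipeline is deterministic. What they
do not show: robustness to inner-filter effects, probe depletion,
multi-site binding, docking-score inaccuracy, model-ensemble bias, or
primer-efficiency drift — none of which the generators emulate.

## Numerical choices and problem sizes

* LM fits: `ftol = ptol = 1e-15`, ≤ 500 iterations, positivity bounds;
  failures fall through to interpolation (competition) or an error
  (saturation) rather than returning boundary estimates.
* Interpolation is log-linear in concentration; a bracketing point at
  exactly 50% short-circuits to the lower concentration.
* RMSD uses a vectorised flattened-coordinate norm; the test oracle
  recomputes it independently via `stats::dist`.
* Validation sizes used by the test suite: 100-seed repetitions for
  noisy-recovery medians (saturation, competition, ΔΔCt), 200 seeded
  ensembles of 100 models for planted-cluster recovery, and 100 random
  ensembles of ≤ 12 poses for the clustering oracle — sizes chosen to
  make medians and the ≥ 95% recovery criterion stable across seeds
  while keeping the suite fast.

## Known limitations

* Ki values computed from the total (not free) reporter concentration
  carry the 1–3% bias discussed above.
* Leader clustering is order-dependent by design (energy order is the
  specification); a different tie order could split borderline clusters
  differently. All ties are fully specified, so results are reproducible.
* The free = 0 weighting convention (weight 1 + flag) is a boundary
  patch, not thermodynamics.
* `summarizeReplicates()` treats folds as exchangeable draws; it does not
  model the technical/biological replicate hierarchy.
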