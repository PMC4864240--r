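# cspAffinity

Quantitative analysis of ligand binding and gene expression for insect
chemosensory proteins (CSPs) — small soluble proteins that bind hydrophobic
ligands and are implicated in chemosensation and xenobiotic defense in
insects such as the whitefly *Bemisia tabaci*. The package implements the
three quantitative stages used to characterize a CSP functionally, each
testable end-to-end against seeded synthetic data:

1. **Competitive fluorescence binding.** The probe 1-NPN
   (N-phenyl-1-naphthylamine) fluoresces when bound; titrating protein with
   probe gives the probe dissociation constant K<sub>probe</sub> from the
   one-site model *I = B<sub>max</sub>·c/(K<sub>probe</sub> + c)*, fitted by
   nonlinear least squares or Scatchard linearisation. A competitor ligand
   displaces the probe; the displacement curve (percent fluorescence vs
   competitor concentration) is fitted with a four-parameter logistic to
   locate the IC50, which converts to the inhibition constant

   K<sub>i</sub> = IC50 / (1 + [1-NPN]/K<sub>probe</sub>)

   with an "undetermined" (u.d.) rule for weak binders whose IC50 exceeds
   100 µM.

2. **Ensemble-docking consensus.** Docking one ligand against an ensemble
   of N homology models yields poses (binding energy ΔG + ligand
   coordinates in a shared receptor frame). Poses are clustered by
   coordinate RMSD (greedy, energy-ordered leader clustering, no
   superposition); the most populated cluster — counted in distinct
   receptor models — is the consensus binding mode. Its mean per-model
   best energy converts to K<sub>d</sub> = exp(ΔG/RT) at T = 300 K
   (R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹), then is weighted by the *free/bound*
   model ratio to penalize modes not supported across the ensemble.

3. **Relative expression.** qPCR Ct tables are reduced to fold changes by
   the 2<sup>−ΔΔCt</sup> method (target normalized to a housekeeping gene
   and a calibrator sample), with replicate sd propagated through the
   exponential.

Seeded generators (`simulateSaturation`, `simulateCompetition`,
`simulatePoseEnsemble`, `simulateCtTable`) emulate each assay with known
ground truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(cspAffinity)

## probe titration -> probe dissociation constant
sat <- simulateSaturation(kProbe = 11.66, noiseSd = 0.02, seed = 42)
fit <- fitSaturation(sat)
fit
#> SaturationFit (nonlinear) for CSP1: K_probe = 11.393 uM, Bmax = 100 AU, R2 = 0.9950

## displacement curve -> IC50 -> Ki
cs <- simulateCompetition(ki = 5.78, kProbe = 11.66, probeConc = 2,
                          noiseSd = 0.02, proteinId = "CSP1",
                          ligandId = "linoleic acid", seed = 42)
computeAffinity(cs, fitCompetition(cs), kProbe = kProbe(fit))
#> AffinityResult: linoleic acid vs CSP1 - IC50 = 6.702 uM, Ki = 5.701 uM

## ensemble docking consensus
pe <- simulatePoseEnsemble(nModels = 100, occupancy = 0.6,
                           energyMean = -6.8635, energySd = 0.25, seed = 42)
consensusPipeline(pe)
#> ConsensusAffinity: ligand vs CSP1
#>   mean dG = -6.798 +/- 0.247 kcal/mol
#>   Kd = 11.17 uM; bound/free = 60/40; weighted Kd = 7.446 uM

## expression fold changes
ct <- simulateCtTable(foldChanges = c(control = 1, thiamethoxam = 12),
                      noiseSd = 0.2, seed = 42)
ddCtFoldChange(ct, "CSP1", "actin", "control")[, c("sample_id", "fold_change")]
#>      sample_id fold_change
#> 1      control     1.00000
#> 2 thiamethoxam    12.13292
```

The titration recovers the generating K<sub>probe</sub> (11.39 vs 11.66 µM
at 2% noise); the displacement fit locates the IC50 at 6.70 µM and converts
it to K<sub>i</sub> = 5.70 µM, within noise of the generating 5.78 µM. The
consensus pipeline finds the planted 60-model binding mode, converts its
mean energy to a ~11 µM K<sub>d</sub>, and down-weights it by the 40/60
free/bound ratio. The expression stage recovers the simulated 12-fold
induction.

A thin subcommand CLI over the same functions is installed at
`inst/scripts/cspaffinity.R` (`fit-saturation`, `fit-competition`, `ki`,
`consensus`, `ddct`, `simulate`, `run`); `runPipeline()` drives all stages
from a YAML configuration and writes tabular + JSON outputs plus a replay
log.

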