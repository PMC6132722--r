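# flowKE

Ventricular blood kinetic energy from 4D-flow cardiac MRI.

4D-flow MRI measures the three-component blood velocity in every voxel of
the heart over the cardiac cycle. The kinetic energy of the
intraventricular blood,

    KE = Σ_voxels ½ · ρ · V_voxel · |v|²,    ρ = 1.05 g/cm³,

summed per ventricle and time phase, characterizes ventricular function:
its systolic and diastolic peaks, their ratio (S/D), and the indexations to
stroke volume, cardiac output, body surface area and flow. In patients with
pulmonary regurgitation (PR) — typically after repaired tetralogy of Fallot
— diastolic right-ventricular KE mixes tricuspid inflow with the
regurgitant jet; flowKE separates the two with Lagrangian coherent
structures (backward-time FTLE fields computed at the diastolic KE peak)
and quantifies the fraction of RV KE carried by the regurgitant jet.

The package is aimed at cardiovascular imaging researchers who have
velocity volumes, ventricular segmentations and great-vessel flow curves
and want a tested, scriptable pipeline from raw phase-contrast volumes to
cohort-level statistics. It provides:

* **I/O** — NIfTI-1 velocity/mask volumes with a JSON metadata sidecar
  (VENC, timing, units), flow-curve and result CSVs, cine-to-4D
  segmentation transfer (`readVelocity()`, `transferSegmentation()`, ...);
* **preprocessing** — first-order background phase correction and
  VENC anti-aliasing (`fitBackground()`, `unwrapVelocity()`);
* **volumetry** — planimetric EDV/ESV/SV/EF and flow-derived regurgitant
  volume and fraction (`computeVolumeCurve()`, `computeRegurgitation()`);
* **kinetic energy** — voxel KE, per-ventricle curves with peak detection,
  S/D ratio, five indexation schemes, heart-rate-independent cohort curves
  (`voxelKE()`, `keCurve()`, `indexKE()`, `normalizeTime()`);
* **LCS separation** — RK4 particle advection, FTLE fields, and the
  PR/non-PR partition of the right ventricle (`advect()`, `ftle()`,
  `partitionRV()`);
* **physiology & statistics** — restrictive-RV classification from the
  pulmonary flow curve, Cohen's kappa, Student/paired t tests, Spearman
  correlation with exact small-sample p (`classifyRestrictive()`,
  `cohensKappa()`, `compareGroups()`, `spearmanCorr()`);
* **synthetic data** — analytic two-ventricle phantoms and cohorts with
  closed-form ground truth, plus the classical double-gyre benchmark flow
  (`phantomSpec()`, `generateVentriclePhantom()`, `generateCohort()`,
  `generateDoubleGyre()`), so the entire pipeline is testable without
  patient data.

See the vignette `vignettes/ventricular-kinetic-energy.Rmd` for the models,
parameter defaults and numerical choices.

## Worked example

A patient-like phantom with a 36% regurgitant fraction, analyzed end to
end (preprocessing is skipped here because the phantom has no injected
phase artifacts):

```r
library(flowKE)

spec <- phantomSpec(dims = c(28, 28, 22), spacing = 3, nPhases = 20, rr = 800,
                    lvEdv = 28, rvEdv = 34, regurgFraction = 0.36,
                    noiseSd = 1.5, seed = 42)
bundle <- generateVentriclePhantom(spec)
result <- analyzeBundle(bundle, lcs = TRUE)
print(result)
```

```
Subject phantom (phantom):
  LV peak KE 0.50 mJ (systole) / 0.20 mJ (diastole), S/D 2.54
  RV peak KE 0.30 mJ (systole) / 0.77 mJ (diastole), S/D 0.39
  PR 6.7 ml (36%), restrictive: FALSE
RV partition: KE(PR) 0.587 mJ, KE(non-PR) 0.186 mJ (75.9% in PR)
```

Reading the numbers: this small phantom heart ejects normally on the left
(LV systolic peak 0.50 mJ, S/D ratio above 1), while the regurgitant right
ventricle shows the characteristic inversion — its diastolic peak KE
(0.77 mJ) exceeds the systolic peak (0.30 mJ), so S/D = 0.39. The
regurgitant volume integrates to 6.7 ml (36% of forward flow, matching the
requested fraction), the pulmonary flow curve shows no end-diastolic
forward flow (not restrictive), and the Lagrangian partition attributes
75.9% of the diastolic-peak RV KE to blood that entered through the
pulmonary valve — exactly the generator's ground truth for this phantom.

`generateCohort()` + `analyzeCohort()` + `cohortStats()` run the same
analysis over a seeded patient/control cohort and return the group
comparisons, S/D dichotomy and kappa agreement; `writeResults()` exports
the tidy result table.

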