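---
title: "Ventricular kinetic energy from 4D-flow MRI: models, phantoms and numerical choices"
author: "flowKE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricular kinetic energy from 4D-flow MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowKE)
```

## The problem

Time-resolved three-directional phase-contrast MRI (4D-flow) measures the
full blood velocity vector in every voxel of the heart across the cardiac
cycle. The kinetic energy of the intraventricular blood,

$$\mathrm{KE} = \sum_{\text{voxels}} \tfrac12\, \rho\, V_{\mathrm{voxel}}\,
  |\mathbf v|^2,$$

with $\rho = 1.05$ g/cm³ the density of blood and $\mathbf v$ the
three-component voxel velocity, is the work needed to accelerate that blood
from rest to its instantaneous velocity. Summed over a ventricle per time
phase it yields a KE-versus-time curve whose systolic and diastolic peaks,
and their ratio, characterize ventricular function. In patients with
pulmonary regurgitation (PR) after repaired tetralogy of Fallot, the
diastolic right-ventricular (RV) KE mixes two inflows — tricuspid filling
and the regurgitant jet — which this package separates with Lagrangian
coherent structures (LCS).

flowKE implements the full chain: phase-contrast preprocessing, planimetric
volumetry, voxel KE with peak detection and five indexation schemes, the
LCS partition, restrictive-physiology classification and cohort statistics.
Because no patient data are redistributable, every stage is validated
against analytic phantoms with closed-form ground truth.

## Units and conventions

One set of conventions is used everywhere and asserted at I/O: velocities
in cm/s, voxel spacing in mm, time in ms from the R-wave over one RR
interval, flow in ml/s with antegrade flow positive, volumes in ml, KE in
mJ. Voxel indices are 0-based with world position
$\mathbf x = \mathbf o + \text{index} \times \text{spacing}$. With these
units one 3×3×3 mm voxel moving at 100 cm/s carries
$\tfrac12 \cdot 1050\ \mathrm{kg/m^3} \cdot 2.7\times10^{-8}\ \mathrm{m^3}
\cdot (1\ \mathrm{m/s})^2 = 1.4175\times10^{-5}$ J = 0.0142 mJ.

## Phase-contrast preprocessing

Two corrections precede any KE computation.

**Background phase (eddy currents).** Residual background phase appears as
a slowly varying velocity offset on static tissue. We model it as
first-order — linear in the three spatial voxel coordinates and constant in
time — and fit it per velocity component by least squares to the
time-averaged velocity of static-tissue voxels (`fitBackground()`,
`applyBackground()`). The static mask is supplied explicitly or derived as
voxels with per-component temporal SD below 2 cm/s and mean speed below
10 cm/s (`staticTissueMask()`). Fitting on the time-average (rather than
per phase) is a deliberate interpretation: it is the minimal model
consistent with "first-order", and it makes the fit exactly identifiable
from four non-coplanar voxels. On noiseless phantoms an injected plane is
recovered to machine precision; under Gaussian noise the coefficient
standard error shrinks as $1/\sqrt{n}$ with the static-voxel count.

**Velocity anti-aliasing (unwrapping).** Velocities beyond the encoding
limit VENC wrap by multiples of $2\,\mathrm{VENC}$ into
$(-\mathrm{VENC}, +\mathrm{VENC}]$. `unwrapVelocity()` restores them with a
temporal-spatial consistency scheme: a voxel whose speed drops below
VENC/2 at some phase is *trusted* there (aliasing is impossible at low
speed), and its cycle is walked phase-by-phase from that most-trusted
phase, at each step choosing the wrap count $k \in [-k_{max}, k_{max}]$
(default $k_{max}=2$) that best matches the previous phase. This exploits
that a voxel's own velocity history is smooth even across sharp jet
boundaries where *spatial* neighbours jump by more than VENC — the case
that defeats purely spatial region growing. Voxels that are never slow are
then resolved per phase by spatial region growing against the median of
already-unwrapped 6-neighbours; whatever no consensus can reach is left
unmodified and counted in a QC attribute. The scheme is exact whenever
phase-to-phase increments stay below VENC, which holds for pulsatile jets
sampled at 20–40 phases; wrap-then-unwrap is an identity on phantom jets at
1.8×VENC. Order of operations on real data: unwrap first, then fit the
background plane — aliased static voxels would corrupt the fit.

## Volumes, KE curves and indexation

Planimetric volumes are voxel counts times voxel volume per phase
(`computeVolumeCurve()`). EDV and ESV are the curve maximum and minimum —
not pinned to specific trigger phases, for robustness to trigger jitter —
and the end-systolic phase (argmin, earliest on ties) defines the
systole/diastole boundary used for peak detection: the systolic peak is the
KE maximum in phases [start, ES], the diastolic peak in (ES, end]. Peaks
are detected on raw phase samples; linear time-interpolation
(`normalizeTime()`, default 40 points) is used only to average curves
across subjects with different heart rates for display.

Five indexation schemes are computed per ventricle and phase type
(`indexKE()`): absolute peak KE (mJ); KE per planimetric stroke volume
(EDV−ESV); KE per systemic cardiac output (aortic net volume × heart
rate); KE per body surface area; and the inverted flow indexations Q/KE
and Q/KE/BSA, where Q is the relevant vessel's net forward volume (aortic
for the LV, pulmonary for the RV). Because it is ambiguous whether the
diastolic PR-excluded comparison should index to planimetric or net SV,
both columns are reported (`kePerSv`, `kePerNetSv`) with explicit names.
Non-positive denominators yield `NA`, never zero.

Regurgitation is quantified from the pulmonary flow curve by trapezoidal
integration (`computeRegurgitation()`): forward volume $\int \max(Q,0)dt$,
regurgitant volume $\int \max(-Q,0)dt$, fraction their ratio ×100.

## Lagrangian separation of the regurgitant jet

At the RV diastolic KE peak, the package partitions RV blood into the
territory that entered through the pulmonary valve versus the rest.
Machinery:

* `advect()` — classical RK4 particle integration; the velocity is sampled
  trilinearly in space, linearly in time, cyclically over the RR interval.
  Default step: one fifth of the phase spacing, giving ample fourth-order
  headroom (self-convergence order ≈ 3.9 on the double gyre). Particles
  leaving the blood-pool mask are frozen and flagged. An analytic velocity
  `function(t, pos)` can be advected through the same stepper, which is how
  the double-gyre oracle tests and the Galilean-invariance property (a
  proper frame boost $v'(x,t) = v(x-ut,t)+u$, under which RK4 commutes
  exactly with the boost) are run.
* `ftle()` — Cauchy–Green strain of the flow-map gradient (central
  differences, one-sided at borders and next to excluded seeds), largest
  eigenvalue by the closed-form symmetric solver,
  $\mathrm{FTLE} = \ln\sqrt{\lambda_{max}}/|T|$. Planar seed grids use the
  in-plane 2×2 tensor.
* `partitionRV()` — the separation itself.

The partition is computed backward in time from the diastolic-peak phase
over a horizon reaching back to end-systole: attracting structures at the
peak are shaped by the preceding inflow. Although a single short-axis LCS
plane suffices for visualization, the KE fraction in the PR jet is a
volumetric quantity, so FTLE is computed on the full 3D voxel seed grid.
Three mechanisms combine:

1. **Orifice-mouth attribution.** A seed whose backward trajectory actually
   travels (stationary seeds frozen by mask motion are ignored) and ends
   laterally within an orifice disc, at or above the valve plane, is
   attributed to that inflow. This is the primary evidence: it encodes
   backward travel time to the orifice by construction, and it resolves
   contested territory between the pulmonary and tricuspid jets. Lateral
   (in-plane) distance to the valve axis is used because it is insensitive
   to along-axis overshoot or stalling at the mouth.
2. **Ridge-restricted growth.** The FTLE ridge set — values above a
   configurable percentile within the RV (default 80th) — acts as a
   transport barrier; the attributed sets grow simultaneously through
   sub-ridge voxels (6-connectivity, layered BFS, contested voxels to the
   PR side deterministically). Percentile thresholding plus connected
   growth is a deliberate approximation to formal ridge-surface extraction,
   appropriate at 3 mm resolution. This stage is monotone: lowering the
   percentile (more ridge voxels) never grows the PR region.
3. **Mop-up.** Remaining voxels — ridge shells and unreached pockets,
   typically carrying near-zero KE — join the nearest grown region (off
   by `mopUp = FALSE`; the mop-up is not guaranteed monotone in the
   percentile, which is why the monotonicity property is asserted on the
   growth stage).

KE bookkeeping is exactly conservative by construction:
$\mathrm{KE}_{PR} + \mathrm{KE}_{non\text{-}PR} = \mathrm{KE}_{RV}$, and
with no regurgitation the PR region is empty rather than an error. On
two-jet phantoms at the default noise level the partition captures ≥ 99%
of the true regurgitant-jet KE with < 1% contamination, and reproduces a
tuned two-thirds PR-KE fraction within a fraction of a percentage point.

## Restrictive physiology and statistics

Restrictive RV physiology is defined by end-diastolic forward flow in the
pulmonary artery. The published definition carries no operational
threshold, so `classifyRestrictive()` fixes one honestly: the mean flow
over the final 15% of the cycle must exceed
$\max(1\ \mathrm{ml/s},\ 2\,\mathrm{SD})$ of the flow over a quiescent
reference window (default fractions 0.70–0.85 of the cycle). Both window
fractions and the floor are exposed as arguments and recorded in the
result; the decision depends only on the end-diastolic segment.

`cohensKappa()` implements $\kappa = (p_o - p_e)/(1 - p_e)$ for the 2×2
agreement between the S/D-ratio dichotomy (ratio > 1 versus ≤ 1 — the
boundary is fixed, not configurable, because borderline cases sit exactly
there) and restrictive status. `compareGroups()` wraps the classical
pooled-variance Student t test and the paired t test; a constant paired
shift is reported exactly with a degenerate flag. `spearmanCorr()` uses
mid-ranks; for n ≤ 8 without ties the two-sided p comes from exhaustive
permutation enumeration (n! ≤ 40 320 orders — full enumeration beyond
n = 8 is combinatorially pointless when the t approximation is already
adequate), otherwise from the t approximation, with ties flagged. No
multiple-testing correction is applied, matching common practice in small
physiological cohorts; this is a documented limitation.

## What the phantoms emulate — and what they do not

`generateVentriclePhantom()` builds an analytic two-ventricle phantom:

* two axis-aligned ellipsoidal blood pools whose semi-axes breathe with a
  raised-cosine contraction envelope (end-systole at 35% of the cycle by
  default), voxelized per phase into the segmentation;
* top-hat cylindrical valve jets (aortic, mitral, pulmonary, tricuspid,
  plus the regurgitant jet sharing the pulmonary orifice) with
  raised-cosine temporal speed envelopes. Jet voxel sets are clipped to the
  end-systolic pool and held phase-constant, which keeps each voxel's
  velocity history temporally smooth (required by the unwrapping
  round-trip) and the total KE a closed form,
  $\mathrm{KE}(t) = \tfrac12 \rho V_{vox} \sum_j N_j v_j(t)^2$;
* analytic flow curves: outflows are the exact time derivatives of the
  volume envelopes (so aortic forward volume equals LV stroke volume by
  construction) and the regurgitant volume is an exact fraction of the
  ejected RV stroke volume;
* a restrictive variant encoding both the defining sign (a late-diastolic
  forward pulmonary bump) and the hypothesized mechanism (diastolic jet
  speeds scaled down — default factor 0.6 — at equal regurgitant volume,
  with an early-concentrated regurgitant envelope), so the classifier and
  the KE-difference property are testable independently;
* optional first-order background planes, aliasing above VENC
  (`injectPhaseArtifacts()`, default VENC 100 cm/s) and isotropic Gaussian
  velocity noise (default SD 1.5 cm/s per component, a realistic
  phase-noise magnitude at VENC 100).

`generateCohort()` draws a patient group (regurgitant fraction from a
truncated normal, mean 0.36, SD 0.13, support above the 0.20 inclusion
threshold; restrictive physiology assigned by a deterministic 10-of-15
quota) and a control group (no PR), with group-distinct heart rates,
BSA and jet-speed distributions and a per-subject log-normal speed jitter.

Deliberate non-goals: no MR physics (k-space, eddy-current fields beyond a
first-order plane, partial volume), no turbulence or intravoxel velocity
dispersion, no surgical RVOT anatomy — the outflow geometry is a single
orifice-radius parameter. Phantom ventricular volumes in the cohort are
scaled to roughly a quarter of adult size so that whole cohorts fit
32×32×26-voxel grids; consequently absolute KE values are on the order of
1 mJ rather than the several mJ of adult ventricles, and cohort-level
checks are directional (orderings, significance, agreement), not
reproductions of printed magnitudes. Passing tests therefore demonstrate
correctness of the computational chain on data whose structure — jets,
regurgitation, restrictive filling, phase artifacts — mimics the real
setting, not agreement with any particular patient cohort.

## Numerical choices and degenerate inputs

* Problem sizes: test phantoms use 28×28×22 voxels × 20 phases; cohorts
  32×32×26 × 24 phases; double-gyre validation uses a 128×64 velocity
  grid, 64×32 seeds, and a 4×-resolution brute-force oracle. These sizes
  were chosen once as the smallest that keep every geometric feature
  (jet cross-sections of several voxels, ridge separation) resolved.
* Trapezoidal quadrature for all flow integrals (second-order; a 36%
  regurgitant fraction integrates back to 35.97% at 20 phases).
* Peak ties break to the earliest phase; the ES phase ties likewise.
* `advect()` rejects `dt >= |horizon|`; `ftle()` requires ≥ 3 seeds along
  every non-degenerate axis (a single-seed axis denotes a planar grid).
* Degenerate statistics are flagged, not silently zeroed: empty flow
  curves give undefined regurgitant fractions, zero diastolic peaks give
  `NA` S/D ratios, degenerate kappa marginals give `NA`.
* Readers reject NaN/Inf voxels and non-monotone timing by name of the
  offending file; the JSON sidecar, not NIfTI headers, is authoritative
  for VENC and timing. Nearest-neighbour label resampling is used for
  segmentation transfer (labels are categorical), with temporal matching
  in fraction-of-RR units because cine and 4D acquisitions have different
  temporal resolutions.

## Known limitations

The LCS partition assumes valve discs normal to the long (z) axis at the
basal pole, as in the phantoms; oblique valve planes would need an axis
parameter. The restrictive-physiology threshold is an implementation
choice, recorded in the output but not validated against clinical
adjudication. The backward-FTLE horizon (ES to diastolic peak) and the
80th-percentile ridge are defaults exposed as configuration, not claims
about the only reasonable values.
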