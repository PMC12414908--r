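---
title: "Methods: voxel-level dose painting, conformity scoring, and TCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-level dose painting, conformity scoring, and TCP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic phantom does and
does not emulate, and the numerical and design choices that were genuinely
open. Every number quoted here is computed by the test suite or by
`scripts/acceptance.R`; nothing below is an empirical claim beyond what the
shipped code reproduces.

## The pipeline

The analysis chain mirrors a dose-painting planning study:

1. a **cellularity map** (clonogenic cells per voxel) on the gross tumour
   volume (GTV) — here synthetic, in a clinical study derived from
   diffusion-weighted MRI cell-density estimates times the voxel volume;
2. a **per-voxel prescription** over the clinical target volume (CTV):
   linear in cell count inside the GTV, a fixed floor in the CTV∖GTV
   safety margin, and its complementary **inverse map** for import into a
   planning system;
3. one or more **delivered dose distributions** — here generated by a
   perturbation model, in a study exported from the planning system;
4. **plan scoring**: quality factor with per-voxel maps, DVH metrics,
   generalized EUD, clinical-goal tables;
5. **radiobiology**: Poissonian linear-quadratic tumour control
   probability (TCP) over the GTV;
6. **cohort statistics**: paired Wilcoxon signed-rank tests with
   Holm–Šidák correction between the dose-painting and uniform arms.

## Models and parameters

### Prescription (linear dose painting by numbers)

Inside the GTV, with $\rho_i$ the cells in voxel $i$ and
$\rho_{\min},\rho_{\max}$ the GTV extremes *of that patient on the grid
where the map is evaluated*:

$$D_i \;=\; (D_{\max}-D_{\min})\,
  \frac{\rho_i-\rho_{\min}}{\rho_{\max}-\rho_{\min}} + D_{\min},$$

so the least-cellular voxel receives exactly $D_{\min}$ and the most
cellular exactly $D_{\max}$. Defaults are the skull-base chordoma protocol:
$D_{\min} = 74$ Gy(RBE) (standard of care), $D_{\max} = 81$ Gy(RBE), 37
fractions. The escalated cap is nominally 110% of standard of care; the
printed protocol value 81 (not the literal $74 \times 1.10 = 81.4$) is the
default, and the parameter is exposed. The margin rule "at least
$D_{\min}$" is implemented as *exactly* $D_{\min}$: the floor is the only
constraint the prescription itself states; exceeding it is a property of a
delivered plan, not of the prescription. Only the normalized position of
$\rho$ between its extremes matters, so the prescription is invariant to
any positive rescaling of the cellularity map (units cancel).

Two degenerate situations are defined explicitly rather than left to
floating-point chance. A flat cellularity field makes the linear map 0/0;
the whole GTV then receives $D_{\min}$ (the safest clinical reading) with a
warning. Cellularity values outside $[\rho_{\min},\rho_{\max}]$ — possible
after interpolating a resampled map — are clamped before the mapping so the
prescription stays inside $[D_{\min},D_{\max}]$ by construction.

### Conformity

$$QF = 100 - \frac{100}{n}\sum_{i\in ROI}
  \frac{|D^{plan}_i - D^{presc}_i|}{D^{presc}_i} \quad [\%]$$

The per-voxel map stores $100 - 100\,|\Delta_i|/D^{presc}_i$ on the ROI
(fill 0 outside, the ROI mask acting as validity mask), and the scalar QF
is exactly the ROI mean of that map. Voxels with a prescription but no
plan dose are an error, never silently skipped — silent truncation would
inflate QF. GTV conformity of a dose-painting plan is scored against the
heterogeneous map restricted to the GTV; the uniform arm is scored against
its own flat 74 Gy(RBE) map.

### Dose metrics, EUD, goals

$D_{x\%}$ is the nearest-rank quantile: the smallest dose received by at
least $x\%$ of the ROI volume, computed from the empirical distribution
without interpolation. This makes every value an actual voxel dose and the
metric checkable against a sort-and-count oracle; DVH interpolation
conventions differ between systems and none is canonical. The generalized
EUD is the power mean $(\tfrac1n\sum D_i^a)^{1/a}$, evaluated in log space
so organ parameters as large as $a = 200$ do not overflow ($a=1$ is the
mean dose; large $a$ approaches the maximum). Clinical goals use inclusive
thresholds (achieved = threshold passes), reading "max dose of X" as
$\le X$; target coverage objectives ("min DVH $D$ to $V\%$") are evaluated
as $D_{V\%} \ge D$. The default goal set is the chordoma protocol table
(brainstem max dose 61; chiasm max DVH 54 to 1%; optic nerves 50 to 1%;
cochleae max EUD 45 at $a=1$; carotids 75.5 to 1%; temporal lobes 71 to
1.7%; CTV max dose 83 for painting arms, 76 for uniform). The "robust"
flag is carried as metadata only — scenario-based robust evaluation is out
of scope.

### Tumour control probability

$$TCP = \prod_{i=1}^{Z} \exp\!\big(-N_{0,i}\,
  e^{-\alpha D_i - \beta D_i^2/n}\big)$$

with $\alpha = 0.1\ \mathrm{Gy}^{-1}$ and $\alpha/\beta = 2.4$ Gy
(chordoma cell-line values) and $n = 37$ fractions. $\beta$ is always
derived from $\alpha$ and $\alpha/\beta$, never set independently. The
fractionation term is the literal $\beta D_i^2/n$ with $D_i$ the *total*
voxel dose — equal dose per fraction per voxel; per-fraction dose tracking
is out of scope. Accumulation is in natural-log space with Kahan
compensation, so a tumour with $10^6$-fold too many surviving clonogens
reports `tcp = 0` but an exact finite `log_tcp`. The TCP ROI is the GTV
(where the cellularity map is defined), evaluated on the full delivered
dose including any margin hotspots that overlap it.

The mechanism that makes dose painting pay off is a concavity property
verified in the tests: at fixed mean dose, moving dose from low- to
high-clonogen voxels strictly increases TCP, while "anti-painting"
decreases it.

### Paired statistics

The Wilcoxon matched-pairs signed-rank test drops zero differences
(Wilcoxon convention), uses tie-averaged ranks, and computes the exact
two-sided p-value by enumerating all $2^m$ sign assignments for $m \le 15$
nonzero pairs — at cohort scale (10 patients) every p-value is exact — with
a continuity- and tie-corrected normal approximation above.
Commercial statistics packages differ in their zero/tie policies, so these
conventions are stated explicitly rather than left implicit.
Holm–Šidák adjustment is the step-down
$\max_{j\le k}\{1-(1-p_{(j)})^{m-j+1}\}$, clipped to 1. The multiplicity
family is the set of metrics passed to one `compare_arms()` call — the
metrics reported together in one table — and is configurable, since no
single family definition is canonical.

## The synthetic phantom

`phantom_spec()` defines the study conditions; its defaults were chosen
once, as follows, and are not tuned to any test outcome.

* **Geometry**: $64^3$ grid at 2 mm spacing — desk-scale (a full patient
  simulates in about a second) while keeping $\gtrsim 1.5\times10^3$ GTV
  voxels for stable statistics. GTV = ellipsoid with semi-axes 18/14/12 mm
  (a few-cm skull-base tumour); CTV = exact morphological dilation by a
  6 mm isotropic margin; spherical OARs (brainstem-, chiasm-, cochlea-like)
  placed disjoint from the GTV.
* **Cellularity**: lognormal, spatially correlated. White Gaussian noise is
  smoothed to a 6 mm correlation length, standardised analytically to unit
  marginal variance, exponentiated with log-sd 0.6, and scaled to a median
  density of 150 cells/mm³. Lognormal positivity plus spatial correlation
  is the minimal structure the linear prescription needs (a strictly
  positive field with a non-degenerate min/max). The density scale is a
  *clonogen* density, far below total cell density: it was set so that the
  uniform 74 Gy(RBE) arm lands in a TCP regime of order 0.1 — the operating
  regime in which comparing plans by TCP is informative at all (at ~10⁵
  cells/mm³ every plan's TCP would be numerically 0, at ~1 cell/mm³
  numerically 1). No public cellularity statistics exist for this tumour
  site to calibrate against.
* **Plan deviation** = penumbra + blur + noise + margin hotspots, one knob
  each. The prescription is extended outside the CTV by the nearest
  prescription level (masked normalized convolution) decayed by a Gaussian
  of the distance to the CTV surface (falloff σ 5 mm, a proton-like steep
  penumbra); the volume is blurred (FWHM 4 mm, the finite modulation scale
  of pencil-beam delivery); white noise (sd 0.8 Gy(RBE)) models residual
  optimiser/delivery error; and 2 Gaussian hotspots (amplitude 4 Gy(RBE),
  σ 3 mm) are seeded at random CTV∖GTV voxels, reproducing the hotspots
  that optimisers place in safety margins. Both arms of one phantom share
  the same random stream, so the *only* systematic difference between the
  dose-painting and uniform arms is the prescription.

With these defaults the phantom reproduces the qualitative findings the
pipeline is meant to detect: CTV conformity QF ≈ 98 (slightly below ideal,
above the 95% goal), hotspots that can push the CTV maximum above the GTV
maximum, and a TCP advantage for the painted arm.

**What the phantom does not emulate.** Doses are not physical proton
transport: no range/setup errors, no beam geometry, no RBE variation
(everything is RBE-weighted by assumption). The white-noise term is
symmetric where a real optimiser's residuals are one-sided (optimisers
respect hard constraints), so D95 coverage goals evaluated on noisy
phantoms sit at the floor minus noise and can nominally fail while mean
conformity stays high — on real plan exports this artefact is absent.
Cellularity is stationary lognormal; real tumours have necrotic cores,
rims, and imaging noise. Passing tests therefore demonstrate correctness
of the *analysis* under controlled statistical structure, not clinical
performance on patient data.

## Numerical choices

* **Grid convention**: 0-based voxel indices; world position
  $= R\,(\mathrm{index}\circ\mathrm{spacing}) + \mathrm{origin}$ with $R$
  the orthonormal direction matrix (voxel-centre, NIfTI sform semantics).
  Geometry round-trips through NIfTI to better than $10^{-6}$ mm; voxel
  values bit-exactly.
* **Resampling** is pull-based: output voxel centres are mapped through
  the inverse transform and interpolated (nearest for masks, trilinear
  for scalar maps); out-of-domain voxels get a declared fill value,
  default 0 (contributes no dose and no cells). Masks resampled linearly
  are re-binarised at 0.5. The implementation is verified against an
  exhaustive per-voxel oracle.
* **Dilation** (GTV→CTV) is an exact shift-OR over the ball-offset
  stencil in physical mm, so the CTV is the true grid dilation, not an
  enlarged ellipsoid.
* **Smoothing** is separable Gaussian convolution with row-normalised
  kernels (constants are preserved; Neumann-like boundaries), truncated
  at $4\sigma$. The random field uses unnormalised kernels with exact
  per-voxel variance standardisation instead, so its marginals are exactly
  lognormal everywhere including edges.
* **Seeds**: one integer per phantom; internal stages (cellularity, plan
  perturbation) draw from fixed substreams derived from it, in a
  documented order, so cohorts are bit-reproducible and plan arms share
  their noise.

## Problem sizes

The shipped tests run phantoms of $32^3$ (most unit tests), $48^3$–$64^3$
(field-statistics and conformity checks), and a 10-patient $32^3$ cohort;
the acceptance script uses the default $64^3$ phantom. These sizes were
chosen so the full suite completes in well under a minute on one CPU while
every statistical check retains $\ge 10^3$–$10^4$ voxels where its
tolerance calculation assumes it.

## Known limitations

* The linear cellularity→dose map is the only prescription function;
  outcome-optimised or nonlinear mappings are future work upstream of this
  package.
* Radiosensitivity is spatially uniform ($\alpha,\beta$ scalars); voxelwise
  heterogeneity is a known model limitation, not implemented.
* No DICOM-RT I/O (NIfTI only), no deformable registration, no robust
  scenario evaluation, no NTCP.
* The Wilcoxon normal approximation (only engaged beyond 15 nonzero pairs)
  is approximate by nature; cohort-scale comparisons use the exact path.
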