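---
title: "Modeling tDCS target engagement in volume-conductor head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tDCS target engagement in volume-conductor head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsim)
```

## The physical model

Transcranial direct current stimulation (tDCS) injects a weak direct
current (1–4 mA) through sponge electrodes on the scalp. At these
frequencies the head behaves as a purely resistive volume conductor: the
potential $\varphi$ obeys the current-conservation (Laplace) equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with the tissue conductivity $\sigma(\mathbf{x})$ piecewise constant over
the segmented compartments, zero-flux (Neumann) conditions on every
interface with non-conducting space (exterior air and air cavities), and
the injected current entering through the electrode surfaces. The electric
field is $\mathbf{E} = -\nabla\varphi$; its magnitude $|\mathbf{E}|$ and
its component normal to the cortical surface $E_n$ (inward positive) are
the quantities from which engagement measures are derived.

`tdcsim` discretizes this continuum problem with a cell-centered
finite-volume scheme on the voxel grid of the segmented volume. The
conductance of the face between 6-neighboring voxels $i,j$ is the harmonic
mean $2\sigma_i\sigma_j/(\sigma_i+\sigma_j)$ times the voxel edge length,
which is the discretization that keeps the normal current continuous
across tissue interfaces; faces toward $\sigma = 0$ voxels carry no flux.
Voxels with $\sigma = 0$ are excluded from the computational domain
entirely rather than regularized with a small conductivity — "air is an
insulator" is taken literally, and exclusion avoids the ill-conditioning a
tiny $\sigma$ would introduce. The resulting symmetric system is singular
with a constant null vector (only potential differences are physical); the
right-hand side is projected to consistency and the solution referenced to
zero mean over the conductive domain, a symmetric gauge that avoids the
sensitivity of pinning a single voxel.

The system is solved by conjugate gradients with a Jacobi (diagonal)
preconditioner, implemented in compiled code, to a relative residual of
$10^{-8}$ (default; configurable). At that tolerance the engagement
metrics move by well under 0.1% on further tightening, which we verified
by re-solving at $10^{-12}$. On a $64^3$ head this takes roughly 400–500
iterations.

### Electrode model

Sponge pads are 5 cm × 7 cm × 5 mm (surface from common clinical sponges;
the thickness is a typical sponge value and results are weakly sensitive
to it because current is injected on the outer face). Pads are voxelized
as conformal patches hugging the scalp: background voxels within the pad
thickness of the head surface whose geodesic tangent-plane coordinates at
the anchor fall inside the pad rectangle. Each pad's total current is
distributed uniformly over its exposed outer-face voxels (constant current
density on the surface away from the head); we deliberately do not impose
an equipotential-plate condition, which would be a stronger assumption
about the electrode than constant-current drive requires. Pad anchors use
10-20 scalp coordinates constructed geometrically on the phantom (ring
sites at 10/20% arc steps on the circumference, parasagittal sites as
geodesic midpoints, e.g. F3 between Fz and F7); hyphenated anchors such as
`F3-FP1` resolve to the geodesic midpoint of the two sites. The three
montage presets are:

| Preset | Anode | Cathode(s) | Currents at 2 mA |
|---|---|---|---|
| `LUL` | F3-FP1 | T3-P3 (option: P3) | +2 / −2 |
| `BL` | F3-FP1 | FP2 | +2 / −2 |
| `TWO_BY_ONE` | F3-FP1 | T3-P3, T4-P4 | +2 / −1 / −1 |

The LUL cathode placement is reported inconsistently across descriptions
of this montage (temporoparietal "P3" vs the T3-P3 midpoint); the package
defaults to T3-P3 and exposes `lul_cathode` to select the alternative.

### Conductivities

Default isotropic conductivities (S/m): gray matter 0.33, white matter
0.14, CSF 1.79, skin 0.43, skull 0.0132, air 0, electrode sponge (saline)
1.4. All are overridable via `default_conductivities(overrides = ...)` or
YAML configuration. Tensor (anisotropic) conductivity is out of scope.

## The synthetic cohort

Real segmented head models of the kind used in individual-level tDCS
studies are rarely redistributable, so the package ships a synthetic-data
generator that emulates a small cohort of them with multi-shell spherical
phantoms. A phantom is defined by five concentric boundaries
(skin > skull > CSF > gray > white), an optional air cavity, and the
voxel grid. Defaults: $64^3$ voxels at 3 mm with shell radii
88/82/78/75/60 mm. These dimensions were chosen so that the scalp radius
is anatomically adult-sized — with a much smaller head, two real-sized
5 × 7 cm sponges cannot be placed at F3-FP1 and FP2 without overlapping —
while the grid stays small enough that a solve takes seconds. The
submillimeter resolutions typical of published individual head models are
not needed for the physics to be right at the level of the analytic
oracles (the slab field is exact to machine
precision and the sphere potential within 5% of the Legendre series at
this scale), but gyral folding, skull inhomogeneity, and realistic CSF
geometry are of course absent: passing tests on phantoms validates the
*method* — discretization, solver, metrics, statistics — not any
anatomical claim about a particular brain.

Inter-individual variability is emulated by jittering each shell
*thickness* by a uniform ±5% multiplicative factor (jittering thicknesses
rather than radii preserves the strict shell ordering by construction) and
each ROI center by ±3 mm per axis. These magnitudes produce coefficients
of variation of a few percent to ~10% in peak field across five heads,
the order observed across real individual head models. Each head's seed
derives from the master seed, so cohorts are bit-reproducible.

The default target network is a set of ten bilateral regions named for the
cortical and subcortical areas recurrently implicated in auditory verbal
hallucinations (IFGo, IFGt, ACG, PreCG, PoCG, HES, STG, HIP, INS, THA),
placed as spheres at plausible angular positions and depths and clipped to
brain tissue. The exact coordinate list behind such networks is study-
specific configuration, not fixed truth: `make_roiset()` accepts any
specification, and the `roi_network` functions (`apply_affine()`,
`map_to_atlas()`, `roiset_from_atlas()`) prescribe ROIs from external
coordinate tables and label atlases instead.

## Engagement measures

Two measures are computed per head, montage, and amplitude:

* **Peak field** — the maximum of $|\mathbf{E}|$ over an ROI's voxels.
  "Peak" is defined here as the strict maximum; because voxelized corners
  can carry spurious maxima, a robust upper-percentile variant
  (`percentile = 0.999`) is available but off by default, and the choice
  is recorded in the value's `definition` attribute.
* **Modulated volume** — the percentage of a network side's volume where
  $|\mathbf{E}| / E_{\mathrm{th}} \ge 1$, with $E_{\mathrm{th}} = 0.2$ V/m
  by default (the most commonly reported minimum direct-current field that
  shifts neuronal firing in vitro; reported estimates range 0.18–0.5 V/m,
  and the threshold is configurable). The inequality is inclusive: a voxel
  exactly at threshold counts. The denominator is the union of that side's
  ROI masks, so overlapping ROIs are counted once. Peaks are taken over
  the full anatomical ROI mask (gray and white voxels alike); restricting
  to gray matter is a configuration choice left to the caller's masks.

Because the problem is linear in the injected current, one solve at a
reference amplitude yields the full 1–4 mA sweep: peaks scale exactly,
modulated volumes are recomputed against the scaled field. The pipeline's
`resolve_each_amplitude` flag re-solves every amplitude instead, which we
use to validate the shortcut (agreement to solver tolerance). Peak field
is linear in amplitude; modulated volume is not, which is why its
between-montage variability changes qualitatively along the sweep.

Inter-individual variability is summarized by the coefficient of variation
(sample SD / mean) of each metric across heads. Montage differences are
tested per outcome (per ROI for peak field, per side × amplitude for
modulated volume) with one-way fixed-effects ANOVA across montages using
heads as replicates, followed by Bonferroni-corrected two-sided
pooled-variance t tests for the three montage pairs and absolute Cohen's
d effect sizes. With the same heads appearing under every montage a
repeated-measures treatment would also be defensible; the package defaults
to the independent one-way layout (df = (2, 12) for 3 montages × 5 heads)
as the simplest reading, and the choice is visible in the report's
degrees of freedom. When an outcome saturates identically in all heads
(e.g. 0% or 100% modulated volume in every head for two montages), the
pairwise effect size is reported as 0 for equal means and `Inf` for
separated constants rather than failing the whole report.

## Numerical choices and degenerate inputs

* Face conductances use harmonic means; arithmetic means would overstate
  current through thin resistive layers (skull).
* Currents are converted mA → A and grid spacing mm → m internally; fields
  are reported in V/m, potentials in V.
* Surface normals for $E_n$ come from the gradient of a Gaussian-smoothed
  (σ = 1 voxel, configurable) brain indicator, which stabilizes normals on
  staircase surfaces; $E_n$ is reported on gray-matter surface voxels with
  the inward direction positive.
* A montage whose currents do not sum to zero, a pad that misses the
  scalp, overlapping pads, a disconnected conductive domain, an empty ROI
  after clipping, a non-positive threshold, or a CV of a zero-mean sample
  are all rejected with named errors rather than silently patched.
* Zero injected current returns the zero potential without invoking the
  iterative solver.
* The sphere oracle's Legendre series diverges at the electrode points;
  comparisons exclude a 2-voxel ball around each electrode and use
  truncation order 200 (orders 40 vs 80 agree to 0.1% at r ≤ 0.9R).

## Problem sizes used in the shipped tests

Unit tests run on $32^3$–$40^3$ phantoms at 4–5 mm voxels (seconds per
solve); the verification oracles run at the demonstration scale of $64^3$
(slab and sphere, the latter refined to $96^3$); and the end-to-end
demonstration — 5 heads × 3 montages × 7 amplitudes at $64^3$, one solve
per head-montage pair plus linear scaling — completes in a few minutes on
one CPU. These sizes are the package's chosen desk-scale defaults; the
solver itself is resolution-agnostic and the oracle errors shrink under
refinement.

## Known limitations

* Spherical phantoms have no gyri, no skull layering, and no realistic
  CSF geometry; absolute field values in real heads will differ even
  though the pipeline's comparative logic (montage contrasts, amplitude
  scaling, variability) transfers.
* Isotropic conductivities only; white-matter anisotropy is not modeled.
* Electrode-skin contact impedance and gel spreading are not modeled;
  current is injected at constant density over the outer pad face.
* The modulation threshold treats 0.2 V/m as a hard cutoff; modulated
  volume inherits every caveat of that postulate.
* Only direct current (quasi-static) stimulation; no AC/tACS, no neuron
  polarization model downstream of the field.

## A minimal worked run

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 7)
head <- make_spherical_head(spec)
rois <- make_roiset(head)

mont <- preset_montage("TWO_BY_ONE", amplitude_mA = 2)
headp <- voxelize_pads(head, mont)
sigma <- assign_conductivity(headp)
sol <- compute_field(
  solve_potential(sigma, attr(headp, "pads"), head$voxel_size))

peak_field(sol$E_mag, rois$masks$STG_L)
modulated_volume(sol$E_mag, side_union(rois, "right"), e_th = 0.2)
sweep_currents(sol, reference_mA = 2, rois)

# the full cohort experiment
res <- run_experiment(default_config(seed = 7), out_dir = "demo_out")
res$report
```

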