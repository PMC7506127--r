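---
title: "Methods: plan-quality dosimetry at tissue-air interfaces under a 1.5-T field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plan-quality dosimetry at tissue-air interfaces under a 1.5-T field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrplanqa)
```

## What the package models

An integrated MR scanner and linear accelerator (MR-linac) delivers
radiotherapy under a static 1.5-T magnetic field. The Lorentz force
curls secondary electrons: where they leave tissue into air they are
bent back onto the surface (the electron return effect), which raises
dose in the most superficial tissue layer and redistributes dose
across air-cavity walls. Head-and-neck plans are particularly
exposed: targets are superficial, and the airway runs through the
treated volume.

`mrplanqa` evaluates that effect the way a planning study would:
three plan conditions per patient — `B0` (optimised without the
field), `B15_RECAL` (identical segments and monitor units,
recalculated with the field), `B15_REOPT` (reoptimised under the
field with the original cost function) — compared on DVH metrics,
bespoke interface regions, a summary plan-quality score, and paired
nonparametric tests. Because clinical dose grids are rarely sharable,
the package includes a synthetic phantom and dose generator that
reproduces the *statistical structure* of these effects, so every
stage is exercised end to end without patient data.

## Grids, masks and distances

All doses and masks live on one common voxel grid, by default
1 × 1 × 3 mm (head-and-neck CT convention: 1-mm planar voxels, 3-mm
slices). Using a single grid keeps 1-mm shell dosimetry well defined;
resampling a coarser dose grid onto 1-mm shells would blur exactly
the quantity under study.

All derived regions reduce to one primitive: the anisotropic
Euclidean distance between voxel centres, computed exactly by a
separable lower-envelope distance transform (`src/edt.cpp`; verified
in the tests against exhaustive nearest-neighbour search). The
conventions, chosen once and testable:

- **Skin shell** — body voxels with distance to the body exterior
  ≤ 1 mm (closed threshold). On a 1 × 1 × 3 mm grid this selects one
  in-plane voxel ring and no purely axial face layer (axial
  neighbours are 3 mm away), matching slice-wise contouring practice.
  Whether superior/inferior end slices of a scan belong to a skin
  contour is a genuinely open convention; this package excludes them.
- **Cavity interface shell** — tissue voxels (in body, not cavity)
  within 1 mm of the cavity.
- **PRV margins** — all voxels within the margin of the organ,
  clipped to the body (3 mm brain stem, 5 mm spinal cord).
- **Normal tissue (NT)** — body voxels *strictly* farther than 10 mm
  from the PTV. The closed shell/margin thresholds and the strict NT
  threshold make NT and the 10-mm PTV expansion an exact partition of
  the body, which the tests assert.
- The world beyond the grid faces counts as "outside" for
  distance-to-complement, so degenerate masks that fill the grid
  still have finite boundary distances.

One quantitative note: the 1-mm shell of a digitised smooth surface
is its face-boundary voxel layer, and for a sphere on an isotropic
1-mm grid that layer counts about 0.8 × (smooth area × thickness)
(staircase digitisation); for an in-plane cylinder wall the factor is
about 0.96. Shell *means* are unaffected — the layer is still exactly
one voxel thick along the surface normal — but anyone comparing shell
volumes against analytic areas should expect that factor.

## DVHs and plan metrics

Cumulative DVHs are built from the in-mask voxel-dose multiset at
0.01-Gy resolution, with a 10⁻⁹-Gy guard so doses exactly at a bin
edge or prescription level count as receiving it despite binary
floating point. `Dq%` is read from the curve by linear interpolation,
with ties resolved toward the higher dose ("hottest q%"); `V_d` is
exact to one bin. `Dmax` is the single hottest voxel (the point
maximum a Monte Carlo TPS reports — users comparing with D2%-style
near-maxima should note the difference) and `Dmean` the arithmetic
in-mask mean.

`HI = (D2% − D98%)/D50%` is reported as a *fraction* (0–0.2/0–0.3
scoring intervals), not ×100. For `CI` the treated volume is clipped
to the body, because Monte Carlo grids deposit dose in the air
outside the patient. A plan in which no voxel reaches the
prescription yields CI = 0 flagged degenerate. Both high-dose targets
(PGTVtb, GTVnd) are evaluated against the composite 69.96-Gy isodose
— they share one prescription, and a per-target isodose would credit
dose the other target receives.

## The plan-quality metric

Each of the 15 submetrics has an evaluation interval
`[M_l, M_u]` and a clamped linear value function worth 0–10 points;
coverage and CI increase, everything else decreases. Clamping is
deliberate: an unbounded ramp would let one spectacular metric buy
back a failing one. All submetrics are weighted equally — the
proportioning between targets and organs at risk is carried by the
*number* of metrics per structure (9 target vs 6 OAR rows), not by
weights; `pqm_table()` accepts custom tables (and `s_min`/`s_max`
ranges) where a clinic weighs differently. The default intervals are
cohort-adapted clinical ranges (e.g. PGTVtb coverage 80–95%, cord
Dmax 30–40 Gy, NT Dmean 10–30 Gy); treat them as a starting point,
not a standard. Parotids are scored on the union of both lobes, which
is what a single "parotids" interval implies.

## Statistics

`summarize_values()` reports the *population* standard deviation
(÷ n) by default: cohort tables in planning studies print that form
(the sample form is one option away). `wilcoxon_signed_rank()`
reproduces the SPSS asymptotic output exactly: zeros dropped,
mid-ranks for ties, tie-corrected variance, **no** continuity
correction, two-sided normal p. The reported `W` is min(W⁺, W⁻) while
`z` is computed from W⁺, so swapping the two samples flips `z` but
not `W` or `p`. Exhaustive comparison against the exact 2ⁿ sign
distribution shows the approximation stays within 0.05 of the exact p
for n ≥ 10 everywhere (worst case 0.0499 at n = 10); below n = 5 the
result carries an `approx_unreliable` flag. No multiple-testing
correction is applied — each metric is tested on its own at α = 0.05,
mirroring planning-study practice; with ~22 metrics × 3 contrasts a
user wanting family-wise control should apply `p.adjust` downstream.
Presentation rounding is half-away-from-zero (`round_half_away()`);
all computation is full precision.

## The synthetic phantom and dose model

`phantom_spec()` describes a neck-like cylinder (default radius
45 mm, 120 mm long) containing an anterior larynx/trachea air tube
and a superior pharyngeal air pocket, a central tumour-bed target
(PGTVtb) and a lateral nodal target (GTVnd) — both excluding air —
a PTV grown 8 mm from their union, and posterior/lateral OARs (brain
stem, cord, parotids, thyroid). Geometry is deterministic;
`generate_cohort()` jitters radii and the nodal position per patient
from seeds derived from one master seed by a fixed offset.

The dose engine is **phenomenological, not transport physics**. Its
fidelity target is the downstream metric structure: DVH shapes,
shell statistics, score orderings. It composes

1. nine equiangular in-plane beams with a build-up rise and
   exponential depth attenuation (depth computed analytically against
   the fitted body cylinder),
2. a conformal component: uniform over the PTV, exponential falloff
   (6 mm) outside,
3. a high-dose boost with a compact 2.5-mm cosine taper around
   PGTVtb/GTVnd — compact support keeps the low-dose PTV plateau
   genuinely flat, which is what lets coverage at the prescription
   stay above 90% while the PTV median stays within 2% of 60.06 Gy,
4. multiplicative Gaussian noise (σ = 1%) emulating Monte Carlo
   statistical uncertainty.

The two amplitudes are calibrated per realisation so the PTV median
lands at 1.018 × 60.06 Gy and the PGTVtb/GTVnd median at
1.016 × 69.96 Gy; after noise the PTV median is re-pinned exactly
(noise smears the plateau against the one-sided boost tail and would
otherwise drift the median up ~0.5%). The headrooms were fixed once:
large enough that 1% voxel noise leaves ≥ 90% of the PTV at the
prescription, small enough to stay within 2% of it.

The **field perturbation** has three parts:

- a skin boost `A·exp(−d/λ)` (λ = 5 mm) on angular sectors centred on
  the nine beam-exit directions — 20° sectors (half the
  circumference) for `B15_RECAL`, 40° (full ring) for `B15_REOPT`.
  The sector geometry is a free choice (no published map of beam-exit
  skin regions exists); the half/full split reproduces the reported
  signature that recalculated plans show ΔDmax ≫ ΔDmean while
  reoptimised plans show ΔDmax ≈ ΔDmean. Amplitudes (4.4 and 1.6 Gy)
  were set analytically from the target cohort-mean skin ΔDmean
  levels (1.8 and 1.3 Gy) via the shell-mean depth factor (≈ 0.82)
  and sector fraction, then frozen.
- an antisymmetric ±B shift across each cavity interface (sign by
  the side of the cavity's slice-wise centroid along a configurable
  direction), which cancels in the both-sided shell mean — the
  "dose down on one side, up on the other" interface signature.
- a 3% multiplicative coverage degradation of target-region dose for
  `B15_RECAL` only.

Both field conditions reuse the base plan's noise realisation by
default. Re-noising them independently is available
(`noise_sigma_fraction`), but it double-counts Monte Carlo noise on
top of an already-noisy base and systematically erodes reoptimised
coverage scores, contradicting the expected reoptimised ≈ no-field
pattern.

### What the generator does and does not emulate

It emulates: prescription-consistent SIB target DVHs, realistic shell
and OAR dose scales, the skin ΔDmean/ΔDmax orderings and magnitudes,
near-cancelling interface shifts, and the uniform per-patient
plan-quality ordering PQM(`B15_RECAL`) < PQM(`B0`) ≈
PQM(`B15_REOPT`). It does **not** emulate: fluence optimisation and
segment shapes, oblique-incidence ERE physics, buildup asymmetry in
the field, or realistic partial coverage loss — because the generated
target DVHs are tight (a requirement of keeping the median within 2%
of prescription *and* coverage above 90%), the 3% recalculation
scale-down collapses coverage rather than trimming it by a few
percent as clinical cohorts show. Consequently the synthetic PQM drop
under recalculation (~27 points) overshoots the ~14 points typical of
real cohorts, while its sign and uniformity are faithful. Passing the
cohort tests therefore demonstrates the *pipeline's* correctness and
the *pattern* of field effects, not patient-level dose realism.

## Problem sizes and numerical choices

Default grid 104 × 104 × 44 (≈ 0.5 M voxels); a 10-patient,
3-condition cohort with full metric extraction runs in well under a
minute, which is the scale the test suite and the acceptance script
use. Dose comparisons carry a 10⁻⁹-Gy tolerance; DVH bin width
0.01 Gy; distance thresholds are closed except the strict NT
exclusion; amplitude calibration iterates eight damped fixed-point
steps (convergence to machine precision in practice). Difference maps
are reported in cGy with a ±700-cGy rendering clip alongside the raw
signed map.

## Known limitations

- Masks only; no DICOM RT-STRUCT polygons, no EQD2/BED conversion.
- The dose model's OAR doses are plausible but not plan-optimised;
  OAR submetrics typically score near their best limits, so synthetic
  PQM differences are carried almost entirely by the target metrics.
- `Dmax` as a point maximum is noise-sensitive by construction
  (matching TPS reporting), which is visible in the skin ΔDmax
  spread.
- The Wilcoxon normal approximation is reported even for 5 ≤ n < 10,
  where its error against the exact distribution can reach ~0.07;
  the `approx_unreliable` flag marks n < 5 only.
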