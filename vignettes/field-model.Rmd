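---
title: "The two-conductor field model behind needle-electrode electroporation planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-conductor field model behind needle-electrode electroporation planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlefield)
```

## The problem

Electrochemotherapy (ECT) and non-thermal irreversible electroporation
(NTIRE) succeed only where the local electric field magnitude reaches a
tissue- and protocol-dependent threshold: `E_rev` for reversible membrane
permeabilization, `E_irrev` for cell death. Treatment planning with needle
electrodes is routinely misjudged with the parallel-plate estimate
`E ≈ U/d` (applied voltage over electrode distance), which is only valid
between infinite plates. For two parallel needle electrodes the field is
strongly inhomogeneous: it diverges at the conductor surfaces and sags well
below `U/d` between them. `needlefield` computes the exact two-dimensional
electrostatic field of parallel cylindrical conductor pairs, composes
multi-electrode configurations from those pairs, and reports
threshold-coverage statistics for a circular tumor target inside a square
tissue slice.

## The model

The cross-section of two long parallel cylindrical conductors of radius
$\rho_0$, centre distance $d_{AB}$ and applied voltage $V_{AB}$ admits a
classical image-charge solution. The equivalent line charges do not sit on
the geometric axes: each is displaced toward the other conductor by the
eccentricity

$$e = \frac{d_{AB}}{2} - \sqrt{\left(\frac{d_{AB}}{2}\right)^2 - \rho_0^2},
\qquad e\,(d_{AB} - e) = \rho_0^2 ,$$

so the *electrical axes* lie $2s$ apart with
$s = \sqrt{(d_{AB}/2)^2 - \rho_0^2}$. With $\rho_A$, $\rho_B$ the distances
from a field point to the two electrical axes, the potential and field
magnitude are

$$V(x,y) = C \ln\frac{\rho_B}{\rho_A}, \qquad
C = \frac{V_{AB}}{2 \ln\!\dfrac{d_{AB} + \sqrt{d_{AB}^2 - 4\rho_0^2}}{2\rho_0}},$$

$$E(x,y) = C\sqrt{
 \left[\frac{x'_A-x}{\rho_A^2}-\frac{x'_B-x}{\rho_B^2}\right]^2 +
 \left[\frac{y'_A-y}{\rho_A^2}-\frac{y'_B-y}{\rho_B^2}\right]^2},$$

where $(x'_A, y'_A)$, $(x'_B, y'_B)$ are the electrical-axis coordinates,
each geometric centre displaced by $e$ toward the other electrode. This
construction makes each conductor surface an exact equipotential at
$\pm V_{AB}/2$. At the midpoint of a symmetric pair the field reduces to
$2C/s$. For the reference configuration (1300 V, $d_{AB}$ = 1.6 cm,
$\rho_0$ = 0.1 cm) this gives $C$ = 234.77 V and a midpoint field of
591.6 V/cm — very different from the naive $U/d$ = 812.5 V/cm, which is
the model's central pedagogical point:

```{r closed-forms}
pair_constant(1300, 0.016, 0.001)
pg <- electrical_axes(electrode(-0.008, 0, "anode"),
                      electrode(0.008, 0, "cathode"),
                      rho0 = 0.001, voltage = 1300)
pair_field(0, 0, pg) / 100   # V/cm
1300 / 1.6                   # the naive plate estimate, V/cm
```

Three reading choices deserve a note:

* **$\rho_0$ is the conductor radius.** Only the radius interpretation
  makes the conductor surface an equipotential circle of the electrode's
  physical size (and keeps $s$ real whenever the conductors do not
  overlap). The user-facing configuration field is `electrode_diameter_mm`
  and is halved on ingestion.
* **Natural logarithm.** The derivation carries $q/2\pi\varepsilon_0$
  factors that cancel only in base $e$; `log` here is always `ln`.
* **Quadrant-aware angles.** The displacement direction of each electrical
  axis is computed with the two-argument arctangent `atan2(Δy, Δx)`, which
  is defined for vertical pairs and distinguishes the A→B direction from
  B→A — a plain coordinate-ratio arctangent cannot.

## Multi-electrode composition

Pulse generators energise one anode–cathode pair at a time. A group is
therefore one electrode of one polarity plus one or more of the other at a
single voltage; a group of $n$ electrodes decomposes into $n-1$ pairs
sharing the singleton, pairs are never formed across groups, and the field
relevant for electroporation at a point is the **pointwise maximum** over
all pairs — not a superposition. `evaluate_mesh()` applies this on a
pixel-centre mesh (default 400 × 400 = 160,000 points) over the square
tissue region. Groups mixing several anodes with several cathodes are
rejected at construction: the pairing would be ambiguous, and the
single-opposite-polarity rule matches how such groups are defined in
electroporation practice.

Points within one conductor radius of any electrode centre are masked
`inside_electrode` (globally — the conductor occupies that area no matter
which pair is pulsed): the analytic expression diverges at the electrical
axes and a field value inside a conductor is not meaningful in this model.
Masked points are excluded from statistics and colour scaling.

## Mesh and coordinate conventions

The origin is the centre of the tissue square, x rightward, y upward, SI
metres internally; mm and V/cm appear only at I/O boundaries. Mesh samples
are **pixel centres**, `x_i = (i − 0.5)/n · L − L/2`; there is no sample
exactly on the boundary and, for even `n`, none exactly at the origin. TSV
export and PNG rendering place row 1 at the **top** of the display
(maximum y). Tissue is a square of side `sqrt(area)`; the tumor is a
centred circle whose diameter is `tumor_tissue_ratio × side` (a diameter
ratio, chosen over an area ratio so that the circle drawn on screen scales
linearly with the setting).

## Coverage statistics

`coverage_report()` reports extrema and, per region (tumor vs surrounding
tissue), the percentage of unmasked pixels with `E ≥ threshold`. The
comparison is inclusive: a pixel *reaching* the threshold counts as
covered. Percentages are pixel-count fractions, not integrated areas, so
they carry a resolution dependence of order one pixel-row along the region
boundary; at the default 400 × 400 mesh this is below 0.5 % for
tumor-sized regions. A region with no unmasked pixels reports `NA`, never
0 %. Thresholds default to 300 / 800 V/cm (typical reversible /
irreversible values; both strongly tissue- and protocol-dependent) and may
be given in V/cm, V/mm or V/in.

## Validation oracles

Two independent checks are built in rather than left to the test suite,
because they are useful diagnostics in their own right:

* `numeric_gradient_field()` differentiates the potential numerically
  (second-order central differences). Agreement with the closed-form
  magnitude is ≤ 10⁻⁴ relative at step `1e-6 · d_AB`.
* `fd_laplace_solve()` solves the Laplace boundary-value problem by
  successive over-relaxation on an n × n grid, with ±V/2 fixed on the
  conductor circles and the analytic potential imposed on the outer ring
  (so the comparison isolates interior accuracy — a validation choice, not
  a physics claim). Free nodes whose stencil arms are cut by a conductor
  circle use the Shortley–Weller fractional-arm stencil. Without it the
  Dirichlet data effectively sit on a staircase polygon whose radius is
  wrong by up to half a grid step; under a near-logarithmic potential that
  alone produces ~17 % deviation at n = 200, an artefact of the
  discretization rather than of either solution. With the corrected
  stencil the two solutions agree to 0.2 % (max deviation over nodes at
  least 5ρ₀ from the electrodes, normalized by the largest analytic
  potential magnitude among those nodes — the potential crosses zero on
  the pair bisector, so a pointwise relative error is undefined there).
  SOR uses relaxation factor 1.9, row-major sweeps, tolerance 10⁻⁸ V on
  the per-sweep update, and an iteration cap of 50,000; non-convergence is
  an error, never a silent result.

## Rendering

`colorize()` maps field values linearly (optionally log₁₀) onto a palette
ramp between explicit or automatic scale limits; auto-scaling uses
[0, 99.5th percentile of unmasked values] because the analytic field grows
without bound at the conductor surfaces and a plain maximum would wash out
the map. Four palettes ship (`hot`, `gray`, `jet`, `coolwarm`); the gray
ramp is luminance-monotone. Rendering is pure — identical inputs yield
bit-identical PNG bytes — and read-only over the field map. The colour bar
draws threshold lines at their linear positions with a small built-in
bitmap digit font, keeping the output byte-reproducible across systems
with no font dependencies.

## Configuration layer

Configurations are JSON (canonical; YAML accepted on input). Validation
enforces the tool's bounds — tissue area 1.61–16129.00 mm², electrode
diameter 0.10–2.00 mm, 2–12 electrodes in 1–6 groups — and reports *all*
violations at once, each naming the field, the offending value and the
admissible range. The tumor-to-tissue `conductivity_ratio` is accepted and
round-tripped but deliberately unused: the field model treats the whole
slice as homogeneous in conductivity, and the setting is flagged with a
warning so nobody mistakes it for physics. Outputs use 6 significant
digits with a `.` decimal separator regardless of locale, so identical
configurations produce byte-identical TSV and JSON artifacts.

## What the fixtures emulate — and what they do not

`make_fixture_layout()` provides three canonical arrangements: an opposed
`pair` (the reference two-electrode case), `two_rows` (3 + 3 electrodes in
three groups, the common hexagonal-needle-array workflow of paired
opposite rows) and `hex6` (six electrodes on a circle with alternating
polarity). The defaults — 1.6 cm spacing, 1300 V, 0.5–1 mm conductor
radius — are the scale of clinical ECT needle arrays and of the reference
configuration above. Passing tests on these fixtures validates the
electrostatics, the composition rule and the analytics; it does **not**
validate the model against real tissue, which is inhomogeneous and
anisotropic in conductivity, three-dimensional near electrode tips, and
nonlinear once electroporation itself changes conductivity. The model is
an educational and planning aid, not a dosimetry substitute.

## Numerical choices and degenerate inputs

* Electrodes closer than `2ρ0 + 1 nm` are rejected at layout validation,
  not at computation time; `eccentricity()` and `pair_constant()` also
  refuse touching conductors (`s = 0` makes both singular).
* Potential and field evaluation exactly on an electrical axis is an
  error for the scalar API; the mesh engine masks such points instead.
* Problem sizes used by the shipped checks: 400 × 400 mesh for the
  headline counts, 40–120 grids for property sweeps, n = 200 for the SOR
  comparison (about 2,100 iterations, ~1.5 s) — sizes chosen so the whole
  validation suite re-runs in well under a minute while leaving every
  comparison margin an order of magnitude away from its bound.

## Known limitations

Two-dimensional (a slice far from electrode tips, parallel insertion
assumed); homogeneous conductivity; one pair active at a time (no
superposition mode); coverage by pixel counting; no thermal, drug-
transport or pulse-shape modelling. These mirror the scope of the
analytical engine the package implements.
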