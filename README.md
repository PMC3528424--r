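# needlefield

Analytical electric-field modelling for needle-electrode electroporation
treatment planning.

Electrochemotherapy (ECT) and non-thermal irreversible electroporation
(NTIRE) destroy tumor cells only where the local electric field magnitude
reaches a threshold — `E_rev` for reversible permeabilization, `E_irrev`
for ablation. Planning needle-electrode treatments with the parallel-plate
estimate `E ≈ U/d` badly misjudges the field: between two needles the true
field sags well below `U/d` and diverges at the conductor surfaces.
`needlefield` is aimed at people learning or teaching electroporation
dosimetry: it computes the exact 2-D electrostatics of parallel needle
pairs, composes multi-electrode arrays, and reports how much of a tumor
the field actually covers.

## The model

For two parallel cylindrical conductors (radius ρ₀, centre distance d_AB,
voltage V_AB) the image-charge solution places equivalent line charges on
*electrical axes*, each displaced from its geometric centre by the
eccentricity e = d_AB/2 − √((d_AB/2)² − ρ₀²), which satisfies
e·(d_AB − e) = ρ₀². With ρ_A, ρ_B the distances from a point to the two
axes:

    V(x,y) = C ln(ρ_B/ρ_A),   C = V_AB / (2 ln[(d_AB + √(d_AB² − 4ρ₀²)) / (2ρ₀)])

and E(x,y) = |−∇V| in closed form. Each conductor surface is an exact
equipotential at ±V_AB/2; the field at the midpoint of a symmetric pair is
2C/s with s = √((d_AB/2)² − ρ₀²).

Generators pulse one anode–cathode pair at a time, so an electrode group
(one electrode of one polarity, one or more of the other, one voltage)
decomposes into pairs and the planning-relevant field is the **pointwise
maximum** over all pairs on a mesh (default 400 × 400). Coverage
statistics count the unmasked pixels of the tumor circle and of the
surrounding tissue with E at or above each threshold (defaults 300 and
800 V/cm).

An independent successive-over-relaxation Laplace solver and a numerical
potential-gradient check are included as validation oracles; the test
suite holds the closed form against both.

## Worked example

The reference configuration: one pair, 1300 V, 1.6 cm apart, 1 mm
conductor radius, in a 64 mm tissue square with a 20 mm tumor.

```r
library(needlefield)

pair_constant(1300, 0.016, 0.001)
#> [1] 234.7707

pg <- electrical_axes(electrode(-0.008, 0, "anode"),
                      electrode(0.008, 0, "cathode"),
                      rho0 = 0.001, voltage = 1300)
pair_field(0, 0, pg) / 100        # midpoint field, V/cm
#> [1] 591.5665
1300 / 1.6                        # the naive U/d estimate, V/cm
#> [1] 812.5

lay <- make_fixture_layout("pair", spacing = 0.016, voltage = 1300,
                           electrode_radius = 0.001)
fm  <- evaluate_mesh(lay)          # 400 x 400 mesh
rep <- coverage_report(fm, region_masks(lay, fm$spec), thresholds())
rep
#> <nf_coverage_report> (V/cm)
#>   E range: [18.28, 2551.4]
#>   tumor:       87.65% >= E_rev, 16.34% >= E_irrev (12016 px)
#>   surrounding: 2.339% >= E_rev, 0.06498% >= E_irrev (147744 px)
```

Read: the potential scale C is 234.77 V; the field midway between the
needles is 591.6 V/cm, a third less than the 812.5 V/cm the plate formula
suggests — and indeed only 87.65 % of the tumor reaches the reversible
threshold, so this single pair would under-treat the margins. 16.34 % of
the tumor (the strip between the needles) exceeds the irreversible
threshold.

Render the map and colour bar, or drive everything from a JSON
configuration on the command line:

```sh
Rscript inst/cli/needlefield demo pair --out pair.json
Rscript inst/cli/needlefield report --config pair.json --out results/
Rscript inst/cli/needlefield render --config pair.json --out results/
```

(After installation the script lives at
`system.file("cli", "needlefield", package = "needlefield")`.)

## Package layout

- `R/geometry.R` — electrodes, groups, layouts, electrical axes, pair
  enumeration, fixture layouts
- `R/field_core.R` — pair constant/potential/field, mesh engine, TSV export
- `R/coverage.R` — thresholds, region labels, coverage reports, record log
- `R/oracle.R`, `src/sor.cpp` — validation oracles (numeric gradient, SOR
  Laplace with Shortley–Weller boundary stencil)
- `R/viz.R` — palettes, raster rendering, annotated colour bar, PNG output
- `R/config.R`, `R/cli.R` — JSON/YAML configuration schema, validation,
  command-line interface
- `vignettes/field-model.Rmd` — the model, its assumptions and numerical
  choices
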