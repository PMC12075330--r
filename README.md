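# prepvol

Parametric tooth-preparation geometry and volumetric substance-removal
analysis in R.

Preparing a tooth for an all-ceramic restoration removes substance; how
much depends on four parameters: the **preparation angle** (half of the
convergence angle — the axial wall's tilt from the crown's long axis), the
**chamfer depth** (radial width of the finish-line curvature), the
**finish-line distance** above the cementoenamel junction (CEJ; 1 mm ≈
full crown, 4 mm ≈ partial crown, 6 mm ≈ occlusal onlay), and the
**occlusal reduction** (vertical clearance for the restorative material).
prepvol builds the preparation digitally — a chamfer profile is swept along
the margin into a hollow axial cutter, an anatomic occlusal cutter follows
the reduced occlusal table, both are Boolean-subtracted from a watertight
tooth solid, and the seams are smoothed — then reports the removed volume
as

```
removed vol% = 100 · (V_intact_crown − V_prepared_crown) / V_intact_crown
```

with both crowns cut from the root along the identical CEJ cap, so the
root never enters the computation. A factorial layer sweeps the full
5 × 8 × 6 × 3 = 720-design grid, tabulates per-step removal increments,
ranks parameter effects, and compares restorative materials at their
minimum layer thicknesses.

The package is self-contained scientific R: it ships its own triangle-mesh
kernel (STL/OBJ I/O, divergence-theorem volumes, watertightness
diagnostics, a 3-axis majority-vote voxel oracle) and an exact
implicit-field Boolean for the axis-star-shaped solid class the workflow
produces. Synthetic tooth fixtures replace the unavailable scanned molar:
an analytic cylinder with closed-form preparation volumes (the test
oracle) and a molar-like crown with cusps, fossa, cervical bulge and a
non-planar CEJ. See `vignettes/preparation-geometry.Rmd` for the methods.

## Worked example

```r
library(prepvol)

tooth <- make_molar_like(tooth_spec(), resolution = mesh_resolution(preset = "fast"))
tooth
#> <tooth_model 'molar_seed42': crown 598.1 mm3, 31968 faces, CEJ amp 1.00 mm>

params <- prep_params(prep_angle_deg = 8, chamfer_depth_mm = 1.0,
                      finish_line_distance_mm = 4, occlusal_reduction_mm = 1.0)
prep <- apply_preparation(tooth, params, crown_only = TRUE)
removal_percent(tooth, prep)
#> <removal_result: 21.5 vol% (128.826 of 598.120 mm3)>

voxel_oracle_percent(tooth, prep, voxel_mm = 0.1)   # independent cross-check
#> [1] 21.5
```

A partial-crown preparation (8°, 1 mm chamfer, margin 4 mm above the CEJ,
1 mm occlusal clearance) removes 128.8 mm³ — 21.5 % of this crown's
598.1 mm³ — and the voxel oracle confirms the Boolean result. Moving the
margin toward the CEJ dominates the loss:

```r
grid <- study_grid(angle_deg = 8, chamfer_mm = c(0.4, 1.0, 1.6),
                   finish_line_mm = c(1, 4, 6), occlusal_mm = 1)
study <- run_factorial_study(tooth, grid)
increment_table(study, "finish_line")
#>        step min_vol_pct max_vol_pct mean_vol_pct
#> 1 6 to 4 mm    4.075142    11.82066     8.072926
#> 2 4 to 1 mm    9.226612    23.25338    16.408772
```

Each row is the spread, over the other parameters, of the extra removal
incurred by lowering the finish line across that step: the closer the
margin gets to the CEJ, the more each millimetre costs. `effect_ranking()`
ranks finish-line distance first and chamfer depth second on this fixture;
`material_comparison()` evaluates onlay / partial-crown / full-crown
preparations at published material thicknesses, and `export_results()`
writes the factorial table as CSV.

A command-line wrapper is installed with the package
(`system.file("cli/prepvol", package = "prepvol")`):

```sh
prepvol generate --tooth fixture:molar --angle 8 --chamfer 1.0 --finish-line 4 --occlusal 1.0 --out prep_out/
prepvol study --tooth fixture:molar --out results.csv
prepvol materials --tooth fixture:molar --out materials.csv
```

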