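# rodsfrt

**Virtual-rod spatially fractionated radiotherapy (SFRT) boost planning in R.**

## The problem

The curative boost in locally advanced cervical cancer is normally delivered
with brachytherapy: a deliberately heterogeneous dose, very hot near the
sources, prescribed at the 90% coverage level (D90%) of the high-risk
clinical target volume (CTV). Where brachytherapy is not available, uniform
external-beam boosts have performed worse. A virtualised SFRT alternative
plants cylindrical **rods** inside the CTV and uses them as high-dose
optimisation seeds, producing brachytherapy-like peaks (with or without an
explicitly cooled "valley" between them) while respecting the organ-at-risk
(OAR) constraints of brachytherapy practice.

`rodsfrt` is a planning toolkit for this technique, aimed at medical
physicists and algorithm developers. It provides:

* **Rod geometry** — straight rod grids (5 mm diameter, 15 mm pitch, three
  rods by default, arbitrary ZX/ZY tilt) and spline-bent tubular rods
  through seed points; valley (cooling) structures; Euclidean PTV margins.
* **A surrogate dose optimizer** — projected gradient descent on a
  non-negative intensity field under a Gaussian deliverability kernel,
  realising peak-and-valley (`SFRT_1`), peak-only (`SFRT_2`) and uniform
  (`SBRT`) strategies. (It stands in for a commercial VMAT engine; see the
  methods vignette for exactly what that does and does not represent.)
* **The evaluation chain** — 0.02 Gy-binned cumulative DVHs; D90%, D2cm3,
  V45Gy, V60Gy; normalisation of CTV D90% to the 30 Gy / 5-fraction
  prescription; EQD2 conversion
  `EQD2 = nd (1 + d/(α/β)) / (1 + 2/(α/β))` with cumulative EBRT+boost
  constraints (α/β = 10 for CTV, 3 for OARs); coverage-mitigation
  renormalisation; cohort summaries (mean ± SD [min, max]).
* **Synthetic pelvic phantoms** — a deterministic, seeded generator (bent
  super-ellipsoid CTV of 30–90 cm³; bladder, rectum, sigmoid, bowel at
  anatomical offsets) so the whole chain runs without patient data.
* **I/O** — NIfTI masks and dose grids, DVH CSVs, plan-report JSON,
  RT-structure-style contour export (per-slice closed polygons, JSON), and
  a command-line front end (`inst/cli/rodsfrt`) with `phantom`, `rods`,
  `optimize`, `evaluate` and `cohort` subcommands.

## Worked example

```r
library(rodsfrt)

# a 51 cm3 phantom on a 2.5 mm grid (1.25 mm is the default)
phantom <- generate_phantom(phantom_spec(seed = 1, spacing_mm = 2.5))
ctv     <- get_structure(phantom, "CTV")
rods    <- generate_straight_rods(ctv, straight_rod_spec())
valley  <- make_valley(ctv, rods)

plan <- sfrt_plan(phantom, rods, valley, optimizer_config("SFRT_1"))
summary(plan)
#> SFRT surrogate plan (SFRT_1)
#>   CTV D90%: 30.74 Gy   V45Gy: 23.9%   V60Gy: 0.6%
#>   mean peak/valley dose ratio: 1.64
#>   final objective: 1.549

norm   <- normalize_to_d90(plan$dose, ctv, target_gy = 30)
report <- evaluate_plan(norm$dose, phantom)
report
#> <plan_report> scale 1.0000, 0 hard-limit violation(s), 3 aim violation(s)
#>   CTV      D90%      30.00 Gy   cum EQD2 84.25 Gy
#>   CTV      V45Gy     21.21 %   (aim not met)
#>   CTV      V60Gy      0.00 %   (aim not met)
#>   PTV2mm   D90%      30.00 Gy   cum EQD2 84.25 Gy
#>   PTV5mm   D90%      19.32 Gy   cum EQD2 66.57 Gy (aim not met)
#>   bladder  D2cm3      4.23 Gy   cum EQD2 46.45 Gy
#>   rectum   D2cm3      2.47 Gy   cum EQD2 44.92 Gy
#>   sigmoid  D2cm3      0.02 Gy   cum EQD2 43.21 Gy
#>   bowel    D2cm3      1.32 Gy   cum EQD2 44.06 Gy
```

(At this coarse 2.5 mm spacing a 2 mm expansion adds no voxel centres, so
`PTV2mm` coincides with the CTV; at the default 1.25 mm grid it is a true
margin and its D90% drops accordingly.)

Reading the numbers: after normalisation the dose covering 90% of the CTV is
exactly the 30 Gy prescription, and its cumulative EQD2 — boost plus the
45 Gy / 25-fraction pelvic course — is the 84.25 Gy objective. The rod peaks
push part of the CTV towards 45–60 Gy (the V45Gy/V60Gy heterogeneity aims;
a surrogate plan at this coarse resolution meets them only partially, which
the report flags as aim misses). Every OAR's near-to-maximum dose (D2cm3)
sits far below its hard limit, so the coverage mitigation can rescale the
plan upwards until the first organ reaches its limit:

```r
mit <- mitigate_renormalize(norm$dose, phantom)
mit$scale; mit$binding_oar
#> [1] 6.501
#> [1] "bladder"
```

(On synthetic phantoms the surrogate's dose bath is much tighter than a real
three-arc VMAT plan, so OAR doses — and hence this headroom — are larger
than clinical experience; see the vignette's limitations section.)

The same chain, end to end, in one call:

```r
res <- run_single_plan(seed = 7, strategy = "SFRT_1", mitigation = "renormalize")
```

## Documentation

* `vignette("virtual-rod-sfrt-methods")` — the planning model, every tunable
  parameter with units and defaults, numerical choices, and limitations.
* `?sfrt_plan`, `?generate_phantom`, `?straight_rod_spec`, `?evaluate_plan`
  for the main entry points.
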