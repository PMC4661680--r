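# retisim

Monte-Carlo ray tracing of a schematic human eye viewing a Snellen chart,
with two ways of degrading the retinal image: **myopic defocus** (axial
elongation, 0–10 D) and **lens opacity**, emulated as an N×N array of
~10 µm hole features with period *P* placed in *L* layers on the anterior
lens surface. A flux-vs-diopter **calibration curve** — whole-chart
retinal flux, normalized to 1 at plano — is inverted to assign an
**equivalent myopia** severity to any opacity configuration, the way an
early cataract's straylight damage can be graded against defocus.

The package is for vision scientists and optical modelers who want a
fully scriptable, seed-reproducible version of this pipeline: schematic
eye (Le Grand four-surface preset, every parameter overridable), block
5×5 Snellen optotypes rendered as an emissive source, sequential tracer
with exact power accounting, hole-array opacity models (absorbing or
cone-scattering), and the calibration/prediction machinery.

## The quantities

* Eye: four refracting surfaces; equivalent power
  `P = -n' u' / y ≈ 59.94 D`; emmetropia at infinity by construction;
  myopia `D` induced so the far point sits at `1/D` m.
* Chart: a 20/X row subtends `5·X/20` arc min at the 20 ft reference;
  the 5×5 block "E" fills 17/25 of its letter square.
* Opacity: distribution area `(N·P)² · L` (mm²); hole coverage
  `(π/4)(d_h/P)²`.
* Calibration: `f(D) = Φ(D)/Φ(0)` over the whole-chart retinal ROI,
  strictly decreasing, inverted piecewise-linearly; predictions report
  diopters and centi-diopter "degrees" (100 per diopter).

## Worked example

```r
library(retisim)

eye   <- build_schematic_eye()          # Le Grand preset, 4 mm pupil
chart <- render_chart()                 # 8-row Snellen chart at 20 ft
curve <- build_calibration(eye, chart, n_rays = 2e5, seed = 1)
print(curve)
#> Calibration curve, region 'whole', invertible
#>    diopters normalized_flux
#> 1         0          1.0000
#> 2         1          0.9709
#> 3         2          0.9339
#> 4         3          0.8912
#> 5         4          0.8423
#> 6         5          0.7916
#> 7         6          0.7415
#> 8         7          0.6933
#> 9         8          0.6454
#> 10        9          0.5987
#> 11       10          0.5566

spec <- microstructure_spec(50, 0.04, layers = 2)   # the "D8" configuration
array_area(50, 0.04, 2)
#> [1] 8

report <- predict(curve, spec, eye, chart, n_rays = 2e5, seed = 1)
print(report)
#> Equivalent-myopia prediction (block model): status ok
#>   normalized flux 0.9839 (deficit 0.0161, threshold 0.0012)
#>   equivalent myopia 0.55 D (55 centi-diopter degrees)
```

Reading: 10 D of defocus drains the whole-chart flux to 0.557 of plano;
the 50×50/2-layer/0.04 mm array removes 1.6% of the flux (well above the
3-standard-error detection threshold of 0.12%), which the curve maps to
an equivalent myopia of 0.55 D, i.e. 55 "degrees". Absolute severities
depend strongly on the configured pupil and scatter model (see the
methods vignette); orderings and invariants are the robust outputs.

## Command line

```sh
inst/exec/retisim area --n 100 --period 0.05          # prints 25
inst/exec/retisim render-chart --out run1 --region E
inst/exec/retisim simulate --out run1 --myopia 5 --rays 200000 --seed 1
inst/exec/retisim calibrate --out run1 --seed 1
inst/exec/retisim predict --spec micro.json --curve run1/calibration --out run1
inst/exec/retisim fixtures --out fixtures --seed 1
```

Every artifact is plain text (PGM images, CSV tables, JSON sidecars) and
embeds the fully resolved configuration and package version, so any run
can be reproduced bit-for-bit from its own metadata.

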