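---
title: "retisim: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retisim: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`retisim` simulates what a schematic human eye sees when it looks at a
Snellen acuity chart, and how that retinal image degrades under two kinds
of insult:

* **myopic defocus** — the eye is axially elongated until its far point
  sits at $1/D$ meters, for $D$ between 0 and 10 diopters;
* **lens opacity** — an $N \times N$ array of small (default 10 µm)
  opaque or scattering features with center period $P$ is placed on the
  anterior lens surface, in $L$ coincident layers, emulating the
  straylight damage of an early cataract.

The link between the two is a *flux calibration curve*: the total light
flux landing inside the retinal image of the whole chart, as a function
of defocus, normalized to 1 at plano. Because that curve is strictly
decreasing for the whole chart, it can be inverted; the *equivalent
myopia* of an opacity configuration is the defocus whose whole-chart flux
equals the flux measured with the opacity in place. Severities are
reported both in diopters and in the centi-diopter "degree" convention
(100 degrees = 1 D).

### The eye

The default preset is modeled on the Le Grand full theoretical relaxed
eye: four spherical refracting surfaces (anterior/posterior cornea,
anterior/posterior lens; radii 7.8, 6.5, 10.2, −6.0 mm; media indices
1.3771, 1.3374, 1.4200, 1.3360), corneal center thickness 0.55 mm
(within the anatomical 0.5–0.6 mm band), corneal diameter 11.5 mm, lens
diameter 10 mm, equivalent power ≈ 59.94 D. Every number lives in one
preset function and can be overridden through the configuration, so the
preset is replaceable data rather than hard-coded physics; all
calibration and prediction results are *properties* of whatever eye is
configured (emmetropia, far points, monotone flux), never of these
specific values.

The retina is a flat detector plane placed at the solved paraxial focus.
Emmetropia is defined at infinity (parallel rays focus on the retina),
which keeps two contracts simultaneously exact: inducing 0 D is the
identity, and the far point of an eye with $D$ diopters induced is
exactly $1/D$ m. Defining emmetropia at the 6.1 m chart instead would
leave a 0.16 D offset in one of the two; that option remains available
via `emmetropize_at`.

Myopia is induced by axial elongation — the retina moves back, the
optics stay fixed — because the severity sweep varies only "degree of
myopia". A lens-based mechanism (steepening the posterior lens radius at
fixed retina) is provided as `method = "lens"` but is not the default.

The pupil is a fixed 4 mm stop placed 0.05 mm ahead of the anterior lens
vertex (photopic, no adaptation), configurable via `pupil_diameter` and
`stop_z`.

### The chart

Letters are block optotypes on the classic 5×5 stroke grid (the "E"
fills 17 of 25 cells); the glyph table is data. Row heights follow the
acuity definition: a 20/X row subtends $5 X/20$ arc minutes at the 20 ft
reference distance, so the 20/20 stroke is 1.77 mm. The chart sits at
20 ft by default — consistent with the acuity definition — with a 6 ft
preset for the alternative placement. Eight rows run from 20/200 ("E")
to 20/20.

Six selection regions reproduce the region-wise analysis: the whole
chart, the single top "E", rows 1–2 ("E,F,P"), rows 1–3, rows 2–4 and
rows 5–8. Region boxes are letter bounding boxes padded by 10% of the
tallest included letter (configurable).

The chart is an *emissive extended source*: sample points are drawn
uniformly over the lit cell area (cell-exact, so the per-letter sampling
density is exactly proportional to lit area) and each point launches one
ray aimed at a uniform point of the paraxial entrance pupil (importance
sampling into the cone subtending the pupil). Per-ray power is the total
emitted power divided by the ray count, so the source side of the power
ledger is exact by construction. The pupil-solid-angle weighting this
implies cancels in every normalized quantity the package reports.

### The tracer

Sequential Monte-Carlo tracing: sphere/plane intersection with aperture
vignetting, vector Snell refraction at each surface, an aperture test at
the stop, the microstructure interaction at the anterior lens surface,
and binning on the retina (default 256×256 bins over a square window
sized to the paraxial whole-chart image plus a 20% margin). One
wavelength; no diffraction, polarization or non-sequential paths.

Accounting invariants are enforced rather than estimated: every launched
ray ends `landed`, `vignetted` or `absorbed`; total internal reflection
absorbs (stray reflected paths are irrelevant to the flux trend); rays
crossing the retina outside the map window are counted as vignetted so
that the bin sum equals the landed power exactly. The conservation
residual is asserted at $10^{-9}$ relative in every simulation.

### The microstructure

Hole centers form a centered $N \times N$ lattice with period $P$
(`periodic`), or are drawn uniformly in the footprint per layer
(`random`, seeded). The footprint side $N P$ must fit inside the lens
aperture. The distribution area bookkeeping is $(N P)^2 L$, which
reproduces all twelve published configuration areas exactly.

Rays hitting a hole disc are absorbed (`block`, default) or deflected by
a folded-Gaussian polar angle with uniform azimuth (`cone`, default
half-angle 5°), tested independently per layer. The published account
says only that the features "cause scattering" with no phase function,
so blocking is the conservative default and every prediction report
carries the model tag. Note one geometric consequence of coincident
periodic layers: identical lattices block the same rays, so extra layers
add damage only in `random` placement or `cone` mode.

## Seeds and reproducibility

Every stochastic entry point takes an integer seed and restores the
caller's RNG state. Calibration uses one master seed with a fixed
derivation rule per grid point (independent substreams); common random
numbers across curve points are *not* used by default, matching the
"fresh substream" policy, but any simulation can be re-run bit-for-bit
from the seeds recorded in its JSON sidecar.

## Numerical choices

* Paraxial solves propagate reduced vergence ($P = (n_2-n_1)/R$,
  translation $V' = V/(1 - tV/n)$); they agree with an independent
  2×2 ray-transfer-matrix oracle to $10^{-9}$ relative in power and
  $10^{-6}$ mm in image distance, and the far point is solved by
  bisection to $10^{-12}$.
* Sphere intersection picks the quadratic root on the vertex-side cap;
  flat surfaces use the plane formula (radius 0 or `Inf` is flat).
* Curve inversion is monotone piecewise-linear interpolation, exact at
  the grid nodes; normalized flux above 1 or below the deepest
  calibrated value raises a typed out-of-range condition.
* A prediction whose flux deficit is below `detection_k` (default 3)
  Monte-Carlo standard errors of the plano flux is reported
  `indistinguishable` — the quantitative version of the published "—"
  (cannot be distinguished) entries, which state no criterion.
* Non-monotone curves: for the whole chart this is a hard error at the
  configured budget; for sub-regions it is a warning and the curve is
  flagged non-invertible instead of being inverted.

## What the synthetic world does and does not establish

The source generator emulates an idealized, noise-free emissive chart:
exact block glyphs, uniform luminance, single wavelength, no room
illumination, no ocular media scatter other than the configured hole
array, no photoreceptor sampling or neural transfer. A green test
therefore establishes properties of geometric flux transport through
the configured eye — conservation, monotone blur growth, region
nesting, rank orderings — not clinical validity for any real cataract.
The published absolute severities (250–970 centi-diopters) depend on an
undisclosed commercial eye model and scatter physics and are *not*
reproduction targets; only exactly-reproducible arithmetic (the area
table) and qualitative/ordering properties are asserted.

### The severity rank order and the pupil

One ordering property deserves its own account, because the stated
default world does **not** reproduce it. Within the homogeneous
published family D5–D10 (50×50 holes, 2 layers, period 0.07 → 0.02 mm)
the published severities increase strictly as the period shrinks. Under
block physics the expected flux removed by the array is

$$\Delta F \;=\; N^2 \tfrac{\pi}{4} d_h^2 \,\bar\rho(\text{footprint}),$$

with $d_h$ the hole diameter and $\bar\rho$ the mean illumination over
the footprint at the anterior lens. Through the default 4 mm pupil that
illumination is a uniform disc of radius ≈ 1.95 mm (the stop sits
0.05 mm ahead of the lens, so field-dependent offsets at that plane are
below 0.01 mm). Every footprint that fits inside the disc — D7 through
D10, sides 1.0–2.5 mm — therefore removes *identical* expected flux:
the family contains exact statistical ties, and no ray budget or seed
policy can order ties strictly. The corresponding acceptance check is
deliberately left failing rather than weakened, with the analysis
recorded.

The ordering *is* geometrically possible when the beam at the lens fits
inside the smallest (1.0 mm) footprint: the deficit then reduces to the
hole coverage $\tfrac{\pi}{4}(d_h/P)^2$, which grows strictly as $P$
shrinks — 1.6% up to 19.7% across the family. A ~1 mm pupil realizes
this coverage-dominated regime, and a property test ranks the measured
deficits there (Spearman −1 against area, three seeds). The published
strong ordering thus implies an effective beam at the lens of about a
millimeter — far from a photopic 4 mm pupil — or damage physics beyond
geometric blocking; the package exposes the pupil as configuration and
reports which regime a run used. (At such a small pupil the defocus
curve itself becomes too shallow to invert at realistic budgets, which
is why the property test ranks fluxes rather than inverted severities.)

Two further aperture notes of the same kind: the paraxial blur-disc and
centroid oracles are validated at ~1 mm pupils, because paraxial
predictions are small-aperture statements — at 4 mm the preset eye's
spherical aberration (~0.8 D at the margin) inflates the RMS spot at
5 D by roughly 10%, which is aberration physics, not a tracer defect.

### Straylight and sub-region curves

Region-wise calibration masks the source to the region by default,
matching region-wise imaging. The non-monotone sub-region behavior is
attributed, in the published account, to straylight from *outside* the
selected region; the `stray_light = TRUE` option reproduces that
mechanism by keeping the whole chart lit while integrating only the
sub-region ROI. The qualitative regression test freezes one
configuration (rows 2–4, whole chart lit, minimum budget) observed to
produce a flagged non-monotone curve.

## Known limitations

* No accommodation, gradient-index lens, astigmatism or chromatic
  dispersion; one wavelength.
* Flat retina by default; the curved option only changes the detector
  plane, not the optics.
* The corneal periphery (0.6–0.8 mm thick) cannot be represented by a
  single-thickness surface pair; not modeled.
* `random` hole placement allows overlapping holes; expected coverage
  is $1-(1-a/A)^{N^2}$, slightly below $N^2 a/A$, and the tests assert
  the overlap-corrected value.
* Absolute flux units are arbitrary (luminance × area); only normalized
  quantities are comparable across configurations.
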