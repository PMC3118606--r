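---
title: "Thin-shell membrane stress in the vestibular labyrinth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thin-shell membrane stress in the vestibular labyrinth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestress)
```

## The model

The membranous labyrinth of the inner ear is a set of communicating,
endolymph-filled chambers — semicircular canals, their ampullae, and the
utricle — kept inflated by a slight positive transmural pressure. Because
the chambers communicate, they all see the same pressure; what differs
between them is geometry. `vestress` asks the resulting question: given each
chamber's wall thickness, radius of curvature, and shape, how unevenly is
pressure-induced tensile (hoop) stress distributed across the labyrinth?

Each chamber is emulated by a prolate ellipsoid of revolution with
equatorial radius $a$ and polar semi-axis $b \ge a$. Membrane (bending-free)
shell theory gives the peak hoop stress at the equator as

$$t_{hoop} = \mathrm{GSF} \cdot p, \qquad
  \mathrm{GSF} = s \,\frac{r}{w}, \qquad
  s = 1 - \frac{a^2}{2b^2},$$

where $p$ is the transmural pressure, $r$ the radius of curvature, $w$ the
wall thickness, and $s$ the dimensionless shape coefficient. The two limits
of the ellipsoidal continuum are exact: a sphere ($b = a$) has $s = 1/2$ and
a cylinder ($b \to \infty$) has $s = 1$. The cylinder is represented by an
explicit `Inf` sentinel in `ellipsoid_geometry()`, not a large finite
number, so the limit is reached exactly rather than approximately.

Because $p$ is unknown (it need only be slightly positive to keep the
membranes inflated), all pipeline outputs are pressure-free: stresses are
reported per unit pressure, and chambers are compared through the
normalized hoop stress

$$t_n = \frac{\mathrm{GSF}_{chamber}}{\mathrm{GSF}_{reference}},$$

with the reference chamber chosen (under the default `"auto"` rule) as the
one with the smallest mean GSF, so every mean $t_n \ge 1$ and the
reference's is exactly 1.

### Assumptions

* **Membrane behaviour.** Walls carry tension only, no bending. The
  engineering criterion is a thinness ratio $r/w \ge 5$;
  `thin_membrane_check()` flags each chamber and reports an `"approaches"`
  band over $[4, 5)$ so borderline chambers (a canal at 4.4) remain visible
  instead of being silently accepted or rejected.
* **Shared pressure.** All chambers communicate, so normalized stresses
  cancel $p$ exactly.
* **Luminal radii.** Radii are the inner (endolymph-side) values as
  measured in surgery; no midwall correction is applied.
* **Static loading.** Only the resting inflation pressure is modelled, not
  inertial oscillations from head movement, and no material constitutive
  law is invoked — outputs are stress factors, not strains.

## The full meridian profile

`meridian_stress_profile()` generalizes the equatorial formula to any
latitude using the membrane-equilibrium relations for a shell of revolution
with principal radii $r_1$ (meridional) and $r_2$ (normal):

$$\sigma_{merid} = \frac{p\, r_2}{2w}, \qquad
  \sigma_{hoop} = \frac{p\, r_2}{w}\left(1 - \frac{r_2}{2 r_1}\right).$$

Latitude is the parametric (reduced) latitude of the meridian ellipse
$(a\cos t,\ b\sin t)$, in radians, 0 at the equator. At $t = 0$ the hoop
expression collapses algebraically to $p\,(a/w)\,s$, and the test suite
checks this to $10^{-9}$ relative over randomized geometries, with the
principal radii independently verified by finite-difference curvature of
the parametrized meridian. Two classical facts fall out as corollaries and
are asserted as tests: a sphere is isotropic (hoop = meridional, constant in
latitude) and a cylinder's axial stress is half its hoop stress.

```{r meridian}
st <- meridian_stress_profile(ellipsoid_geometry(a = 1, b = 2),
                              w = 0.1, load_condition(1), latitude = 0)
c(hoop = st$hoop, meridional = st$meridional)
```

## Toroidal canals

A semicircular canal is really a torus, and its inner equator is
anticlastic: the two principal curvatures have opposite signs, which raises
hoop stress above the straight-cylinder value. `torus_equatorial_factors()`
returns the hoop multipliers at the inner and outer equators,

$$f_{inner} = \frac{r}{w}\,\frac{2R - r}{2(R - r)}, \qquad
  f_{outer} = \frac{r}{w}\,\frac{2R + r}{2(R + r)},$$

which bracket the cylinder value $r/w$ and converge to it as $R/r \to
\infty$. A 5% inner-equator excess corresponds to a loop radius of eleven
tube radii ($f_{inner}/(r/w) = 21/20$ at $R = 11r$). No toadfish loop
radius has been published, so the package treats the toroidal correction as
an available operation, not as part of the headline table, and no general
anticlastic (hourglass) ellipsoid is modelled — such shapes would need
dimensions that do not exist in the source data.

## The toadfish analysis

The package ships the surgical morphometry of the Oyster toadfish
labyrinth (three chambers, each with mean/max/min wall thickness and radius
in microns) as `toadfish_fixture()` and as a CSV under `inst/extdata/`. The
whole analysis is:

```{r pipeline}
summaries <- normalize_stress(summarize_chambers(toadfish_fixture()))
cat(build_report(summaries), sep = "\n")
```

### Numerical and display conventions

* **Display rounding.** Printed tables round half away from zero at one
  decimal. The displayed $t_n$ divides each chamber's unrounded mean GSF by
  the reference mean GSF *rounded to one decimal* (the convention under
  which published tables of this kind are internally consistent:
  $6.0086/4.4 \to 1.4$, $17.375/4.4 \to 3.9$, whereas the fully unrounded
  utricle ratio, 3.9617, would display as 4.0). Both scales are exposed —
  `t_n_*` columns carry full precision, `t_n_*_display` the printed
  convention — and full precision is always used for further computation.
* **Extreme pairings.** Individual $(r, w)$ pairs are not published, only
  per-chamber extremes, so the stress envelope pairs $r_{max}$ with
  $w_{min}$ (maximizing) and $r_{min}$ with $w_{max}$ (minimizing). These
  are envelope bounds, not observed individuals.
* **Individual disparity.** The largest individual-envelope stress can be
  referred either to the reference chamber's mean GSF (≈ 7.5-fold here) or
  to its minimum-pairing GSF (≈ 10.4-fold). Both conventions are defensible
  and give materially different numbers, so `extremes_analysis()` and the
  text report surface both rather than asserting one.
* **Degenerate inputs.** Zero-variance measurements (min = mean = max) are
  valid and propagate to a splay-free table; zero wall thickness, negative
  lengths, oblate ellipsoids (unless `allow_oblate = TRUE`) and
  $R_{loop} \le r_{tube}$ tori are rejected with errors naming the chamber
  and field.

## The synthetic cohort generator

`generate_cohort()` emulates the variability structure that a morphometry
table summarizes: per-individual $(w, r)$ draws within each chamber's
recorded (min, max) range, collapsed by `cohort_to_measurements()` into the
same mean/max/min summary the real table reports. Defaults are chosen once
to mirror the source conditions: uniform sampling over the recorded ranges
(only ranges are published, so uniformity is the least-informative choice),
independent draws within and across chambers (no covariance information
exists), and 12 individuals (the lower end of the 12–25 measurements from
3–5 fish behind the real table). A truncated normal is available for
sensitivity checks. A single integer seed governs the cohort; per-chamber
substreams are derived deterministically from it, so cohorts are
bit-reproducible and adding a chamber does not perturb the others' draws.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: correlation between wall thickness and radius within
an individual, left/right asymmetry, measurement error, or growth. One
consequence is tested explicitly: the table convention (ratio of means,
$\bar r/\bar w$) systematically underestimates the mean per-individual
stress factor $s\,\mathbb{E}[r]\,\mathbb{E}[1/w]$ when $w$ varies, by
Jensen's inequality; the pipeline follows the table convention because that
is what the source data support.

```{r cohort}
spec <- cohort_spec(toadfish_chamber_specs(), n_individuals = 12, seed = 42)
head(generate_cohort(spec)$draws, 3)
```

## Problem sizes used in the test suite

Property tests run 1,000 randomized geometries for the equatorial
specialization, 20–50 randomized measurement sets for normalization and
round-trip invariants, and Monte-Carlo cohorts of $10^4$–$10^5$ draws for
distributional checks against closed-form uniform moments (3-standard-error
bands). These sizes make the statistical assertions sharp at desk scale;
the deterministic assertions are size-independent.

## Limitations

* Results are stress *factors*; absolute stresses require a transmural
  pressure that has not been measured.
* The analysis is cross-sectional over summary statistics; no inference
  across fish is possible without per-individual raw data.
* The cylinder model of the utricle uses its narrowest point; hourglass
  (anticlastic) regions would carry higher stress than reported.
* Fixation-corrected archival material would need a contraction correction
  that this package does not implement.
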