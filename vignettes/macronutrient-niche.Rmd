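---
title: "Macronutrient niche analysis in the right-angled mixture triangle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macronutrient niche analysis in the right-angled mixture triangle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmtniche)
```

## The model

Nutritional geometry treats a diet not as a list of foods but as a point in
macronutrient space. `rmtniche` implements the scat-based variant of this
analysis used in wildlife nutritional ecology:

1. **Energetics.** Each food's proximate composition — crude protein (CP),
   ether extract (EE, crude fat) and available carbohydrate (AC, estimated
   by difference as 100% minus ash, CP, EE, moisture and crude fiber) — is
   converted to metabolizable energy with the standard factors 4 kcal/g
   (protein, carbohydrate) and 9 kcal/g (lipid), and expressed as
   percentages of total macronutrient-derived energy. A food's profile is
   the triple $(P, L, C)$ with $P + L + C = 100$:
   $$P = \frac{100 \cdot 4\,\mathrm{CP}}{T},\quad
     L = \frac{100 \cdot 9\,\mathrm{EE}}{T},\quad
     C = \frac{100 \cdot 4\,\mathrm{AC}}{T},\qquad
     T = 4\,\mathrm{CP} + 9\,\mathrm{EE} + 4\,\mathrm{AC}.$$
   Crude fiber, ash and moisture contribute no macronutrient energy; the
   conversion is invariant to rescaling the three masses jointly, so it does
   not matter whether CP/EE/AC are reported on a dry-matter or as-fed basis
   as long as they share one.

2. **Diet mixing.** A group's diet table gives each identified food's
   percent relative frequency (RF%) from pooled microhistological scat
   analysis, plus an unidentified remainder. Mixing weights renormalize RF%
   over identified items ($w_i = \mathrm{RF}_i / \sum_j \mathrm{RF}_j$),
   and the **realized macronutrient niche** (the diet point) is the
   weighted mean of the food profiles — a convex combination, so it always
   lies inside the convex hull of its foods.

3. **Niche breadth.** Profiles are plotted in the right-angled mixture
   triangle (RMT): two macronutrients are explicit x/y axes and the third
   is implicit as $100 - x - y$. The macronutrient niche breadth of a group
   is the area of the convex hull around its food points, and breadth is
   compared between groups as the ratio of hull areas (a relative effect
   size, reported as larger/smaller).

## Tunable parameters

* `energy_conversion(protein = 4, lipid = 9, carbohydrate = 4)` — kcal/g
  factors. The 4/9/4 defaults are the standard (Atwater-type) factors;
  digestibility-corrected sets can be substituted, which changes profiles
  and everything downstream (that sensitivity is itself a useful check:
  `reproduce_reference(conversion = energy_conversion(lipid = 4))` flags
  non-reproduction, confirming the harness can fail).
* `axes` in `to_rmt()` / `niche_analysis()` — which two macronutrients are
  explicit. Defaults to x = carbohydrate, y = protein (lipid implicit),
  the natural choice for herbivore-dominated, high-carbohydrate diets.
  Hull areas are provably identical for all three axis choices (dropping
  any one coordinate of the plane $P+L+C=100$ scales in-plane areas by the
  same factor $1/\sqrt{3}$), so only plot cosmetics depend on it; the test
  suite asserts this invariance on random profile sets.
* Tolerances in `reproduce_reference()`: `tol_pct = 0.1` on percentage
  quantities and ratios, `tol_sdcv = 0.02` on SDs and CVs. Computed values
  are first rounded half-up to the precision at which the reference table
  reports them; the tolerance then absorbs the rounding path of the
  upstream inputs (RF% and proximate values are printed at 1–2 dp).

## The bundled dataset

The package bundles the diet (RF%) and proximate tables for Asiatic black
bear (*Ursus thibetanus*) in two Nepalese study areas — the Dhorpatan
Hunting Reserve (DHR) and the Kailash Sacred Landscape (KSL) — in summer
and autumn (fixtures `dhr_summer`, `dhr_autumn`, `ksl_summer`,
`ksl_autumn`; 209 scats in total). Ants and termites in the DHR diets were
not assayed; their profiles are literature energy-proportion constants
(37.7P:45.8L:16.4C and 26.8P:55.9L:17.3C), renormalized to sum exactly
100. The DHR-summer diet includes fern (*Matteuccia struthiopteris*) but
the DHR proximate table has no fern record, so `bear_profiles("dhr_summer")`
substitutes the KSL-summer record of the same species and flags it in the
`substituted` attribute; with this substitution the DHR-summer diet point
recomputes to its reported value exactly.

```{r}
reproduce_reference()[1:6, ]
```

## Design choices

Several choices were genuinely open and are fixed as follows:

* **Pooling is unweighted.** The overall diet and the seasonal/study-area
  group means are unweighted means of diet points; scat counts are carried
  as metadata only. The scat-weighted alternative is inconsistent with the
  reference results the bundled dataset reproduces (e.g. it shifts pooled
  protein from 20.2 to 19.5), and an unweighted mean treats each
  study-area/season as one observation, which matches how the groups were
  formed.
* **SD uses the sample (n−1) denominator**, so a two-point group has
  $\mathrm{SD} = |a-b|/\sqrt{2}$; CV = SD/mean. Both are computed from
  unrounded diet points — rounding first breaks the 2-dp SDs.
* **Profiles are carried unrounded** end to end; half-up rounding to 1 dp
  (2 dp for CV) happens only at display/report time.
* **Hull contract.** Andrew's monotone chain, with collinear points
  interior to an edge excluded, vertices ordered counter-clockwise from the
  lexicographically smallest — a deterministic, minimal vertex set. Area is
  the shoelace formula; degenerate inputs (fewer than three distinct
  points, or all collinear) yield a flagged zero-area hull, and breadth
  ratios over degenerate hulls are an error rather than an Inf/NaN.
  Hulls are built around the identified-food points only; the diet point is
  plotted but never enters its hull, and the unidentified fraction has no
  coordinates to contribute.
* **Insect constants are stored as energy proportions**, not synthetic
  proximate rows, because that is the form in which they exist.

## The synthetic-data generator

`simulate_scenario()` emulates the *structure* of the real inputs so the
pipeline is testable with known ground truth: food profiles drawn from a
Dirichlet law (default concentration (2, 2, 2), a realistic spread for
plant foods across the simplex; the bundled foods span a comparable
range), RF weights from a symmetric Dirichlet, a fixed unidentified
fraction (default 0.05, inside the 1.6–5.4% range of the bundled tables),
and RF% rounded to 1 dp with largest-remainder repair so synthetic tables
satisfy the same "totals 100" invariant as printed ones.
`gen_proximate_from_profile()` inverts the energy conversion exactly — it
solves for CP/EE/AC masses under a moisture/ash/fiber budget — and takes
no seed because the inverse is deterministic.

What the generator does **not** emulate: scat-level multinomial sampling
and fragment counting (RF% appears only as the already-pooled table),
differential digestibility between foods, assay noise in proximate
chemistry, and any correlation structure between a food's profile and its
RF%. Passing recovery tests therefore show that the pipeline's arithmetic
is right and stable under table rounding (truth diet points are recovered
within ~0.15 per component, the propagated bound of 0.05-unit RF
rounding), not that field RF% is an unbiased intake estimator — no fecal
correction factors are applied anywhere, matching the design of the
bundled analysis.

Problem sizes used in the tests (scenario recovery over 200 seeds with 6
foods, hull oracles on up to 12 random points, 100-seed breadth power
check at a 4-fold concentration contrast) keep every property exercised
while the whole suite runs in seconds.

## Limitations

* RF% is a fragment-frequency measure, not a mass or energy intake
  measure; diet points inherit that bias.
* Composite proximate samples give one record per food/area/season, so no
  within-food variance propagates into the diet points; group SDs describe
  spread between diet points only.
* Niche breadth as hull area is sensitive to single extreme foods (the
  insect profiles drive most of the DHR/KSL contrast) and does not account
  for point density inside the hull; hull-overlap metrics and
  kernel-density niche estimators are deliberate non-goals.
* With two diet points per group, SD and CV are extremely coarse; they are
  reported because the reference table reports them, not because they are
  powerful statistics.
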