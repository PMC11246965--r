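---
title: "Species-change scenarios and ecosystem services on forest inventory plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-change scenarios and ecosystem services on forest inventory plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestadapt)
library(dplyr)
```

## The problem

Climate change is shifting the climatic envelope of the main stand-forming
tree species of Central European forests. Where a species that dominates a
stand today will no longer find suitable climate by the end of the century,
it is expected to fail to regenerate and to disappear locally. What happens
to the ecosystem services that stand provides — timber production,
tree-species richness, and, on mountain terrain, protection against
avalanches and rockfall — depends on what takes its place: nothing, another
native species, or a non-native tree species (NNT).

`forestadapt` implements this question as a deterministic, rule-based
pipeline at the level of forest-inventory centroids (survey sites of up to
four subplots, aggregated). The inputs are (1) a plot table with per-species
stand shares, stand volume over bark, terrain and environmental-zone
attributes; (2) per-species probabilities of occurrence for a historical
reference period and future periods under two forcings (RCP 4.5 and
RCP 8.5), typically taken from ensemble species distribution models (SDMs);
and (3) a registry of 15 stand-forming taxa — six native entries (the two
white oaks merged as *Quercus* spp.) and nine NNT — with per-species
parameters. SDM fitting itself is out of scope: the package consumes
probabilities, it does not produce them.

## From probability to suitability

Each species has a cut-off threshold (percent). A species is *climatically
suitable* at a plot when its probability of occurrence reaches the cut-off;
below the cut-off it is treated as absent. Equality counts as suitable: the
convention is that values *below* the threshold are zeroed, and `>=` is the
complement of that rule. *Relative suitability* is probability divided by
cut-off, so 1 marks the threshold for every species, and it is the ranking
key used to choose replacement species. "Relative to the cut-off" could
also be read as a difference; we use the ratio and expose a difference mode
(`relative_suitability(mode = "difference")`, affine so that the unit point
at the threshold is preserved) because the two only differ in cross-species
ranking, not in the suitable/unsuitable decision.

Inventory composition does not separate *Quercus petraea* from
*Q. robur*, so their SDM outputs are merged per plot and period by taking
the higher probability and judging it against the merged *Quercus* spp.
cut-off; the winning species is retained as provenance. A missing
probability (plot outside a raster) is treated as 0, i.e. unsuitable — the
conservative choice — and flagged rather than raised as an error.

## The five species-change scenarios

A species occurring today but unsuitable in the chosen future period is a
*failing* species: it vacates its growing space. The scenarios differ in how
that space is filled:

| label | pool | rule |
|---|---|---|
| `no_adaptation` | residents only | vacated share goes to surviving suitable residents, proportionally to their current shares; if none survives the plot is unstocked |
| `native_mss` | 6 native taxa | most suitable species (highest relative suitability) |
| `combi_mss` | all 15 taxa | most suitable species |
| `native_ccbb` | 6 native taxa | conifer-for-conifer / broadleaf-for-broadleaf, falling back to the overall most suitable when no same-form candidate is suitable |
| `combi_ccbb` | all 15 taxa | same, with NNT allowed |

Design choices where the rules left room:

* **One receiver per failing species.** The rule selects *the* most
  suitable species — singular — so shares are transferred whole, not split
  across several receivers.
* **Receivers may already be present** — their shares merge. This is what
  allows, e.g., oak frequency to rise under adaptation.
* **A species never replaces itself**, and failing species cannot receive
  (they are unsuitable by definition).
* **Ties** in relative suitability are broken by higher standardized
  increment, then lexicographic species code — an arbitrary but
  deterministic and reproducible order.
* **CC/BB is strict form-first**: any suitable same-form candidate
  pre-empts a better other-form candidate; no suitability margin is
  applied before switching form.
* **Volume.** Under `no_adaptation` the stand volume is reduced by the
  failing species' share of the composition: an unadapted stand simply
  loses that timber. Under the adaptation scenarios share and volume travel
  together to the receiver, so volume is conserved whenever every failing
  species finds one. This split is what makes rockfall protection (a pure
  volume rule) deteriorate only without adaptation while composition-based
  services still change under adaptation.
* **Vacated composition under `no_adaptation`** is redistributed over the
  surviving residents proportionally to their shares (the
  minimal-assumption reading of "replaced by species which already occur");
  a `redistribution = "drop"` switch leaves the space vacant instead,
  because the volume rule above can also be read that way. The default
  couples redistributed composition with reduced volume.

All scenario machinery is deterministic given its inputs; there is no
randomness outside the synthetic generator.

## Service scoring

* **Production.** Each species has a mean annual increment (m³ over bark
  ha⁻¹ yr⁻¹) standardized by the arithmetic mean over all 15 taxa
  (standardized value 1 corresponds to about 12.6 m³ ha⁻¹ yr⁻¹). The
  printed standardized column of the registry is canonical — recomputing
  increment/mean reproduces it only to about ±0.03, and downstream
  category edges are defined on the printed values — while
  `standardize_increments()` serves user-supplied increment sets. A plot's
  production value is the *unweighted* mean of the standardized increments
  of the species present — averaging over species, not shares, treats a
  stand as characterized by what can grow there; a share-weighted mode is
  available. Categories: high > 0.78,
  low < 0.63, moderate in the closed band between — edges anchored on the
  two highest- and two lowest-increment native species.
* **Richness** is the count of registry taxa with share > 0 (merged oaks
  count once). **NNT share** is the non-native share divided by the total
  stocked share, so partial stocking does not dilute it.
* **Avalanche protection** is only assessed on release-capable terrain:
  altitude above 800 m and slope 25–60°. Risk is driven by the share of
  wintergreen (evergreen) species, whose winter canopy intercepts snow,
  with stand volume as a stocking proxy: volume ≤ 100 m³/ha means a
  not-fully-stocked stand and is high risk regardless of composition
  (the "or" in the rule table gives the volume clause precedence);
  otherwise wintergreen share ≥ 70% is low risk, ≤ 40% high, and the
  remainder moderate. The printed bands leave gaps (40–41%, 69–70%); we
  close them by making the low-risk bound inclusive (≥ 70) and leaving the
  high-risk bound as printed (≤ 40), since the prose uses "equal or above
  70%". The wintergreen proportion is share-based (volume-based was the
  alternative; shares are what the scenarios manipulate). Wintergreen
  membership comes from the registry's evergreen flag, so a planted
  non-native evergreen counts; `native_wintergreen_only = TRUE` restricts
  to the three named native wintergreens (spruce, silver fir, Scots pine —
  larch is the registry's only deciduous conifer). Evergreen flags for the
  nine NNT are not specified by the source procedure; the default registry
  freezes the botanical reading (all NNT conifers evergreen, all NNT
  broadleaves deciduous), configurable per species via a registry override.
* **Rockfall protection** is assessed only inside mapped rockfall hazard
  zones (an input flag): volume ≥ 360 m³/ha low risk, ≤ 180 high, between
  moderate; the same gap-closure convention applies.
* **Unstocked plots** score production 0 (low), richness 0, NNT share 0,
  and high risk for both protective services — a bare slope protects
  nothing — keeping every category partition total.
* **Change versus current** is reported as a sign (−1/0/+1) on the
  service's ordinal scale (risk ordered high < moderate < low) and, for
  volume-based services, as percent of current volume (undefined and
  flagged when current volume is 0 and the scenario volume is not).

## The synthetic study region

The inventory data the analysis was designed around is confidential, so the
package ships a seeded generator that emulates its statistical structure;
every full-pipeline check in the package runs on this synthetic region.
Defaults are frozen design choices, not tuning knobs:

* **1423 / 1448 / 150 survey sites** in the Alpine-South, Continental and
  Pannonian zones, four subplots each, aggregated to centroids with mean
  (shares, volume) and median (altitude, slope); about 3.7% of sites carry
  none of the 15 taxa and are dropped during aggregation, mirroring the
  117-of-3141 exclusion rate of the real inventory.
* **Terrain** is drawn from zone-specific normals (Alpine ≈ 1250 ± 400 m,
  30 ± 10°; Continental ≈ 600 ± 250 m, 15 ± 8°; Pannonian ≈ 250 ± 80 m,
  3 ± 2°), chosen so that the avalanche-eligibility filter retains roughly
  29% of centroids (almost none of them Pannonian) and so that
  zone-specific rockfall hazard-zone probabilities (0.30 / 0.07 / 0)
  give roughly 17% of centroids in rockfall zones — the proportions of the
  protective-service subsamples in the emulated study design.
* **Composition**: one to four native species per site, weights zone-
  specific (spruce-dominant uplands, oak-dominant Pannonian), shares from a
  Dirichlet draw; with zone-specific probability a site additionally
  carries one NNT whose total share is a Beta draw. Presence probability ×
  mean share equals the configured current NNT-share target — about 1% in
  the two upland zones and 16% in the Pannonian — so the target is the
  exact expectation and parameter recovery is a well-posed unbiasedness
  check. Stocking multiplies all shares by a Beta(20, 1.5) factor
  (mean ≈ 0.93), leaving some stands partially stocked.
* **Volume** is lognormal with mean 360 m³/ha (sdlog 0.7), truncated at
  1700 — right-skewed with the documented range and mean of the emulated
  volumes.
* **Suitability** is mechanistic, not resampled: each species occupies an
  altitude band (rising and falling logistic edges, 150 m scale) with a
  peak probability; under climate impact (0 historical, 1 for RCP 4.5,
  2 for RCP 8.5) the lower edge retreats uphill by a per-species `ret`
  (decline) and the upper edge advances by `adv` (expansion). Spruce, pine
  and beech retreat strongly; the oaks and several NNT expand upward. The
  construction makes the monotonicity properties provable: impact 0
  reproduces the historical table exactly, and raising `ret` can only
  lower future probabilities (noise is drawn once per plot × species,
  shared across periods, and clamping to [0, 100] preserves the ordering).
  Rarely-planted NNT get peak probabilities below or near their (high)
  cut-offs, so they stay rare, as in the emulated region.

What the generator does **not** emulate: spatial autocorrelation of real
forests, real bioclimate fields, stand age and structure, management
history, and any correlation between composition and suitability beyond
altitude. Passing cohort-level checks therefore demonstrates that the
*rules* behave as designed under realistic marginals, not that national
result tables are reproduced.

## Problem sizes and numerical conventions

Full-pipeline checks use one default-size cohort (~3000 centroids, 16
species × 3 periods of suitability) and both future periods; rule-level
checks use exhaustive grids (risk bands over wintergreen share × volume)
and ~1000 randomized micro-plots compared against an independent
exhaustive oracle implementation of the replacement rules. All randomness
is seeded; scenario application itself is deterministic. Share vectors in
outcomes are kept in alphabetical code order; equality at every category
or threshold edge is resolved as documented above (suitable at the
cut-off, moderate at 0.78, high risk at 100/180 m³, low risk at 70%/360 m³).

## Limitations

Single-step replacement: no temporal dynamics between now and the end of
the century, no regeneration, competition or invasion-risk modelling, and
increments are static species constants (no site effects, no growth
response to climate). Protective-service rules are volume- and share-based
proxies; stem density, diameters, stand age and canopy cover are not
modelled. These mirror the scope of the procedure the package implements;
extending them would change the science, not just the code.
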