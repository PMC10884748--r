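---
title: "Estimating basic wood-density from increment cores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating basic wood-density from increment cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corewood)
```

## The problem

Basic wood-density — oven-dry mass per green (water-saturated) volume,
in g/cm³ — is the quantity used to convert tree volumes into biomass and
carbon stocks. Increment-borer cores taken in a national forest
inventory are, in practice, measured in the herbarium months later, at
ambient humidity: the green volume was never observed. Because wood
below its fiber-saturation point shrinks as it dries, ambient mass over
ambient volume is not basic density, and a model is needed to convert
one into the other.

`corewood` implements that conversion and everything around it: the
per-sample laboratory chain, schema validation and summaries for the
inventory tables, species-level aggregation and classification, a
forward-model synthetic-data generator used to verify the pipeline end
to end, and attribute-level tabulation of forest-vegetation provinces.

## The shrinkage model

Let $G_b$ be basic specific gravity (basic density relative to water),
$w$ the water content as % of oven-dry mass, and $D_w$ the density
measured at water content $w$. Regression of total volumetric shrinkage
on basic specific gravity, averaged over softwoods and hardwoods, gives
a slope $s = 0.265$ through the origin. Below the fiber-saturation
point (taken as $w_{fs} = 30\%$), a sample has shrunk in proportion to
how far below $w_{fs}$ it has dried:

$$
D_w \;=\;
\begin{cases}
\dfrac{G_b\,(1 + w/100)}{1 - s\,G_b\,\frac{30 - w}{30}} & 0 \le w \le 30,\\[2ex]
G_b\,(1 + w/100) & w > 30.
\end{cases}
$$

The two branches agree at $w = 30$, so the model is continuous in $w$.
With $D_b = G_b\,\rho_{water}$ (here $\rho_{water} = 0.9982$ g/cm³ at
20 °C), solving the first branch for $D_b$ gives the closed form

$$
D_b \;=\; \frac{300\, D_w\, \rho_{water}}
{3w + 300\,(1 + s\,D_w) - 10\, s\, D_w\, w},
$$

which is what `basic_from_ambient()` evaluates.

### The two numerator modes

At the default constants, $300\,\rho_{water} = 299.46$; written over a
30000-unit denominator the numerator constant is 29946. The formula as
commonly printed instead carries **29466** — an apparent digit
transposition — and its worked example ($D_b = 0.409$ g/cm³ at
$D_w = 0.5$, $w = 12$) reproduces only with 29466. Both conventions are
therefore implemented:

* `numerator_mode = "as_published"` (default): the printed constant, so
  published and deposited values reproduce;
* `numerator_mode = "derivation_consistent"`: the algebraically exact
  constant.

The two differ by the constant factor $29466/29946 \approx 0.9840$ for
every input, which the test suite asserts.

```{r modes}
basic_from_ambient(0.5, 12)  # printed convention
basic_from_ambient(0.5, 12,
  conversion_params(numerator_mode = "derivation_consistent"))
```

### The two moisture models

The closed form is derived from the shrinkage branch, which is only
physically meaningful below fiber saturation. The procedure as usually
applied evaluates it over the whole observed 0–200 % moisture range
(`moisture_model = "uniform_closed_form"`, the default). The
alternative, `"piecewise_fiber_saturation"`, inverts the no-shrinkage
branch exactly for $w \ge 30$: $D_b = \rho_{water} D_w/(1 + w/100)$.
The generator's bias test documents the consequence of the uniform
choice: for samples above fiber saturation the uniform closed form
overestimates basic density, increasingly so with $w$.

A subtlety worth stating: the forward map treats $G_b$ numerically as a
density in g/cm³ (its exact inverse image is
$D_w = D_b(1+w/100)/(\rho_{water}\cdot shrink)$), so the synthetic
generator emits dry masses as $G_b V_{green}$; the recovered basic
density is then exactly $G_b\,\rho_{water}$. The ≈0.18 % gap between
that convention and literal mass-based physics is inherent to the
published model, not to this implementation.

## The laboratory chain

`process_core_samples()` mirrors the measurement protocol: core length
by caliper (0.01 mm precision), two perpendicular diameters around the
nominal 0.508 cm bore (cores deform slightly on drying, so the
cross-section is treated as an ellipse, $V = d_{min} d_{max}\pi l/400$),
ambient mass and 105 °C/48 h oven-dry mass on a 0.001 g balance, then
$D_w = m_1/V$, $w = 100(m_1-m_2)/m_2$, and the conversion above.
Instrument precisions are treated as metadata, not enforced rounding.

Rows are screened before computation. Mathematically invalid readings
(non-positive dimensions, $m_1 < m_2$) and rows outside plausibility
windows are rejected with a recorded reason, never silently dropped.
The windows — diameters in (2.5, 8.0) mm, lengths in the observed
0.56–26.99 cm range widened by 10 % — describe one inventory rather
than physical limits, which is why they reject rows instead of raising
errors, and why `validate_derived()` applies the same widened-range
policy to derived quantities.

## Species-level aggregation

Within-species density distributions can be highly asymmetrical, so the
species-level statistic is the median (`species_medians()`). Medians
are classified at 0.4 and 0.75 g/cm³ into light, medium and heavy wood;
since the verbal definition of those bounds is ambiguous exactly at the
thresholds, the package fixes half-open intervals
$[0, 0.40)$, $[0.40, 0.75)$, $[0.75, \infty)$ and makes them
configurable, so the convention can be flipped if a reference dataset
demands it. Rankings (`extreme_species()`) break ties alphabetically.

`variance_partition()` splits total density variance into among- and
within-species components with method-of-moments one-way random-effects
ANOVA, using the unbalanced-design correction
$n_0 = (N - \sum n_i^2/N)/(k-1)$ and truncating negative among-species
estimates at zero; only species with ≥ 2 samples enter, because
singletons carry no within-species information. No reference method is
prescribed for this quantity, so the choice was made for robustness on
heavily unbalanced designs; the tests cross-check the mean squares
against `stats::aov()` and the resulting split against a REML fit
(`lme4`), and verify by simulation that a known 69/31 among/within
split is recovered within ±3 points on a 200-species × 5-sample design
and essentially without bias over 100 replicates.

## The synthetic-data generator

`generate_core_dataset()` and `generate_site_dataset()` are first-class,
seeded generators that emulate the marginal structure of the inventory
tables:

* species basic specific gravity: truncated normal, mean 0.53, sd 0.14
  on (0.05, 0.95) — matches the deposited mean and range without
  asserting the true distribution shape;
* samples per species: zipf-like law, exponent 1.7 capped at 177
  (median 2, mean ≈ 6.4);
* within-species coefficient of variation 0.17, calibrated so that
  about 69 % of total variance lies among species under the gravity law
  above;
* eliminated moisture: gamma (shape 4, scale 2.44) truncated at 95 %,
  median ≈ 9 %;
* core length: log-normal around a 6.11 cm median within
  0.56–26.99 cm; borer bore 0.508 cm with a volume-preserving elliptic
  deformation of the dried cross-section;
* instrument noise (off by default): additive balance noise sd 0.001 g
  and caliper noise sd 0.01 mm;
* sites: uniform in the continental bounding box (lat 14.5–32.5, lon
  −116.6 to −86.8), trees per site zipf-like with exponent 1.6 capped
  at 33 (median 2), heights/diameters log-normal within 1–42 m and
  3–421 cm, jointly missing for 7.4 % of trees.

Truth (per-sample gravity, green volume, species) is retained next to
every emitted measurement, so the pipeline can be verified: with zero
noise and matching conversion modes, processing recovers
$G_b\,\rho_{water}$ to machine precision; with the stated instrument
noise, the median absolute density error stays below 0.01 g/cm³.

What the generator does **not** emulate: real taxonomy (names are
deterministic placeholders), spatial structure of species
distributions, climate covariates, within-tree radial gradients, or
heartwood/sapwood differences. Passing tests therefore demonstrate the
correctness of the computational chain under the stated laws, not the
field realism of any particular dataset.

## Provinces

The province module is attribute-level only: polygon dissolves and
intersections are an upstream GIS step. `load_category_mapping()`
enforces a total mapping from land-use/vegetation categories onto seven
major forest-vegetation types plus "Other surfaces";
`make_province_name()` joins a major type and one of the 15 mainland
floristic provinces with a hyphen, refusing "Mangrove and wetland
forest" (water dominates its floristic composition) and "Other
surfaces"; `tabulate_province_areas()` sums duplicate pairs, reports
excluded types in a remainder table so totals reconcile to the
continental area (default 1,954,658 km²), and recomputes relative
areas. Spanish output names are package-supplied translations.

## Numerical choices

* Bisection oracle: bracket $(10^{-6}, 1.6)$ on $G_b$, tolerance
  $10^{-10}$, max 200 iterations; kept independent of the closed form
  so the two can check each other.
* Water density: anchor table at 0, 4, 20, 30, 40 °C with linear
  interpolation; exact at the 4/20/30 °C anchors used in practice.
* Piecewise override applies from $w \ge w_{fs}$ inclusive, so the
  fiber-saturation boundary itself is the exact no-shrink inverse in
  both numerator modes (in derivation-consistent mode the two branches
  coincide there anyway).
* Medians interpolate the two central order statistics for even counts.
* $w = 0$ is a valid oven-dry measurement:
  $D_b = \rho D_w/(1 + s D_w)$.
* Display rounding (3 decimals for densities, 1 for percentages) is
  applied only in reports; computation is at full precision.

## Problem sizes used in verification

The suite runs the oracle agreement at 1,000 random conversion points,
zero-noise recovery at ≈450 samples, noisy recovery at ≥600 samples,
the variance-partition recovery at 200 species × 5 samples plus a
100-replicate unbiasedness simulation, and the site generator at
≈6,000 trees — sizes at which every stochastic check is stable under
its fixed seed while the full suite stays fast enough to run on every
change.

## Limitations

The conversion inherits the published model's assumptions: a single
average shrinkage slope (no species- or anatomy-specific values), a
universal 30 % fiber-saturation point, and linearity of shrinkage in
specific gravity. The printed-constant mode intentionally reproduces a
formula whose constant disagrees with its own derivation by 1.6 %; which
constant produced any given deposited value cannot be verified from the
published text alone. The province module performs no geometry, and the
generator makes no claim of spatial or taxonomic realism.
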