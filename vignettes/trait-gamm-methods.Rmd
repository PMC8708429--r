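---
title: "Trait-based analysis of phytoplankton monitoring data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based analysis of phytoplankton monitoring data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Summertime coastal phytoplankton monitoring produces taxon-by-sample
counting tables: for every sample, the counting units observed under the
microscope (cells, colonies, coenobia, chains, 100 µm filament pieces),
their abundance, biovolume and wet-weight biomass. `planktraits`
re-expresses such tables in terms of morpho-functional traits — the
potential for atmospheric N~2~ fixation, mixotrophy, motility, buoyancy,
harmfulness, and cell size — and models how trait-specific biomasses and
their shares of total biomass relate to environmental gradients
(surface temperature, salinity, water transparency, stratification, total
phosphorus, nutrient loading source type) across nested survey designs
(stations inside water bodies inside sea areas). Because traits transcend
local taxonomy, such summaries are candidates for status indicators that
transfer across salinity gradients and regions.

The workflow is: trait table → exclusion filters → trait resolution →
response matrix + morphometrics → hydrographic covariates → one additive
mixed model per response → Tukey-adjusted regional contrasts. A
hierarchical simulator with known ground truth makes every stage testable
without access to monitoring databases.

## Trait resolution

Each taxon record carries binary *potential* flags (the organism can fix
N, can swim, ...), a group (cyanobacteria vs eukaryote), and an optional
exclusion category. Records identified above species level are treated as
potential carriers of a trait when any member species in the table carries
it (a logical OR). Named exceptions override the OR rule and are stored in
the table itself (`override_note`, e.g. `buoyancy=0`), not in code: the
shipped examples are non-buoyant *Snowella* spp., non-harmful
*Amphidinium* spp., harmful *Anabaena* spp. and *Aphanizomenon* spp., and
the harmful order Prymnesiales (resolved at order rank directly, without
member enumeration). Taxa absent from the table fail loudly — defaulting
silently to "no trait" would bias every share downwards.

Harmfulness is split three ways (harmful cyanobacteria, harmful
eukaryotes, non-harmful) because bloom-forming cyanobacteria are a
systematically coherent group in brackish summer communities while other
harmful taxa are scattered across lineages.

## Exclusion filters

Heterotrophs, akinetes, heterocytes, cysts, mainly benthic/littoral taxa,
single-celled picoplankton and *Synechococcus* are removed before any
aggregation; inverted light microscopy of Lugol-preserved samples cannot
enumerate the last two reliably. *Anabaena* records are retained because
that name was historically applied to pelagic *Dolichospermum*. Exclusion
is driven entirely by the table's `excluded_category` column — no name
heuristics — and the filter reports counts removed per category.

## Size traits

The small/large classification applies to the *counting unit*: a colony
of 2 µm cells with a 40 µm maximum dimension is large. The boundary is
inclusive at 10 µm. The equivalent spherical diameter treats each cell as
a sphere: with per-cell biovolume $V$,
$ESD = (6V/\pi)^{1/3}$, and the sample statistic is the cell-count
weighted mean $aveESD = \sum_i n_i d_i / \sum_i n_i$ over taxa. When
`cells_per_unit` is missing the only fallback is an explicit per-taxon
defaults table; there is no literature lookup chain at run time. Cells
recorded with zero biovolume contribute no ESD; whether their cells count
in the denominator is a documented toggle (default: they do, with a
warning), since silently dropping them would shift the statistic.

## Hydrography

Surface-layer means of temperature, salinity and TP are unweighted
averages over 0–10 m (the whole column at stations shallower than 10 m).
Density uses the EOS-80 one-atmosphere polynomial (pure-water term plus
salinity correction); the pressure term is irrelevant at coastal depths.
The implementation reproduces the published check values 999.96675
kg m^-3^ (5 °C, 0 psu) and 1027.67547 kg m^-3^ (5 °C, 35 psu). No
independent equation-of-state package is available in the test
environment, so the oracle in the tests is those published values plus an
independently transcribed Horner-form evaluation of the polynomial.

The stratification index is
$E = (\sigma_{bottom} - \sigma_{surface}) \times 1000 / depth$,
with the bottom density taken from the deepest joint temperature/salinity
measurement and `depth` the depth of that measurement (not the charted
bottom). The ×1000 scaling is kept as conventionally printed and the unit
is carried opaquely. $E$ may be negative for unstable columns.

Water bodies are classified into five loading source types from the
dominant (argmax) N and P loading source: (1) N+P offshore, (2) N river /
P point, (3) N river / P offshore, (4) N+P river, (5) N river /
P sediment. Ties and combinations outside the enumeration raise errors
rather than being silently assigned — the typology presupposes clear
dominance.

## Responses and transformation

For each binary trait the per-sample biomass of carriers and of
non-carriers, and their shares of total biomass, are computed, plus the
two size classes, the three-way harmfulness partition and aveESD — 27
responses in total. Shares are kept as fractions internally. Complementary
pairs partition the total exactly; the tests enforce 10^-9^ µg L^-1^ on
biomass sums and 10^-12^ on share sums.

Biomass-type responses are strongly right-skewed, so each response is
Box–Cox transformed before modeling: the exponent maximizes the profile
log-likelihood over λ ∈ [−2, 2] in steps of 0.01, one λ per response on
the pooled data. Responses containing zeros are shifted by half the
smallest positive value first (recorded per response); strictly positive
responses are not shifted. The transform is invertible given (λ, shift).

## The per-response model

Each transformed response is fitted with a penalized-spline additive
mixed model: cubic regression splines (k = 6; small bases suit ~900
samples carrying five smooths) for temperature, salinity, Secchi depth,
E and TP, estimated by REML; loading type and sea area as parametric
factors; nested random intercepts for water body and station (sea area is
a *fixed* factor since regional contrasts are of direct interest, and an
additional area-level intercept would be confounded with it — a toggle is
deliberately not offered); a continuous-time AR(1) residual correlation
within station with decay φ^Δt on a weekly time scale; and one residual
variance multiplier per sea area. The fit is delegated to `mgcv::gamm`
(nlme backend), which iterates the smoothing parameters, variance
components, correlation and variance weights jointly; when a
specification requests none of the mixed structures the model reduces to
`mgcv::gam(method = "REML")`. Non-convergence is flagged honestly on the
returned object and such fits are excluded from direction classification
and contrast tables.

Term tests are Wald-type: mgcv's test on the penalized coefficients at
the estimated effective degrees of freedom for smooths, and a joint Wald
test for factor terms (how the original analyses tested factors is not
documented; the joint Wald test is the standard choice exposed by the
fitting engine). Because 27 models with seven terms each are examined,
only p < 0.001 is treated as significant throughout.

### Direction classification

Significant smooth effects are classified `positive`, `negative` or
`nonlinear` for result tables. The classifier evaluates the fitted smooth
on a 200-point grid over the observed covariate range and reads the
direction off its shape: monotone increasing → positive, monotone
decreasing → negative, non-monotone (typically unimodal) → nonlinear;
non-significant terms are `ns`. A small counter-directional excursion
(0.5% of the fitted range) is tolerated so that boundary wiggles in an
otherwise monotone curve do not flip the class. An alternative gate on
the effective degrees of freedom (e.g. requiring edf ≤ 1.5 for a
directional call) was evaluated and rejected: REML edf for a truly linear
effect fluctuates around 1–2 whenever shared survey-level noise happens
to align with a covariate, which made the classification unstable, while
monotonicity separates directional from unimodal responses exactly as the
grey-vs-colored distinction in the result tables intends.

### Marginal means and regional contrasts

Estimated marginal means for sea area are model predictions per area at
reference values of the other covariates — numeric covariates at their
data means, loading type averaged with equal weights over its levels —
with the covariance propagated from the (Bayesian) coefficient covariance
of the fit. All pairwise differences are tested with the studentized
range distribution on the contrast t-statistics
($p = P(q_{k,\nu} > \sqrt{2}\,|t|)$, ν the residual degrees of freedom of
the fit). With equal group sizes this reproduces classical Tukey HSD
(verified to 10^-6^ in the tests); with two levels it collapses to the
unadjusted t-test. With unbalanced groups the marginal means are
covariate-adjusted predictions and deliberately differ from raw group
means.

## The synthetic world

The generator restates the design of the motivating monitoring data
set: four sea areas (BS, AS, wGF, eGF) with 17/24/31/8 stations and
110/201/460/141 samples respectively (912 samples, 80 stations), 44 water
bodies split across areas roughly proportionally to stations (9/13/17/5;
the per-area split is not published, only the total), sampled 1 July–15
September over 2009–2020 with distinct dates per station. Per-area
environmental distributions span the reported summer ranges (temperature
8–26 °C with AS warmest; salinity ≈ 0.5–7 psu with AS highest and eGF
freshest; Secchi 0.2–8.8 m; TP 1.5–135 µg L^-1^, log-normal, wGF highest
and most variable; wGF also carries the largest residual variance
multiplier, 1.4). Depth profiles place a cooler, saltier near-bottom
measurement under the surface layer so the implied stratification index
is positive for most samples; the covariates handed to the community
model are computed from those profiles *by the package's own hydrography
module*, so the generator and the pipeline cannot drift apart.

Communities are generated at taxon level and aggregated by the real
pipeline, so trait assignment, filtering and aggregation code paths are
all exercised. Per-taxon log-biomass follows

log b = taxon baseline + Σ effects × standardized covariates
+ water-body intercept + station intercept + CAR(1) residual
(shared within sample) + per-taxon noise,

with intercept SDs 0.3, φ = 0.4 per week, residual SD σ = 0.5 and
per-taxon noise SD 0.3. Effects are *standardized*: log-units per
covariate SD, in units of σ. A carrier receives, per covariate, the
contribution of its largest-magnitude carried trait rather than the sum
over traits — stacking would give multi-trait carriers steeper slopes and
make each trait's aggregate biomass log-convex in the covariate, whereas
the configuration semantics are that *the trait's* biomass responds
log-linearly with the stated coefficient. The default effect pattern
mirrors the qualitative outcome the models are meant to detect:
temperature favors N-fixers, buoyant taxa and harmful cyanobacteria
(+0.8/+0.8/+0.6) and disfavors motile and mixotrophic taxa (−0.6);
transparency relates negatively to all biomass (−0.6); TP relates
positively to biomass (+0.4) and negatively to mixotrophs (−0.5);
salinity, stratification and loading type have zero injected effect.
Trait flags are drawn at their marginal prevalences (N-fixation 0.10,
mixotrophy 0.25, motility 0.35, buoyancy 0.12, harmfulness 0.15 over a
200-taxon pool) and made internally consistent: N-fixers are
non-mixotrophic heterocystous cyanobacteria, motility/mixotrophy imply a
flagellated eukaryote, buoyancy is confined to cyanobacteria. The taxon
baseline SD (0.8 on the natural log) and the geometry distributions
(log-normal cell diameters around 8 µm; colonies, chains and filament
pieces with realistic cells-per-unit) are one-time realism choices.

All randomness flows from one master seed through a fixed splitting
scheme (table: seed+1, environment: seed+2, communities: seed+3), so
bundles are bitwise reproducible.

What the generator does *not* emulate: species turnover and zero-inflated
occurrence (every pool taxon occurs in every sample), mechanistic bloom
dynamics, seasonal succession within the window, measurement error in
counting, and real taxonomies. A green recovery test therefore
establishes that the estimation machinery recovers known structure from
data of this shape and scale — not that the generator reproduces the
Baltic Sea.

## Numerical choices and scaled-down test design

* Box–Cox grid [−2, 2] step 0.01; grid argmax cross-checked against the
  MASS profile in tests.
* Loading-share argmax ties are errors, not silent choices.
* Zero-total-biomass samples are dropped from response construction with
  a warning (shares undefined).
* Non-converged mixed fits are reported with `converged = FALSE` and
  excluded from downstream tables; they are never re-tried silently.
* The statistical recovery suites keep the stated acceptance intervals
  but run reduced replicate counts where each replicate needs an
  nlme-backed mixed fit (25 replicates for the station-SD and CAR(1)
  recoveries, against intervals stated for the replicate *median*, whose
  Monte Carlo error at 25 replicates is far inside the bands; 10 reduced
  surveys for the null-coverage property). The type-I error suite runs
  the full 500 null replicates since each is a cheap fixed-effects fit.

## Known limitations

* The trait table ships as a small example and simulated tables; no
  external taxonomic name resolution is attempted.
* Degrees of freedom for the marginal-mean contrasts use the fit's
  residual degrees of freedom; with few groups per stratum a
  Kenward–Roger-style correction would be more conservative.
* Share-type responses largely cancel the shared sample-level random
  components, so random-effect recovery is only meaningful for
  biomass-type responses.
* The CAR(1) time scale is weeks; correlation across years is effectively
  zero by construction, as intended for within-season autocorrelation.
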