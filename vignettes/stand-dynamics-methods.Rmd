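---
title: "Methods: demography, spatial association and competition in stem-mapped stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demography, spatial association and competition in stem-mapped stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standdyn)
```

## Scope

`standdyn` analyses repeated censuses of a stem-mapped forest plot — every
stem at or above 2.0 cm diameter at breast height (DBH) tagged, mapped and
re-measured at a handful of census years — together with optional tree-ring
series. Its reference use case is a 0.5-ha (50 × 100 m) conifer–hardwood
mixed stand in central Japan censused in 2002, 2007, 2012 and 2015, where
three growth forms codominate: evergreen conifers (EC), deciduous hardwoods
(DH) and evergreen hardwoods (EH). The package computes demographic rates
with bootstrap confidence intervals, stage-classified matrix population
models, bivariate spatial association with torus-shift nulls, growth-release
chronologies from ring widths, and neighborhood-competition model selection,
and ships a stand simulator with known ground truth so that every stage is
testable without field data.

## Demographic rates

For a census period of $t$ years the three annualized rates are log-ratios:

$$\text{ingrowth} = \frac{100}{t}\,\ln\frac{BA_s}{BA_i}, \qquad
  \text{mortality} = \frac{100}{t}\,\ln\frac{N_i}{N_s}, \qquad
  \text{recruitment} = \frac{100}{t}\,\ln\frac{N_f}{N_s},$$

with $N_i$ the stems alive at the period start, $N_s$ the survivors at the
end, $N_f = N_s$ plus all recruits reaching 2.0 cm during the period
(including recruits that were tagged at an intermediate census and died
before the end), $BA_i$ the basal area of all initial stems and $BA_s$ that
of the survivors at the period end. Mortality and recruitment are undefined
at $N_s = 0$; the functions return an annotated missing value rather than a
number. Survivor counts below 5 are flagged (`flag_low_n`): with so small a
denominator both rates are easily overestimated, and downstream trait
analyses exclude flagged species from the PCA while keeping them in the
plain correlations.

Period length is the exact integer difference of census years (5, 5, 3, and
13 for the whole span of the reference design). Without recruitment the
time-weighted sub-period mortalities recompose the whole-period rate to
machine precision, which the tests exercise.

**Bootstrap.** Confidence intervals are percentile intervals over `B = 1000`
resamples. The resampling unit is the individual tree, drawn with
replacement within the grouping unit and stratified by species when a unit
pools several. Resamples on which the statistic is undefined are redrawn
and counted; more than 50% undefined aborts with a diagnostic. The
percentile method (not BCa) is used: nothing in the estimands' definition
calls for acceleration corrections, and the plain method is reproducible
from the seed alone. On simulated stands of 500 trees with a known constant
annual death probability the intervals cover the true rate in about 94-95%
of 200 stands, within the 95% ± 3% band the tests enforce.

**Size classes.** The default scheme is 2.0–3.9, 4.0–7.9, 8.0–15.9,
16.0–31.9, ≥ 32 cm, half-open `[lo, hi)`. Between periods the initial
number per class is recalculated: recruits that reached 2.0 cm by a period
start join that period's initial counts and survivors that crossed a class
boundary are re-binned, so per-class cohort bookkeeping is exact.

## Ring-width release detection

Percent growth change at year $y$ is
$(M_2 - M_1)/M_1 \times 100$, where $M_1$ is the mean ring width of the 10
years up to and including $y$ and $M_2$ the mean of the 10 years after it.
Both windows must be complete; no partial windows are evaluated. Thresholds
are 25% (moderate) and 50% (major). Within a run of consecutive
super-threshold years one event is reported at the peak-pgc year, earliest
year on ties: counting every year of a run as a separate release would
double-count a single canopy-opening episode inside a 5-year bin. One core
per tree (the longer chronology) is the expected input convention.

Chronologies aggregate events into calendar-aligned 5-year bins (…,
1916–1920, 1921–1925, …). The numerator is trees with at least one event in
the bin; the denominator (sample depth) is trees with an evaluable pgc in at
least one year of the bin. A step of multiplier $m$ at year $Y$ makes the
pgc peak at $Y-1$ (the last all-baseline window), so the detector's
ground-truth tolerance of ±1 year is the natural one. At 10% lognormal
noise, planted three-fold episodes are found within ±1 year in ≥ 95% of
trees, with zero events on constant series.

## Bivariate spatial association

Layers are understory (2.0 ≤ DBH < 10.0 cm) and overstory (DBH ≥ 10.0 cm);
a stem at exactly 10.0 cm is overstory. For patterns 1 and 2 in the plot
rectangle,

$$\hat K_{12}(r) = \frac{A}{n_1 n_2}\sum_i \sum_j w_{ij}\,
  \mathbf 1[d_{ij} \le r], \qquad
  L_{12}(r) = \sqrt{\hat K_{12}(r)/\pi} - r,$$

so $L_{12} \approx 0$ under independence, above 0 under attraction. The
default edge correction is the translation correction
$w_{ij} = WH/((W-|\Delta x|)(H-|\Delta y|))$ — exact and closed-form on
rectangles, which makes single-pair hand verification possible (one pair at
distance 1 in a 10 × 10 window gives $K = 100 \cdot 100/90 = 111.1$).
Ripley's isotropic correction is available behind a flag; its circle-arc
weights are verified in the tests against numeric integration of the
circle fraction inside the window. The C++ kernel is checked against a
brute-force R double loop to 10⁻¹².

The null model is the Lotwick–Silverman torus shift: pattern 1 is
translated by a uniform random vector with wrap-around while pattern 2
stays fixed, preserving each pattern's internal structure. With `n_sim`
shifts the pointwise envelope at each distance takes the
$\lceil n_\mathrm{sim}(1-\ell)/2 \rceil$-th smallest and symmetric largest
simulated $L_{12}$ — ranks 5 and 996 at the 99% level with 1,000 shifts.
Envelopes are pointwise, not simultaneous, so across the default grid
$r = 1, \dots, 10$ m a few excursions are expected under the null; the
null-coverage experiment accordingly asks for "independent" at ≥ 9 of 10
distances in ≥ 90% of runs, which independent Poisson pairs satisfy with
room to spare. One caution follows from the rank rule: comparing envelopes
across different `n_sim` is only meaningful at matched tail mass
(`rank/n_sim`), because `n_sim = 99` maps to the 1st percentile while
`n_sim = 1000` maps to the 0.5th.

## Neighborhood competition

The response is the absolute diameter growth rate
ADGR $= (D_f - D_i)/t$ (cm/yr), negative values retained. Crowding
covariates are basal-area sums over the 10 × 10 m quadrat containing the
target tree (the field convention for this plot design; edge quadrats carry
no correction), divided by the 100 m² quadrat area, separately per growth
form and per competition mode: two-sided sums count all live neighbors
≥ 2 cm (symmetric competition for soil resources), one-sided sums only
neighbors strictly larger than the target (asymmetric competition for
light). The target tree is excluded from its own sums — a tree does not
compete with itself — and quadrat membership is half-open with the upper
plot edge assigned to the last quadrat.

The growth model is a Gaussian linear mixed model with a per-tree random
intercept — trees contribute one observation per survived period, so
repeated measures are correlated within tree. Fits use maximum likelihood,
not REML, because AIC comparisons across fixed-effect structures require
it; $\mathrm{AIC} = -2\log L + 2k$ with $k$ = fixed coefficients + 2
variance parameters. All $2^8 = 256$ subsets of {Species, DBH, six crowding
terms} are fitted and ranked by AIC, ties broken toward fewer terms; fit
failures (e.g. a species factor with one level) are recorded per subset and
do not abort the enumeration. Species enters as a categorical within growth
form, and selection is intended to run separately per growth form.

A note on selection behaviour: with AIC each irrelevant predictor enters
the best model with probability ≈ $P(\chi^2_1 > 2) \approx 0.16$, so even
under a pure DBH-only truth the exact true model is recovered in only
roughly a third of replicates. The meaningful guarantees — the true signal
is contained in the best model, and a strong planted crowding effect is
recovered — are what the tests assert.

## Matrix population models

Stages are the five DBH classes of the mortality analysis (the only size
partition the reference design states). Per period and stage the estimator
records survival $\sigma_j$ (survivors/initial), the distribution of
survivors over destination stages (multi-stage moves and retrogression
allowed, to the observed stage), and per-capita recruitment. Annualization
uses $p_\mathrm{ann} = 1 - (1-p_\mathrm{period})^{1/t}$ for mortality and
for the total advance probability (destinations keep their period
proportions), and divides fecundities by $t$. Periods are pooled weighted
by stem-years at risk. Fecundity is allocated to stages 2+ in proportion to
stage basal area — reproduction scales with size — as a documented,
swappable rule; recruits enter stage 1.

Population growth is the dominant eigenvalue λ via power iteration
(tolerance 10⁻¹⁰, ≤ 10⁵ iterations) cross-checked against direct
eigendecomposition, with fallback and a warning on reducible or periodic
matrices. The headline rate is $r = \ln\lambda$, which can be negative for
declining populations; λ and λ−1 are emitted alongside since conventions
differ between reports. Dominant species are those with ≥ 2% of plot
density or basal area at the first census.

**Recovery experiment design.** The simulator-based validation uses a
3-stage truth with stasis/advance columns (0.81/0.12, 0.81/0.12, 0.88),
fecundities proportional to class-midpoint basal area (scale 0.0025,
λ ≈ 1.0), 5,000 individuals allocated 2000/2000/1000 and three annual
steps. At these sizes every entry's sampling error is ≤ ~4% relative, so
"all entries within 10% of truth" holds in ≈ 98 of 100 seeds; a declining
variant rescaled to λ = 0.97 yields $\hat r < 0$ in ≈ 100 of 100 seeds.
Allocating most individuals to one stage instead makes the smallest advance
entries' error ~5% and the all-entries criterion fails in a fifth of seeds
— a property of the experiment, not of the estimator.

## The stand simulator

`simulate_stand()` draws initial DBH as 2 cm + exponential (reverse-J size
structure; rejection above a species maximum preserves the shape), places
stems uniformly or by a Thomas cluster process (offspring assigned
uniformly to Poisson parents so the configured density is exact; the
configured density is authoritative over the nominal mean offspring), and
then steps annually: grow (increment $a_0 + a_2 D$ + tree effect +
residual, floored at zero — the simulator does not shrink stems even though
the analysis tolerates negative ADGR), kill (Bernoulli with a
logistic-in-DBH annual probability; with zero size slope the annual
probability is exactly the configured baseline, keeping the binomial
survival oracle exact), recruit (Poisson, entering at 2.0–2.5 cm, uniform
or clustered on conspecific adults). States are recorded only at census
years; recruits that die before their first census are never tagged, as in
the field protocol, while recruits tagged at an intermediate census and
dying later still raise $N_f$. Annual time-stepping rather than a
continuous hazard keeps census arithmetic and the oracles exact.

The default species pool is six species, two per growth form, whose
densities (262, 654 and 888 stems/ha for EC, DH, EH), size scales, growth
coefficients and turnover echo the growth-form aggregates of the reference
stand. What the simulator does **not** emulate: climate-driven growth
variation, spatially correlated mortality (gap formation), sprouting, and
measurement error beyond the 0.01 cm recording precision. Passing tests
therefore demonstrate correctness of the estimators under the stated
generative model, not robustness to those field realities.

`simulate_rings()` multiplies a baseline width by the product of active
episode multipliers and lognormal noise, with episodes synchronized across
trees (stand-level disturbance). `simulate_from_matrix()` projects
individuals multinomially from a stage matrix — row-1 entries in columns
2+ are read as fecundities, since stasis and fecundity are not separately
identifiable in a single matrix — and emits a census table with each stage
at its class mid-DBH so the matrix estimator can be validated end to end.

## Numerical and I/O conventions

- Coordinates and DBH are recorded at 0.01 precision (m, cm); `write_census()`
  fixes that precision so write→read round-trips are bit-identical and two
  writes of one table are byte-identical.
- Quadrat and size-class membership are half-open `[lo, hi)`; the upper
  plot edge belongs to the last quadrat, and a stem at exactly 10.0 cm DBH
  is overstory.
- Months at exactly 5 °C contribute to neither the warmth nor the cold
  index (both definitions use strict inequalities).
- PCA uses the correlation matrix (traits mix cm and % yr⁻¹ units), with
  loading signs fixed so each component's largest-magnitude loading is
  positive; variance explained equals the eigenvalues and sums to the
  number of traits.
- Pipeline outputs are CSVs plus a manifest of md5 hashes; the same inputs
  and seed reproduce identical hashes.

## Problem sizes used in the validation suite

The test-suite experiments run at deliberately moderate sizes chosen to
make the statistical criteria sharp while keeping the suite quick: 200
simulated stands of 500 trees for bootstrap coverage, 20–50 runs × 1,000
torus shifts of 200-point patterns for envelope null coverage, 100 seeds ×
5,000 individuals for matrix recovery, 100 trees for release sensitivity,
and 50 random instances for estimator-vs-oracle agreement. All are
reproducible from a single integer seed.

## Known limitations

- The per-run release rule (one event per super-threshold run) is one of
  several defensible conventions; detectors that report every
  super-threshold year will count more events on long episodes.
- Fecundity allocation proportional to stage basal area is an assumption;
  where size-specific fecundity data exist the allocation rule should be
  replaced.
- Quadrat-based crowding ignores neighbors just across a quadrat boundary;
  this is the plot-design convention, not a modelling recommendation.
- Envelope classification is pointwise; treating the whole r-grid as one
  test requires simultaneous envelopes, which are out of scope.
- The end-to-end pipeline treats stages independently; it does not
  propagate demographic uncertainty into the matrix model or the PCA.

## Interface

The package's functions are the interface; `run_pipeline()` is the
end-to-end driver (census table + optional rings in, CSV bundle + manifest
out). See the README for a worked example with printed output.
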