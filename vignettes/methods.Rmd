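---
title: "Pooling heterogeneous biomarker summaries by Monte Carlo re-simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling heterogeneous biomarker summaries by Monte Carlo re-simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expopool)
```

## The model

expopool treats every study stratum — one row of the study table, with a
matrix (urine or serum), province, sampling years, sex, age range and
sample size `n` — as a window onto an underlying individual-level
concentration distribution. Two families are supported, matching the two
simulation branches used in spreadsheet-based exposure pooling:

* **normal**: concentrations `X ~ N(AM, SD)`,
* **lognormal**: `ln X ~ N(ln GM, ln GSD)` with geometric mean GM and
  geometric SD `GSD >= 1`.

Simulated individuals are drawn by the inverse-CDF construction
`x = max(floor, F^{-1}(u))` with `u ~ Uniform(0, 1)`. The floor encodes
the conventional substitution of non-detects by half the limit of
detection; the default policy is the constant 0.5 ng/mL hard-coded in the
spreadsheet formulas this engine mirrors, and
`floor_policy = list(half_lod = TRUE)` instead uses the study's recorded
LOD/2 (falling back to 0.5 when no LOD was reported). Because the floor
is applied to the quantile, not to a rejection sampler, the simulated
minimum equals the floor exactly whenever the distribution has mass
below it — a property the tests assert.

All concentrations are harmonized to ng/mL first (1 ug/L = 1 ng/mL,
1 ng/mL = 100 ng/dL = 1000 ng/L). Creatinine-adjusted units
(ug/g-creatinine) have no volume-basis equivalent without creatinine
data and are rejected; such studies are skipped with a logged reason
rather than aborting the run.

## Converting reported summaries

| reported | conversion |
|---|---|
| GM, GSD | lognormal spec, unchanged |
| AM, SD | normal spec, unchanged |
| AM, 95% CI | normal spec, `SD = sqrt(N) (UCI - LCI) / 3.92` |
| q1, median, q3 | quantile-matching (below) |
| min, median, max | quantile-matching (below) |

**CI inversion.** The divisor 3.92 is `2 * 1.96`; multiplying the CI
width by `sqrt(N)` inverts the standard CI-of-the-mean identity. A
`sd_from_ci_mode = "literalN"` flag multiplies by `N` instead; that
reading produces SDs that grow linearly in the sample size, which is
dimensionally implausible, so `sqrtN` is the default.

**Quantile matching.** Medians with quartiles or ranges are converted by
the closed-form estimators

* quartiles: `AM = (q1 + median + q3) / 3`,
  `SD = (q3 - q1) / (2 z((0.75 n - 0.125) / (n + 0.25)))`,
* range: `AM = (min + 2 median + max) / 4`,
  `SD = (max - min) / (2 z((n - 0.375) / (n + 0.25)))`,

where `z` is the standard normal quantile function. As `n` grows the
quartile SD estimator approaches the familiar normal-theory limit
`IQR / 1.349` (asserted to 1% at `n = 1e5` in the tests). These closed
forms replace the interactive quantile-estimation tools often used for
this step in evidence synthesis; they are testable against sampling
oracles and carry no service dependency. No skewness-adaptive or
iterative-likelihood refinement is attempted.

**Which family for median-based reports?** The reporting kind pins the
family for GM/GSD (lognormal) and AM/SD, AM/CI (normal; the simulation
formula for that branch takes AM and SD on the arithmetic scale). For
median/quartile and median/range reports the choice is genuinely open,
and it matters. Concentration biomarkers are conventionally lognormal,
and quantiles transform exactly under the logarithm, so the default
(`median_family = "lognormal"`) applies the estimators above to the
log-quantiles and exponentiates, giving a lognormal (GM, GSD) spec. This
is both the statistically natural reading — a distribution-fit check on
skewed concentration data selects the lognormal branch — and an
approximately unbiased one: applying the arithmetic-scale estimators to
quantiles of a lognormal sample with GSD 2 and re-simulating through the
normal branch biases the pooled GM by roughly −7% (quartiles) and worse
for ranges at large `n`, because a normal distribution fitted to skewed
quantiles places substantial mass at low values where the logarithm is
steep. The arithmetic-scale mapping remains available as
`median_family = "normal"`, and is used automatically for records
containing a zero quantile (where log-matching is undefined).

The same geometry explains a documented limitation: AM/SD and AM/CI
reports of lognormal data *must* go through the normal branch, and carry
an inherent GM bias of a few percent (about +6% at GM 1.7, −2% at
GM 2.9, GSD 2, floor 0.5). This is a property of the re-simulation
method itself, not of the implementation; the test suite asserts it
directionally rather than pretending it away.

## The Monte Carlo engine

`run_simulation()` generates `replicates` (default 100) independent
replicate tables. Per study the draw count defaults to the study's
reported `n`, which makes downstream pooling implicitly sample-size
weighted; a fixed count can be configured. Every (study, replicate) cell
draws from its own RNG substream keyed by `(seed, study_id, replicate)`,
so results are bitwise reproducible, replicates are independent, and
adding or removing a study never perturbs the draws of the others. The
caller's RNG state is saved and restored around every run.

## Pooling

Within a stratum (any subset of matrix × period × province × sex ×
age band) and replicate `r`, the pooled geometric mean is
`GM_r = exp(mean(ln x))` over the concatenated draws of all member
studies. The reported estimate is `mean(GM_r)` with the 2.5/97.5
replicate percentiles as interval. Computing the GM per replicate and
then averaging (rather than pooling all replicates jointly) changes the
point estimate only negligibly but yields an interval that reflects
replicate-to-replicate spread, which is the quantity the 100 replicate
tables exist to measure. Draws are concatenated across studies without
explicit weights; with `draws_per_study = "n"` this is precisely
sample-size weighting. No random-effects model or heterogeneity
statistic is fitted — the estimator is a pooled simulated database, not
a meta-analysis.

**Period bins.** Urine studies use five bins (2006–2008, 2009–2011,
2012–2014, 2015–2017, 2018–2019) and serum four (2004–2007, 2008–2011,
2012–2015, 2016–2019). Multi-year studies are binned by their midpoint
year, rounded half-up — a fixed deterministic rule, since source corpora
rarely state how spanning studies were assigned. Midpoints outside every
bin get an `"unbinned"` sentinel and are excluded from temporal pooling
with a warning. Coarser custom binnings (e.g. the two-bin groupings used
for mapping) can be supplied via `period_bins`.

**Age bands.** The finest band among 0–6, 7–18, 19–44, 45+ fully
containing the study's age range is assigned, nesting into the
children/adults split 0–18 vs 19+. Ranges crossing the 18/19 boundary
get a `"mixed"` sentinel and are excluded from age-stratified pooling.
The two fine adult bands are an interpretive refinement of the
children/adults split (school-age and young-adult groups); only the
0–18/19+ split is used for the formal contrast.

## Group contrasts and covariate associations

Sex and children/adults contrasts apply the Mann–Whitney U test (midrank
ties) to the per-replicate pooled GMs of the two groups. When
`choose(n_a + n_b, n_a) <= 2e5` the two-sided p-value is computed by full
enumeration of group labelings — valid under ties, and exact for the
small-sample cases where the normal approximation is weakest; otherwise
a tie-corrected normal approximation with continuity correction is used.
The two branches agree within 0.02 at `n_a = n_b = 10` (tested), and the
no-ties exact branch reproduces `wilcox.test`'s exact p-values.

Province-level pooled GMs are ln-transformed (configurable) and paired
with each environmental covariate aggregated per province — by default
the mean over the years the province's studies actually sampled, with
`"all"`-years and `"latest"`-year rules as alternatives, since corpora
rarely state the year-matching rule. Pearson's r with the t-based
two-sided p-value is reported per covariate; at least three matched
provinces are required, and a strict-join flag controls whether
provinces missing from the covariate table are an error or are dropped.
Significance is read at 0.05, two-sided, with no multiple-testing
correction — deliberately matching common practice in this literature,
and documented as such.

## The synthetic corpus generator

`generate_corpus()` emulates the literature corpus the pipeline is built
for, with known ground truth. Per stratum it takes a true (GM, GSD);
per study it draws a sample size, a latent lognormal sample, and a
reporting kind, then summarizes the *latent sample* with that kind —
so the conversion layer is exercised on realistic sampling noise, not on
idealized parameters. Covariates are generated per province and year as
`intercept + 100 * slope * ln(GM_province) + N(0, 100 * noise_sd)`.
Defaults, chosen once as a realistic corpus and not revisited:

* **summary-kind mix** 35% median+IQR, 10% median+range, 25% GM/GSD,
  20% AM/SD, 10% mean+CI — median-based reporting dominates real corpora,
  with geometric/arithmetic means less common;
* **sample sizes** uniform on 10–3426, the envelope of a national BPA
  corpus; median+range studies are capped at `n <= 100`, since min–max
  reporting is a small-cohort practice and range estimators are only
  rated for small samples;
* **LOD 1.0 ng/mL**, so LOD/2 coincides with the conventional 0.5
  substitution floor;
* **covariate noise** defaults to signal-to-noise 2 (noise SD = half the
  between-province spread of slope × ln GM).

Ground-truth helpers encode the study conditions used throughout the
tests: `temporal_truth()` (five urine periods at GMs 1.9, 1.8, 1.9, 1.7,
2.9 ng/mL, GSD 2 — flat then peaking in the final period) and
`province_truth()` (18 provinces, GMs log-spaced 3.5 down to 0.8 ng/mL).
The truth table is a first-class output so tests never re-derive
generating parameters.

What the generator does *not* emulate: publication and selection bias,
within-study censoring detail (non-detect counts), creatinine-adjusted
reporting, correlated strata from multi-arm articles, or non-lognormal
truth. Passing recovery tests therefore demonstrates that the pipeline
is internally consistent and approximately unbiased under lognormal
truth with heterogeneous reporting — not that any particular published
estimate is correct.

## Numerical choices and degenerate inputs

* Empirical quartiles use R's default type-7 definition, both in the
  generator and in tests.
* Zero-variance specs (SD 0 or GSD 1) return the floored location
  exactly; a floor above the entire distribution returns the floor for
  every draw.
* `GSD < 1`, negative concentrations, inverted CIs and misordered
  quantiles are rejected at validation with row-level messages.
* The exact Mann–Whitney branch is capped at `choose(n, n_a) <= 2e6`
  enumerated labelings; beyond that the approximation is used.
* Replicate-percentile intervals use type-7 quantiles over 100 replicate
  GMs; with a single replicate the interval collapses to the point.
* Pipeline outputs are plain CSV plus a JSON manifest without
  timestamps, so a fixed seed reproduces every output byte for byte.

## Problem sizes used in validation

The test suite validates the estimator at the full study conditions —
five periods × 20 studies at sample sizes 10–3426 with 100 replicates
(about 15 million draws, a few seconds) — and uses smaller corpora
(3–4 studies per stratum, n 20–80, 5–20 replicates) for structural and
property checks, including 100-seed sign-recovery runs for the
association layer. `scripts/acceptance.R` re-runs the full-scale
temporal, sex-contrast and 18-province analyses from scratch at each
invocation.

## Known limitations

* Arithmetic-branch (AM/SD, AM/CI) re-simulation of skewed data biases
  pooled GMs by a few percent, as analyzed above; with median-heavy
  corpora the net effect stays within a few percent but it is not zero.
* Near the floor the pooled GM is truncation-biased upward (asserted
  directionally in tests); estimates for strata with true GM close to
  0.5 ng/mL should be read as upper-ish values.
* Studies are treated as independent rows; sex-split and pooled rows
  from the same article are not de-duplicated, matching the flat
  structure of extracted corpora. Document corpus construction
  accordingly.
* No between-study heterogeneity modelling; the replicate interval
  reflects Monte Carlo spread, not between-study variance.
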