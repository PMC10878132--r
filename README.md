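# expopool

Monte Carlo pooling of heterogeneous biomarker concentration summaries
into stratified geometric-mean exposure estimates.

## The problem

National exposure assessments for biomarkers such as urinary or serum
bisphenol A (BPA) must combine dozens of small biomonitoring studies that
each report a different summary of the same kind of data: an arithmetic
mean with SD, a geometric mean with GSD, a median with quartiles or
min–max range, or a mean with its 95% confidence interval. expopool is
for exposure scientists and epidemiologists who need to pool such a
literature corpus into population-level estimates stratified by sampling
period, province, sex and age band, and to relate regional estimates to
environmental covariates.

## The method

Each study stratum is converted to a simulatable concentration
distribution:

* `GM_GSD` reports give a lognormal distribution directly;
* `AM_SD` reports give a normal distribution directly;
* `MEAN_CI` reports recover the SD from the CI of the mean,
  `SD = √N (U_CI − L_CI) / 3.92`;
* `MEDIAN_IQR` / `MEDIAN_RANGE` reports are quantile-matched with
  closed-form estimators, e.g. `AM = (q1 + median + q3)/3`,
  `SD = (q3 − q1) / (2 z((0.75n − 0.125)/(n + 0.25)))`. By default the
  matching is done on the log scale (concentration biomarkers are
  conventionally lognormal), yielding a lognormal (GM, GSD) spec.

Simulated individuals are then drawn by inverse-CDF Monte Carlo with a
detection-limit floor, mirroring the spreadsheet construction

```
x = max(0.5, NORM.INV(u, AM, SD))            # normal branch
x = max(0.5, LOGNORM.INV(u, ln GM, ln GSD))  # lognormal branch
```

with `u ~ Uniform(0, 1)`, `n` draws per study, and 100 independent
replicate tables. Within each stratum and replicate the pooled geometric
mean is `exp(mean(ln x))` over the concatenated draws of all member
studies; the reported GM is the mean over replicates with a 2.5–97.5%
replicate-percentile interval. Sex and children/adults contrasts use the
Mann–Whitney U test (exact by enumeration for small samples); pooled
province GMs are correlated with province-level garbage disposal,
domestic sewage and waste incineration volumes by Pearson's r on
ln-transformed GMs.

A synthetic-corpus generator (`generate_corpus()`) emulates the
literature corpus from known lognormal ground truth, so every stage of
the pipeline is validated end to end against parameters it should
recover.

## Worked example

A small study table ships with the package:

```r
library(expopool)
studies <- read_study_table(system.file("extdata", "example_studies.csv",
                                        package = "expopool"))
fit <- mc_pool(studies, by = c("matrix", "period"), replicates = 100,
               seed = 17)
print(fit)
#> Monte Carlo pooled geometric means (ng/mL)
#>   6 studies, 100 replicates, seed 17; stratified by matrix x period
#> serum/2008-2011 serum/2016-2019 urine/2009-2011 urine/2012-2014 urine/2015-2017
#>           1.918           6.028           1.873           2.377           1.712
#> urine/2018-2019
#>           2.947
```

Each number is the pooled geometric mean concentration (ng/mL) of the
biomarker in that matrix and sampling-period stratum; for instance the
single 2018–2019 urine study (GM 2.9, GSD 2.1) is re-simulated and pooled
to 2.947 ng/mL, and `confint(fit)` gives the replicate-percentile
intervals. `run_pipeline()` runs the same estimator over the standard
period/province/sex/age stratifications, adds the Mann–Whitney contrasts
and covariate correlations, and writes CSV tables plus a reproducibility
manifest.

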