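test_that("period assignment follows the matrix-specific bins via midpoint year", {
  expect_equal(assign_period("urine", 2010, 2010), "2009-2011")
  expect_equal(assign_period("serum", 2004, 2007), "2004-2007")
  expect_equal(assign_period("urine", 2003, 2003), "unbinned")
  expect_equal(assign_period("serum", 2018, 2019), "2016-2019")
  # multi-year span binned by (half-up rounded) midpoint
  expect_equal(assign_period("urine", 2008, 2011), "2009-2011")
  # custom coarse bins (two-bin map groupings) are supported
  coarse <- list(urine = data.frame(start = c(2008, 2012), end = c(2011, 2019)))
  expect_equal(assign_period("urine", 2010, 2010, bins = coarse), "2008-2011")
  expect_equal(assign_period("urine", 2015, 2015, bins = coarse), "2012-2019")
})

test_that("age bands nest into the children/adults split with a mixed sentinel", {
  expect_equal(assign_age_band(0, 6), "0-6")
  expect_equal(assign_age_band(7, 18), "7-18")
  expect_equal(assign_age_band(19, 44), "19-44")
  expect_equal(assign_age_band(50, 70), "45+")
  expect_equal(assign_age_band(3, 15), "0-18")
  expect_equal(assign_age_band(20, 60), "19+")
  expect_equal(assign_age_band(10, 30), "mixed")
})

test_that("pooling computes exact geometric means for degenerate draws", {
  # two point-mass studies at 1 and 4, one draw each: gm = 2 exactly
  studies <- rbind(make_study("A", s1 = 1, s2 = 1),
                   make_study("B", s1 = 4, s2 = 1))
  sim <- run_simulation(studies, replicates = 3, seed = 1,
                        draws_per_study = 1L,
                        floor_policy = list(constant = 0))
  p <- pool(sim, by = "matrix")
  expect_equal(p$gm, 2)
  expect_equal(p$ci_low, 2)   # zero-width interval
  expect_equal(p$ci_high, 2)
  expect_equal(p$n_studies, 2L)
  expect_equal(p$n_draws, 2)
})

test_that("pooled gm is permutation-invariant and scale-equivariant", {
  # lognormal-branch kinds only so that a zero floor still yields positive
  # draws and equivariance is exact
  cfg <- generator_config(studies_per_stratum = 4, n_range = c(20, 80),
                          summary_kind_mix = c(AM_SD = 0, GM_GSD = 0.5,
                                               MEDIAN_IQR = 0.5,
                                               MEDIAN_RANGE = 0, MEAN_CI = 0),
                          seed = 21)
  corpus <- generate_corpus(cfg)
  st <- corpus$studies
  p1 <- pool(run_simulation(st, replicates = 5, seed = 2), by = c("matrix", "period"))
  p2 <- pool(run_simulation(st[rev(seq_len(nrow(st))), ], replicates = 5, seed = 2),
             by = c("matrix", "period"))
  expect_equal(p1$gm, p2$gm)
  # scaling all reported concentrations by c scales gm by c (floor 0)
  st3 <- st
  st3$s1 <- st3$s1 * 3
  st3$s3 <- st3$s3 * 3
  st3$s2 <- ifelse(st3$summary_kind == "GM_GSD", st3$s2, st3$s2 * 3)
  p3 <- pool(run_simulation(st3, replicates = 5, seed = 2,
                            floor_policy = list(constant = 0)),
             by = c("matrix", "period"))
  p0 <- pool(run_simulation(st, replicates = 5, seed = 2,
                            floor_policy = list(constant = 0)),
             by = c("matrix", "period"))
  expect_equal(p3$gm, 3 * p0$gm, tolerance = 1e-12)
})

test_that("pooled gm never exceeds the arithmetic mean of the draws", {
  sim <- run_simulation(generate_corpus(tiny_temporal_config(5))$studies,
                        replicates = 2, seed = 7)
  am <- mean(unlist(sim$draws))
  p <- pool(sim, by = "matrix")
  expect_lte(p$gm, am)
})

test_that("strata near the floor are truncation-biased upward, far strata are not", {
  near <- generator_config(strata = temporal_truth(gms = rep(0.6, 5)),
                           studies_per_stratum = 6, n_range = c(100, 300),
                           seed = 13)
  fit <- mc_pool(generate_corpus(near)$studies, replicates = 20, seed = 14)
  expect_true(all(fit$estimates$gm >= 0.6))  # documented truncation bias
})

test_that("studies outside bins or crossing the age boundary are excluded with warnings", {
  studies <- rbind(make_study("A", year_start = 2010L, year_end = 2010L),
                   make_study("B", year_start = 1999L, year_end = 1999L),
                   make_study("C", age_min = 10L, age_max = 30L))
  sim <- run_simulation(studies, replicates = 2, seed = 1)
  expect_warning(p <- pool(sim, by = c("matrix", "period")), "outside the period bins")
  expect_equal(sum(p$n_studies), 2L)
  expect_warning(pa <- pool(sim, by = "age_band"), "18/19 boundary")
  expect_equal(sum(pa$n_studies), 2L)
})

test_that("unstratified key columns are reported as 'all'", {
  sim <- run_simulation(make_study("A"), replicates = 2, seed = 1)
  p <- pool(sim, by = "sex")
  expect_equal(p$province, "all")
  expect_equal(p$period, "all")
  expect_equal(p$sex, "mixed")
})
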