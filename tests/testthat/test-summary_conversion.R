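# Frozen expected values below were computed beforehand with an
# independent normal-quantile routine (scipy.stats.norm.ppf).

test_that("sd_from_ci inverts the CI-of-the-mean identity", {
  expect_equal(sd_from_ci(100, 0.804, 1.196), 1.0)
  expect_equal(sd_from_ci(4, 0, 3.92), 2.0)
  # literal-N reading preserved behind the mode flag
  expect_equal(sd_from_ci(100, 0.804, 1.196, mode = "literalN"), 10)
  expect_error(sd_from_ci(1, 0.8, 1.2), "n < 2")
  expect_error(sd_from_ci(10, 1.2, 0.8), "uci")
})

test_that("quartile and range conversions match the quantile-matching closed forms", {
  qq <- mean_sd_from_quartiles(1, 2, 3, 50)
  expect_equal(qq[["am"]], 2)                       # symmetric: AM = median
  expect_equal(qq[["sd"]], 1.5266091616463286, tolerance = 1e-10)
  rr <- mean_sd_from_range(0, 2, 4, 100)
  expect_equal(rr[["am"]], 2)
  expect_equal(rr[["sd"]], 0.800451274909868, tolerance = 1e-10)
  dg <- mean_sd_from_range(2, 2, 2, 30)
  expect_equal(dg[["sd"]], 0)                       # degenerate range
  expect_error(mean_sd_from_quartiles(3, 2, 1, 50), "q1 <= median <= q3")
  expect_error(mean_sd_from_quartiles(1, 2, 3, 1), "n too small")
})

test_that("SD estimators are scale-equivariant and AM equals the median for symmetry", {
  for (n in c(10, 100, 1000)) {
    base_q <- mean_sd_from_quartiles(1, 2.5, 4, n)
    scaled <- mean_sd_from_quartiles(3, 7.5, 12, n)
    expect_equal(scaled, 3 * base_q)
    expect_equal(mean_sd_from_range(0, 3, 6, n)[["am"]], 3)
  }
})

test_that("summary kinds map to the documented distribution families", {
  # GM/GSD passes through to the lognormal branch with the 0.5 floor
  sp <- to_distribution_spec(make_study(s1 = 1.78, s2 = 2))
  expect_equal(unclass(sp)[c("family", "p1", "p2", "floor")],
               list(family = "lognormal", p1 = 1.78, p2 = 2, floor = 0.5))
  # degenerate point mass
  sp <- to_distribution_spec(make_study(summary_kind = "AM_SD", s1 = 2, s2 = 0))
  expect_equal(sp$family, "normal")
  expect_equal(c(sp$p1, sp$p2), c(2, 0))
  # MEAN_CI composes with sd_from_ci
  rec <- make_study(summary_kind = "MEAN_CI", s1 = 2, s2 = 1.8, s3 = 2.2,
                    n = 100L)
  sp <- to_distribution_spec(rec)
  expect_equal(sp$p2, sd_from_ci(100, 1.8, 2.2))
  expect_equal(to_distribution_spec(rec, sd_from_ci_mode = "literalN")$p2,
               sd_from_ci(100, 1.8, 2.2, mode = "literalN"))
})

test_that("median summaries are quantile-matched on the log scale by default", {
  rec <- make_study(summary_kind = "MEDIAN_IQR", s1 = 1, s2 = 2, s3 = 4,
                    n = 50L)
  sp <- to_distribution_spec(rec)
  expect_equal(sp$family, "lognormal")
  expect_equal(sp$p1, exp(mean(log(c(1, 2, 4)))))
  ln_sd <- mean_sd_from_quartiles(log(1), log(2), log(4), 50)[["sd"]]
  expect_equal(sp$p2, exp(ln_sd))
  # arithmetic-scale branch is available, and is the fallback at zero quantiles
  spn <- to_distribution_spec(rec, median_family = "normal")
  expect_equal(spn$family, "normal")
  expect_equal(spn$p1, mean(c(1, 2, 4)))
  rec0 <- make_study(summary_kind = "MEDIAN_RANGE", s1 = 0, s2 = 2, s3 = 4,
                     n = 50L)
  expect_equal(to_distribution_spec(rec0)$family, "normal")
})

test_that("unit conversion happens before parameterization", {
  rec <- make_study(summary_kind = "AM_SD", s1 = 200, s2 = 80,
                    unit = "ng/dL", lod = 100)
  sp <- to_distribution_spec(rec, floor_policy = list(half_lod = TRUE))
  expect_equal(c(sp$p1, sp$p2), c(2, 0.8))
  expect_equal(sp$floor, 0.5)  # 100 ng/dL -> 1 ng/mL -> LOD/2
  expect_error(to_distribution_spec(make_study(unit = "ug/g-creatinine")),
               "non-convertible")
})

test_that("floor policy resolves constants and half-LOD with fallback", {
  rec <- make_study(lod = 0.6)
  expect_equal(to_distribution_spec(rec)$floor, 0.5)
  expect_equal(to_distribution_spec(rec, floor_policy = list(half_lod = TRUE))$floor, 0.3)
  rec$lod <- NA_real_
  expect_equal(to_distribution_spec(rec, floor_policy = list(half_lod = TRUE))$floor, 0.5)
  expect_equal(to_distribution_spec(rec, floor_policy = list(constant = 0))$floor, 0)
  expect_error(distribution_spec("lognormal", 2, 0.9), "GSD")
})
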