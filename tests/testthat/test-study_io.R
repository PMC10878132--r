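test_that("a well-formed table reads, validates and round-trips through CSV", {
  df <- rbind(make_study("S1"),
              make_study("S2", summary_kind = "MEDIAN_IQR",
                         s1 = 1, s2 = 2, s3 = 3, n = 3426L),
              make_study("S3", matrix = "serum", summary_kind = "AM_SD",
                         s1 = 2.5, s2 = 0.8, lod = NA_real_))
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(df, path)
  back <- read_study_table(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back, validate_study_table(df))
  # corpus-envelope maximum sample size is accepted
  expect_equal(back$n[2], 3426L)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_study_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invariant violations are reported with row, field and rule", {
  bad <- rbind(make_study("S1"),
               make_study("S2", summary_kind = "MEDIAN_IQR",
                          s1 = 5, s2 = 2, s3 = 3))
  expect_error(validate_study_table(bad), "row 2.*q1 <= median <= q3")
  expect_error(validate_study_table(make_study(n = 0L)), "n must be >= 1")
  expect_error(
    validate_study_table(make_study(year_start = 2012L, year_end = 2010L)),
    "year_start")
  expect_error(validate_study_table(make_study(s2 = 0.8)), "GSD must be >= 1")
  expect_error(
    validate_study_table(make_study(summary_kind = "MEAN_CI",
                                    s1 = 2, s2 = 2.5, s3 = 3)),
    "LCI <= AM <= UCI")
})

test_that("unknown enum values are rejected listing the allowed set", {
  expect_error(validate_study_table(make_study(summary_kind = "MEDIAN")),
               "allowed: AM_SD, GM_GSD, MEDIAN_IQR")
  expect_error(validate_study_table(make_study(unit = "mg/dL")),
               "allowed: ng/mL, ug/L")
  expect_error(validate_study_table(make_study(province = "Atlantis")),
               "unknown province")
  # canonical-spelling normalization is applied, not a silent pass-through
  ok <- validate_study_table(make_study(province = "guangdong"))
  expect_equal(ok$province, "Guangdong")
})

test_that("unit conversion applies the fixed linear factors", {
  expect_equal(convert_unit(1, "ug/L"), 1)
  expect_equal(convert_unit(100, "ng/dL"), 1)
  expect_equal(convert_unit(0, "ng/L"), 0)
  expect_equal(convert_unit(1, "μg/L"), 1) # micro sign accepted
  # idempotent for ng/mL and invertible by the reciprocal factor
  vals <- c(0.5, 1, 2.9)
  expect_identical(convert_unit(vals, "ng/mL"), vals)
  for (u in c("ug/L", "ng/dL", "ng/L")) {
    one <- convert_unit(1, u)
    expect_equal(convert_unit(vals, u) / one, vals)
  }
  expect_error(convert_unit(1, "ug/g-creatinine"), "non-convertible")
  expect_error(convert_unit(1, "mg/dL"), "unknown unit")
})

test_that("harmonize_units rescales concentrations but not the GSD", {
  df <- rbind(make_study("S1", unit = "ng/dL", s1 = 200, s2 = 2, lod = 100),
              make_study("S2", unit = "ng/L", summary_kind = "AM_SD",
                         s1 = 2000, s2 = 500, lod = 1000))
  h <- harmonize_units(df)
  expect_equal(h$unit, c("ng/mL", "ng/mL"))
  expect_equal(h$s1, c(2, 2))
  expect_equal(h$s2, c(2, 0.5))  # GSD untouched, SD rescaled
  expect_equal(h$lod, c(1, 1))
})

test_that("covariate tables validate schema and non-negativity", {
  cv <- data.frame(province = "Zhejiang", year = 2010L,
                   garbage_disposal = 500, domestic_sewage = 800,
                   waste_incineration = 300)
  expect_silent(validate_covariate_table(cv))
  cv$domestic_sewage <- -1
  expect_error(validate_covariate_table(cv), ">= 0")
  expect_error(validate_covariate_table(cv[, 1:3]), "missing covariate")
})
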