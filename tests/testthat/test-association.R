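test_that("Mann-Whitney exact enumeration reproduces hand-enumerable cases", {
  # complete separation: U = 0; 2 of the C(6,3) = 20 labelings are as extreme
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 0.1)
  expect_match(mw$method, "exact")
  # identical multisets: U = n^2 / 2 and p = 1
  mw <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(mw$u_statistic, 8)
  expect_equal(mw$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("U and p are invariant under the log transform of both groups", {
  set.seed(4)
  a <- rlnorm(8, 0, 1); b <- rlnorm(9, 0.5, 1)
  raw <- mann_whitney(a, b)
  ln <- mann_whitney(log(a), log(b))
  expect_equal(raw$u_statistic, ln$u_statistic)
  expect_equal(raw$p_value, ln$p_value)
  expect_true(raw$u_statistic >= 0 && raw$u_statistic <= 8 * 9)
})

test_that("enumeration, normal approximation and wilcox.test agree", {
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    ex <- mann_whitney(a, b, exact = TRUE)
    ap <- mann_whitney(a, b, exact = FALSE)
    expect_lt(abs(ex$p_value - ap$p_value), 0.02)
    # independent implementation as oracle (no ties: wilcox exact)
    wt <- wilcox.test(a, b, exact = TRUE, correct = TRUE)
    expect_equal(ex$u_statistic, unname(wt$statistic))
    expect_equal(ex$p_value, wt$p.value, tolerance = 1e-12)
  }
  # tied data: approximation branch against wilcox's tie-corrected normal
  a <- c(1, 2, 2, 3, 3, 3, 4, 5, 6, 7, 8, 8, 9, 9, 10, 11, 12, 12, 13, 14, 15)
  b <- a + 1
  ap <- mann_whitney(a, b, exact = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(ap$p_value, wt$p.value, tolerance = 1e-12)
})

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  expect_equal(pearson_cor(x, y)$r, 0.5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  set.seed(12)
  u <- rnorm(20); v <- 0.3 * u + rnorm(20)
  pc <- pearson_cor(u, v)
  r_hand <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pc$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(18 / (1 - r_hand^2))
  expect_equal(pc$p_value, 2 * pt(-abs(t_hand), 18), tolerance = 1e-12)
  # affine invariance and sign flip
  expect_equal(pearson_cor(3 * u + 2, v)$r, pc$r)
  expect_equal(pearson_cor(-u, v)$r, -pc$r)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("covariate correlation pairs provinces and honors the strict join", {
  provs <- provinces_cn()[1:6]
  pooled <- data.frame(province = provs, gm = exp(seq(0.2, 1.2, length.out = 6)))
  cov <- data.frame(province = rep(provs, each = 2), year = rep(2010:2011, 6))
  # covariate exactly linear in ln(gm) => r = 1
  cov$garbage_disposal <- 100 + 50 * log(pooled$gm)[rep(1:6, each = 2)]
  cov$domestic_sewage <- 5 - 2 * log(pooled$gm)[rep(1:6, each = 2)]
  cov$waste_incineration <- 10 + 3 * log(pooled$gm)[rep(1:6, each = 2)]
  res <- suppressWarnings(
    correlate_with_covariates(pooled, cov, year_rule = "all"))
  expect_equal(res$r[res$covariate == "garbage_disposal"], 1)
  expect_equal(res$r[res$covariate == "domestic_sewage"], -1)
  expect_equal(res$n, rep(6L, 3), ignore_attr = TRUE)

  # a pooled province missing from the covariate table
  cov2 <- cov[cov$province != provs[1], ]
  expect_error(correlate_with_covariates(pooled, cov2, year_rule = "all"),
               "missing from covariate table")
  ok <- correlate_with_covariates(pooled, cov2, year_rule = "all",
                                  strict = FALSE)
  expect_equal(ok$n, rep(5L, 3), ignore_attr = TRUE)
  expect_error(
    correlate_with_covariates(pooled[1:2, ], cov, year_rule = "all"),
    "fewer than 3|at least 3")
})
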