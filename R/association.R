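# Group comparisons (Mann-Whitney U with midrank ties and an
# exact-enumeration small-sample branch) and Pearson correlation of
# province-level pooled estimates with environmental covariates.

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent groups. The U
#' statistic uses midranks for ties. For small samples (number of
#' distinct group labelings `choose(n_a + n_b, n_a) <= 2e5`, which covers
#' `n_a * n_b <= 400` in the balanced case) the two-sided p-value is
#' computed by full enumeration of all labelings of the observed values,
#' which is valid under ties; otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration branch;
#'   default `NULL` chooses by size.
#' @return object of class `mw_test`: list with `u_statistic` (U for group
#'   `a`), `p_value` (two-sided), `n_a`, `n_b`, `gm_a`, `gm_b` (geometric
#'   means, `NA` when values are not all positive) and `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (is.null(exact)) exact <- choose(n, na) <= 2e5
  if (exact && choose(n, na) > 2e6) {
    stop("exact enumeration infeasible for these group sizes")
  }
  if (exact) {
    idx <- combn(n, na)
    Uall <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tie <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  gm <- function(x) if (all(x > 0)) exp(mean(log(x))) else NA_real_
  structure(list(u_statistic = U, p_value = p, n_a = na, n_b = nb,
                 gm_a = gm(a), gm_b = gm(b), method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n_a = %d, n_b = %d), p = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$p_value, x$method))
  if (!is.na(x$gm_a)) {
    cat(sprintf("  GM a = %.4g, GM b = %.4g ng/mL\n", x$gm_a, x$gm_b))
  }
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with the t-based two-sided p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# mean covariate over the years each province was actually sampled
# (falling back to all available years for provinces without year overlap)
.aggregate_covariate <- function(cov, value_col, province, years_by_prov,
                                 year_rule) {
  vapply(province, function(p) {
    rows <- cov[cov$province == p, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    if (year_rule == "latest") {
      return(rows[[value_col]][which.max(rows$year)])
    }
    if (year_rule == "sampled" && !is.null(years_by_prov[[p]])) {
      sel <- rows$year %in% years_by_prov[[p]]
      if (any(sel)) rows <- rows[sel, , drop = FALSE]
    }
    mean(rows[[value_col]])
  }, numeric(1))
}

#' Correlate province-level pooled estimates with environmental covariates
#'
#' Pairs each province's pooled geometric mean (ln-transformed by default)
#' with its aggregated covariate value and reports Pearson r per covariate
#' column (garbage disposal, domestic sewage, waste incineration).
#'
#' Covariates are aggregated over years per province: `"sampled"` (default)
#' averages over the years in which the province's studies sampled (so
#' `studies` must be supplied), `"all"` averages all available years, and
#' `"latest"` takes the most recent year.
#'
#' @param pooled data frame with one row per province and columns
#'   `province` and `gm` (e.g. the province stratification of [pool()]).
#' @param covariates validated covariate data frame (or path).
#' @param studies study data frame used to determine sampled years (only
#'   needed for `year_rule = "sampled"`).
#' @param log_gm correlate `ln(gm)` (default) rather than raw `gm`.
#' @param year_rule `"sampled"`, `"all"` or `"latest"`.
#' @param strict error when a pooled province is absent from the covariate
#'   table (default); with `FALSE` unmatched provinces are dropped.
#' @return data frame with columns `covariate`, `r`, `p_value`, `n`.
#' @export
correlate_with_covariates <- function(pooled, covariates, studies = NULL,
                                      log_gm = TRUE,
                                      year_rule = c("sampled", "all", "latest"),
                                      strict = TRUE) {
  year_rule <- match.arg(year_rule)
  if (is.character(covariates)) covariates <- read_covariate_table(covariates)
  covariates <- validate_covariate_table(covariates)
  pooled <- as.data.frame(pooled)
  pooled <- pooled[pooled$province != "all", , drop = FALSE]
  if (!nrow(pooled)) stop("`pooled` has no province-level rows")
  if (anyDuplicated(pooled$province)) {
    stop("`pooled` must contain one row per province")
  }
  if (year_rule == "sampled" && is.null(studies)) {
    stop("year_rule = \"sampled\" requires the `studies` table")
  }
  years_by_prov <- NULL
  if (year_rule == "sampled") {
    studies <- validate_study_table(studies)
    years_by_prov <- lapply(split(studies, studies$province), function(d) {
      sort(unique(unlist(Map(seq, d$year_start, d$year_end))))
    })
  }
  matched <- pooled$province %in% covariates$province
  if (strict && !all(matched)) {
    stop("provinces missing from covariate table: ",
         paste(pooled$province[!matched], collapse = ", "))
  }
  pooled <- pooled[matched, , drop = FALSE]
  if (nrow(pooled) < 3) stop("fewer than 3 matched provinces")
  y <- if (log_gm) log(pooled$gm) else pooled$gm
  cols <- .covariate_columns[3:5]
  res <- lapply(cols, function(cl) {
    x <- .aggregate_covariate(covariates, cl, pooled$province,
                              years_by_prov, year_rule)
    pc <- pearson_cor(x, y)
    data.frame(covariate = cl, r = pc$r, p_value = pc$p_value, n = pc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
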