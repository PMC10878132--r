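# Conversion of reported summary statistics to simulatable distribution
# parameters: a normal (AM, SD) or lognormal (GM, GSD) specification plus a
# lower floor standing in for values below the limit of detection.

#' Distribution specification for one study
#'
#' Constructs the per-study simulated distribution: a `normal` family with
#' arithmetic mean `p1` and SD `p2`, or a `lognormal` family with geometric
#' mean `p1` and geometric SD `p2` (GSD >= 1). `floor` is the lower bound
#' substituted for smaller simulated values (half the limit of detection;
#' 0.5 ng/mL in the default policy).
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param p1 location: AM (normal) or GM (lognormal), ng/mL. Must be > 0
#'   for the lognormal family.
#' @param p2 scale: SD >= 0 (normal) or GSD >= 1 (lognormal).
#' @param floor non-negative concentration in ng/mL.
#' @param study_id optional identifier carried along.
#' @return object of class `distribution_spec`.
#' @export
distribution_spec <- function(family = c("normal", "lognormal"), p1, p2,
                              floor = 0.5, study_id = NA_character_) {
  family <- match.arg(family)
  stopifnot(is.numeric(p1), is.numeric(p2), is.numeric(floor),
            length(p1) == 1L, length(p2) == 1L, length(floor) == 1L)
  if (is.na(p1) || is.na(p2)) stop("distribution parameters must not be NA")
  if (floor < 0) stop("floor must be >= 0")
  if (family == "lognormal") {
    if (p1 <= 0) stop("GM must be > 0 for a lognormal spec")
    if (p2 < 1) stop("GSD must be >= 1")
  } else {
    if (p2 < 0) stop("SD must be >= 0")
  }
  structure(list(family = family, p1 = p1, p2 = p2, floor = floor,
                 study_id = study_id),
            class = "distribution_spec")
}

#' @export
print.distribution_spec <- function(x, ...) {
  lab <- if (x$family == "normal") c("AM", "SD") else c("GM", "GSD")
  cat(sprintf("<distribution_spec> %s(%s=%.4g, %s=%.4g), floor %.3g ng/mL\n",
              x$family, lab[1], x$p1, lab[2], x$p2, x$floor))
  invisible(x)
}

#' Standard deviation from a 95% confidence interval of the mean
#'
#' Recovers the sample SD from a reported 95% CI of the arithmetic mean.
#' The default `"sqrtN"` mode inverts the CI-of-the-mean identity
#' `width = 2 * 1.96 * SD / sqrt(N)`, i.e. `SD = sqrt(N) * (UCI - LCI) /
#' 3.92`. The `"literalN"` mode multiplies by `N` instead of `sqrt(N)`,
#' preserving a literal reading of the source formula; it yields SDs that
#' grow linearly in `N` and is provided for comparability only.
#'
#' @param n sample size (>= 2).
#' @param lci,uci lower and upper 95% confidence limits, ng/mL.
#' @param mode `"sqrtN"` (default) or `"literalN"`.
#' @return SD in ng/mL.
#' @examples
#' sd_from_ci(100, 0.804, 1.196) # 1
#' @export
sd_from_ci <- function(n, lci, uci, mode = c("sqrtN", "literalN")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n), is.numeric(lci), is.numeric(uci))
  if (any(n < 2)) stop("n must be >= 2: a CI width is undefined for n < 2")
  if (any(uci < lci)) stop("uci must be >= lci")
  fac <- if (mode == "sqrtN") sqrt(n) else n
  fac * (uci - lci) / 3.92
}

# quantile-matching z-scores (Wan-style positions)
.z_quartile <- function(n) qnorm((0.75 * n - 0.125) / (n + 0.25))
.z_range <- function(n) qnorm((n - 0.375) / (n + 0.25))

#' Mean and SD from median and quartiles
#'
#' Closed-form quantile-matching estimator for samples reported as
#' (q1, median, q3): `AM = (q1 + median + q3) / 3` and
#' `SD = (q3 - q1) / (2 * z((0.75 n - 0.125) / (n + 0.25)))`, `z` the
#' standard normal quantile function. As `n` grows the SD estimator
#' approaches the normal-theory limit `IQR / 1.349`.
#'
#' @param q1,med,q3 quartiles in ng/mL, `q1 <= med <= q3`.
#' @param n sample size (>= 2; the quantile position must give z > 0).
#' @return named numeric vector `c(am = , sd = )`.
#' @export
mean_sd_from_quartiles <- function(q1, med, q3, n) {
  stopifnot(is.numeric(q1), is.numeric(med), is.numeric(q3))
  if (any(q1 > med | med > q3)) stop("requires q1 <= median <= q3")
  p <- (0.75 * n - 0.125) / (n + 0.25)
  if (any(p <= 0 | p >= 1)) stop("quantile position outside (0, 1); n too small")
  z <- qnorm(p)
  if (any(z <= 0)) stop("n too small for the quartile SD estimator (need n >= 2)")
  c(am = (q1 + med + q3) / 3, sd = (q3 - q1) / (2 * z))
}

#' Mean and SD from median and range
#'
#' Closed-form quantile-matching estimator for samples reported as
#' (min, median, max): `AM = (min + 2 median + max) / 4` and
#' `SD = (max - min) / (2 * z((n - 0.375) / (n + 0.25)))`.
#'
#' @param xmin,med,xmax minimum, median and maximum in ng/mL.
#' @param n sample size (>= 2).
#' @return named numeric vector `c(am = , sd = )`.
#' @export
mean_sd_from_range <- function(xmin, med, xmax, n) {
  stopifnot(is.numeric(xmin), is.numeric(med), is.numeric(xmax))
  if (any(xmin > med | med > xmax)) stop("requires min <= median <= max")
  if (any(n < 2)) stop("n must be >= 2")
  p <- (n - 0.375) / (n + 0.25)
  if (any(p <= 0 | p >= 1)) stop("quantile position outside (0, 1)")
  c(am = (xmin + 2 * med + xmax) / 4, sd = (xmax - xmin) / (2 * qnorm(p)))
}

# Resolve the simulation floor for one study from the floor policy.
# list(constant = 0.5): fixed floor; list(half_lod = TRUE): LOD/2 when the
# study records an LOD (converted to ng/mL), 0.5 otherwise.
.resolve_floor <- function(lod_ngml, floor_policy) {
  if (!is.list(floor_policy)) stop("floor_policy must be a list")
  if (!is.null(floor_policy$constant)) {
    fl <- floor_policy$constant
    if (!is.numeric(fl) || fl < 0) stop("constant floor must be >= 0")
    return(fl)
  }
  if (isTRUE(floor_policy$half_lod)) {
    return(if (is.na(lod_ngml)) 0.5 else lod_ngml / 2)
  }
  stop("floor_policy must be list(constant = <x>) or list(half_lod = TRUE)")
}

#' Convert a study record to a distribution specification
#'
#' Maps the reported summary statistics of one validated study stratum to
#' the simulated distribution family and parameters:
#' \itemize{
#'   \item `GM_GSD` records become a lognormal spec unchanged;
#'   \item `AM_SD` records become a normal spec unchanged;
#'   \item `MEAN_CI` records become a normal spec with SD from
#'     [sd_from_ci()];
#'   \item `MEDIAN_IQR` / `MEDIAN_RANGE` records are quantile-matched.
#'     With `median_family = "lognormal"` (default) the matching is done on
#'     the log scale, so the reported quantiles are treated as quantiles of
#'     a lognormal concentration distribution and converted to (GM, GSD);
#'     concentration biomarkers are conventionally lognormal, and quantiles
#'     transform exactly under the logarithm. With
#'     `median_family = "normal"` the estimators of
#'     [mean_sd_from_quartiles()] / [mean_sd_from_range()] are applied on
#'     the arithmetic scale. Records containing a zero quantile fall back
#'     to the arithmetic scale automatically.
#' }
#' All concentrations are converted to ng/mL first; creatinine-adjusted
#' records raise a non-convertible-unit error.
#'
#' @param record single study record: one-row data frame or named list with
#'   the study-table fields.
#' @param floor_policy `list(constant = 0.5)` (default) or
#'   `list(half_lod = TRUE)`.
#' @param sd_from_ci_mode passed to [sd_from_ci()].
#' @param median_family `"lognormal"` (default) or `"normal"`; branch used
#'   for `MEDIAN_IQR` and `MEDIAN_RANGE` records.
#' @return a [distribution_spec()].
#' @export
to_distribution_spec <- function(record, floor_policy = list(constant = 0.5),
                                 sd_from_ci_mode = c("sqrtN", "literalN"),
                                 median_family = c("lognormal", "normal")) {
  sd_from_ci_mode <- match.arg(sd_from_ci_mode)
  median_family <- match.arg(median_family)
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  unit <- .normalize_unit(record$unit)
  cv <- function(x) convert_unit(x, unit)
  lod <- if (is.null(record$lod) || is.na(record$lod)) NA_real_ else cv(record$lod)
  fl <- .resolve_floor(lod, floor_policy)
  kind <- record$summary_kind
  id <- if (is.null(record$study_id)) NA_character_ else record$study_id

  if (kind == "GM_GSD") {
    return(distribution_spec("lognormal", cv(record$s1), record$s2, fl, id))
  }
  if (kind == "AM_SD") {
    return(distribution_spec("normal", cv(record$s1), cv(record$s2), fl, id))
  }
  if (kind == "MEAN_CI") {
    sdv <- sd_from_ci(record$n, cv(record$s2), cv(record$s3),
                      mode = sd_from_ci_mode)
    return(distribution_spec("normal", cv(record$s1), sdv, fl, id))
  }
  if (!(kind %in% c("MEDIAN_IQR", "MEDIAN_RANGE"))) {
    stop("unknown summary_kind '", kind, "'")
  }
  q <- cv(c(record$s1, record$s2, record$s3))
  est <- if (kind == "MEDIAN_IQR") mean_sd_from_quartiles else mean_sd_from_range
  if (median_family == "lognormal" && all(q > 0)) {
    ln <- est(log(q[1]), log(q[2]), log(q[3]), record$n)
    distribution_spec("lognormal", exp(ln[["am"]]), exp(ln[["sd"]]), fl, id)
  } else {
    ms <- est(q[1], q[2], q[3], record$n)
    distribution_spec("normal", ms[["am"]], ms[["sd"]], fl, id)
  }
}
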