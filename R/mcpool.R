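# Front-door estimator: simulate + pool in one call, returning a classed
# object with the usual modelling methods.

#' Monte Carlo pooled geometric-mean exposure estimates
#'
#' Runs the full estimator on a study corpus: converts each study's
#' reported summary statistics to a normal or lognormal distribution with
#' a detection-limit floor, simulates `replicates` replicate tables of
#' floored inverse-CDF draws (the study's sample size `n` draws per study
#' by default), and pools the simulated database into stratified
#' geometric means with replicate-percentile intervals.
#'
#' @param studies validated study data frame or path to `studies.csv`.
#' @param by stratification variables, subset of
#'   `c("matrix", "period", "province", "sex", "age_band")`.
#' @param replicates number of Monte Carlo replicate tables (default 100).
#' @param seed integer master seed; the result is deterministic given
#'   `(studies, seed)`.
#' @param draws_per_study,floor_policy,sd_from_ci_mode,median_family
#'   simulation settings, see [run_simulation()].
#' @param period_bins optional custom period bins, see [assign_period()].
#' @param level confidence level of the replicate-percentile intervals.
#' @return object of class `mc_pool` with components `estimates` (the
#'   [pool()] table), `replicate_gms`, `by`, `replicates`, `seed`,
#'   `settings`, `n_studies`, `skipped` and `call`. Methods: `print`,
#'   `summary`, `coef` (named GM vector), `confint`, `plot`.
#' @examples
#' corpus <- generate_corpus(generator_config(studies_per_stratum = 3,
#'                                            n_range = c(10, 50), seed = 7))
#' fit <- mc_pool(corpus$studies, replicates = 10, seed = 7)
#' coef(fit)
#' @export
mc_pool <- function(studies, by = c("matrix", "period"), replicates = 100L,
                    seed = 1L, draws_per_study = "n",
                    floor_policy = list(constant = 0.5),
                    sd_from_ci_mode = "sqrtN",
                    median_family = "lognormal", period_bins = NULL,
                    level = 0.95) {
  sim <- run_simulation(studies, replicates = replicates, seed = seed,
                        draws_per_study = draws_per_study,
                        floor_policy = floor_policy,
                        sd_from_ci_mode = sd_from_ci_mode,
                        median_family = median_family, keep_draws = FALSE)
  est <- pool(sim, by = by, period_bins = period_bins, level = level)
  structure(list(estimates = est,
                 replicate_gms = attr(est, "replicate_gms"),
                 by = by, replicates = sim$replicates, seed = sim$seed,
                 settings = sim$settings, n_studies = nrow(sim$studies),
                 skipped = sim$skipped, level = level,
                 call = match.call()),
            class = "mc_pool")
}

.stratum_labels <- function(x) {
  apply(x$estimates[x$by], 1, paste, collapse = "/")
}

#' @export
print.mc_pool <- function(x, ...) {
  cat("Monte Carlo pooled geometric means (ng/mL)\n")
  cat(sprintf("  %d studies, %d replicates, seed %d; stratified by %s\n",
              x$n_studies, x$replicates, x$seed,
              paste(x$by, collapse = " x ")))
  gm <- setNames(round(x$estimates$gm, 3), .stratum_labels(x))
  print(gm)
  invisible(x)
}

#' @export
summary.mc_pool <- function(object, ...) {
  est <- object$estimates
  cat("Monte Carlo pooled exposure estimates\n")
  cat(sprintf("  studies: %d   replicates: %d   seed: %d\n",
              object$n_studies, object$replicates, object$seed))
  if (nrow(object$skipped)) {
    cat(sprintf("  skipped studies: %d\n", nrow(object$skipped)))
  }
  cat(sprintf("  floor policy: %s   sd_from_ci: %s   median family: %s\n",
              paste(deparse(object$settings$floor_policy), collapse = ""),
              object$settings$sd_from_ci_mode,
              object$settings$median_family))
  print(as.data.frame(est), row.names = FALSE)
  invisible(est)
}

#' @export
coef.mc_pool <- function(object, ...) {
  setNames(object$estimates$gm, .stratum_labels(object))
}

#' @export
confint.mc_pool <- function(object, parm, level = 0.95, ...) {
  G <- object$replicate_gms
  alpha <- (1 - level) / 2
  ci <- t(apply(G, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  rownames(ci) <- .stratum_labels(object)
  colnames(ci) <- sprintf("%.1f %%", 100 * c(alpha, 1 - alpha))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.mc_pool <- function(x, ...) {
  est <- x$estimates
  labs <- .stratum_labels(x)
  n <- nrow(est)
  plot(seq_len(n), est$gm, xaxt = "n", xlab = "", pch = 19,
       ylim = range(c(est$ci_low, est$ci_high)),
       ylab = "pooled GM (ng/mL)", ...)
  axis(1, at = seq_len(n), labels = labs, las = 2, cex.axis = 0.8)
  arrows(seq_len(n), est$ci_low, seq_len(n), est$ci_high,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}
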