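# Seeded Monte Carlo engine: floored inverse-CDF draws per study per
# replicate. Draws mirror spreadsheet-style construction
# max(floor, NORM.INV(u, AM, SD)) / max(floor, LOGNORM.INV(u, ln GM, ln GSD))
# with u uniform(0, 1), rather than calling a native normal sampler, so the
# floored-quantile semantics stay literal.

# Deterministic substream seed from (seed, study_id, replicate): a rolling
# 31x hash mod a prime < 2^31. Keyed per study so adding or removing one
# study never perturbs the draws of the others.
.substream_seed <- function(seed, study_id, replicate) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(study_id))) h <- (h * 31 + ch) %% m
  h <- (h * 31 + replicate %% 65536) %% m
  h <- (h * 31 + replicate %/% 65536) %% m
  as.integer(h)
}

.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

#' Draw floored concentrations from a study distribution
#'
#' Inverse-CDF sampling: for uniforms `u` the normal family returns
#' `max(floor, qnorm(u, AM, SD))` and the lognormal family
#' `max(floor, exp(qnorm(u, ln GM, ln GSD)))`. Zero-variance
#' specifications (SD 0 or GSD 1) return the location floored.
#'
#' @param spec a [distribution_spec()].
#' @param k number of draws (>= 1).
#' @param u optional vector of `k` uniforms in `[0, 1)`; by default drawn
#'   from the current RNG state.
#' @return numeric vector of `k` concentrations, all `>= spec$floor`.
#' @export
draw_study <- function(spec, k, u = NULL) {
  stopifnot(inherits(spec, "distribution_spec"), k >= 1)
  if (is.null(u)) {
    u <- runif(k)
  } else {
    stopifnot(length(u) == k, all(u >= 0 & u < 1))
  }
  x <- if (spec$family == "normal") {
    if (spec$p2 == 0) rep(spec$p1, k) else qnorm(u, spec$p1, spec$p2)
  } else {
    sdlog <- log(spec$p2)
    if (sdlog == 0) rep(spec$p1, k) else exp(qnorm(u, log(spec$p1), sdlog))
  }
  pmax(spec$floor, x)
}

#' Run the Monte Carlo simulation over a study corpus
#'
#' Converts each validated study record to a distribution specification
#' (see [to_distribution_spec()]) and generates `replicates` independent
#' replicate tables of floored draws per study. Per-study draw counts
#' default to the study's reported sample size `n`, so downstream pooling
#' is implicitly sample-size weighted. Records that cannot be converted
#' (for example creatinine-adjusted units) are skipped with a logged
#' reason; simulation proceeds for the rest.
#'
#' Reproducibility: each (study, replicate) cell draws from its own
#' substream seeded by `(seed, study_id, replicate)`, so identical seeds
#' give bitwise-identical draws and adding a study leaves all other draws
#' unchanged. The caller's RNG state is preserved.
#'
#' @param studies validated study data frame (or a path to `studies.csv`).
#' @param replicates number of replicate tables (default 100).
#' @param seed integer master seed.
#' @param draws_per_study `"n"` (default: the study's sample size) or a
#'   fixed positive integer.
#' @param floor_policy,sd_from_ci_mode,median_family passed to
#'   [to_distribution_spec()].
#' @param keep_draws keep the full draw vectors (`TRUE`, default). With
#'   `FALSE` only the per-study per-replicate log-sums needed for
#'   geometric-mean pooling are retained, which bounds memory for large
#'   corpora.
#' @return object of class `mc_simulation`: list with elements `studies`
#'   (validated records that simulated), `specs`, `draws` (nested list
#'   `[[study]][[replicate]]`, or `NULL`), `sumlog` (matrix studies x
#'   replicates of sums of log draws), `k` (draws per study), `skipped`
#'   (data frame of study_id, reason), `replicates`, `seed`, `settings`.
#' @export
run_simulation <- function(studies, replicates = 100L, seed = 1L,
                           draws_per_study = "n",
                           floor_policy = list(constant = 0.5),
                           sd_from_ci_mode = "sqrtN",
                           median_family = "lognormal",
                           keep_draws = TRUE) {
  if (is.character(studies)) studies <- read_study_table(studies)
  studies <- validate_study_table(studies)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  if (anyDuplicated(studies$study_id)) {
    stop("study_id values must be unique")
  }

  specs <- vector("list", nrow(studies))
  skip_id <- character(0); skip_reason <- character(0)
  for (i in seq_len(nrow(studies))) {
    specs[i] <- list(tryCatch(
      to_distribution_spec(studies[i, ], floor_policy = floor_policy,
                           sd_from_ci_mode = sd_from_ci_mode,
                           median_family = median_family),
      error = function(e) {
        skip_id <<- c(skip_id, studies$study_id[i])
        skip_reason <<- c(skip_reason, conditionMessage(e))
        NULL
      }))
  }
  ok <- !vapply(specs, is.null, logical(1))
  if (length(skip_id)) {
    message("skipping ", length(skip_id), " of ", nrow(studies),
            " studies (unconvertible records); see $skipped")
  }
  studies <- studies[ok, , drop = FALSE]
  rownames(studies) <- NULL
  specs <- specs[ok]
  if (!nrow(studies)) stop("no simulatable studies after conversion")

  k <- if (identical(draws_per_study, "n")) {
    studies$n
  } else {
    kk <- as.integer(draws_per_study)
    if (is.na(kk) || kk < 1L) stop("draws_per_study must be \"n\" or a positive integer")
    rep(kk, nrow(studies))
  }

  sumlog <- matrix(NA_real_, nrow(studies), replicates)
  draws <- if (keep_draws) {
    lapply(seq_len(nrow(studies)), function(i) vector("list", replicates))
  } else NULL
  .with_preserved_rng({
    for (i in seq_len(nrow(studies))) {
      for (r in seq_len(replicates)) {
        set.seed(.substream_seed(seed, studies$study_id[i], r))
        x <- draw_study(specs[[i]], k[i])
        sumlog[i, r] <- sum(log(x))
        if (keep_draws) draws[[i]][[r]] <- x
      }
    }
  })
  if (keep_draws) names(draws) <- studies$study_id
  rownames(sumlog) <- studies$study_id

  structure(list(
    studies = studies, specs = specs, draws = draws, sumlog = sumlog,
    k = setNames(k, studies$study_id),
    skipped = data.frame(study_id = skip_id, reason = skip_reason,
                         stringsAsFactors = FALSE),
    replicates = replicates, seed = as.integer(seed),
    settings = list(draws_per_study = draws_per_study,
                    floor_policy = floor_policy,
                    sd_from_ci_mode = sd_from_ci_mode,
                    median_family = median_family)
  ), class = "mc_simulation")
}

#' @export
print.mc_simulation <- function(x, ...) {
  cat(sprintf(
    "<mc_simulation> %d studies x %d replicates, %s draws total (seed %d)\n",
    nrow(x$studies), x$replicates,
    format(sum(x$k) * x$replicates, big.mark = ","), x$seed))
  if (nrow(x$skipped)) {
    cat("  skipped:", nrow(x$skipped), "studies (see $skipped)\n")
  }
  invisible(x)
}

#' Simulated draws in long format
#'
#' @param sim an `mc_simulation` run with `keep_draws = TRUE`.
#' @return data frame with columns `study_id`, `replicate`, `draw_index`,
#'   `value`.
#' @export
sim_to_long <- function(sim) {
  stopifnot(inherits(sim, "mc_simulation"))
  if (is.null(sim$draws)) stop("simulation was run with keep_draws = FALSE")
  out <- lapply(names(sim$draws), function(id) {
    reps <- sim$draws[[id]]
    do.call(rbind, lapply(seq_along(reps), function(r) {
      data.frame(study_id = id, replicate = r,
                 draw_index = seq_along(reps[[r]]), value = reps[[r]],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}
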