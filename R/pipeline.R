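# Pipeline orchestration: simulate -> pool over standard stratifications
# -> group comparisons -> covariate associations, with CSV outputs and a
# run manifest. Long-format CSV is the interchange so each stage remains
# independently runnable.

.default_stratifications <- function() {
  list(period = c("matrix", "period"),
       province = c("matrix", "province"),
       sex = c("matrix", "sex"),
       age = c("matrix", "age_band"))
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_pipeline()] (`studies`,
#' `covariates`, `out_dir`, `replicates`, `seed`, `floor_policy`,
#' `sd_from_ci_mode`, `median_family`, `draws_per_study`, `year_rule`,
#' `associate`).
#'
#' @param path YAML file path.
#' @return named list usable as `run_pipeline(config = )`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  yaml::read_yaml(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pooling pipeline
#'
#' Reads the study (and optionally covariate) tables, runs the Monte Carlo
#' simulation once, pools it by period, province, sex and age band, tests
#' the sex and children/adults contrasts on per-replicate geometric means
#' (Mann-Whitney U), correlates province-level estimates with the
#' environmental covariates, and writes every table plus a run manifest to
#' `out_dir`. Deterministic given (inputs, seed): re-running with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config named list (or path to a YAML file, see
#'   [read_run_config()]) with elements: `studies` (path or data frame,
#'   required), `covariates` (path or data frame, optional), `out_dir`
#'   (required), `replicates` (default 100), `seed` (default 1),
#'   `draws_per_study`, `floor_policy`, `sd_from_ci_mode`,
#'   `median_family`, `year_rule`, `associate` (default: covariates
#'   supplied), `stratifications` (named list of `by` vectors).
#' @return invisible list with the pooled tables, comparison and
#'   association tables, and output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$studies)) stop("config$studies is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  replicates <- if (is.null(config$replicates)) 100L else config$replicates
  seed <- if (is.null(config$seed)) 1L else config$seed
  floor_policy <- if (is.null(config$floor_policy)) list(constant = 0.5) else config$floor_policy
  sd_mode <- if (is.null(config$sd_from_ci_mode)) "sqrtN" else config$sd_from_ci_mode
  med_fam <- if (is.null(config$median_family)) "lognormal" else config$median_family
  dps <- if (is.null(config$draws_per_study)) "n" else config$draws_per_study
  year_rule <- if (is.null(config$year_rule)) "sampled" else config$year_rule
  strats <- if (is.null(config$stratifications)) .default_stratifications() else config$stratifications
  associate <- if (is.null(config$associate)) !is.null(config$covariates) else isTRUE(config$associate)

  if (associate) {
    if (is.null(config$covariates)) {
      stop("stage 'associate' failed: covariate table required when ",
           "association is requested", call. = FALSE)
    }
    if (is.character(config$covariates) && !file.exists(config$covariates)) {
      stop("stage 'associate' failed: covariate file not found: ",
           config$covariates, call. = FALSE)
    }
  }

  studies <- .stage("read", {
    if (is.character(config$studies)) read_study_table(config$studies)
    else validate_study_table(config$studies)
  })
  covariates <- if (associate) .stage("read", {
    if (is.character(config$covariates)) read_covariate_table(config$covariates)
    else validate_covariate_table(config$covariates)
  }) else NULL

  sim <- .stage("simulate",
    run_simulation(studies, replicates = replicates, seed = seed,
                   draws_per_study = dps, floor_policy = floor_policy,
                   sd_from_ci_mode = sd_mode, median_family = med_fam,
                   keep_draws = FALSE))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  pooled <- .stage("pool", {
    res <- list()
    for (nm in names(strats)) {
      p <- suppressWarnings(pool(sim, by = strats[[nm]]))
      path <- file.path(config$out_dir, paste0("pooled_", nm, ".csv"))
      write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
      outputs[paste0("pooled_", nm)] <- path
      res[[nm]] <- p
    }
    res
  })

  comparisons <- .stage("compare", {
    meta <- sim$studies
    band <- .coarse_age(assign_age_band(meta$age_min, meta$age_max))
    rows <- list()
    for (m in unique(meta$matrix)) {
      in_m <- meta$matrix == m
      cmp <- function(label, sel_a, sel_b, name_a, name_b) {
        if (!any(sel_a) || !any(sel_b)) return(NULL)
        ga <- .group_replicate_gms(
          list(sumlog = sim$sumlog[sel_a, , drop = FALSE], k = sim$k[sel_a]),
          rep("g", sum(sel_a)))
        gb <- .group_replicate_gms(
          list(sumlog = sim$sumlog[sel_b, , drop = FALSE], k = sim$k[sel_b]),
          rep("g", sum(sel_b)))
        mw <- mann_whitney(as.vector(ga), as.vector(gb))
        data.frame(matrix = m, comparison = label, group_a = name_a,
                   group_b = name_b, gm_a = mw$gm_a, gm_b = mw$gm_b,
                   u_statistic = mw$u_statistic, p_value = mw$p_value,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(
        cmp("sex", in_m & meta$sex == "male", in_m & meta$sex == "female",
            "male", "female"),
        cmp("age", in_m & band == "0-18", in_m & band == "19+",
            "0-18", "19+")))
    }
    out <- do.call(rbind, rows)
    if (!is.null(out) && nrow(out)) {
      path <- file.path(config$out_dir, "comparisons.csv")
      write.csv(out, path, row.names = FALSE, quote = FALSE)
      outputs["comparisons"] <- path
    }
    out
  })

  associations <- if (associate) .stage("associate", {
    rows <- list()
    for (m in unique(sim$studies$matrix)) {
      pm <- suppressWarnings(pool(
        list_subset_sim(sim, sim$studies$matrix == m),
        by = "province"))
      if (nrow(pm) < 3) next
      a <- correlate_with_covariates(pm, covariates, studies = sim$studies,
                                     year_rule = year_rule, strict = FALSE)
      a <- cbind(matrix = m, a, stringsAsFactors = FALSE)
      rows[[m]] <- a
    }
    if (!length(rows)) {
      stop("fewer than 3 provinces in every matrix; cannot correlate")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    path <- file.path(config$out_dir, "associations.csv")
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    outputs["associations"] <- path
    out
  }) else NULL

  manifest <- .stage("manifest", {
    man <- list(
      package = "expopool",
      version = as.character(packageVersion("expopool")),
      seed = as.integer(seed), replicates = as.integer(replicates),
      settings = list(draws_per_study = dps, floor_policy = floor_policy,
                      sd_from_ci_mode = sd_mode, median_family = med_fam,
                      year_rule = year_rule),
      inputs = list(
        studies = if (is.character(config$studies)) config$studies else "<data frame>",
        covariates = if (is.null(config$covariates)) NULL
                     else if (is.character(config$covariates)) config$covariates
                     else "<data frame>"),
      n_studies = nrow(sim$studies),
      n_skipped = nrow(sim$skipped),
      skipped = sim$skipped,
      outputs = as.list(setNames(basename(outputs), names(outputs))))
    path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    path
  })

  invisible(list(pooled = pooled, comparisons = comparisons,
                 associations = associations, manifest = manifest,
                 outputs = outputs, sim = sim))
}

# restrict an mc_simulation to a logical subset of its studies
list_subset_sim <- function(sim, sel) {
  out <- sim
  out$studies <- sim$studies[sel, , drop = FALSE]
  out$sumlog <- sim$sumlog[sel, , drop = FALSE]
  out$k <- sim$k[sel]
  out$specs <- sim$specs[sel]
  if (!is.null(sim$draws)) out$draws <- sim$draws[sel]
  out
}
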