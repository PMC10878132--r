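# Synthetic literature-corpus generator. Each stratum has a known
# lognormal ground truth (GM, GSD); studies draw a latent individual-level
# sample and report it with one of the five summary kinds, so every
# conversion path of the pipeline is exercised against known parameters.
# Province-level covariates are linear in ln(GM) plus Gaussian noise.

#' Temporal ground-truth strata
#'
#' Five urine sampling periods with geometric means echoing a realistic
#' national trend (flat around 1.7-1.9 ng/mL, jumping to 2.9 ng/mL in the
#' final period) at GSD 2.
#'
#' @param gms geometric means per period, ng/mL.
#' @param gsd common geometric SD.
#' @param province,sex,age_band stratum metadata.
#' @return data frame of generator strata.
#' @export
temporal_truth <- function(gms = c(1.9, 1.8, 1.9, 1.7, 2.9), gsd = 2,
                           province = "Guangdong", sex = "mixed",
                           age_band = "19-44") {
  periods <- .bin_labels(.urine_bins)
  stopifnot(length(gms) == length(periods))
  data.frame(matrix = "urine", period = periods, province = province,
             sex = sex, age_band = age_band, true_gm = gms, true_gsd = gsd,
             stringsAsFactors = FALSE)
}

#' Province-level ground-truth strata
#'
#' Eighteen provinces with geometric means log-spaced over a realistic
#' national range (default 3.5 down to 0.8 ng/mL, the highest assigned to
#' Guangdong), one urine stratum per province.
#'
#' @param n_provinces number of provinces (up to 18 defaults).
#' @param gm_range range (high, low) of geometric means, ng/mL.
#' @param gsd common geometric SD.
#' @param period period label for every stratum.
#' @return data frame of generator strata.
#' @export
province_truth <- function(n_provinces = 18, gm_range = c(3.5, 0.8),
                           gsd = 2, period = "2012-2014") {
  provs <- c("Guangdong", "Zhejiang", "Fujian", "Jiangsu", "Shandong",
             "Shanghai", "Beijing", "Tianjin", "Hebei", "Henan", "Hubei",
             "Hunan", "Sichuan", "Chongqing", "Liaoning", "Jilin",
             "Heilongjiang", "Anhui")
  stopifnot(n_provinces >= 3, n_provinces <= length(provs))
  provs <- provs[seq_len(n_provinces)]
  gms <- exp(seq(log(gm_range[1]), log(gm_range[2]),
                 length.out = n_provinces))
  data.frame(matrix = "urine", period = period, province = provs,
             sex = "mixed", age_band = "19-44", true_gm = gms,
             true_gsd = gsd, stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' Defines the synthetic corpus: ground-truth strata, number of studies
#' per stratum, the envelope of study sample sizes, the mix of reported
#' summary kinds, the limit of detection, and the strength of the linear
#' relationship between province ln(GM) and the environmental covariates.
#'
#' Defaults emulate a literature corpus in which most studies report the
#' median with quartiles and fewer report geometric or arithmetic means;
#' min-max-range studies are restricted to small cohorts
#' (`n <= range_n_max`), where that reporting style occurs in practice and
#' where range-based estimators are rated. The default LOD of 1 ng/mL
#' makes LOD/2 coincide with the conventional 0.5 ng/mL substitution
#' floor.
#'
#' @param strata data frame as from [temporal_truth()] or
#'   [province_truth()] (columns matrix, period, province, sex, age_band,
#'   true_gm, true_gsd).
#' @param studies_per_stratum studies generated per stratum.
#' @param n_range integer envelope of study sample sizes, within
#'   `[10, 3426]`.
#' @param summary_kind_mix named probabilities over the five summary
#'   kinds, summing to 1.
#' @param lod limit of detection, ng/mL, recorded on every study.
#' @param covariate_slope linear coefficient linking province ln(GM) to
#'   each covariate (on the covariate scale of 100 units per ln unit).
#' @param noise_sd SD of the Gaussian covariate noise on the ln(GM) scale;
#'   default half the between-province SD of ln(GM) times the slope
#'   (signal-to-noise 2).
#' @param range_n_max maximum sample size assigned to MEDIAN_RANGE
#'   studies.
#' @param seed integer generator seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(strata = temporal_truth(),
                             studies_per_stratum = 20L,
                             n_range = c(10L, 3426L),
                             summary_kind_mix = c(AM_SD = 0.20,
                                                  GM_GSD = 0.25,
                                                  MEDIAN_IQR = 0.35,
                                                  MEDIAN_RANGE = 0.10,
                                                  MEAN_CI = 0.10),
                             lod = 1.0, covariate_slope = 1.0,
                             noise_sd = NULL, range_n_max = 100L,
                             seed = 1L) {
  if (!is.data.frame(strata) || !nrow(strata)) {
    stop("`strata` must be a non-empty data frame")
  }
  need <- c("matrix", "period", "province", "sex", "age_band", "true_gm",
            "true_gsd")
  missing_cols <- setdiff(need, names(strata))
  if (length(missing_cols)) {
    stop("strata columns missing: ", paste(missing_cols, collapse = ", "))
  }
  if (any(strata$true_gm <= 0)) stop("true_gm must be > 0")
  if (any(strata$true_gsd < 1)) stop("true_gsd must be >= 1")
  if (!setequal(names(summary_kind_mix), .summary_kinds)) {
    stop("summary_kind_mix must name exactly the five summary kinds")
  }
  if (abs(sum(summary_kind_mix) - 1) > 1e-8) {
    stop("summary_kind_mix probabilities must sum to 1")
  }
  if (any(summary_kind_mix < 0)) stop("summary_kind_mix must be >= 0")
  n_range <- as.integer(n_range)
  if (length(n_range) != 2L || n_range[1] > n_range[2] ||
      n_range[1] < 10L || n_range[2] > 3426L) {
    stop("n_range must be within [10, 3426]")
  }
  if (is.null(noise_sd)) {
    lngm <- tapply(log(strata$true_gm), strata$province, mean)
    s <- if (length(lngm) > 1) sd(lngm) else 0.2
    noise_sd <- abs(covariate_slope) * s / 2
    if (noise_sd == 0) noise_sd <- 0.1
  }
  structure(list(strata = strata,
                 studies_per_stratum = as.integer(studies_per_stratum),
                 n_range = n_range, summary_kind_mix = summary_kind_mix,
                 lod = lod, covariate_slope = covariate_slope,
                 noise_sd = noise_sd, range_n_max = as.integer(range_n_max),
                 seed = as.integer(seed)),
            class = "generator_config")
}

.parse_period <- function(label) {
  as.integer(strsplit(label, "-", fixed = TRUE)[[1]])
}

.band_to_ages <- function(band) {
  map <- list("0-6" = c(0L, 6L), "7-18" = c(7L, 18L), "19-44" = c(19L, 44L),
              "45+" = c(45L, 79L), "0-18" = c(0L, 18L), "19+" = c(19L, 79L))
  if (is.null(map[[band]])) stop("unknown age_band '", band, "'")
  map[[band]]
}

# summarize one latent sample according to the assigned summary kind
.summarize_latent <- function(x, kind, n) {
  if (kind == "AM_SD") {
    c(mean(x), sd(x), NA_real_)
  } else if (kind == "GM_GSD") {
    c(exp(mean(log(x))), exp(sd(log(x))), NA_real_)
  } else if (kind == "MEDIAN_IQR") {
    unname(quantile(x, c(0.25, 0.5, 0.75)))
  } else if (kind == "MEDIAN_RANGE") {
    c(min(x), median(x), max(x))
  } else {
    m <- mean(x); se <- sd(x) / sqrt(n)
    c(m, max(0, m - 1.96 * se), m + 1.96 * se)
  }
}

#' Generate a synthetic literature corpus
#'
#' For every stratum and study: draws a sample size from `n_range`, a
#' latent individual-level sample from Lognormal(true_gm, true_gsd), and a
#' summary kind from `summary_kind_mix`; summarizes the latent sample
#' accordingly; and assigns a sampling year range inside the stratum's
#' period bin. Covariate tables are emitted per province and year as
#' `intercept + 100 * slope * ln(GM_province) + noise`. The truth table
#' records every stratum's generating parameters, so tests never re-derive
#' them.
#'
#' The corpus is deterministic given `config$seed`; the caller's RNG state
#' is preserved.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_corpus`: list with validated
#'   `studies`, `covariates` and `truth` data frames plus the `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  st <- config$strata
  .with_preserved_rng({
    set.seed(config$seed)
    rows <- vector("list", nrow(st) * config$studies_per_stratum)
    idx <- 0L
    for (i in seq_len(nrow(st))) {
      yr <- .parse_period(st$period[i])
      ages <- .band_to_ages(st$age_band[i])
      mu <- log(st$true_gm[i]); sig <- log(st$true_gsd[i])
      for (j in seq_len(config$studies_per_stratum)) {
        idx <- idx + 1L
        kind <- sample(names(config$summary_kind_mix), 1L,
                       prob = config$summary_kind_mix)
        nhi <- if (kind == "MEDIAN_RANGE") {
          max(config$n_range[1], min(config$n_range[2], config$range_n_max))
        } else config$n_range[2]
        nn <- seq(config$n_range[1], nhi)
        n <- nn[sample.int(length(nn), 1L)]
        latent <- exp(rnorm(n, mu, sig))
        s <- .summarize_latent(latent, kind, n)
        yrs <- seq(yr[1], yr[2])
        y0 <- yrs[sample.int(length(yrs), 1L)]
        y1 <- min(yr[2], y0 + sample(0:1, 1L, prob = c(0.7, 0.3)))
        rows[[idx]] <- data.frame(
          study_id = sprintf("S%04d", idx), matrix = st$matrix[i],
          province = st$province[i], year_start = y0, year_end = y1,
          sex = st$sex[i], age_min = ages[1], age_max = ages[2], n = n,
          summary_kind = kind, s1 = s[1], s2 = s[2], s3 = s[3],
          unit = "ng/mL", lod = config$lod, stringsAsFactors = FALSE)
      }
    }
    studies <- do.call(rbind, rows)

    provs <- unique(st$province)
    lngm <- tapply(log(st$true_gm), st$province, mean)[provs]
    years <- 2004:2019
    intercepts <- c(garbage_disposal = 500, domestic_sewage = 800,
                    waste_incineration = 300)
    cv <- expand.grid(province = provs, year = years,
                      stringsAsFactors = FALSE)
    cv <- cv[order(cv$province, cv$year), , drop = FALSE]
    for (cl in names(intercepts)) {
      cv[[cl]] <- pmax(0, intercepts[[cl]] +
                         100 * config$covariate_slope * lngm[cv$province] +
                         rnorm(nrow(cv), 0, 100 * config$noise_sd))
    }
    truth <- cbind(stratum_id = sprintf("T%03d", seq_len(nrow(st))), st,
                   n_studies = config$studies_per_stratum,
                   stringsAsFactors = FALSE)

    structure(list(studies = validate_study_table(studies),
                   covariates = validate_covariate_table(cv),
                   truth = truth, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d studies across %d strata, %d provinces (seed %d)\n",
    nrow(x$studies), nrow(x$truth),
    length(unique(x$covariates$province)), x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus to CSV files
#'
#' Emits `studies.csv`, `covariates.csv` and `truth.csv` in `dir`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(studies = file.path(dir, "studies.csv"),
             covariates = file.path(dir, "covariates.csv"),
             truth = file.path(dir, "truth.csv"))
  write_study_table(corpus$studies, paths[["studies"]])
  write.csv(corpus$covariates, paths[["covariates"]], row.names = FALSE,
            quote = FALSE)
  write.csv(corpus$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
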