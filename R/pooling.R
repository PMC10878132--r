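# Stratified geometric-mean pooling of simulated draws over period,
# province, sex and age band. Within each replicate the draws of all
# studies in a stratum are concatenated and ln-transformed; the replicate
# geometric mean is exp(mean(ln x)). The reported GM is the mean over
# replicates and its interval the 2.5/97.5 percentiles of the replicate
# GMs.

.urine_bins <- data.frame(start = c(2006, 2009, 2012, 2015, 2018),
                          end   = c(2008, 2011, 2014, 2017, 2019))
.serum_bins <- data.frame(start = c(2004, 2008, 2012, 2016),
                          end   = c(2007, 2011, 2015, 2019))

#' Default sampling-period bins
#'
#' Five three-to-two-year bins for urine (2006-2008 through 2018-2019) and
#' four four-year bins for serum (2004-2007 through 2016-2019).
#'
#' @return named list of data frames with columns `start`, `end`.
#' @export
default_period_bins <- function() {
  list(urine = .urine_bins, serum = .serum_bins)
}

.bin_labels <- function(bins) sprintf("%d-%d", bins$start, bins$end)

#' Assign a sampling period bin
#'
#' A study spanning `year_start..year_end` is assigned to the bin
#' containing its midpoint year (rounded half-up); studies whose midpoint
#' falls outside every bin get the sentinel `"unbinned"` and are excluded
#' from temporal pooling.
#'
#' @param matrix character vector, `"urine"` or `"serum"`.
#' @param year_start,year_end integer sampling years.
#' @param bins optional custom bin list as from [default_period_bins()];
#'   e.g. coarse two-bin map groupings can be supplied here.
#' @return character vector of period labels (`"2009-2011"` style) or
#'   `"unbinned"`.
#' @export
assign_period <- function(matrix, year_start, year_end, bins = NULL) {
  if (is.null(bins)) bins <- default_period_bins()
  stopifnot(length(matrix) == length(year_start),
            length(year_start) == length(year_end))
  mid <- floor((year_start + year_end) / 2 + 0.5)
  out <- rep("unbinned", length(mid))
  for (m in unique(matrix)) {
    b <- bins[[m]]
    if (is.null(b)) stop("no period bins defined for matrix '", m, "'")
    sel <- which(matrix == m)
    idx <- vapply(mid[sel], function(y) {
      w <- which(b$start <= y & y <= b$end)
      if (length(w)) w[1] else NA_integer_
    }, integer(1))
    out[sel][!is.na(idx)] <- .bin_labels(b)[idx[!is.na(idx)]]
  }
  out
}

.age_bands_fine <- list("0-6" = c(0, 6), "7-18" = c(7, 18),
                        "19-44" = c(19, 44), "45+" = c(45, Inf))
.age_bands_coarse <- list("0-18" = c(0, 18), "19+" = c(19, Inf))

#' Assign an age band
#'
#' Returns the finest band (`0-6`, `7-18`, `19-44`, `45+`) fully containing
#' `[age_min, age_max]`, falling back to the coarse children/adults split
#' (`0-18`, `19+`). Ranges crossing the 18/19 boundary get the sentinel
#' `"mixed"` and are excluded from age-stratified pooling.
#'
#' @param age_min,age_max integer ages in years.
#' @return character vector of band labels.
#' @export
assign_age_band <- function(age_min, age_max) {
  stopifnot(length(age_min) == length(age_max))
  bands <- c(.age_bands_fine, .age_bands_coarse)
  vapply(seq_along(age_min), function(i) {
    for (b in names(bands)) {
      if (age_min[i] >= bands[[b]][1] && age_max[i] <= bands[[b]][2]) return(b)
    }
    "mixed"
  }, character(1))
}

# coarse children/adults label from a fine band label
.coarse_age <- function(band) {
  ifelse(band %in% c("0-6", "7-18", "0-18"), "0-18",
         ifelse(band %in% c("19-44", "45+", "19+"), "19+", "mixed"))
}

# Per-replicate geometric means for an arbitrary grouping of studies.
# groups: factor of length nrow(sim$studies); returns matrix levels x
# replicates.
.group_replicate_gms <- function(sim, groups) {
  groups <- droplevels(as.factor(groups))
  S <- rowsum(sim$sumlog, groups)
  n <- as.vector(rowsum(as.numeric(sim$k), groups))
  exp(S / n)
}

#' Pool simulated draws into stratified geometric means
#'
#' @param sim an `mc_simulation` object from [run_simulation()].
#' @param by character vector of stratification variables, a subset of
#'   `c("matrix", "period", "province", "sex", "age_band")`.
#' @param period_bins optional custom period bins (see [assign_period()]).
#' @param level confidence level for the replicate-percentile interval.
#' @return data frame of class `pooled_estimates` with the five key
#'   columns (unstratified dimensions set to `"all"`), `gm`, `ci_low`,
#'   `ci_high`, `n_studies` and `n_draws`. The matrix of per-replicate
#'   geometric means is attached as attribute `"replicate_gms"`.
#' @export
pool <- function(sim, by = c("matrix", "period"), period_bins = NULL,
                 level = 0.95) {
  stopifnot(inherits(sim, "mc_simulation"))
  keys_all <- c("matrix", "period", "province", "sex", "age_band")
  if (!length(by) || !all(by %in% keys_all)) {
    stop("`by` must be a non-empty subset of: ",
         paste(keys_all, collapse = ", "))
  }
  st <- sim$studies
  meta <- data.frame(
    matrix = st$matrix,
    period = assign_period(st$matrix, st$year_start, st$year_end,
                           bins = period_bins),
    province = st$province,
    sex = st$sex,
    age_band = assign_age_band(st$age_min, st$age_max),
    stringsAsFactors = FALSE)

  keep <- rep(TRUE, nrow(meta))
  if ("period" %in% by && any(meta$period == "unbinned")) {
    warning(sum(meta$period == "unbinned"),
            " studies outside the period bins excluded from temporal pooling")
    keep <- keep & meta$period != "unbinned"
  }
  if ("age_band" %in% by && any(meta$age_band == "mixed")) {
    warning(sum(meta$age_band == "mixed"),
            " studies crossing the 18/19 boundary excluded from age pooling")
    keep <- keep & meta$age_band != "mixed"
  }
  if ("sex" %in% by) keep <- keep  # mixed sex is a legitimate stratum level
  if (!any(keep)) stop("no studies left after stratification exclusions")

  sub <- list(studies = st[keep, , drop = FALSE],
              sumlog = sim$sumlog[keep, , drop = FALSE],
              k = sim$k[keep])
  meta <- meta[keep, , drop = FALSE]
  key <- interaction(meta[by], drop = TRUE, sep = "\r", lex.order = TRUE)
  G <- .group_replicate_gms(sub, key)
  alpha <- (1 - level) / 2
  qs <- t(apply(G, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))

  parts <- do.call(rbind, strsplit(rownames(G), "\r", fixed = TRUE))
  out <- data.frame(matrix = "all", period = "all", province = "all",
                    sex = "all", age_band = "all",
                    stringsAsFactors = FALSE)[rep(1, nrow(G)), , drop = FALSE]
  for (j in seq_along(by)) out[[by[j]]] <- parts[, j]
  out$gm <- rowMeans(G)
  out$ci_low <- qs[, 1]
  out$ci_high <- qs[, 2]
  out$n_studies <- as.vector(table(key)[rownames(G)])
  out$n_draws <- as.vector(rowsum(as.numeric(sub$k), key)[rownames(G), 1])
  rownames(out) <- NULL
  attr(out, "replicate_gms") <- G
  attr(out, "by") <- by
  class(out) <- c("pooled_estimates", "data.frame")
  out
}
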