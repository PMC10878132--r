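# Study-record and covariate table IO and validation.
#
# studies.csv schema (fixed column order, one stratum per row):
#   study_id, matrix, province, year_start, year_end, sex, age_min, age_max,
#   n, summary_kind, s1, s2, s3, unit, lod
# Semantics of s1..s3 depend on summary_kind:
#   AM_SD        -> (AM, SD, NA)
#   GM_GSD       -> (GM, GSD, NA)          (GSD is dimensionless)
#   MEDIAN_IQR   -> (q1, median, q3)
#   MEDIAN_RANGE -> (min, median, max)
#   MEAN_CI      -> (AM, LCI, UCI)          (95% CI of the mean)

.study_columns <- c("study_id", "matrix", "province", "year_start",
                    "year_end", "sex", "age_min", "age_max", "n",
                    "summary_kind", "s1", "s2", "s3", "unit", "lod")
.covariate_columns <- c("province", "year", "garbage_disposal",
                        "domestic_sewage", "waste_incineration")
.summary_kinds <- c("AM_SD", "GM_GSD", "MEDIAN_IQR", "MEDIAN_RANGE",
                    "MEAN_CI")
.matrices <- c("urine", "serum")
.sexes <- c("male", "female", "mixed")

#' Canonical Chinese province-level divisions
#'
#' Province names accepted in study and covariate tables (matched
#' case-insensitively and normalized to this spelling).
#' @return character vector of canonical names.
#' @export
provinces_cn <- function() {
  c("Anhui", "Beijing", "Chongqing", "Fujian", "Gansu", "Guangdong",
    "Guangxi", "Guizhou", "Hainan", "Hebei", "Heilongjiang", "Henan",
    "Hubei", "Hunan", "Inner Mongolia", "Jiangsu", "Jiangxi", "Jilin",
    "Liaoning", "Ningxia", "Qinghai", "Shaanxi", "Shandong", "Shanghai",
    "Shanxi", "Sichuan", "Tianjin", "Tibet", "Xinjiang", "Yunnan",
    "Zhejiang", "Hong Kong", "Macao", "Taiwan")
}

.normalize_province <- function(x) {
  canon <- provinces_cn()
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  idx <- match(tolower(x), tolower(canon))
  out <- canon[idx]
  out[is.na(idx)] <- NA_character_
  attr(out, "unknown") <- x[is.na(idx)]
  out
}

#' Validate a study-record table
#'
#' Checks the documented schema and per-row invariants: allowed enum values,
#' `n >= 1`, `year_start <= year_end`, `age_min <= age_max`, non-negative
#' concentrations, the ordering constraints of each summary kind
#' (q1 <= median <= q3; min <= median <= max; LCI <= AM <= UCI) and
#' GSD >= 1. Province names are normalized against [provinces_cn()];
#' unknown provinces are an error.
#'
#' @param studies data frame with the `studies.csv` columns.
#' @return the validated data frame (provinces normalized, units
#'   micro-sign-normalized), invisibly classed as before.
#' @export
validate_study_table <- function(studies) {
  if (!is.data.frame(studies)) stop("`studies` must be a data frame")
  missing_cols <- setdiff(.study_columns, names(studies))
  if (length(missing_cols)) {
    stop("missing study table columns: ", paste(missing_cols, collapse = ", "))
  }
  studies <- studies[.study_columns]
  for (col in c("year_start", "year_end", "age_min", "age_max", "n")) {
    studies[[col]] <- as.integer(studies[[col]])
  }
  for (col in c("s1", "s2", "s3", "lod")) {
    studies[[col]] <- as.numeric(studies[[col]])
  }
  studies$unit <- .normalize_unit(studies$unit)
  errs <- character(0)
  add <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      errs <<- c(errs, sprintf("row %d: %s", which(rows), msg))
    }
  }
  bad_kind <- !(studies$summary_kind %in% .summary_kinds)
  add(bad_kind, paste0("unknown summary_kind; allowed: ",
                       paste(.summary_kinds, collapse = ", ")))
  add(!(studies$matrix %in% .matrices),
      paste0("unknown matrix; allowed: ", paste(.matrices, collapse = ", ")))
  add(!(studies$sex %in% .sexes),
      paste0("unknown sex; allowed: ", paste(.sexes, collapse = ", ")))
  add(!(studies$unit %in% .allowed_units),
      paste0("unknown unit; allowed: ", paste(.allowed_units, collapse = ", ")))
  prov <- .normalize_province(studies$province)
  add(is.na(prov) & !is.na(studies$province),
      "unknown province (not a Chinese province-level division)")
  studies$province <- as.vector(prov)
  add(is.na(studies$n) | studies$n < 1L, "n must be >= 1")
  add(studies$year_start > studies$year_end, "year_start must be <= year_end")
  add(studies$age_min > studies$age_max, "age_min must be <= age_max")
  add(studies$age_min < 0L, "age_min must be >= 0")
  add(!is.na(studies$lod) & studies$lod < 0, "lod must be >= 0")

  k <- studies$summary_kind
  two_val <- k %in% c("AM_SD", "GM_GSD")
  add(two_val & (is.na(studies$s1) | is.na(studies$s2)),
      "s1 and s2 are required for this summary_kind")
  add(!two_val & (k %in% .summary_kinds) &
        (is.na(studies$s1) | is.na(studies$s2) | is.na(studies$s3)),
      "s1, s2 and s3 are required for this summary_kind")
  add(studies$s1 < 0 | (!is.na(studies$s2) & studies$s2 < 0) |
        (!is.na(studies$s3) & studies$s3 < 0),
      "summary values must be >= 0")
  add(k == "GM_GSD" & studies$s2 < 1, "GSD must be >= 1")
  add(k == "MEDIAN_IQR" & (studies$s1 > studies$s2 | studies$s2 > studies$s3),
      "MEDIAN_IQR requires q1 <= median <= q3")
  add(k == "MEDIAN_RANGE" & (studies$s1 > studies$s2 | studies$s2 > studies$s3),
      "MEDIAN_RANGE requires min <= median <= max")
  add(k == "MEAN_CI" & (studies$s2 > studies$s1 | studies$s1 > studies$s3),
      "MEAN_CI requires LCI <= AM <= UCI")

  if (length(errs)) {
    stop("invalid study table:\n  ", paste(errs, collapse = "\n  "))
  }
  rownames(studies) <- NULL
  studies
}

#' Read a study-record table from CSV
#'
#' Reads `studies.csv` (UTF-8, header row, one study stratum per row; see
#' [validate_study_table()] for the schema) and validates every row.
#' Validation errors name the offending row, field and rule.
#'
#' @param path path to the CSV file.
#' @return validated data frame of study records.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("study table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_study_table(df)
}

#' Write a study-record table to CSV
#'
#' @param studies validated study data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  studies <- validate_study_table(studies)
  write.csv(studies, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate an environmental-covariate table
#'
#' Schema: `province, year, garbage_disposal, domestic_sewage,
#' waste_incineration` (volumes in 10^4 tons, all non-negative).
#'
#' @param covariates data frame.
#' @return validated data frame with normalized province names.
#' @export
validate_covariate_table <- function(covariates) {
  if (!is.data.frame(covariates)) stop("`covariates` must be a data frame")
  missing_cols <- setdiff(.covariate_columns, names(covariates))
  if (length(missing_cols)) {
    stop("missing covariate table columns: ",
         paste(missing_cols, collapse = ", "))
  }
  covariates <- covariates[.covariate_columns]
  prov <- .normalize_province(covariates$province)
  if (anyNA(prov)) {
    stop("unknown province in covariate table: ",
         paste(unique(attr(prov, "unknown")), collapse = ", "))
  }
  covariates$province <- as.vector(prov)
  covariates$year <- as.integer(covariates$year)
  for (col in .covariate_columns[3:5]) {
    covariates[[col]] <- as.numeric(covariates[[col]])
    if (any(covariates[[col]] < 0, na.rm = TRUE)) {
      stop("covariate volumes must be >= 0 (", col, ")")
    }
  }
  rownames(covariates) <- NULL
  covariates
}

#' Read an environmental-covariate table from CSV
#'
#' @param path path to `covariates.csv`.
#' @return validated data frame.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path)) stop("covariate table not found: ", path)
  validate_covariate_table(read.csv(path, stringsAsFactors = FALSE,
                                    encoding = "UTF-8"))
}

#' Harmonize study summary values to ng/mL
#'
#' Converts `s1`..`s3` and `lod` to ng/mL using [convert_unit()]. Values
#' that are dimensionless for their summary kind (the GSD in `GM_GSD`
#' records) are left untouched. Errors on creatinine-adjusted units.
#'
#' @param studies validated study data frame.
#' @return data frame with concentrations in ng/mL and `unit` set to
#'   `"ng/mL"`.
#' @export
harmonize_units <- function(studies) {
  studies <- validate_study_table(studies)
  for (i in seq_len(nrow(studies))) {
    u <- studies$unit[i]
    if (u == "ng/mL") next
    scale_s2 <- studies$summary_kind[i] != "GM_GSD"
    studies$s1[i] <- convert_unit(studies$s1[i], u)
    if (scale_s2 && !is.na(studies$s2[i])) {
      studies$s2[i] <- convert_unit(studies$s2[i], u)
    }
    if (!is.na(studies$s3[i])) studies$s3[i] <- convert_unit(studies$s3[i], u)
    if (!is.na(studies$lod[i])) {
      studies$lod[i] <- convert_unit(studies$lod[i], u)
    }
    studies$unit[i] <- "ng/mL"
  }
  studies
}
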