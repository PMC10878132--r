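# Unit harmonization. All concentrations are carried internally in ng/mL.

# linear factors to ng/mL; creatinine-adjusted units are not convertible
# without per-study creatinine data and are rejected downstream
.unit_factors <- c("ng/mL" = 1, "ug/L" = 1, "ng/dL" = 0.01, "ng/L" = 0.001)
.nonconvertible_units <- "ug/g-creatinine"
.allowed_units <- c(names(.unit_factors), .nonconvertible_units)

# map micro signs to ASCII "u" and trim whitespace
.normalize_unit <- function(unit) {
  gsub("μ|µ", "u", trimws(as.character(unit)))
}

#' Convert a concentration to ng/mL
#'
#' Applies the fixed linear conversion factors 1 ug/L = 1 ng/mL,
#' 1 ng/mL = 100 ng/dL and 1 ng/mL = 1000 ng/L. Creatinine-adjusted
#' concentrations (ug/g-creatinine) cannot be converted to a volume basis
#' without creatinine measurements and raise an error.
#'
#' @param value numeric vector of non-negative concentrations.
#' @param unit character vector (recycled) of units; one of `"ng/mL"`,
#'   `"ug/L"`, `"ng/dL"`, `"ng/L"`. A Greek micro sign is accepted in place
#'   of `"u"`.
#' @return numeric vector of concentrations in ng/mL.
#' @examples
#' convert_unit(1, "ug/L")    # 1
#' convert_unit(100, "ng/dL") # 1
#' @export
convert_unit <- function(value, unit) {
  stopifnot(is.numeric(value))
  unit <- .normalize_unit(unit)
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  if (length(unit) != length(value)) {
    stop("`unit` must have length 1 or length(value)")
  }
  bad <- unit %in% .nonconvertible_units
  if (any(bad)) {
    stop("non-convertible unit '", unit[bad][1L],
         "': creatinine-adjusted concentrations cannot be converted to ng/mL")
  }
  unknown <- !(unit %in% names(.unit_factors))
  if (any(unknown)) {
    stop("unknown unit '", unit[unknown][1L], "'; allowed units: ",
         paste(.allowed_units, collapse = ", "))
  }
  if (any(value < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  unname(value * .unit_factors[unit])
}
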