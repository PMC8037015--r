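#' @keywords internal
"_PACKAGE"

# Canonical internal units: mg/L for water concentrations, mg/kg bw/day for
# doses. Everything downstream converts on entry and reports on exit.

.conc_factors <- c("ng/L" = 1e-6, "ug/L" = 1e-3, "mg/L" = 1)
.dose_factors <- c("ug/kg bw/day" = 1e-3, "mg/kg bw/day" = 1)

#' Supported water-concentration units
#'
#' @return Character vector of unit labels accepted by [convert_conc()].
#' @export
conc_units <- function() names(.conc_factors)

#' Supported dose units
#'
#' @return Character vector of unit labels accepted by [convert_dose()].
#' @export
dose_units <- function() names(.dose_factors)

# Accept the micro sign and a few spelling variants, map to the canonical label.
normalize_conc_unit <- function(unit) {
  u <- trimws(tolower(as.character(unit)))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("\\s+", "", u)
  map <- c("ng/l" = "ng/L", "ug/l" = "ug/L", "mg/l" = "mg/L")
  out <- map[u]
  if (anyNA(out)) {
    bad <- unique(unit[is.na(out)])
    stop("unknown concentration unit: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(conc_units(), collapse = ", "), ")",
         call. = FALSE)
  }
  unname(out)
}

normalize_dose_unit <- function(unit) {
  u <- trimws(tolower(as.character(unit)))
  u <- gsub("µ|μ", "u", u)
  u <- gsub("\\s+", " ", u)
  map <- c("ug/kg bw/day" = "ug/kg bw/day", "mg/kg bw/day" = "mg/kg bw/day",
           "ug/kg bw/d"   = "ug/kg bw/day", "mg/kg bw/d"   = "mg/kg bw/day",
           "ug/kg/day"    = "ug/kg bw/day", "mg/kg/day"    = "mg/kg bw/day")
  out <- map[u]
  if (anyNA(out)) {
    bad <- unique(unit[is.na(out)])
    stop("unknown dose unit: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(dose_units(), collapse = ", "), ")",
         call. = FALSE)
  }
  unname(out)
}

#' Convert water concentrations between units
#'
#' Metric-prefix conversion between ng/L, ug/L (µg/L accepted) and mg/L.
#' Vectorised over `value`; `from` may be a vector of per-element units.
#'
#' @param value Non-negative numeric vector.
#' @param from,to Unit labels (see [conc_units()]).
#' @return Numeric vector in `to` units.
#' @examples
#' convert_conc(1, "mg/L", "ng/L")      # 1e6
#' convert_conc(5.496, "ng/L", "mg/L")  # 5.496e-6
#' @export
convert_conc <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE))
    stop("concentration values must be non-negative", call. = FALSE)
  from <- normalize_conc_unit(from)
  to <- normalize_conc_unit(to)
  value * unname(.conc_factors[from]) / unname(.conc_factors[to])
}

#' Convert doses between units
#'
#' @param value Non-negative numeric vector.
#' @param from,to Unit labels (see [dose_units()]).
#' @return Numeric vector in `to` units.
#' @export
convert_dose <- function(value, from, to) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE))
    stop("dose values must be non-negative", call. = FALSE)
  from <- normalize_dose_unit(from)
  to <- normalize_dose_unit(to)
  value * unname(.dose_factors[from]) / unname(.dose_factors[to])
}

#' Cramer-class threshold of toxicological concern doses
#'
#' Generic human oral-exposure thresholds by Cramer structural class:
#' class 1 (low concern) 30, class 2 (intermediate) 9, class 3 (significant
#' toxicity) 1.5 ug/kg bw/day.
#'
#' @param cramer_class Integer vector with values in 1:3.
#' @param unit Output dose unit (default `"ug/kg bw/day"`).
#' @return Numeric vector of TTC doses.
#' @examples
#' cramer_ttc(1:3)  # 30, 9, 1.5
#' @export
cramer_ttc <- function(cramer_class, unit = "ug/kg bw/day") {
  cc <- as.integer(cramer_class)
  if (length(cc) == 0 || anyNA(cc) || any(cc < 1L | cc > 3L))
    stop("cramer_class must be 1, 2 or 3", call. = FALSE)
  tab <- hbttc_constants("cramer_ttc")
  ttc_ug <- tab$ttc_ug_kgbw_day[match(cc, tab$cramer_class)]
  convert_dose(ttc_ug, "ug/kg bw/day", unit)
}

#' Exposure defaults for drinking-water quality standards
#'
#' Bundles the parameters of the drinking-water abstraction scenario:
#' body weight `bw` (kg, default 70 per the WFD technical guidance; 60 kg is
#' the common TTC-approach variant), daily water uptake `wu` (L/day, default
#' 2), the 10% allocation of the toxicological standard to drinking water,
#' and the acceptable lifetime cancer risk (default 1e-6).
#'
#' @param bw Body weight in kg, > 0.
#' @param wu Daily water uptake in L/day, > 0.
#' @param allocation Fraction of the toxicological standard allocated to the
#'   drinking-water route, in (0, 1].
#' @param risk_level Acceptable additional cancer risk, > 0.
#' @return An object of class `exposure_defaults`.
#' @export
exposure_defaults <- function(bw = 70, wu = 2, allocation = 0.1,
                              risk_level = 1e-6) {
  for (nm in c("bw", "wu", "allocation", "risk_level")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive number", call. = FALSE)
  }
  if (allocation > 1)
    stop("allocation must be in (0, 1]", call. = FALSE)
  structure(list(bw = bw, wu = wu, allocation = allocation,
                 risk_level = risk_level),
            class = "exposure_defaults")
}

#' @export
print.exposure_defaults <- function(x, ...) {
  cat(sprintf(
    "Exposure defaults: bw = %g kg, wu = %g L/day, allocation = %g, risk = %g\n",
    x$bw, x$wu, x$allocation, x$risk_level))
  invisible(x)
}

#' Chemical record constructor
#'
#' A chemical is carcinogenic, for the purposes of the compound-specific
#' branch, exactly when an oral slope factor or an explicit cancer-risk
#' drinking-water concentration is supplied; status is never inferred from
#' the name or structure.
#'
#' @param cas CAS registry number (string; format only, no checksum).
#' @param name Chemical name.
#' @param smiles Optional SMILES string.
#' @param verhaar_class Optional integer in 1:5 (fish acute mode of action).
#' @param cramer_class Optional integer in 1:3 (oral toxicity structural class).
#' @param oral_slope_factor Optional cancer potency, per (mg/kg bw/day).
#' @param cancer_dw_conc Optional drinking-water concentration (mg/L) at the
#'   stated acceptable cancer risk.
#' @return A one-row data.frame of class `chemical_record` with a derived
#'   logical column `is_carcinogen`.
#' @export
chemical_record <- function(cas, name, smiles = NA_character_,
                            verhaar_class = NA_integer_,
                            cramer_class = NA_integer_,
                            oral_slope_factor = NA_real_,
                            cancer_dw_conc = NA_real_) {
  vc <- as.integer(verhaar_class)
  cc <- as.integer(cramer_class)
  if (!is.na(vc) && !(vc %in% 1:5))
    stop("verhaar_class must be in 1..5", call. = FALSE)
  if (!is.na(cc) && !(cc %in% 1:3))
    stop("cramer_class must be in 1..3", call. = FALSE)
  if (!is.na(oral_slope_factor) && oral_slope_factor <= 0)
    stop("oral_slope_factor must be positive", call. = FALSE)
  if (!is.na(cancer_dw_conc) && cancer_dw_conc <= 0)
    stop("cancer_dw_conc must be positive", call. = FALSE)
  out <- data.frame(
    cas = as.character(cas), name = as.character(name),
    smiles = as.character(smiles),
    verhaar_class = vc, cramer_class = cc,
    oral_slope_factor = as.numeric(oral_slope_factor),
    cancer_dw_conc = as.numeric(cancer_dw_conc),
    is_carcinogen = !is.na(oral_slope_factor) || !is.na(cancer_dw_conc),
    stringsAsFactors = FALSE)
  class(out) <- c("chemical_record", class(out))
  out
}

# 4-significant-digit display rounding; all comparisons use full precision.
signif4 <- function(x) signif(x, 4)
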