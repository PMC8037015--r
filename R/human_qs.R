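# Human branch: translate a toxicological standard (a dose) into a
# drinking-water quality standard (a concentration) under the
# drinking-water-abstraction scenario of the EU Water Framework Directive
# guidance:
#
#   QS = allocation * TL * bw / wu          (non-cancer; allocation 0.1)
#   TL = NOAEL / 100                        (NOAEL route)
#   QS = (risk_level / SF) * bw / wu        (oral-slope-factor route)
#
# With TL in mg/kg bw/day, bw in kg and wu in L/day, QS comes out in mg/L.

new_human_qs <- function(value, basis, tl = NA_real_, defaults,
                         risk_level = NA_real_, flagged = FALSE,
                         considered = NULL) {
  structure(list(value = value, basis = basis, tl = tl,
                 bw = defaults$bw, wu = defaults$wu,
                 allocation = defaults$allocation,
                 risk_level = risk_level, flagged = flagged,
                 considered = considered),
            class = "human_qs")
}

#' Quality standard from a human toxicological standard (dose)
#'
#' @param tl Toxicological standard, a positive dose.
#' @param tl_unit Unit of `tl` (default mg/kg bw/day).
#' @param defaults An [exposure_defaults()] object.
#' @param basis Label of the toxicological basis (bookkeeping only).
#' @return Object of class `human_qs`; `value` is in mg/L.
#' @examples
#' # Cramer class 1 TTC dose, WFD body weight:
#' qs <- qs_from_tl(cramer_ttc(1), "ug/kg bw/day")
#' convert_conc(qs$value, "mg/L", "ug/L")  # 105
#' @export
qs_from_tl <- function(tl, tl_unit = "mg/kg bw/day",
                       defaults = exposure_defaults(), basis = "tl") {
  if (!is.numeric(tl) || length(tl) != 1L || !is.finite(tl) || tl <= 0)
    stop("tl must be a single positive dose", call. = FALSE)
  stopifnot(inherits(defaults, "exposure_defaults"))
  tl_mg <- convert_dose(tl, tl_unit, "mg/kg bw/day")
  new_human_qs(defaults$allocation * tl_mg * defaults$bw / defaults$wu,
               basis = basis, tl = tl_mg, defaults = defaults)
}

#' Quality standard for a Cramer class
#'
#' Convenience wrapper: the class TTC dose through [qs_from_tl()].
#'
#' @param cramer_class Integer in 1:3.
#' @inheritParams qs_from_tl
#' @return A `human_qs` object.
#' @export
qs_cramer <- function(cramer_class, defaults = exposure_defaults()) {
  qs <- qs_from_tl(cramer_ttc(cramer_class), "ug/kg bw/day",
                   defaults = defaults, basis = "cramer_ttc")
  qs$cramer_class <- as.integer(cramer_class)
  qs
}

#' Toxicological standard from a NOAEL
#'
#' Divides the no-observed-adverse-effect level by the fixed uncertainty
#' factor of 100 (10 for interspecies x 10 for intraspecies variability).
#'
#' @param noael Positive dose.
#' @param noael_unit Unit of `noael` (default mg/kg bw/day).
#' @return The toxicological standard in mg/kg bw/day.
#' @export
tl_from_noael <- function(noael, noael_unit = "mg/kg bw/day") {
  if (!is.numeric(noael) || length(noael) != 1L || !is.finite(noael) ||
      noael <= 0)
    stop("noael must be a single positive dose", call. = FALSE)
  convert_dose(noael, noael_unit, "mg/kg bw/day") / 100
}

#' Quality standard for a carcinogen from its oral slope factor
#'
#' Back-calculates the drinking-water concentration corresponding to the
#' acceptable cancer risk: `QS = (risk_level / SF) * bw / wu`.
#'
#' @param sf Oral slope factor, per (mg/kg bw/day), > 0.
#' @param defaults An [exposure_defaults()] object (supplies `risk_level`,
#'   default 1e-6).
#' @return A `human_qs` object; `value` in mg/L.
#' @examples
#' qs_carcinogen(1)$value  # (1e-6 / 1) * 70 / 2 = 3.5e-5 mg/L
#' @export
qs_carcinogen <- function(sf, defaults = exposure_defaults()) {
  if (!is.numeric(sf) || length(sf) != 1L || !is.finite(sf) || sf <= 0)
    stop("oral slope factor must be a single positive number", call. = FALSE)
  stopifnot(inherits(defaults, "exposure_defaults"))
  new_human_qs((defaults$risk_level / sf) * defaults$bw / defaults$wu,
               basis = "slope_factor", defaults = defaults,
               risk_level = defaults$risk_level)
}

#' Hazard profile of a single chemical
#'
#' Container for the human-branch inputs of the compound-specific pathway.
#' All doses in mg/kg bw/day, concentrations in mg/L; `NA` means absent.
#'
#' @param noael,adi,tdi,rfd,bmd Optional positive doses (mg/kg bw/day).
#' @param oral_slope_factor Optional positive potency, per (mg/kg bw/day).
#' @param cancer_dw_conc Optional positive drinking-water concentration
#'   (mg/L) at the stated acceptable cancer risk.
#' @param pnec Optional positive PNEC (mg/L), carried for the combiner.
#' @return Object of class `hazard_profile`.
#' @export
hazard_profile <- function(noael = NA_real_, adi = NA_real_, tdi = NA_real_,
                           rfd = NA_real_, bmd = NA_real_,
                           oral_slope_factor = NA_real_,
                           cancer_dw_conc = NA_real_, pnec = NA_real_) {
  vals <- list(noael = noael, adi = adi, tdi = tdi, rfd = rfd, bmd = bmd,
               oral_slope_factor = oral_slope_factor,
               cancer_dw_conc = cancer_dw_conc, pnec = pnec)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && (!is.numeric(v) || v <= 0))
      stop(nm, " must be positive when supplied", call. = FALSE)
  }
  structure(vals, class = "hazard_profile")
}

#' Compound-specific human quality standard
#'
#' Routes a hazard profile through the applicable pathway. Carcinogens
#' (an oral slope factor or an explicit cancer drinking-water concentration
#' present) take the cancer route, overriding any non-cancer field: a
#' supplied `cancer_dw_conc` is returned as-is, otherwise the slope factor
#' is back-calculated. Non-carcinogens use ADI/TDI/RfD/BMD directly as the
#' toxicological standard and NOAEL via the factor-100 reduction; with
#' several fields present, `tl_mode = "conservative"` (default) keeps the
#' lowest resulting QS (flagging the result), `"precedence"` uses the fixed
#' order ADI > TDI > RfD > BMD > NOAEL.
#'
#' @param profile A [hazard_profile()].
#' @param defaults An [exposure_defaults()] object.
#' @param tl_mode `"conservative"` or `"precedence"`.
#' @return A `human_qs` object; `considered` lists every candidate QS
#'   evaluated (named, mg/L).
#' @export
compound_qs <- function(profile, defaults = exposure_defaults(),
                        tl_mode = c("conservative", "precedence")) {
  stopifnot(inherits(profile, "hazard_profile"))
  tl_mode <- match.arg(tl_mode)

  if (!is.na(profile$cancer_dw_conc)) {
    qs <- new_human_qs(profile$cancer_dw_conc, basis = "cancer_dw_conc",
                       defaults = defaults, risk_level = defaults$risk_level)
    return(qs)
  }
  if (!is.na(profile$oral_slope_factor))
    return(qs_carcinogen(profile$oral_slope_factor, defaults))

  fields <- c("adi", "tdi", "rfd", "bmd", "noael")
  avail <- fields[!vapply(profile[fields], is.na, logical(1L))]
  if (length(avail) == 0L)
    stop("hazard profile has no human-branch field; supply one of ",
         paste(c(fields, "oral_slope_factor", "cancer_dw_conc"),
               collapse = ", "), call. = FALSE)

  tls <- vapply(avail, function(f) {
    if (f == "noael") tl_from_noael(profile$noael) else profile[[f]]
  }, numeric(1L))
  qs_values <- defaults$allocation * tls * defaults$bw / defaults$wu
  names(qs_values) <- avail

  pick <- if (tl_mode == "conservative") which.min(qs_values) else 1L
  new_human_qs(unname(qs_values[pick]), basis = avail[pick],
               tl = unname(tls[pick]), defaults = defaults,
               flagged = tl_mode == "conservative" && length(avail) > 1L,
               considered = qs_values)
}

#' @export
print.human_qs <- function(x, ...) {
  cat(sprintf("Human QS: %g mg/L (%g ug/L), basis %s\n", signif4(x$value),
              signif4(convert_conc(x$value, "mg/L", "ug/L")), x$basis))
  if (!is.na(x$tl))
    cat(sprintf("  TL %g mg/kg bw/day, allocation %g, bw %g kg, wu %g L/day\n",
                signif4(x$tl), x$allocation, x$bw, x$wu))
  if (!is.na(x$risk_level))
    cat(sprintf("  acceptable cancer risk %g\n", x$risk_level))
  invisible(x)
}
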