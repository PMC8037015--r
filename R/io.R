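# Readers and writers for the delimited-text schemas, plus the run
# configuration. Dialect: comma-separated, UTF-8, header required,
# decimal point ".". Invalid rows are reported with their line numbers and
# dropped; the valid remainder is kept.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Read an aquatic toxicity endpoint table
#'
#' Required columns: `chemical_id`, `trophic_group`, `duration_class`,
#' `value`, `unit`; `endpoint_label` is optional. Rows failing validation
#' (unknown category, non-positive or unparseable value, unknown unit) are
#' dropped with a warning naming their line numbers and are returned in the
#' `rejected` attribute.
#'
#' @param path CSV file path.
#' @return A `tox_endpoints` data.frame (values converted to mg/L),
#'   possibly with zero rows; attribute `rejected` holds a data.frame of
#'   `line`, `reason` for dropped rows.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("chemical_id", "trophic_group", "duration_class",
                        "value", "unit"), path)
  if (!"endpoint_label" %in% names(df))
    df$endpoint_label <- rep(NA_character_, nrow(df))
  if (nrow(df) == 0L) {
    warning("empty endpoint table: ", path, call. = FALSE)
    out <- empty_endpoints()
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }

  value <- suppressWarnings(as.numeric(df$value))
  tg <- tolower(trimws(df$trophic_group))
  dc <- tolower(trimws(df$duration_class))
  unit_ok <- !vapply(df$unit, function(u)
    inherits(try(normalize_conc_unit(u), silent = TRUE), "try-error"),
    logical(1L))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(value)] <- "unparseable value"
  reason[!is.na(value) & value <= 0] <- "non-positive value"
  reason[is.na(reason) & !tg %in% TROPHIC_GROUPS] <- "unknown trophic_group"
  reason[is.na(reason) & !dc %in% DURATION_CLASSES] <- "unknown duration_class"
  reason[is.na(reason) & !unit_ok] <- "unknown unit"

  bad <- which(!is.na(reason))
  if (length(bad)) {
    warning(length(bad), " invalid row(s) dropped from ", path, " (lines ",
            paste(bad + 1L, collapse = ", "), ")", call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(df)), bad)
  out <- if (length(keep)) {
    data.frame(chemical_id = df$chemical_id[keep],
               trophic_group = tg[keep], duration_class = dc[keep],
               value = convert_conc(value[keep], df$unit[keep], "mg/L"),
               unit = "mg/L",
               endpoint_label = df$endpoint_label[keep],
               stringsAsFactors = FALSE)
  } else empty_endpoints()
  class(out) <- c("tox_endpoints", "data.frame")
  attr(out, "rejected") <- data.frame(line = bad + 1L, reason = reason[bad],
                                      stringsAsFactors = FALSE)
  out
}

empty_endpoints <- function() {
  data.frame(chemical_id = character(), trophic_group = character(),
             duration_class = character(), value = numeric(),
             unit = character(), endpoint_label = character(),
             stringsAsFactors = FALSE)
}

#' Write an endpoint table
#'
#' @param records A `tox_endpoints` data.frame.
#' @param path Output CSV path.
#' @export
write_endpoints <- function(records, path) {
  cols <- c("chemical_id", "trophic_group", "duration_class", "value",
            "unit", "endpoint_label")
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a PNEC table
#'
#' Required columns: `chemical_id`, `verhaar_class`, `pnec`, `unit`.
#'
#' @param path CSV file path.
#' @return data.frame with `chemical_id`, `verhaar_class` (integer), `pnec`
#'   in mg/L.
#' @export
read_pnec_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("chemical_id", "verhaar_class", "pnec", "unit"), path)
  pnec <- as.numeric(df$pnec)
  if (anyNA(pnec) || any(pnec <= 0))
    stop("PNEC values must be positive numbers: ", path, call. = FALSE)
  vc <- as.integer(df$verhaar_class)
  if (anyNA(vc) || any(!vc %in% 1:5))
    stop("verhaar_class must be in 1..5: ", path, call. = FALSE)
  data.frame(chemical_id = as.character(df$chemical_id), verhaar_class = vc,
             pnec = convert_conc(pnec, df$unit, "mg/L"),
             stringsAsFactors = FALSE)
}

#' Read a human hazard table
#'
#' Required column: `chemical_id`. Optional dose columns `noael`, `adi`,
#' `tdi`, `rfd`, `bmd` (mg/kg bw/day), `oral_slope_factor`
#' (per mg/kg bw/day), `cancer_dw_conc` (mg/L), `pnec` (mg/L). Empty cells
#' mean "absent".
#'
#' @param path CSV file path.
#' @return List of [hazard_profile()] objects named by `chemical_id`.
#' @export
read_hazard_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, "chemical_id", path)
  fields <- c("noael", "adi", "tdi", "rfd", "bmd", "oral_slope_factor",
              "cancer_dw_conc", "pnec")
  for (f in setdiff(fields, names(df))) df[[f]] <- NA_real_
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    do.call(hazard_profile, lapply(df[i, fields], as.numeric))
  })
  names(profiles) <- as.character(df$chemical_id)
  profiles
}

#' Run configuration
#'
#' Validated bundle of all tunables: the exposure defaults, the assessment
#' factor for the "> 10 chronic data" rule, the toxicological-standard
#' precedence mode and the output unit.
#'
#' @param bw,wu,allocation,risk_level See [exposure_defaults()].
#' @param af_over10 AF for the "> 10 chronic data" rule, in \[1, 5\].
#' @param tl_mode `"conservative"` or `"precedence"` (see [compound_qs()]).
#' @param output_unit Concentration unit for reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(bw = 70, wu = 2, allocation = 0.1, risk_level = 1e-6,
                       af_over10 = 5, tl_mode = "conservative",
                       output_unit = "ng/L") {
  defaults <- exposure_defaults(bw, wu, allocation, risk_level)
  if (!is.numeric(af_over10) || af_over10 < 1 || af_over10 > 5)
    stop("invalid field af_over10: must lie in [1, 5]", call. = FALSE)
  if (!tl_mode %in% c("conservative", "precedence"))
    stop("invalid field tl_mode: must be 'conservative' or 'precedence'",
         call. = FALSE)
  output_unit <- normalize_conc_unit(output_unit)
  structure(list(bw = bw, wu = wu, allocation = allocation,
                 risk_level = risk_level, af_over10 = af_over10,
                 tl_mode = tl_mode, output_unit = output_unit,
                 defaults = defaults),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected by name; the loaded configuration round-trips
#' through [write_config()] unchanged.
#'
#' @param path JSON file path.
#' @return A `run_config` object.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fields <- names(formals(run_config))
  jsonlite::write_json(config[fields], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
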