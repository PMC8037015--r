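# PNEC derivation from aquatic toxicity endpoints.
#
# Endpoints are grouped into the six (trophic group x duration class) cells,
# each cell summarised by the geometric mean of its records, and an
# assessment factor is selected from the data-availability pattern following
# the EU chemical-assessment ladder used by the EnviroTox PNEC calculator:
#
#   1 trophic acute level                                   AF 10000
#   2 trophic acute levels                                  AF  5000 (most sensitive taxon)
#   3 trophic acute levels                                  AF  1000 (most sensitive taxon)
#   3 acute + 1 chronic NOT on most sensitive acute taxon   AF  1000
#   3 acute + 1 chronic ON most sensitive acute taxon       AF   100
#   3 acute + 2 chronic incl. most sensitive acute taxon    AF    50
#   3 acute + 3 chronic levels                              AF    10
#   > 10 chronic data or micro/mesocosm studies             AF 1 to 5 (configurable)

TROPHIC_GROUPS <- c("algae", "invertebrate", "fish")
DURATION_CLASSES <- c("acute", "chronic")

#' Build a validated table of aquatic toxicity endpoints
#'
#' @param chemical_id Single chemical identifier shared by all records.
#' @param trophic_group Character vector in `{"algae","invertebrate","fish"}`.
#' @param duration_class Character vector in `{"acute","chronic"}`.
#' @param value Positive numeric endpoint concentrations.
#' @param unit Concentration unit(s), recycled (default `"mg/L"`).
#' @param endpoint_label Optional free-text labels (e.g. "96h-LC50").
#' @return A data.frame of class `tox_endpoints` with values converted to
#'   mg/L (canonical unit).
#' @export
endpoint_records <- function(chemical_id, trophic_group, duration_class,
                             value, unit = "mg/L", endpoint_label = NA) {
  n <- length(value)
  if (n == 0L) stop("at least one endpoint record is required", call. = FALSE)
  if (length(unique(as.character(chemical_id))) != 1L)
    stop("all records must share one chemical_id", call. = FALSE)
  if (!length(trophic_group) %in% c(1L, n) ||
      !length(duration_class) %in% c(1L, n))
    stop("trophic_group and duration_class must have length 1 or length(value)",
         call. = FALSE)
  trophic_group <- rep_len(tolower(as.character(trophic_group)), n)
  duration_class <- rep_len(tolower(as.character(duration_class)), n)
  if (!all(trophic_group %in% TROPHIC_GROUPS))
    stop("trophic_group must be one of ",
         paste(TROPHIC_GROUPS, collapse = ", "), call. = FALSE)
  if (!all(duration_class %in% DURATION_CLASSES))
    stop("duration_class must be 'acute' or 'chronic'", call. = FALSE)
  if (!is.numeric(value) || anyNA(value) || any(value <= 0))
    stop("endpoint values must be strictly positive", call. = FALSE)
  out <- data.frame(
    chemical_id = as.character(chemical_id[1L]),
    trophic_group = trophic_group,
    duration_class = duration_class,
    value = convert_conc(value, rep_len(unit, n), "mg/L"),
    unit = "mg/L",
    endpoint_label = rep_len(as.character(endpoint_label), n),
    stringsAsFactors = FALSE)
  class(out) <- c("tox_endpoints", "data.frame")
  out
}

#' Geometric mean of positive values
#'
#' Computed as `exp(mean(log(x)))`; invariant to the log base.
#'
#' @param x Positive numeric vector, non-empty.
#' @return The geometric mean.
#' @examples
#' geometric_mean(c(1, 10, 100))  # 10
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L)
    stop("geometric_mean of an empty set is undefined", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stop("geometric_mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

#' Aggregate endpoint records into the (trophic, duration) cell matrix
#'
#' One row per populated cell, summarised by the geometric mean (mg/L) of
#' its records and the record count. Unpopulated cells are absent.
#'
#' @param records A `tox_endpoints` table (see [endpoint_records()]) for a
#'   single chemical.
#' @return A data.frame of class `endpoint_matrix` with columns
#'   `trophic_group`, `duration_class`, `geomean`, `n`; the chemical id is
#'   kept in attribute `chemical_id`.
#' @export
build_matrix <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty tox_endpoints table", call. = FALSE)
  if (length(unique(records$chemical_id)) != 1L)
    stop("build_matrix expects records for a single chemical", call. = FALSE)
  key <- interaction(records$trophic_group, records$duration_class, drop = TRUE)
  cells <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(trophic_group = d$trophic_group[1L],
               duration_class = d$duration_class[1L],
               geomean = geometric_mean(d$value),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  # fixed ordering so identical record multisets give identical output
  cells <- cells[order(match(cells$duration_class, DURATION_CLASSES),
                       match(cells$trophic_group, TROPHIC_GROUPS)), ]
  rownames(cells) <- NULL
  attr(cells, "chemical_id") <- records$chemical_id[1L]
  class(cells) <- c("endpoint_matrix", "data.frame")
  cells
}

# Trophic group with the lowest acute geometric mean; ties broken by the
# fixed order algae < invertebrate < fish.
most_sensitive_taxon <- function(cells) {
  ac <- cells[cells$duration_class == "acute", ]
  if (nrow(ac) == 0L) return(NA_character_)
  ac <- ac[order(ac$geomean, match(ac$trophic_group, TROPHIC_GROUPS)), ]
  ac$trophic_group[1L]
}

lowest_cell <- function(cells, duration) {
  d <- cells[cells$duration_class == duration, ]
  d <- d[order(d$geomean, match(d$trophic_group, TROPHIC_GROUPS)), ]
  d[1L, , drop = FALSE]
}

#' Select the assessment factor from the data-availability pattern
#'
#' Applies the assessment-factor ladder (see the table in the package
#' vignette). The basis cell named in the result is the cell whose geometric
#' mean the factor divides: acute-only rows and the "chronic off the most
#' sensitive taxon" row anchor on the lowest acute cell; rows granting
#' chronic credit anchor on the lowest qualifying chronic cell.
#'
#' Patterns the ladder does not cover (chronic data with fewer than three
#' acute levels; two chronic levels missing the most sensitive acute taxon)
#' fall back to the most conservative applicable rule and are flagged.
#'
#' @param cells An `endpoint_matrix` from [build_matrix()].
#' @param af_over10 Assessment factor for the "> 10 chronic data" row; must
#'   lie in \[1, 5\] (default 5, the conservative end of the stated range).
#' @return A list with `af`, `rule_id`, `basis_cell` (one-row data.frame)
#'   and `flagged` (logical; TRUE when a fallback rule was used).
#' @export
select_af <- function(cells, af_over10 = 5) {
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    stop("empty endpoint matrix: no assessment factor applicable", call. = FALSE)
  if (!is.numeric(af_over10) || length(af_over10) != 1L ||
      af_over10 < 1 || af_over10 > 5)
    stop("af_over10 must lie in [1, 5]", call. = FALSE)

  acute <- cells[cells$duration_class == "acute", ]
  chronic <- cells[cells$duration_class == "chronic", ]
  a <- nrow(acute)        # trophic levels with acute data
  ch <- nrow(chronic)     # trophic levels with chronic data
  n_chronic_records <- sum(chronic$n)
  ms <- most_sensitive_taxon(cells)

  res <- function(af, rule_id, basis, flagged = FALSE)
    list(af = af, rule_id = rule_id,
         basis_cell = basis[, c("trophic_group", "duration_class", "geomean", "n")],
         flagged = flagged)

  if (n_chronic_records > 10L)
    return(res(af_over10, "gt10-chronic", lowest_cell(cells, "chronic")))

  if (a == 3L) {
    if (ch == 0L)
      return(res(1000, "3-acute", lowest_cell(cells, "acute")))
    if (ch == 1L) {
      if (chronic$trophic_group[1L] == ms)
        return(res(100, "3-acute+1-chronic-ms", chronic))
      return(res(1000, "3-acute+1-chronic-other", lowest_cell(cells, "acute")))
    }
    if (ch == 2L) {
      if (ms %in% chronic$trophic_group)
        return(res(50, "3-acute+2-chronic-ms", lowest_cell(cells, "chronic")))
      # two chronic levels but neither on the most sensitive taxon: not in
      # the ladder; grant no chronic credit
      return(res(1000, "3-acute-fallback", lowest_cell(cells, "acute"),
                 flagged = TRUE))
    }
    return(res(10, "3-acute+3-chronic", lowest_cell(cells, "chronic")))
  }

  if (a == 2L)
    return(res(5000, if (ch == 0L) "2-acute" else "2-acute-fallback",
               lowest_cell(cells, "acute"), flagged = ch > 0L))
  if (a == 1L)
    return(res(10000, if (ch == 0L) "1-acute" else "1-acute-fallback",
               lowest_cell(cells, "acute"), flagged = ch > 0L))

  # chronic-only data: no acute rule applies; use the most conservative
  # factor on the lowest chronic cell and flag it
  res(10000, "chronic-only-fallback", lowest_cell(cells, "chronic"),
      flagged = TRUE)
}

#' Derive the predicted no-effect concentration for one chemical
#'
#' Builds the endpoint matrix, selects the assessment factor and divides the
#' basis cell's geometric mean by it.
#'
#' @inheritParams build_matrix
#' @inheritParams select_af
#' @return An object of class `pnec_result`: `chemical_id`, `pnec` (mg/L),
#'   `af`, `basis_value` (mg/L), `basis_cell`, `rule_id`, `flagged`.
#' @examples
#' r <- endpoint_records("chem-1", "fish", "acute", 5, "mg/L")
#' derive_pnec(r)$pnec  # 5 / 10000 = 5e-4 mg/L
#' @export
derive_pnec <- function(records, af_over10 = 5) {
  cells <- build_matrix(records)
  sel <- select_af(cells, af_over10 = af_over10)
  structure(list(
    chemical_id = attr(cells, "chemical_id"),
    pnec = sel$basis_cell$geomean / sel$af,
    af = sel$af,
    basis_value = sel$basis_cell$geomean,
    basis_cell = sel$basis_cell,
    rule_id = sel$rule_id,
    flagged = sel$flagged,
    matrix = cells), class = "pnec_result")
}

#' @export
print.pnec_result <- function(x, ...) {
  cat(sprintf("PNEC for %s: %g mg/L (%g ng/L)\n", x$chemical_id,
              signif4(x$pnec), signif4(convert_conc(x$pnec, "mg/L", "ng/L"))))
  cat(sprintf("  rule %s: AF %g on %s/%s geomean %g mg/L (n = %d)%s\n",
              x$rule_id, x$af, x$basis_cell$trophic_group,
              x$basis_cell$duration_class, signif4(x$basis_value),
              x$basis_cell$n, if (x$flagged) " [fallback rule]" else ""))
  invisible(x)
}
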