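# Human-Biota TTC combiner: the lower of the ecological threshold
# (eco-TTC or compound PNEC) and the human drinking-water quality standard,
# compared in a common unit. Ties are labelled "eco" — the ecological
# branch drives the generic thresholds.

#' Generic Human-Biota TTCs for all Verhaar x Cramer combinations
#'
#' Crosses the five per-Verhaar-class eco-TTCs with the three per-Cramer-
#' class quality standards and keeps the minimum of each pair. With
#' realistic inputs the eco branch is orders of magnitude lower than every
#' human QS, so the 15 combinations collapse to 5 distinct values, one per
#' Verhaar class.
#'
#' @param ecottcs List of five [derive_ecottc()] /
#'   [ecottc_from_candidates()] results, named (or ordered) by Verhaar
#'   class 1..5.
#' @param qs_table List of three `human_qs` objects, named (or ordered) by
#'   Cramer class 1..3.
#' @return A data.frame of class `hbttc_table` with one row per
#'   combination: `verhaar_class`, `cramer_class`, `hbttc_ng_L`,
#'   `limiting_branch`, `eco_ng_L`, `qs_ng_L`, `eco_method`.
#' @export
generic_hbttc <- function(ecottcs, qs_table) {
  ecottcs <- resolve_class_list(ecottcs, 1:5, "eco-TTC", "eco_ttc")
  qs_table <- resolve_class_list(qs_table, 1:3, "quality standard", "human_qs")

  rows <- expand.grid(cramer_class = 1:3, verhaar_class = 1:5)[, 2:1]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    v <- rows$verhaar_class[i]; cr <- rows$cramer_class[i]
    eco <- ecottcs[[v]]
    eco_ng <- convert_conc(eco$value, eco$unit, "ng/L")
    qs_ng <- convert_conc(qs_table[[cr]]$value, "mg/L", "ng/L")
    data.frame(verhaar_class = v, cramer_class = cr,
               hbttc_ng_L = min(eco_ng, qs_ng),
               limiting_branch = if (eco_ng <= qs_ng) "eco" else "human",
               eco_ng_L = eco_ng, qs_ng_L = qs_ng,
               eco_method = eco$method, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("hbttc_table", "data.frame")
  out
}

resolve_class_list <- function(x, classes, what, cls) {
  if (!is.list(x)) stop(what, "s must be supplied as a list", call. = FALSE)
  if (!is.null(names(x)) && all(as.character(classes) %in% names(x)))
    x <- x[as.character(classes)]
  if (length(x) != length(classes))
    stop("need one ", what, " per class ",
         paste(classes, collapse = ", "), "; got ", length(x), call. = FALSE)
  ok <- vapply(x, inherits, logical(1L), what = cls)
  if (!all(ok))
    stop("element(s) ", paste(which(!ok), collapse = ", "),
         " are not of class ", cls, call. = FALSE)
  x
}

#' Compound-specific Human-Biota TTC
#'
#' The lower of a chemical's PNEC and its human drinking-water quality
#' standard.
#'
#' @param pnec Positive PNEC; a number (in `pnec_unit`) or a `pnec_result`.
#' @param qs A `human_qs` object (see [compound_qs()]).
#' @param chemical_id Identifier carried into the result.
#' @param pnec_unit Unit of a numeric `pnec` (default mg/L).
#' @return One-row data.frame of class `hbttc_table`: `chemical_id`,
#'   `hbttc_mg_L`, `limiting_branch`, `pnec_mg_L`, `qs_mg_L`, `qs_basis`.
#' @export
compound_hbttc <- function(pnec, qs, chemical_id = NULL, pnec_unit = "mg/L") {
  if (inherits(pnec, "pnec_result")) {
    if (is.null(chemical_id)) chemical_id <- pnec$chemical_id
    pnec <- pnec$pnec
  } else {
    pnec <- convert_conc(pnec, pnec_unit, "mg/L")
  }
  if (!is.numeric(pnec) || length(pnec) != 1L || !is.finite(pnec) || pnec <= 0)
    stop("pnec must be a single positive concentration", call. = FALSE)
  if (!inherits(qs, "human_qs"))
    stop("qs must be a human_qs object", call. = FALSE)
  out <- data.frame(
    chemical_id = if (is.null(chemical_id)) NA_character_ else as.character(chemical_id),
    hbttc_mg_L = min(pnec, qs$value),
    limiting_branch = if (pnec <= qs$value) "eco" else "human",
    pnec_mg_L = pnec, qs_mg_L = qs$value, qs_basis = qs$basis,
    stringsAsFactors = FALSE)
  class(out) <- c("hbttc_table", "data.frame")
  out
}

#' Generic thresholds from the shipped reference constants
#'
#' Rebuilds the published generic threshold table from the packaged
#' per-class fifth-percentile candidates and the Cramer TTC doses, without
#' any external data: candidates through the minimum rule, Cramer doses
#' through the quality-standard equation, then the eco-vs-human minimum.
#'
#' @param defaults An [exposure_defaults()] object; `bw = 70` reproduces
#'   the WFD column, `bw = 60` the TTC-approach variant.
#' @return An `hbttc_table` with 15 rows (see [generic_hbttc()]).
#' @export
builtin_generic_hbttc <- function(defaults = exposure_defaults()) {
  cand <- hbttc_constants("ecottc_candidates")
  ecottcs <- lapply(1:5, function(v) {
    r <- cand[cand$verhaar_class == v, ]
    ecottc_from_candidates(r$empirical_ng_L, r$normal_ng_L, r$logistic_ng_L,
                           unit = "ng/L", verhaar_class = v)
  })
  qs_table <- lapply(1:3, qs_cramer, defaults = defaults)
  generic_hbttc(ecottcs, qs_table)
}
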