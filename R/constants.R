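# Reference constants ship as versioned CSV files under inst/extdata rather
# than being hard-coded in logic, so they can be audited and diffed:
#   ecottc_candidates   per-Verhaar-class fifth-percentile candidates (ng/L)
#   cramer_ttc          Cramer-class TTC doses (ug/kg bw/day)
#   assessment_factors  the AF ladder with rule ids
#   kienzler2019_ecottc published comparison eco-TTC values (ng/L)

.constants_cache <- new.env(parent = emptyenv())

#' Packaged reference constants
#'
#' @param name One of `"ecottc_candidates"`, `"cramer_ttc"`,
#'   `"assessment_factors"`, `"kienzler2019_ecottc"`.
#' @return The constant table as a data.frame.
#' @export
hbttc_constants <- function(name = c("ecottc_candidates", "cramer_ttc",
                                     "assessment_factors",
                                     "kienzler2019_ecottc")) {
  name <- match.arg(name)
  if (is.null(.constants_cache[[name]])) {
    path <- system.file("extdata", paste0(name, ".csv"), package = "hbttc",
                        mustWork = TRUE)
    .constants_cache[[name]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .constants_cache[[name]]
}
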