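# Synthetic chemicals, endpoint designs and PNEC populations with known
# ground truth. Per-class PNEC populations are lognormal in concentration
# (normal in log10), matching the distributional assumption behind the
# normal-fit fifth-percentile estimator; within-cell endpoint replicates
# scatter lognormally around a true cell mean.
#
# Every generator takes an explicit `seed` and restores the caller's RNG
# state afterwards: no global state leaks.

with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Default per-Verhaar-class log10 PNEC parameters (mg/L scale). Means and a
# common spread of 1.5 log10 units place the analytic 5th percentiles in the
# low ng/L range, the order of magnitude of the published class thresholds,
# with the specifically acting class (4) most toxic.
default_class_params <- function() {
  data.frame(
    verhaar_class = 1:5,
    log10_pnec_mu = c(-2.8, -2.5, -3.2, -4.0, -2.9),
    log10_pnec_sigma = rep(1.5, 5))
}

# Class frequencies: unclassifiable compounds (class 5) dominate real
# screening datasets, followed by baseline narcotics (1) and unspecific
# reactives (3); specifically acting and less-inert classes are rare.
default_class_weights <- function() c(0.25, 0.05, 0.20, 0.05, 0.45)

# Roughly two thirds of screened organics fall in Cramer class 3.
default_cramer_weights <- function() c(0.20, 0.10, 0.70)

#' Generate a lognormal PNEC population with known ground truth
#'
#' Draws `n` PNECs with log10 values Normal(mu, sigma). The analytic fifth
#' percentile `10^(mu + qnorm(0.05) * sigma)` is attached as ground truth
#' for estimator-recovery tests.
#'
#' @param mu,sigma Mean and sd of log10 PNEC (mg/L scale); `sigma >= 0`
#'   (`sigma = 0` gives a degenerate constant sample).
#' @param n Number of draws, >= 2.
#' @param seed Integer seed (required; generation is always reproducible).
#' @param verhaar_class Optional class label carried along.
#' @return Object of class `pnec_sample`: `values` (mg/L),
#'   `log10_values`, `true_p5` (mg/L), `true_log10_p5`, `mu`, `sigma`,
#'   `verhaar_class`, `seed`.
#' @export
gen_pnec_population <- function(mu, sigma, n, seed,
                                verhaar_class = NA_integer_) {
  if (!is.numeric(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (!is.numeric(mu) || !is.finite(mu)) stop("invalid mu", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  lg <- with_local_seed(seed, stats::rnorm(n, mu, sigma))
  structure(list(
    values = 10^lg, log10_values = lg,
    true_p5 = 10^(mu + Z05 * sigma), true_log10_p5 = mu + Z05 * sigma,
    mu = mu, sigma = sigma,
    verhaar_class = as.integer(verhaar_class), seed = seed),
    class = "pnec_sample")
}

#' Generate a synthetic chemical table
#'
#' Chemicals get placeholder CAS-style ids and SMILES tokens and are
#' assigned Verhaar and Cramer classes by the supplied weights.
#'
#' @param n Number of chemicals.
#' @param seed Integer seed.
#' @param class_weights Probability vector over Verhaar classes 1..5.
#' @param cramer_weights Probability vector over Cramer classes 1..3.
#' @return data.frame with columns `chemical_id`, `cas`, `name`, `smiles`,
#'   `verhaar_class`, `cramer_class`.
#' @export
gen_chemicals <- function(n, seed,
                          class_weights = default_class_weights(),
                          cramer_weights = default_cramer_weights()) {
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  check_weights(class_weights, 5L, "class_weights")
  check_weights(cramer_weights, 3L, "cramer_weights")
  with_local_seed(seed, {
    data.frame(
      chemical_id = sprintf("SYN-%05d", seq_len(n)),
      cas = sprintf("%06d-%02d-%d", sample.int(999999L, n, replace = TRUE),
                    sample.int(99L, n, replace = TRUE),
                    sample.int(9L, n, replace = TRUE)),
      name = sprintf("synthetic-compound-%05d", seq_len(n)),
      smiles = "X",  # placeholder token, not a real structure
      verhaar_class = sample.int(5L, n, replace = TRUE, prob = class_weights),
      cramer_class = sample.int(3L, n, replace = TRUE, prob = cramer_weights),
      stringsAsFactors = FALSE)
  })
}

check_weights <- function(w, k, what) {
  if (!is.numeric(w) || length(w) != k || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9)
    stop(what, " must be ", k, " non-negative weights summing to 1",
         call. = FALSE)
  invisible(w)
}

#' Default endpoint design: which cells to populate
#'
#' @param cells Character vector of `"trophic/duration"` cell labels, e.g.
#'   `c("algae/acute", "fish/chronic")`; `"all"` expands to the six cells.
#' @param n_rep Replicate records per cell (recycled).
#' @return data.frame with columns `trophic_group`, `duration_class`,
#'   `n_rep`.
#' @export
endpoint_design <- function(cells = "all", n_rep = 1L) {
  if (identical(cells, "all"))
    cells <- as.vector(outer(TROPHIC_GROUPS, DURATION_CLASSES, paste, sep = "/"))
  parts <- strsplit(cells, "/", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("cells must look like 'trophic/duration'", call. = FALSE)
  tg <- vapply(parts, `[`, "", 1L)
  dc <- vapply(parts, `[`, "", 2L)
  if (!all(tg %in% TROPHIC_GROUPS) || !all(dc %in% DURATION_CLASSES))
    stop("unknown trophic group or duration class in design", call. = FALSE)
  if (length(cells) == 0L) stop("empty endpoint design", call. = FALSE)
  data.frame(trophic_group = tg, duration_class = dc,
             n_rep = rep_len(as.integer(n_rep), length(cells)),
             stringsAsFactors = FALSE)
}

#' Generate synthetic endpoint records for one chemical
#'
#' True cell geometric means are drawn (or supplied), then each cell is
#' populated with `n_rep` lognormal replicates: log10 value =
#' log10(true mean) + Normal(0, noise_sigma). With `noise_sigma = 0` the
#' observed cell geomean equals the true mean exactly.
#'
#' @param chemical_id Identifier for the records.
#' @param design An [endpoint_design()] table.
#' @param cell_means Optional named numeric of true cell geomeans (mg/L),
#'   names `"trophic/duration"`; missing cells are drawn lognormally
#'   around `base_mg_L`.
#' @param base_mg_L Centre of the cell-mean distribution (default 1 mg/L);
#'   chronic cells are drawn one order of magnitude lower than acute ones,
#'   as no-effect levels sit below effect levels.
#' @param noise_sigma Within-cell spread in log10 units (default 0.3).
#' @param seed Integer seed.
#' @return A `tox_endpoints` table with attribute `true_cell_means`.
#' @export
gen_endpoint_records <- function(chemical_id, design = endpoint_design(),
                                 cell_means = NULL, base_mg_L = 1,
                                 noise_sigma = 0.3, seed = 1L) {
  if (!is.data.frame(design) || nrow(design) == 0L)
    stop("empty endpoint design", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  key <- paste(design$trophic_group, design$duration_class, sep = "/")
  with_local_seed(seed, {
    means <- 10^(log10(base_mg_L) +
                   ifelse(design$duration_class == "chronic", -1, 0) +
                   stats::rnorm(nrow(design), 0, 0.5))
    names(means) <- key
    if (!is.null(cell_means)) {
      hit <- intersect(names(cell_means), key)
      means[hit] <- cell_means[hit]
    }
    vals <- unlist(lapply(seq_len(nrow(design)), function(i) {
      10^(log10(means[i]) + stats::rnorm(design$n_rep[i], 0, noise_sigma))
    }))
    rec <- endpoint_records(
      chemical_id,
      rep(design$trophic_group, design$n_rep),
      rep(design$duration_class, design$n_rep),
      vals, unit = "mg/L",
      endpoint_label = rep(
        ifelse(design$duration_class == "acute", "96h-LC50", "21d-NOEC"),
        design$n_rep))
    attr(rec, "true_cell_means") <- means
    rec
  })
}

#' Simulate a full synthetic screening dataset
#'
#' Chemicals with class labels, per-chemical endpoint records, and the
#' per-class lognormal PNEC parameters used, ready to feed the whole
#' pipeline (PNEC derivation, eco-TTC estimation, combination).
#'
#' @param n_chemicals Number of chemicals.
#' @param seed Integer seed.
#' @param class_params data.frame with `verhaar_class`, `log10_pnec_mu`,
#'   `log10_pnec_sigma` (default [default_class_params()]).
#' @param design Endpoint design shared by all chemicals (default: all six
#'   cells, one replicate).
#' @param noise_sigma Within-cell spread in log10 units.
#' @inheritParams gen_chemicals
#' @return List with `chemicals` (data.frame), `endpoints` (one
#'   `tox_endpoints` table per chemical), `class_params`.
#' @export
simulate_dataset <- function(n_chemicals, seed,
                             class_params = default_class_params(),
                             design = endpoint_design(),
                             noise_sigma = 0.3,
                             class_weights = default_class_weights(),
                             cramer_weights = default_cramer_weights()) {
  chems <- gen_chemicals(n_chemicals, seed, class_weights, cramer_weights)
  seeds <- with_local_seed(seed + 1L,
                           sample.int(.Machine$integer.max - 1L, n_chemicals))
  endpoints <- lapply(seq_len(n_chemicals), function(i) {
    p <- class_params[class_params$verhaar_class == chems$verhaar_class[i], ]
    base <- with_local_seed(seeds[i],
                            10^stats::rnorm(1L, p$log10_pnec_mu + 3,
                                            p$log10_pnec_sigma))
    gen_endpoint_records(chems$chemical_id[i], design = design,
                         base_mg_L = base, noise_sigma = noise_sigma,
                         seed = seeds[i] + 1L)
  })
  list(chemicals = chems, endpoints = endpoints, class_params = class_params)
}
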