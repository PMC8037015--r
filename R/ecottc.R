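# Eco-TTC derivation: the fifth percentile of the log10 PNEC distribution
# of a mode-of-action class, estimated three ways (empirical sample
# quantile, normal fit, logistic fit), back-transformed to concentration,
# with the class threshold set to the lowest of the three candidates.

Z05 <- stats::qnorm(0.05)        # -1.6448536...
LOGIT05 <- stats::qlogis(0.05)   # log(0.05/0.95) = -2.9444390...

#' Empirical fifth percentile
#'
#' Linear-interpolation sample quantile with plotting position
#' h = (n - 1) p + 1 on the sorted sample (the default quantile definition
#' of R, type 7).
#'
#' @param log_values Numeric vector, length >= 2 (log10 PNECs).
#' @return The 5th percentile, same (log) scale as the input.
#' @export
fifth_percentile_empirical <- function(log_values) {
  check_sample(log_values)
  stats::quantile(log_values, probs = 0.05, type = 7, names = FALSE)
}

#' Normal-fit fifth percentile
#'
#' Maximum-likelihood normal fit (sd with denominator n), then
#' `mu + qnorm(0.05) * sigma`. A zero-variance sample returns the constant
#' (degenerate fit, attribute `degenerate` set).
#'
#' @inheritParams fifth_percentile_empirical
#' @return The 5th percentile of the fitted normal.
#' @export
fifth_percentile_normal <- function(log_values) {
  check_sample(log_values)
  mu <- mean(log_values)
  sigma <- sqrt(mean((log_values - mu)^2))
  if (sigma == 0)
    return(structure(mu, degenerate = TRUE))
  mu + Z05 * sigma
}

#' Maximum-likelihood logistic fit
#'
#' Fits location and scale of a logistic distribution by direct
#' minimisation of the negative log-likelihood (Nelder-Mead on
#' (location, log scale), started at the moment estimates
#' (median, sqrt(3) * sd / pi), relative tolerance 1e-10).
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return List with `location`, `scale`, `loglik`, `convergence` (0 = ok).
#' @export
fit_logistic_mle <- function(x) {
  check_sample(x)
  s0 <- sqrt(3) * stats::sd(x) / pi
  if (s0 == 0) stop("constant sample: logistic fit is degenerate", call. = FALSE)
  nll <- function(par) -sum(stats::dlogis(x, par[1L], exp(par[2L]), log = TRUE))
  fit <- stats::optim(c(stats::median(x), log(s0)), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 10000L))
  if (fit$convergence != 0L)
    stop("logistic MLE did not converge (optim code ", fit$convergence,
         ", value ", fit$value, ")", call. = FALSE)
  list(location = fit$par[1L], scale = exp(fit$par[2L]),
       loglik = -fit$value, convergence = fit$convergence)
}

#' Logistic-fit fifth percentile
#'
#' MLE logistic fit, then `location + scale * log(0.05/0.95)`. A constant
#' sample returns the constant (degenerate fit, attribute `degenerate` set).
#'
#' @inheritParams fifth_percentile_empirical
#' @return The 5th percentile of the fitted logistic.
#' @export
fifth_percentile_logistic <- function(log_values) {
  check_sample(log_values)
  if (stats::sd(log_values) == 0)
    return(structure(log_values[1L], degenerate = TRUE))
  fit <- fit_logistic_mle(log_values)
  fit$location + LOGIT05 * fit$scale
}

check_sample <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x) || any(!is.finite(x)))
    stop("need at least 2 finite numeric values", call. = FALSE)
  invisible(x)
}

#' Derive the eco-TTC of a mode-of-action class
#'
#' Log10-transforms the PNECs, computes the three fifth-percentile
#' candidates, back-transforms each via `10^x`, and selects the minimum
#' candidate as the class threshold. Ties are broken in the fixed order
#' empirical, normal, logistic.
#'
#' @param values Positive PNEC concentrations (length >= 2).
#' @param unit Unit of `values` (default mg/L); candidates are reported in
#'   this unit.
#' @param verhaar_class Optional class label carried into the result.
#' @return Object of class `eco_ttc`: `log10_candidates` and
#'   `back_transformed` (named numeric, methods empirical/normal/logistic),
#'   `value` (the minimum candidate, in `unit`), `method`, `n`,
#'   `small_sample` (TRUE when n < 30), `unit`, `verhaar_class`.
#' @export
derive_ecottc <- function(values, unit = "mg/L", verhaar_class = NA_integer_) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 PNEC values to derive an eco-TTC", call. = FALSE)
  if (anyNA(values) || any(values <= 0))
    stop("PNEC values must be strictly positive", call. = FALSE)
  lg <- log10(values)
  cand <- c(empirical = as.numeric(fifth_percentile_empirical(lg)),
            normal    = as.numeric(fifth_percentile_normal(lg)),
            logistic  = as.numeric(fifth_percentile_logistic(lg)))
  back <- 10^cand
  pick <- which.min(back)  # which.min keeps the first of tied minima:
                           # empirical, then normal, then logistic
  structure(list(
    verhaar_class = verhaar_class,
    log10_candidates = cand,
    back_transformed = back,
    value = unname(back[pick]),
    method = names(cand)[pick],
    n = length(values),
    small_sample = length(values) < 30L,
    unit = normalize_conc_unit(unit)), class = "eco_ttc")
}

#' @export
print.eco_ttc <- function(x, ...) {
  cls <- if (is.na(x$verhaar_class)) "" else sprintf(" (Verhaar class %d)", x$verhaar_class)
  cat(sprintf("Eco-TTC%s: %g %s [%s, n = %d%s]\n", cls, signif4(x$value),
              x$unit, x$method, x$n,
              if (x$small_sample) ", small sample" else ""))
  cat("  candidates:",
      paste(sprintf("%s %g", names(x$back_transformed),
                    signif4(x$back_transformed)), collapse = ", "), "\n")
  invisible(x)
}

#' Eco-TTC selection from pre-computed candidates
#'
#' Applies the minimum rule to externally supplied back-transformed
#' fifth-percentile candidates (e.g. published per-class values) without
#' refitting.
#'
#' @param empirical,normal,logistic Back-transformed candidates (same unit).
#' @param unit Concentration unit of the candidates.
#' @param verhaar_class Optional class label.
#' @return An `eco_ttc` object (with `n = NA`).
#' @export
ecottc_from_candidates <- function(empirical, normal, logistic,
                                   unit = "ng/L",
                                   verhaar_class = NA_integer_) {
  back <- c(empirical = empirical, normal = normal, logistic = logistic)
  if (!is.numeric(back) || anyNA(back) || any(back <= 0))
    stop("candidates must be positive numbers", call. = FALSE)
  pick <- which.min(back)
  structure(list(
    verhaar_class = verhaar_class,
    log10_candidates = log10(back),
    back_transformed = back,
    value = unname(back[pick]),
    method = names(back)[pick],
    n = NA_integer_,
    small_sample = NA,
    unit = normalize_conc_unit(unit)), class = "eco_ttc")
}
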