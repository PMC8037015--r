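# Independent oracles, deliberately written as literal enumerations so they
# share no code path with the implementation they check.

# Assessment-factor ladder, restated row by row as an explicit pattern
# table. `cells` has columns trophic_group, duration_class, geomean, n.
oracle_af <- function(cells, af_over10 = 5) {
  acute <- cells[cells$duration_class == "acute", ]
  chron <- cells[cells$duration_class == "chronic", ]
  # most sensitive taxon by lowest acute geomean, ties algae < invert < fish
  ms <- NA_character_
  if (nrow(acute) > 0) {
    ord <- order(acute$geomean,
                 match(acute$trophic_group, c("algae", "invertebrate", "fish")))
    ms <- acute$trophic_group[ord[1]]
  }
  a <- nrow(acute); ch <- nrow(chron)
  ms_in_chron <- !is.na(ms) && ms %in% chron$trophic_group

  if (sum(chron$n) > 10) return(list(af = af_over10, rule_id = "gt10-chronic"))
  if (a == 1 && ch == 0) return(list(af = 10000, rule_id = "1-acute"))
  if (a == 2 && ch == 0) return(list(af = 5000, rule_id = "2-acute"))
  if (a == 3 && ch == 0) return(list(af = 1000, rule_id = "3-acute"))
  if (a == 3 && ch == 1 && !ms_in_chron)
    return(list(af = 1000, rule_id = "3-acute+1-chronic-other"))
  if (a == 3 && ch == 1 && ms_in_chron)
    return(list(af = 100, rule_id = "3-acute+1-chronic-ms"))
  if (a == 3 && ch == 2 && ms_in_chron)
    return(list(af = 50, rule_id = "3-acute+2-chronic-ms"))
  if (a == 3 && ch == 3) return(list(af = 10, rule_id = "3-acute+3-chronic"))
  # fallbacks (flagged in the implementation)
  if (a == 3 && ch == 2) return(list(af = 1000, rule_id = "3-acute-fallback"))
  if (a == 2) return(list(af = 5000, rule_id = "2-acute-fallback"))
  if (a == 1) return(list(af = 10000, rule_id = "1-acute-fallback"))
  list(af = 10000, rule_id = "chronic-only-fallback")
}

# Hand-rolled type-7 quantile: h = (n - 1) p + 1 on the sorted sample.
oracle_quantile_p <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# 1-D logistic scale MLE at a fixed (known) location, via golden-section
# search on the profile negative log-likelihood; independent of optim.
oracle_logistic_scale <- function(x, location) {
  nll <- function(s) -sum(stats::dlogis(x, location, s, log = TRUE))
  stats::optimize(nll, c(1e-6, 10 * stats::sd(x)), tol = 1e-10)$minimum
}

# Quick builder for endpoint matrices in tests.
make_records <- function(id = "chem", ...) {
  spec <- list(...)  # e.g. algae_acute = c(1, 2), fish_chronic = 0.5
  tg <- character(); dc <- character(); v <- numeric()
  for (nm in names(spec)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    tg <- c(tg, rep(parts[1], length(spec[[nm]])))
    dc <- c(dc, rep(parts[2], length(spec[[nm]])))
    v <- c(v, spec[[nm]])
  }
  endpoint_records(id, tg, dc, v, unit = "mg/L")
}

# Random availability pattern generator for the AF property test.
random_pattern_records <- function() {
  groups <- c("algae", "invertebrate", "fish")
  a_groups <- sample(groups, sample(0:3, 1))
  c_groups <- sample(groups, sample(0:3, 1))
  if (length(a_groups) == 0 && length(c_groups) == 0)
    c_groups <- sample(groups, 1)
  tg <- character(); dc <- character(); v <- numeric()
  for (g in a_groups) {
    k <- sample(1:2, 1)
    tg <- c(tg, rep(g, k)); dc <- c(dc, rep("acute", k))
    v <- c(v, 10^stats::runif(k, -2, 2))
  }
  for (g in c_groups) {
    k <- sample(1:6, 1)  # up to 18 chronic records: exercises the >10 rule
    tg <- c(tg, rep(g, k)); dc <- c(dc, rep("chronic", k))
    v <- c(v, 10^stats::runif(k, -3, 1))
  }
  endpoint_records("rnd", tg, dc, v, unit = "mg/L")
}
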