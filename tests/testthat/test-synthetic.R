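test_that("PNEC population generation is seeded and carries ground truth", {
  a <- gen_pnec_population(-2, 1, 100, seed = 4)
  b <- gen_pnec_population(-2, 1, 100, seed = 4)
  c <- gen_pnec_population(-2, 1, 100, seed = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_equal(a$true_log10_p5, -2 + stats::qnorm(0.05) * 1)
  expect_equal(a$true_p5, 10^a$true_log10_p5)
  expect_error(gen_pnec_population(-2, -1, 10, 1), "sigma")
  expect_error(gen_pnec_population(-2, 1, 1, 1), "n must be")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(gen_pnec_population(-2, 1, 50, seed = 99))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("degenerate sigma feeds the estimators' constant branches", {
  s <- gen_pnec_population(-2, 0, 10, seed = 1)
  e <- derive_ecottc(s$values)
  expect_equal(unname(e$back_transformed), rep(10^-2, 3), tolerance = 1e-9)
})

test_that("recovery follows the tolerance schedule (0.15 at n = 200, 0.05 at n = 5000)", {
  # spread 0.3: the largest at which both schedule points are >= 3.3 SE
  for (seed in 1:5) {
    s200 <- gen_pnec_population(-2, 0.3, 200, seed = seed)
    expect_lt(abs(fifth_percentile_empirical(s200$log10_values) -
                    s200$true_log10_p5), 0.15)
    expect_lt(abs(fifth_percentile_normal(s200$log10_values) -
                    s200$true_log10_p5), 0.15)
    s5k <- gen_pnec_population(-2, 0.3, 5000, seed = seed)
    expect_lt(abs(fifth_percentile_empirical(s5k$log10_values) -
                    s5k$true_log10_p5), 0.05)
    expect_lt(abs(fifth_percentile_normal(s5k$log10_values) -
                    s5k$true_log10_p5), 0.05)
  }
})

test_that("noise-free endpoint designs reproduce the ladder exactly", {
  des3 <- endpoint_design(c("algae/acute", "invertebrate/acute", "fish/acute"))
  rec <- gen_endpoint_records("syn-1", des3, noise_sigma = 0, seed = 2)
  truth <- attr(rec, "true_cell_means")
  p <- derive_pnec(rec)
  expect_equal(p$af, 1000)
  expect_equal(p$pnec, min(truth) / 1000)

  rec6 <- gen_endpoint_records("syn-2", endpoint_design(), noise_sigma = 0,
                               seed = 3)
  expect_equal(derive_pnec(rec6)$af, 10)
})

test_that("replicated noisy cells concentrate around the true geomean", {
  des <- endpoint_design("fish/acute", n_rep = 200)
  rec <- gen_endpoint_records("syn-3", des, cell_means = c("fish/acute" = 2),
                              noise_sigma = 0.3, seed = 9)
  m <- build_matrix(rec)
  # geomean of lognormal replicates -> true mean, sd 0.3/sqrt(200) log10 units
  expect_lt(abs(log10(m$geomean) - log10(2)), 4 * 0.3 / sqrt(200))
  expect_equal(m$n, 200)
})

test_that("chemical tables validate weights and respect the seed", {
  chems <- gen_chemicals(500, seed = 6)
  expect_true(all(chems$verhaar_class %in% 1:5))
  expect_true(all(chems$cramer_class %in% 1:3))
  expect_identical(chems, gen_chemicals(500, seed = 6))
  expect_error(gen_chemicals(10, 1, class_weights = c(1, 1, 1, 1, 1)),
               "summing to 1")
})

test_that("end-to-end class recovery: eco-TTC tracks the analytic percentile", {
  params <- default_class_params()
  for (v in 1:5) {
    # class locations with the recovery spread 0.3 (see vignette)
    mu <- params$log10_pnec_mu[params$verhaar_class == v]
    s <- gen_pnec_population(mu, 0.3, 5000, seed = 100 + v,
                             verhaar_class = v)
    e <- derive_ecottc(s$values, verhaar_class = v)
    expect_lt(abs(log10(e$value) - s$true_log10_p5), 0.05)
  }
})

test_that("full synthetic pipeline runs and every result honours the min rule", {
  sim <- simulate_dataset(100, seed = 2026, noise_sigma = 0.2)
  pnecs <- vapply(sim$endpoints, function(r) derive_pnec(r)$pnec, numeric(1))
  expect_true(all(pnecs > 0))

  # per-class eco-TTCs from the derived PNECs (classes with >= 2 members)
  by_class <- split(pnecs, sim$chemicals$verhaar_class)
  for (vals in by_class[lengths(by_class) >= 2]) {
    e <- derive_ecottc(vals)
    expect_lte(e$value, min(e$back_transformed) + 1e-15)
  }

  # compound branch with synthetic NOAELs
  set.seed(2027)
  noaels <- 10^stats::runif(length(pnecs), 0, 2)
  for (i in seq_len(25)) {
    qs <- compound_qs(hazard_profile(noael = noaels[i]))
    r <- compound_hbttc(pnecs[i], qs, sim$chemicals$chemical_id[i])
    expect_lte(r$hbttc_mg_L, r$pnec_mg_L)
    expect_lte(r$hbttc_mg_L, r$qs_mg_L)
  }
})
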