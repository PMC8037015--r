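test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometric_mean(c(4, 4)), 4)
  expect_equal(geometric_mean(c(1, 10, 100)), 10)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_error(geometric_mean(numeric()), "empty")
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
})

test_that("build_matrix aggregates per cell and validates", {
  r <- endpoint_records("c1", "fish", "acute", c(2, 8))
  m <- build_matrix(r)
  expect_equal(nrow(m), 1)
  expect_equal(m$geomean, 4)
  expect_equal(m$n, 2)

  full <- make_records("c2",
                       algae_acute = 1, invertebrate_acute = 2, fish_acute = 3,
                       algae_chronic = 0.1, invertebrate_chronic = 0.2,
                       fish_chronic = 0.3)
  expect_equal(nrow(build_matrix(full)), 6)

  mixed <- rbind(endpoint_records("a", "fish", "acute", 1),
                 endpoint_records("b", "fish", "acute", 1))
  class(mixed) <- c("tox_endpoints", "data.frame")
  expect_error(build_matrix(mixed), "single chemical")
  expect_error(build_matrix(empty <- data.frame()), "non-empty")
})

test_that("each ladder row is triggered by its minimal fixture", {
  set.seed(7)
  fixtures <- list(
    list(rec = make_records(fish_acute = 5), af = 10000, rule = "1-acute"),
    list(rec = make_records(fish_acute = 5, algae_acute = 1),
         af = 5000, rule = "2-acute"),
    list(rec = make_records(algae_acute = 1, invertebrate_acute = 10,
                            fish_acute = 100),
         af = 1000, rule = "3-acute"),
    list(rec = make_records(algae_acute = 1, invertebrate_acute = 10,
                            fish_acute = 100, fish_chronic = 0.5),
         af = 1000, rule = "3-acute+1-chronic-other"),
    list(rec = make_records(algae_acute = 1, invertebrate_acute = 10,
                            fish_acute = 100, algae_chronic = 0.5),
         af = 100, rule = "3-acute+1-chronic-ms"),
    list(rec = make_records(algae_acute = 1, invertebrate_acute = 10,
                            fish_acute = 100, algae_chronic = 0.5,
                            fish_chronic = 0.7),
         af = 50, rule = "3-acute+2-chronic-ms"),
    list(rec = make_records(algae_acute = 1, invertebrate_acute = 10,
                            fish_acute = 100, algae_chronic = 0.5,
                            invertebrate_chronic = 0.6, fish_chronic = 0.7),
         af = 10, rule = "3-acute+3-chronic"),
    list(rec = make_records(algae_chronic = 10^runif(4),
                            invertebrate_chronic = 10^runif(4),
                            fish_chronic = 10^runif(4)),
         af = 5, rule = "gt10-chronic"))
  for (f in fixtures) {
    sel <- select_af(build_matrix(f$rec))
    expect_equal(sel$af, f$af, info = f$rule)
    expect_equal(sel$rule_id, f$rule)
  }
})

test_that("the >10-chronic assessment factor is configurable within [1, 5]", {
  rec <- make_records(algae_chronic = 1:4, invertebrate_chronic = 1:4,
                      fish_chronic = 1:4)
  expect_equal(select_af(build_matrix(rec), af_over10 = 2)$af, 2)
  expect_error(select_af(build_matrix(rec), af_over10 = 0.5), "\\[1, 5\\]")
  expect_error(select_af(build_matrix(rec), af_over10 = 6), "\\[1, 5\\]")
})

test_that("uncovered patterns fall back conservatively and are flagged", {
  two_plus_chronic <- make_records(algae_acute = 1, fish_acute = 2,
                                   fish_chronic = 0.5)
  sel <- select_af(build_matrix(two_plus_chronic))
  expect_equal(sel$af, 5000)
  expect_true(sel$flagged)

  chronic_only <- make_records(fish_chronic = 0.5)
  sel <- select_af(build_matrix(chronic_only))
  expect_equal(sel$af, 10000)
  expect_true(sel$flagged)
  expect_equal(sel$basis_cell$duration_class, "chronic")

  two_chronic_no_ms <- make_records(algae_acute = 1, invertebrate_acute = 10,
                                    fish_acute = 100,
                                    invertebrate_chronic = 0.5,
                                    fish_chronic = 0.7)
  sel <- select_af(build_matrix(two_chronic_no_ms))
  expect_equal(sel$af, 1000)
  expect_true(sel$flagged)
})

test_that("derive_pnec applies the factor to the documented basis cell", {
  # single acute cell
  expect_equal(derive_pnec(make_records(fish_acute = 5))$pnec, 5 / 10000)

  # three acute levels: factor on the lowest acute geomean
  p <- derive_pnec(make_records(algae_acute = 1, invertebrate_acute = 10,
                                fish_acute = 100))
  expect_equal(p$pnec, 1 / 1000)
  expect_equal(p$basis_cell$trophic_group, "algae")

  # chronic datum on the most sensitive acute taxon: factor on that chronic
  p <- derive_pnec(make_records(algae_acute = 1, invertebrate_acute = 10,
                                fish_acute = 100, algae_chronic = 0.5))
  expect_equal(p$pnec, 0.5 / 100)
  expect_equal(p$basis_cell$duration_class, "chronic")
})

test_that("pnec = basis / af and pnec <= basis for random inputs", {
  set.seed(101)
  for (i in 1:200) {
    p <- derive_pnec(random_pattern_records())
    expect_equal(p$pnec, p$basis_value / p$af)
    expect_lte(p$pnec, p$basis_value)
    expect_gte(p$af, 1)
  }
})

test_that("result is invariant to record order", {
  set.seed(11)
  rec <- random_pattern_records()
  shuffled <- rec[sample(nrow(rec)), ]
  class(shuffled) <- c("tox_endpoints", "data.frame")
  a <- derive_pnec(rec); b <- derive_pnec(shuffled)
  expect_equal(a$pnec, b$pnec)
  expect_equal(a$rule_id, b$rule_id)
  expect_equal(a$basis_cell$trophic_group, b$basis_cell$trophic_group)
})

test_that("selection agrees with the brute-force pattern oracle", {
  set.seed(2024)
  for (i in 1:1000) {
    rec <- random_pattern_records()
    cells <- build_matrix(rec)
    got <- select_af(cells)
    want <- oracle_af(cells)
    expect_equal(got$af, want$af, info = paste("pattern", i))
    expect_equal(got$rule_id, want$rule_id, info = paste("pattern", i))
  }
})

test_that("most sensitive taxon ties break algae < invertebrate < fish", {
  rec <- make_records(algae_acute = 1, invertebrate_acute = 1, fish_acute = 1,
                      algae_chronic = 0.5)
  sel <- select_af(build_matrix(rec))
  # algae wins the tie, so the chronic datum sits on the most sensitive taxon
  expect_equal(sel$af, 100)
})
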