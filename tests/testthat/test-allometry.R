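test_that("leaf biomass follows the power law and rejects bad input", {
  p <- ref_params()
  expect_equal(leaf_biomass(0, p), 0)
  expect_equal(leaf_biomass(100, p), 2e-5 * 100^1.3, tolerance = 1e-12)
  expect_equal(leaf_biomass(100, p), 0.0079621, tolerance = 1e-5)
  expect_equal(leaf_biomass(7, allometric_params(1, 1)), 7)
  # strictly increasing in length
  l <- sort(runif(50, 0, 500))
  expect_true(all(diff(leaf_biomass(l, p)) > 0))
  expect_error(leaf_biomass(-1, p), class = "zg_domain_error")
  expect_error(allometric_params(-1, 1.3), class = "zg_domain_error")
  expect_error(allometric_params(2e-5, 0), class = "zg_domain_error")
})

test_that("delta and lambda factors match their closed forms and bounds", {
  expect_equal(delta_factor(0, 100, 1.3), 0)
  expect_equal(delta_factor(100, 100, 1.3), 1)
  expect_equal(delta_factor(20, 100, 1.3), 1 - 0.8^1.3, tolerance = 1e-12)
  expect_equal(lambda_ratio(0, 100), 0)
  expect_equal(lambda_ratio(100, 100), 1)
  expect_equal(lambda_ratio(20, 100), 0.2)
  # empty-leaf convention
  expect_equal(delta_factor(0, 0, 1.3), 0)
  expect_equal(lambda_ratio(0, 0), 0)
  expect_error(delta_factor(101, 100, 1.3), class = "zg_domain_error")
  expect_error(lambda_ratio(-1, 100), class = "zg_domain_error")

  cases <- random_leaf_cases(500)
  for (i in seq_len(nrow(cases))) {
    inc <- cases$length_end[i] - cases$length_start[i]
    d <- delta_factor(inc, cases$length_end[i], cases$beta[i])
    lam <- lambda_ratio(inc, cases$length_end[i])
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(lam, 0); expect_lte(lam, 1)
    # concavity/convexity of 1 - (1 - lambda)^beta
    if (cases$beta[i] >= 1) expect_gte(d, lam - 1e-12)
    else expect_lte(d, lam + 1e-12)
  }
})

test_that("allometric increment equals the biomass difference oracle", {
  p <- ref_params()
  lf <- leaf_observation(1, 80, 100, dry_weight_end = 0.008)
  oracle <- leaf_biomass(100, p) - leaf_biomass(80, p)
  expect_equal(biomass_increment_allometric(lf, p), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.0020047, tolerance = 1e-4)
  # linear case: increment times alpha
  expect_equal(
    biomass_increment_allometric(lf, allometric_params(0.3, 1)),
    0.3 * 20, tolerance = 1e-12)
  expect_equal(
    biomass_increment_allometric(leaf_observation(1, 50, 50), p), 0)

  cases <- random_leaf_cases(10000)
  got <- mapply(function(ls, le, a, b) {
    biomass_increment_allometric(list(length_start = ls, length_end = le),
                                 allometric_params(a, b))
  }, cases$length_start, cases$length_end, cases$alpha, cases$beta)
  want <- cases$alpha * (cases$length_end^cases$beta -
                           cases$length_start^cases$beta)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= -1e-15))
  expect_true(all(got <= cases$alpha * cases$length_end^cases$beta + 1e-15))
})

test_that("increment is monotone in the length increment at fixed end length", {
  p <- allometric_params(3e-5, 1.7)
  incs <- seq(0, 250, length.out = 40)
  vals <- sapply(incs, function(i)
    biomass_increment_allometric(list(length_start = 250 - i,
                                      length_end = 250), p))
  expect_true(all(diff(vals) >= 0))
})

test_that("growth decomposition conserves the increment and signs correctly", {
  # hand case: alpha 1, beta 2, whole-unit leaf growing half its length
  gd <- growth_decomposition(list(length_start = 0.5, length_end = 1),
                             allometric_params(1, 2))
  expect_equal(gd$new_tissue, 0.25, tolerance = 1e-12)
  expect_equal(gd$maturation, 0.5, tolerance = 1e-12)

  # beta = 1: no maturation term, ever
  gd1 <- growth_decomposition(list(length_start = 37, length_end = 95),
                              allometric_params(2, 1))
  expect_equal(gd1$maturation, 0, tolerance = 1e-12)

  # whole leaf new: everything is new tissue
  p <- ref_params()
  gdn <- growth_decomposition(list(length_start = 0, length_end = 140), p)
  expect_equal(gdn$maturation, 0, tolerance = 1e-12)
  expect_equal(gdn$new_tissue, leaf_biomass(140, p), tolerance = 1e-12)

  cases <- random_leaf_cases(10000, seed = 7)
  for (i in seq_len(nrow(cases))) {
    pp <- allometric_params(cases$alpha[i], cases$beta[i])
    lf <- list(length_start = cases$length_start[i],
               length_end = cases$length_end[i])
    gd <- growth_decomposition(lf, pp)
    total <- biomass_increment_allometric(lf, pp)
    expect_equal(gd$new_tissue + gd$maturation, total, tolerance = 1e-12)
    if (cases$beta[i] >= 1) expect_gte(gd$maturation, -1e-15 - 1e-12 * total)
  }
})

test_that("leaf observations enforce their invariants", {
  expect_error(leaf_observation(1, 80, 100, increment = 25),
               class = "zg_domain_error")
  expect_error(leaf_observation(1, 100, 80), class = "zg_domain_error")
  expect_error(leaf_observation(1, 80, 100, increment_above_mark = 30),
               class = "zg_domain_error")
  expect_error(leaf_observation(0, 80, 100), class = "zg_usage_error")
  lf <- leaf_observation(2, 80, 100, dry_weight_end = 0.01)
  expect_equal(lf$increment, 20)
  expect_equal(lf$increment_above_mark, 20)
})
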