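test_that("shoot decomposition reproduces its defining sums", {
  # beta = 1 so delta = lambda and the remainder terms are hand-computable:
  # leaves 1, 2 have delta 0.5, 0.2 and allometric end biomasses 0.001,
  # 0.002 g; the rank-3 leaf is separate.
  p <- allometric_params(1e-5, 1)
  sh <- shoot_sample("a", data.frame(
    rank = 1:3,
    length_start = c(50, 160, 280), length_end = c(100, 200, 300),
    dry_weight_end = c(0.001, 0.002, 0.003)))
  dec <- shoot_decomposition(sh, p, p = 12, delta_t = 14)
  expect_equal(dec$rsap, (0.5 * 0.001 + 0.2 * 0.002) / 14, tolerance = 1e-12)
  expect_equal(dec$rsap, 6.4286e-5, tolerance = 1e-4)
  d3 <- delta_factor(20, 300, 1)
  expect_equal(dec$csap, d3 * 12 / 14, tolerance = 1e-12)
  # beta = 1: no maturation anywhere, so rsma = 0 and rsmp = rsap
  expect_equal(dec$rsma, 0, tolerance = 1e-15)
  expect_equal(dec$rsmp, dec$rsap, tolerance = 1e-15)

  # only the third leaf grew: rsap vanishes
  only3 <- shoot_sample("b", data.frame(
    rank = 1:3, length_start = c(40, 80, 200), length_end = c(40, 80, 260),
    dry_weight_end = c(1, 2, 3) * 1e-3))
  expect_equal(shoot_decomposition(only3, ref_params(), 12, 14)$rsap, 0)

  # delta_3 = delta_t / p makes csap exactly 1
  pars <- allometric_params(2e-5, 1)   # delta = lambda, easy to invert
  lam3 <- 14 / 21                      # delta_t / p
  sh1 <- shoot_sample("c", data.frame(
    rank = 1:3, length_start = c(50, 80, 300 * (1 - lam3)),
    length_end = c(60, 100, 300), dry_weight_end = c(1, 2, 3) * 1e-3))
  expect_equal(shoot_decomposition(sh1, pars, 21, 14)$csap, 1,
               tolerance = 1e-12)

  two <- shoot_sample("d", data.frame(
    rank = 1:2, length_start = c(10, 60), length_end = c(40, 80)))
  expect_error(shoot_decomposition(two, ref_params(), 12, 14),
               class = "zg_skip_shoot")
})

test_that("per-shoot and campaign identities hold exactly on allometric data", {
  pars <- ref_params()
  sims <- simulate_campaigns(small_config(weight_noise_sigma = 0,
                                          true_params = pars))
  for (sim in sims) {
    au <- identity_audit(sim$campaign, pars)
    expect_lt(au$r_shoot, 1e-10)
    expect_lt(au$r_campaign, 1e-10)
    expect_lt(au$r_marking_shoot, 1e-10)
    expect_lt(au$r_marking_campaign, 1e-10)
    expect_lt(au$r_rsmp, 1e-10)
    expect_lt(au$r_conservation, 1e-12)
    expect_lt(au$r_bp_reconstruction, 1e-10)
    expect_lt(au$rswa_max, 1e-10)
  }
})

test_that("single-shoot campaign identity equals the shoot identity", {
  pars <- ref_params()
  camp <- exact_campaign(pars, n_shoots = 1)
  bias <- campaign_bias(camp, pars)
  dec <- shoot_decomposition(camp$shoots[[1]], pars, campaign_rates(camp, pars)$p, 14)
  expect_equal(bias$cap, dec$csap, tolerance = 1e-12)
  expect_equal(bias$bap, dec$rsap, tolerance = 1e-12)
  expect_equal(bias$bmp, dec$rsmp, tolerance = 1e-12)
})

test_that("campaign bias terms satisfy their definitions and bounds", {
  pars <- ref_params()
  camp <- exact_campaign(pars, n_shoots = 4, p = 12)
  rt <- campaign_rates(camp, pars)
  bias <- campaign_bias(camp, pars, rt)

  # identical shoots: cap equals the common csap regardless of weights
  decs <- lapply(camp$shoots, shoot_decomposition, params = pars,
                 p = rt$p, delta_t = 14)
  expect_equal(bias$cap, decs[[1]]$csap, tolerance = 1e-12)

  # direct biases are differences against the in situ rate
  expect_equal(bias$bp, rt$lg - rt$lgp, tolerance = 1e-15)
  expect_equal(bias$ba, rt$lg - rt$lga, tolerance = 1e-15)
  expect_equal(bias$bm, rt$lg - rt$lgm, tolerance = 1e-15)
  expect_equal(bias$ba, 0, tolerance = 1e-15)   # exact allometry

  # bound construction and membership
  expect_equal(bias$blap, bias$bap - bias$lgp_allometric, tolerance = 1e-15)
  expect_equal(bias$bp_upper,
               bias$blap + (rt$p / 14) * bias$lgp_allometric,
               tolerance = 1e-15)
  expect_gte(bias$bp_allometric, bias$blap - 1e-12)
  expect_lte(bias$bp_allometric, bias$bp_upper + 1e-12)
})

test_that("noisy data yields positive diagnostics, not identity failures", {
  pars <- allometric_params(2e-5, 1.3)
  sims <- simulate_campaigns(small_config(weight_noise_sigma = 0.2,
                                          true_params = pars))
  au <- identity_audit(sims[[1]]$campaign, pars)
  # allometric-system identities still exact
  expect_lt(au$r_shoot, 1e-10)
  expect_lt(au$r_marking_campaign, 1e-10)
  # measured-vs-allometric residual is genuinely nonzero and reported
  expect_gt(au$rswa_max, 1e-6)
})

test_that("plastochrone proxy underestimates when p <= delta_t on exact data", {
  pars <- ref_params()
  sims <- simulate_campaigns(small_config(weight_noise_sigma = 0,
                                          shoots_per_campaign = 25,
                                          true_params = pars,
                                          plastochrone_days = c(8, 12),
                                          env_p_sd = 0))
  checked <- 0L
  for (sim in sims) {
    rt <- campaign_rates(sim$campaign, pars)
    if (rt$p > rt$delta_t) next
    checked <- checked + 1L
    bias <- campaign_bias(sim$campaign, pars, rt)
    expect_lte(bias$cap, 1 + 1e-12)
    expect_gt(bias$bap, 0)
    expect_gt(bias$bp, 0)                   # the underestimation claim
    # Eq-29-style reconstruction is exact on exact-allometry data
    expect_equal(bias$bp, (bias$cap_measured - 1) * rt$lgp + bias$bap,
                 tolerance = 1e-10)
  }
  expect_gt(checked, 0L)
})

test_that("cap drops strictly below one when the interval exceeds p", {
  pars <- ref_params()
  sims <- simulate_campaigns(small_config(weight_noise_sigma = 0,
                                          shoots_per_campaign = 30,
                                          true_params = pars,
                                          plastochrone_days = c(6, 9),
                                          env_p_sd = 0))
  for (sim in sims) {
    rt <- campaign_rates(sim$campaign, pars)
    expect_lt(rt$p, rt$delta_t)
    bias <- campaign_bias(sim$campaign, pars, rt)
    expect_lt(bias$cap, 1)
    expect_true(all(bias$csap < 1))
  }
})
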