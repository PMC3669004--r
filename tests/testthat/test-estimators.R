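test_that("in situ shoot rate sums weight gains over the interval", {
  sh <- shoot_sample("a", data.frame(
    rank = 1:2, length_start = c(50, 100), length_end = c(60, 120),
    dry_weight_start = c(0.001, 0.002), dry_weight_end = c(0.0015, 0.003)))
  expect_equal(shoot_rate_in_situ(sh, 14), 0.0015 / 14, tolerance = 1e-12)
  expect_equal(shoot_rate_in_situ(sh, 14), 1.0714e-4, tolerance = 1e-4)

  one <- shoot_sample("b", data.frame(
    rank = 1, length_start = 50, length_end = 60,
    dry_weight_start = 0.004, dry_weight_end = 0.004 + 0.0007))
  expect_equal(shoot_rate_in_situ(one, 1), 0.0007, tolerance = 1e-12)

  # missing start weights: explicit unobservable error
  field <- shoot_sample("c", data.frame(
    rank = 1, length_start = 50, length_end = 60, dry_weight_end = 0.002))
  expect_error(shoot_rate_in_situ(field, 14), class = "zg_unobservable_error")
  expect_error(shoot_rate_in_situ(field, 14), "allometric surrogate")
})

test_that("allometric shoot rate projects increments through the power law", {
  p <- ref_params()
  sh <- shoot_sample("a", data.frame(
    rank = 1, length_start = 80, length_end = 100, dry_weight_end = 0.01))
  want <- (leaf_biomass(100, p) - leaf_biomass(80, p)) / 14
  expect_equal(shoot_rate_allometric(sh, p, 14), want, tolerance = 1e-12)
  expect_equal(want, 1.4320e-4, tolerance = 1e-4)

  none <- shoot_sample("b", data.frame(
    rank = 1:2, length_start = c(80, 90), length_end = c(80, 90)))
  expect_equal(shoot_rate_allometric(none, p, 14), 0)

  # on exact allometric data the in situ rate and surrogate coincide
  ex <- exact_shoot(p)
  expect_equal(shoot_rate_in_situ(ex, 14),
               shoot_rate_allometric(ex, p, 14), tolerance = 1e-12)
})

test_that("marking rate distinguishes formal and field modes", {
  p <- ref_params()
  sh <- shoot_sample("a", data.frame(
    rank = 1:2, length_start = c(80, 90), length_end = c(100, 100)))
  want_formal <- 2e-5 * (20^1.3 + 10^1.3) / 14
  expect_equal(shoot_rate_marking(sh, p, 14, mode = "formal"), want_formal,
               tolerance = 1e-12)
  expect_equal(want_formal, 9.869e-5, tolerance = 1e-3)

  # all growth below the mark: field rate is zero
  below <- shoot_sample("b", data.frame(
    rank = 1, length_start = 10, length_end = 30,
    increment_above_mark = 0))
  expect_equal(shoot_rate_marking(below, p, 14, mode = "field"), 0)

  # single leaf wholly above the mark: field equals the allometric
  # above-mark projection of that increment
  above <- shoot_sample("c", data.frame(
    rank = 1, length_start = 80, length_end = 100))
  expect_equal(shoot_rate_marking(above, p, 14, mode = "field"),
               shoot_rate_allometric(above, p, 14), tolerance = 1e-12)

  # field rate never exceeds the allometric full-increment rate
  part <- shoot_sample("d", data.frame(
    rank = 1:3, length_start = c(10, 60, 200), length_end = c(50, 100, 240),
    increment_above_mark = c(20, 40, 40)))
  expect_lte(shoot_rate_marking(part, p, 14, mode = "field"),
             shoot_rate_allometric(part, p, 14) + 1e-15)

  # measured above-mark tissue weights take precedence when present
  meas <- shoot_sample("e", data.frame(
    rank = 1, length_start = 80, length_end = 100,
    above_mark_weight = 0.0042))
  expect_equal(shoot_rate_marking(meas, p, 14, mode = "field"), 0.0042 / 14)

  expect_error(shoot_rate_marking(sh, p, 14, mode = "banana"),
               class = "zg_usage_error")
})

test_that("plastochrone interval is the Jacobs ratio", {
  expect_equal(plastochrone_interval(40, 40, 14), 14)
  expect_equal(plastochrone_interval(20, 28, 14), 10)
  expect_equal(plastochrone_interval(1, 1, 21), 21)
  expect_error(plastochrone_interval(40, 0, 14),
               class = "zg_undefined_interval_error")
})

test_that("plastochrone shoot rate divides the third-leaf weight by p", {
  sh <- shoot_sample("a", data.frame(
    rank = 1:3, length_start = c(10, 50, 90), length_end = c(30, 70, 100),
    dry_weight_end = c(0.001, 0.004, 0.0079621)))
  expect_equal(shoot_rate_plastochrone(sh, 14), 0.0079621 / 14,
               tolerance = 1e-12)
  expect_equal(shoot_rate_plastochrone(sh, 1), 0.0079621, tolerance = 1e-12)

  two <- shoot_sample("b", data.frame(
    rank = 1:2, length_start = c(10, 50), length_end = c(30, 70),
    dry_weight_end = c(0.001, 0.004)))
  expect_error(shoot_rate_plastochrone(two, 14), class = "zg_skip_shoot")
})

test_that("campaign rates average per-shoot rates over contributing shoots", {
  p <- ref_params()
  camp <- exact_campaign(p, n_shoots = 2)
  rt <- campaign_rates(camp, p)
  expect_equal(rt$lga, mean(rt$shoots$lga), tolerance = 1e-12)
  expect_equal(rt$lgp, mean(rt$shoots$lgp), tolerance = 1e-12)
  # identical shoots: campaign means equal the shoot rates
  expect_equal(rt$lga, rt$shoots$lga[1], tolerance = 1e-12)
  # exact data: in situ equals allometric on every shoot and on the mean
  expect_equal(rt$shoots$lg, rt$shoots$lga, tolerance = 1e-12)
  expect_equal(rt$lg, rt$lga, tolerance = 1e-12)

  # shoots without a rank-3 leaf are excluded from the plastochrone mean
  short <- shoot_sample("short", data.frame(
    rank = 1:2, length_start = c(10, 60), length_end = c(40, 80),
    dry_weight_end = c(1e-3, 2e-3), dry_weight_start = c(5e-4, 1e-3)))
  mixed <- campaign("2000-06-01", 14, list(exact_shoot(p), short),
                    n_marked = 3, new_leaves = 2, p = 12)
  rtm <- campaign_rates(mixed, p)
  expect_equal(rtm$n_skipped_plastochrone, 1L)
  expect_equal(rtm$lgp, rtm$shoots$lgp[1], tolerance = 1e-12)

  expect_error(campaign("2000-06-01", 14, list()), class = "zg_usage_error")
})
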