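# Synthetic shoot-marking campaigns.
#
# The generator emulates a biweekly eelgrass marking study: each campaign
# marks ~40 shoots, loses a fraction to retrieval, and records per leaf the
# lengths at both endpoints, the above-mark increment, and dry weights.
# Leaves follow a saturating length-age curve with a seasonal growth
# multiplier; leaf appearance is clocked by a seasonal plastochrone
# interval; dry weights follow the allometric law times a leaf-age maturity
# factor (immature tissue lighter, mature tissue denser than the pooled
# law) times per-leaf lognormal noise.  Setting `weight_noise_sigma = 0`
# selects the exact-allometry regime (noise and maturity off): every weight
# is then exactly `alpha * l^beta`, which is the regime in which all the
# identities of the bias decomposition hold to machine precision.

#' Configuration of the synthetic marking study
#'
#' Defaults emulate a biweekly field campaign (35 visits, about 40 shoots
#' marked per visit, 14-day marking interval, 3-6 leaves per shoot) on a
#' meadow whose leaf allometry has `alpha = 2.1e-5`, `beta = 1.3` (values
#' that print as the commonly reported 0.00002 and 1.3 at their usual
#' precision).
#'
#' @param n_campaigns Number of biweekly campaigns (default 35).
#' @param shoots_per_campaign Shoots marked per campaign (default 40).
#' @param delta_t Marking interval, days (default 14).
#' @param leaves_per_shoot Integer range of leaves per shoot at marking
#'   (default `c(3, 6)`).
#' @param true_params True [allometric_params()] of the simulated meadow.
#' @param plastochrone_days Seasonal range of the true plastochrone
#'   interval, days (default `c(10, 20)`).
#' @param plastochrone_lag_days Lag of the leaf-appearance season behind
#'   the elongation season, days (default 85): appearance of new leaves
#'   tracks water temperature, which in upwelling-influenced coastal
#'   lagoons peaks in late summer, two to three months after peak
#'   insolation.
#' @param leaf_length_max Mean asymptotic leaf length, mm (default 420).
#' @param leaf_length_cv Lognormal coefficient of variation of per-leaf
#'   asymptotic length (default 0.12).
#' @param growth_tau E-folding time of the length-age curve, days
#'   (default 50): young leaves elongate fastest, old leaves barely.
#' @param season_amplitude Relative amplitude of the seasonal growth-rate
#'   multiplier (default 0.25), peaking in late June.
#' @param size_amplitude Relative seasonal amplitude of asymptotic leaf
#'   size (default 0.03): standing mature-leaf size is a slowly varying
#'   stock, in contrast to the strongly seasonal elongation flow.  Each
#'   leaf's asymptote is set by the seasonal conditions around its own
#'   birth, so mature leaves embody past, not current, conditions.
#' @param size_lag_days Days after a leaf's birth at which its size season
#'   is evaluated (default 15, roughly the midpoint of length accretion).
#' @param env_growth_sd Lognormal s.d. of campaign-level environmental
#'   fluctuation of the growth multiplier (default 0.05): biweekly field
#'   series are jagged, not smooth sinusoids.
#' @param env_p_sd Lognormal s.d. of campaign-level fluctuation of the true
#'   plastochrone interval (default 0.12), independent of the growth
#'   fluctuation.
#' @param sheath_length,sheath_sd Mean and s.d. of the per-shoot sheath
#'   length, mm (defaults 25 and 4): growth below this reference is what
#'   classical marking misses.
#' @param weight_noise_sigma Standard deviation of the leaf-level lognormal
#'   weight deviation (default 0.2); `0` selects the exact-allometry
#'   validation regime (maturity structure off as well).
#' @param maturity_deficit Weight multiplier of brand-new tissue relative
#'   to the pooled allometric law (default 0.9).
#' @param maturity_max Asymptotic multiplier of fully mature tissue
#'   (default 1.06).
#' @param maturity_tau E-folding time of tissue maturation, days
#'   (default 20).
#' @param retrieval_loss Fraction of marked shoots not retrieved
#'   (default 0.1).
#' @param start_date First retrieval date (default "1999-03-01").
#' @param seed Integer seed making the simulation deterministic.
#' @return An object of class `simulation_config` (a validated named list).
#' @export
simulation_config <- function(n_campaigns = 35,
                              shoots_per_campaign = 40,
                              delta_t = 14,
                              leaves_per_shoot = c(3, 6),
                              true_params = allometric_params(2.1e-5, 1.3),
                              plastochrone_days = c(10, 20),
                              plastochrone_lag_days = 85,
                              leaf_length_max = 420,
                              leaf_length_cv = 0.12,
                              growth_tau = 50,
                              season_amplitude = 0.25,
                              size_amplitude = 0.03,
                              size_lag_days = 15,
                              env_growth_sd = 0.05,
                              env_p_sd = 0.12,
                              sheath_length = 25,
                              sheath_sd = 4,
                              weight_noise_sigma = 0.2,
                              maturity_deficit = 0.9,
                              maturity_max = 1.06,
                              maturity_tau = 20,
                              retrieval_loss = 0.1,
                              start_date = "1999-03-01",
                              seed = 1L) {
  cfg <- list(
    n_campaigns = n_campaigns, shoots_per_campaign = shoots_per_campaign,
    delta_t = delta_t, leaves_per_shoot = leaves_per_shoot,
    true_params = as_allometric_params(true_params),
    plastochrone_days = plastochrone_days,
    plastochrone_lag_days = plastochrone_lag_days,
    leaf_length_max = leaf_length_max, leaf_length_cv = leaf_length_cv,
    growth_tau = growth_tau, season_amplitude = season_amplitude,
    size_amplitude = size_amplitude, size_lag_days = size_lag_days,
    env_growth_sd = env_growth_sd, env_p_sd = env_p_sd,
    sheath_length = sheath_length, sheath_sd = sheath_sd,
    weight_noise_sigma = weight_noise_sigma,
    maturity_deficit = maturity_deficit, maturity_max = maturity_max,
    maturity_tau = maturity_tau,
    retrieval_loss = retrieval_loss,
    start_date = as.Date(start_date), seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  bad <- character(0)
  pos <- c("n_campaigns", "shoots_per_campaign", "delta_t", "leaf_length_max",
           "growth_tau", "maturity_tau", "sheath_length")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0) bad <- c(bad, f)
  }
  nonneg <- c("leaf_length_cv", "season_amplitude", "size_amplitude",
              "size_lag_days", "sheath_sd", "weight_noise_sigma",
              "env_growth_sd", "env_p_sd", "plastochrone_lag_days")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        !is.finite(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  }
  if (!(is.numeric(cfg$retrieval_loss) && length(cfg$retrieval_loss) == 1L &&
        cfg$retrieval_loss >= 0 && cfg$retrieval_loss < 1)) {
    bad <- c(bad, "retrieval_loss")
  }
  for (f in c("leaves_per_shoot", "plastochrone_days")) {
    v <- cfg[[f]]
    if (!(is.numeric(v) && length(v) == 2L && all(is.finite(v)) &&
          v[1] > 0 && v[1] <= v[2])) bad <- c(bad, f)
  }
  if (!(cfg$maturity_deficit > 0 && cfg$maturity_deficit <= cfg$maturity_max)) {
    bad <- c(bad, "maturity_deficit/maturity_max")
  }
  if (length(bad)) {
    zg_stop_usage(paste0("invalid simulation_config field(s): ",
                         paste(unique(bad), collapse = ", ")))
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config> %d campaigns x %d shoots, delta_t = %g d, ",
           "leaves %d-%d, p in [%g, %g] d,\n  alpha = %g, beta = %g, ",
           "sigma = %g, retrieval loss = %g, seed = %d\n"),
    x$n_campaigns, x$shoots_per_campaign, x$delta_t,
    x$leaves_per_shoot[1], x$leaves_per_shoot[2],
    x$plastochrone_days[1], x$plastochrone_days[2],
    x$true_params$alpha, x$true_params$beta,
    x$weight_noise_sigma, x$retrieval_loss, x$seed))
  invisible(x)
}

# Seasonal multiplier: peaks in late June, unit mean.
season_multiplier <- function(doy, amplitude, lag = 0) {
  1 + amplitude * sin(2 * pi * (doy - lag - 80) / 365)
}

#' Simulate a season of marking campaigns
#'
#' Generates `n_campaigns` biweekly campaigns under the configured study
#' conditions, each carrying the observable [campaign()] (what a field
#' crew would record) and a ground-truth channel: true per-shoot biomass
#' production, true below-mark production, and the true plastochrone
#' interval.  Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of objects of class `simulated_campaign` (the list itself
#'   has class `simulated_season` and keeps the config as an attribute).
#' @examples
#' sims <- simulate_campaigns(simulation_config(n_campaigns = 2, seed = 7))
#' sims[[1]]$campaign
#' @export
simulate_campaigns <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  set.seed(config$seed)
  exact <- config$weight_noise_sigma == 0
  pars <- config$true_params
  p_mid <- mean(config$plastochrone_days)
  p_half <- diff(config$plastochrone_days) / 2
  start_doy <- as.integer(format(config$start_date, "%j"))

  sims <- vector("list", config$n_campaigns)
  for (ci in seq_len(config$n_campaigns)) {
    date <- config$start_date + (ci - 1L) * 14L
    doy <- start_doy + (ci - 1L) * 14L
    s_grow <- season_multiplier(doy, config$season_amplitude) *
      exp(stats::rnorm(1, 0, config$env_growth_sd))
    p_true <- p_season(doy, p_mid, p_half, config$plastochrone_lag_days) *
      exp(stats::rnorm(1, 0, config$env_p_sd))

    # Standing leaf ages follow the integrated appearance history: a leaf
    # of rank r is (r - 1/2) plastochrones old on the clock of past p(t),
    # so age structure lags the current appearance rate.
    back <- 0:200
    cum_appear <- cumsum(1 / p_season(doy - back, p_mid, p_half,
                                      config$plastochrone_lag_days))
    age_of_rank <- stats::approxfun(cum_appear, back, rule = 2)

    retrieved <- which(stats::runif(config$shoots_per_campaign) >=
                         config$retrieval_loss)
    if (!length(retrieved)) retrieved <- 1L

    shoots <- list()
    truth_rows <- list()
    total_new <- 0L
    for (si in seq_along(retrieved)) {
      sh <- simulate_shoot(config, pars, s_grow, doy, p_true, age_of_rank,
                           exact)
      total_new <- total_new + sh$n_new
      id <- sprintf("c%02d_s%02d", ci, si)
      shoots[[si]] <- shoot_sample(id, sh$leaves)
      truth_rows[[si]] <- data.frame(
        shoot_id = id,
        true_production = sh$true_production,
        true_below_mark = sh$true_below_mark,
        n_new_leaves = sh$n_new)
    }

    p_hat <- if (total_new > 0) {
      plastochrone_interval(length(retrieved), total_new, config$delta_t)
    } else NULL
    camp <- campaign(date = date, delta_t = config$delta_t, shoots = shoots,
                     n_marked = config$shoots_per_campaign,
                     new_leaves = total_new, p = p_hat)
    truth <- do.call(rbind, truth_rows)
    sims[[ci]] <- structure(
      list(campaign = camp,
           truth = list(p_true = p_true,
                        season_growth = s_grow,
                        shoots = truth,
                        lg_true = sum(truth$true_production) /
                          (nrow(truth) * config$delta_t))),
      class = "simulated_campaign")
  }
  structure(sims, class = c("simulated_season", "list"), config = config)
}

p_season <- function(doy, p_mid, p_half, lag) {
  p_mid - p_half * sin(2 * pi * (doy - 80 - lag) / 365)
}

# One retrieved shoot: leaves present at marking plus leaves that appeared
# during the interval, with lengths, above-mark increments, weights and
# ground truth.
simulate_shoot <- function(config, pars, s_grow, doy, p_true, age_of_rank,
                           exact) {
  dt <- config$delta_t
  tau <- config$growth_tau
  sheath <- max(5, stats::rnorm(1, config$sheath_length, config$sheath_sd))

  leaf_choices <- seq(config$leaves_per_shoot[1], config$leaves_per_shoot[2])
  n_old <- if (length(leaf_choices) == 1L) leaf_choices else
    sample(leaf_choices, 1L)
  n_new <- stats::rpois(1L, dt / p_true)

  # Ages at marking: old leaves one plastochrone (of appearance history)
  # apart, jittered; new leaves appear during the interval.
  age_old <- sort(age_of_rank(seq_len(n_old) - 0.5 + stats::runif(n_old, -0.3, 0.3)))
  birth_new <- sort(stats::runif(n_new, 0, dt))
  age_new_end <- dt - birth_new            # age at retrieval, youngest first

  age_mark <- c(rep(0, n_new), age_old)    # 0 = not yet present
  age_end <- c(age_new_end, age_old + dt)
  is_new <- c(rep(TRUE, n_new), rep(FALSE, n_old))
  n_leaf <- n_new + n_old

  # Each leaf's asymptotic size reflects the seasonal conditions around its
  # own birth (shifted by size_lag_days, the bulk of its length accretion):
  # standing mature leaves embody past growth conditions, not current ones.
  s_size_leaf <- season_multiplier(doy - age_end + config$size_lag_days,
                                   config$size_amplitude)
  l_max <- config$leaf_length_max * s_size_leaf *
    exp(stats::rnorm(n_leaf, 0, config$leaf_length_cv))
  l_start <- ifelse(is_new, 0, l_max * (1 - exp(-age_mark / tau)))
  l_end <- ifelse(is_new,
                  l_max * (1 - exp(-age_end * s_grow / tau)),
                  l_start + (l_max - l_start) * (1 - exp(-dt * s_grow / tau)))
  increment <- l_end - l_start
  above <- pmin(increment, pmax(0, l_end - pmax(l_start, sheath)))

  if (exact) {
    m_mark <- rep(1, n_leaf); m_end <- rep(1, n_leaf); noise <- rep(1, n_leaf)
  } else {
    m_of <- function(a) config$maturity_max -
      (config$maturity_max - config$maturity_deficit) * exp(-a / config$maturity_tau)
    m_mark <- ifelse(is_new, 1, m_of(age_mark))
    m_end <- m_of(age_end)
    noise <- exp(stats::rnorm(n_leaf, 0, config$weight_noise_sigma))
  }

  bio_start <- pars$alpha * l_start^pars$beta
  bio_end <- pars$alpha * l_end^pars$beta
  bio_above <- pars$alpha * (l_end^pars$beta - (l_end - above)^pars$beta)

  w_start <- bio_start * m_mark * noise
  w_end <- bio_end * m_end * noise
  w_above <- bio_above * m_end * noise

  true_prod <- bio_end * m_end - bio_start * m_mark
  true_above <- bio_above * m_end

  # Ranks at retrieval: youngest (innermost) first.
  ord <- order(age_end)
  leaves <- data.frame(
    rank = seq_len(n_leaf),
    length_start = l_start[ord],
    length_end = l_end[ord],
    increment = increment[ord],
    increment_above_mark = above[ord],
    dry_weight_end = w_end[ord],
    dry_weight_start = w_start[ord],
    above_mark_weight = w_above[ord])

  list(leaves = leaves, n_new = n_new,
       true_production = sum(true_prod),
       true_below_mark = sum(true_prod - true_above))
}

#' True campaign-mean growth rate of a simulated campaign
#'
#' The exact in situ rate from the generator's ground-truth biomass
#' increments (no measurement noise): the reference against which all
#' estimator biases are measured.
#'
#' @param sim A `simulated_campaign` from [simulate_campaigns()].
#' @return Rate in g/day.
#' @export
true_campaign_rate <- function(sim) {
  if (!inherits(sim, "simulated_campaign")) {
    zg_stop_usage("`sim` must be a simulated_campaign")
  }
  sim$truth$lg_true
}

#' @export
print.simulated_campaign <- function(x, ...) {
  print(x$campaign)
  cat(sprintf("  truth: Lg = %.4g g/d, p = %.4g d\n",
              x$truth$lg_true, x$truth$p_true))
  invisible(x)
}

#' @export
print.simulated_season <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<simulated_season> %d campaigns (seed %d)\n",
              length(x), cfg$seed))
  invisible(x)
}
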