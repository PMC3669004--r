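# Season-level assembly: per-campaign rates, biases and audits for a whole
# marking study, and the method-agreement report comparing the three proxy
# methods against the in situ reference.

as_campaign_list <- function(campaigns) {
  if (inherits(campaigns, "simulated_season")) {
    return(lapply(campaigns, function(s) s$campaign))
  }
  if (inherits(campaigns, "campaign")) return(list(campaigns))
  if (is.list(campaigns) && length(campaigns)) {
    if (all(vapply(campaigns, inherits, logical(1), "simulated_campaign"))) {
      return(lapply(campaigns, function(s) s$campaign))
    }
    if (all(vapply(campaigns, inherits, logical(1), "campaign"))) {
      return(campaigns)
    }
  }
  zg_stop_usage("`campaigns` must be campaign objects or a simulated season")
}

#' Estimate rates, biases and identity audits for a whole season
#'
#' Runs [campaign_rates()], [campaign_bias()] and [identity_audit()] on
#' every campaign and collects the results in one table.
#'
#' @param campaigns A list of [campaign()] objects or a simulated season
#'   from [simulate_campaigns()].
#' @param params An [allometric_params()] object used for all allometric
#'   projections.
#' @param marking_mode Passed to [shoot_rate_marking()].
#' @return An object of class `growth_season`: `$table` (one row per
#'   campaign: date, delta_t, p, the four mean rates, the direct biases
#'   `bm`, `ba`, `bp`, the decomposition terms `cap`, `bap`, `bmp`, the
#'   plastochrone-bias bounds, and the identity residuals), plus the full
#'   `$rates`, `$biases`, `$audits` lists and the `params` used.
#' @export
estimate_season <- function(campaigns, params, marking_mode = "field") {
  camps <- as_campaign_list(campaigns)
  params <- as_allometric_params(params)
  rates <- lapply(camps, campaign_rates, params = params,
                  marking_mode = marking_mode)
  biases <- Map(function(cp, rt) campaign_bias(cp, params, rt), camps, rates)
  audits <- lapply(camps, identity_audit, params = params)

  table <- do.call(rbind, Map(function(rt, bs, au) {
    data.frame(
      date = rt$date, delta_t = rt$delta_t, p = rt$p,
      n_retrieved = rt$n_retrieved,
      lg = rt$lg, lgm = rt$lgm, lga = rt$lga, lgp = rt$lgp,
      bm = bs$bm, ba = bs$ba, bp = bs$bp,
      cap = bs$cap, bap = bs$bap, bmp = bs$bmp,
      blap = bs$blap, bp_upper = bs$bp_upper,
      bp_allometric = bs$bp_allometric,
      max_identity_residual = max(au$r_shoot, au$r_campaign,
                                  au$r_marking_shoot, au$r_marking_campaign,
                                  au$r_rsmp))
  }, rates, biases, audits))
  rownames(table) <- NULL

  structure(list(table = table, rates = rates, biases = biases,
                 audits = audits, params = params,
                 marking_mode = marking_mode),
            class = "growth_season")
}

#' @export
print.growth_season <- function(x, ...) {
  tb <- x$table
  cat(sprintf("<growth_season> %d campaigns, %s to %s\n",
              nrow(tb), format(min(tb$date)), format(max(tb$date))))
  cat(sprintf("  mean rates (g/d): Lg = %s, Lgm = %.4g, Lga = %.4g, Lgp = %.4g\n",
              fmt_or_na(mean(tb$lg)), mean(tb$lgm), mean(tb$lga), mean(tb$lgp)))
  cat(sprintf("  max identity residual: %.3e g/d\n",
              max(tb$max_identity_residual)))
  invisible(x)
}

#' Method-agreement report for a season
#'
#' The per-method agreement table comparing the three proxies against the in
#' situ reference: per-method RMSE, Lin's concordance correlation with its
#' 95% confidence interval, the regression of the in situ rate on each
#' proxy through the origin (with the companion with-intercept fit for the
#' plastochrone case, where a proportional fit is typically poor), the
#' fraction of campaigns in which the bias ordering `Bm < Ba < Bp` holds,
#' and the rate time series.
#'
#' @param season A [estimate_season()] result (needs >= 3 campaigns with an
#'   observable in situ rate).
#' @return An object of class `agreement_report`: `$statistics` (one row
#'   per method), `$regressions`, `$bias_ordering`, `$series`.
#' @export
method_comparison_report <- function(season) {
  if (!inherits(season, "growth_season")) {
    zg_stop_usage("`season` must be a growth_season from estimate_season()")
  }
  tb <- season$table
  ok <- !is.na(tb$lg)
  if (sum(ok) < 3L) {
    zg_stop_domain(paste(
      "agreement statistics need at least 3 campaigns with an observable",
      "in situ rate"))
  }
  tb <- tb[ok, , drop = FALSE]
  methods <- c(marking = "lgm", allometric = "lga", plastochrone = "lgp")

  stats_rows <- lapply(names(methods), function(m) {
    proxy <- tb[[methods[[m]]]]
    cc <- lin_ccc(tb$lg, proxy)
    data.frame(method = m,
               rmse = rmse(tb$lg, proxy),
               rho_c = cc$rho_c,
               ci_lower = cc$ci_lower, ci_upper = cc$ci_upper,
               mean_bias = mean(tb$lg - proxy))
  })
  statistics <- do.call(rbind, stats_rows)

  regressions <- lapply(names(methods), function(m) {
    reg <- regression_through_origin(tb[[methods[[m]]]], tb$lg)
    c(list(method = m), reg)
  })
  names(regressions) <- names(methods)

  ordering <- mean(tb$bm < tb$ba & tb$ba < tb$bp)

  structure(
    list(statistics = statistics,
         regressions = regressions,
         bias_ordering = list(
           fraction_bm_lt_ba_lt_bp = ordering,
           fraction_bp_positive = mean(tb$bp > 0),
           fraction_ba_positive = mean(tb$ba > 0),
           fraction_bm_positive = mean(tb$bm > 0)),
         series = tb[, c("date", "delta_t", "p", "lg", "lgm", "lga", "lgp",
                         "bm", "ba", "bp")],
         n_campaigns = nrow(tb)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d campaigns\n", x$n_campaigns))
  st <- x$statistics
  for (i in seq_len(nrow(st))) {
    reg <- x$regressions[[st$method[i]]]
    cat(sprintf(
      "  %-12s RMSE = %.6g, rho_c = %.4f (%.4f, %.4f), origin slope = %.3f (r2 = %.2f)\n",
      st$method[i], st$rmse[i], st$rho_c[i], st$ci_lower[i], st$ci_upper[i],
      reg$slope, reg$r_squared))
  }
  cat(sprintf("  Bm < Ba < Bp in %.0f%% of campaigns; Bp > 0 in %.0f%%\n",
              100 * x$bias_ordering$fraction_bm_lt_ba_lt_bp,
              100 * x$bias_ordering$fraction_bp_positive))
  invisible(x)
}

#' Plot the rate time series of a season
#'
#' Base-graphics comparison of the in situ rate and the three proxies
#' across campaigns (the classical four-line seasonal figure).
#'
#' @param x A `growth_season`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.growth_season <- function(x, ...) {
  tb <- x$table
  y <- as.matrix(tb[, c("lg", "lgm", "lga", "lgp")])
  graphics::matplot(tb$date, y, type = "l", lty = 1:4, col = 1:4,
                    xlab = "retrieval date", ylab = "leaf growth rate (g/d)",
                    ...)
  graphics::legend("topleft", legend = c("in situ", "marking", "allometric",
                                         "plastochrone"),
                   lty = 1:4, col = 1:4, bty = "n")
  invisible(x)
}
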