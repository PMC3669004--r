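# Shoot- and campaign-level containers and the four leaf growth-rate
# estimators: in situ, allometric projection, leaf marking, plastochrone.

leaf_columns <- c("rank", "length_start", "length_end", "increment",
                  "increment_above_mark", "dry_weight_end",
                  "dry_weight_start", "above_mark_weight")

# Normalize a collection of leaves to the canonical data frame.
as_leaf_frame <- function(leaves) {
  if (is.data.frame(leaves)) {
    df <- leaves
  } else if (is.list(leaves)) {
    df <- do.call(rbind, lapply(leaves, function(lf) {
      lf <- as_leaf_fields(lf)
      as.data.frame(lf[intersect(names(lf), leaf_columns)])
    }))
  } else {
    zg_stop_usage("`leaves` must be a data frame or a list of leaf observations")
  }
  for (col in c("increment")) {
    if (is.null(df[[col]])) df[[col]] <- df$length_end - df$length_start
  }
  if (is.null(df$increment_above_mark)) df$increment_above_mark <- df$increment
  for (col in c("dry_weight_end", "dry_weight_start", "above_mark_weight")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  missing <- setdiff(c("rank", "length_start", "length_end"), names(df))
  if (length(missing)) {
    zg_stop_usage(paste0("leaves lack required fields: ",
                         paste(missing, collapse = ", ")))
  }
  df <- df[order(df$rank), leaf_columns, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' The leaves of one retrieved shoot
#'
#' Bundles the `n(s)` leaf observations of a single shoot.  Ranks must be
#' unique and contiguous from 1 (1 = youngest, innermost leaf).
#'
#' @param shoot_id Identifier (character or integer).
#' @param leaves A list of [leaf_observation()] objects or a data frame with
#'   their fields as columns.
#' @return An object of class `shoot_sample`.
#' @examples
#' shoot_sample("s1", list(
#'   leaf_observation(1, 50, 120, dry_weight_end = 0.010),
#'   leaf_observation(2, 200, 250, dry_weight_end = 0.025),
#'   leaf_observation(3, 300, 330, dry_weight_end = 0.038)))
#' @export
shoot_sample <- function(shoot_id, leaves) {
  df <- as_leaf_frame(leaves)
  n <- nrow(df)
  if (n < 1L) zg_stop_domain("a shoot must hold at least one leaf")
  if (!identical(as.integer(sort(df$rank)), seq_len(n))) {
    zg_stop_domain(sprintf(
      "leaf ranks of shoot %s must be unique and contiguous from 1",
      as.character(shoot_id)))
  }
  check_increment_pair(df$increment, df$length_end)
  if (any(abs(df$increment - (df$length_end - df$length_start)) > 1e-9)) {
    zg_stop_domain("increment must equal length_end - length_start")
  }
  if (any(df$increment_above_mark < -1e-12) ||
      any(df$increment_above_mark > df$increment + 1e-9)) {
    zg_stop_domain("increment_above_mark must lie in [0, increment]")
  }
  structure(list(shoot_id = shoot_id, leaves = df), class = "shoot_sample")
}

#' @export
print.shoot_sample <- function(x, ...) {
  cat(sprintf("<shoot_sample> %s: %d leaves, total increment %g mm\n",
              as.character(x$shoot_id), nrow(x$leaves), sum(x$leaves$increment)))
  invisible(x)
}

#' All shoots retrieved at one sampling date
#'
#' A marking campaign: the shoots retrieved at `date` after a marking
#' interval of `delta_t` days, together with the marked-shoot count and the
#' number of new leaves that appeared (the inputs of the plastochrone
#' interval), and optionally the plastochrone interval itself.
#'
#' @param date Retrieval date (`Date` or ISO 8601 string).
#' @param delta_t Interval length in days (> 0).
#' @param shoots List of [shoot_sample()] objects.
#' @param n_marked Number of shoots marked at the start of the interval;
#'   must be >= the number retrieved.
#' @param new_leaves Number of new leaves that appeared on the scored shoots
#'   over the interval.
#' @param p Optional plastochrone interval (days); computed from
#'   `new_leaves` via [plastochrone_interval()] when missing.
#' @return An object of class `campaign`.
#' @export
campaign <- function(date, delta_t, shoots, n_marked = length(shoots),
                     new_leaves = NA_integer_, p = NULL) {
  date <- as.Date(date)
  zg_check_number(delta_t, "delta_t", 0, strict = TRUE)
  if (!is.list(shoots) || !length(shoots) ||
      !all(vapply(shoots, inherits, logical(1), "shoot_sample"))) {
    zg_stop_usage("`shoots` must be a non-empty list of shoot_sample objects")
  }
  n_retrieved <- length(shoots)
  if (n_marked < n_retrieved) {
    zg_stop_domain("n_marked cannot be smaller than the number retrieved")
  }
  if (!is.na(new_leaves) && new_leaves < 0) {
    zg_stop_domain("new_leaves must be >= 0")
  }
  if (!is.null(p)) zg_check_number(p, "p", 0, strict = TRUE)
  structure(
    list(date = date, delta_t = delta_t, shoots = shoots,
         n_retrieved = n_retrieved, n_marked = n_marked,
         new_leaves = new_leaves, p = p),
    class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf(
    "<campaign> %s: %d/%d shoots retrieved, delta_t = %g d, new leaves = %s, p = %s d\n",
    format(x$date), x$n_retrieved, x$n_marked, x$delta_t,
    ifelse(is.na(x$new_leaves), "?", x$new_leaves),
    if (is.null(x$p)) "?" else format(signif(x$p, 4))))
  invisible(x)
}

# Plastochrone interval of a campaign: stored value if set, else Jacobs'
# ratio from the leaf-appearance count.
campaign_p <- function(camp) {
  if (!is.null(camp$p)) return(camp$p)
  if (is.na(camp$new_leaves)) {
    zg_stop_usage("campaign has neither `p` nor a new-leaf count to compute it")
  }
  plastochrone_interval(camp$n_retrieved, camp$new_leaves, camp$delta_t)
}

#' In situ shoot leaf growth rate
#'
#' The reference rate: the summed dry-weight gain of all leaves on the
#' shoot divided by the interval length.  Requires start weights, which
#' field data (destructive at retrieval only) do not carry; in that case
#' the allometric surrogate [shoot_rate_allometric()] is the estimator to
#' use, and this function fails with an explicit error.
#'
#' @param shoot A [shoot_sample()].
#' @param delta_t Interval length, days.
#' @return Rate in g/day.
#' @export
shoot_rate_in_situ <- function(shoot, delta_t) {
  zg_check_number(delta_t, "delta_t", 0, strict = TRUE)
  lv <- shoot$leaves
  if (any(is.na(lv$dry_weight_start)) || any(is.na(lv$dry_weight_end))) {
    zg_stop(paste(
      "in situ rate is unobservable without start dry weights;",
      "use the allometric surrogate shoot_rate_allometric()"),
      "zg_unobservable_error")
  }
  sum(lv$dry_weight_end - lv$dry_weight_start) / delta_t
}

#' Allometric shoot leaf growth rate
#'
#' Projects the shoot's leaf biomass gain from leaf lengths through the
#' allometric law and divides by the interval: the surrogate of the in situ
#' rate available from non-destructive length records.
#'
#' @inheritParams shoot_rate_in_situ
#' @param params An [allometric_params()] object.
#' @return Rate in g/day.
#' @export
shoot_rate_allometric <- function(shoot, params, delta_t) {
  zg_check_number(delta_t, "delta_t", 0, strict = TRUE)
  params <- as_allometric_params(params)
  lv <- shoot$leaves
  check_increment_pair(lv$increment, lv$length_end)
  sum(ab_increment(lv$length_start, lv$length_end, params)) / delta_t
}

#' Leaf-marking shoot growth rate
#'
#' Two variants of the classical marking estimator:
#'
#' * `mode = "formal"`: the allometric biomass of each leaf's full length
#'   increment, `sum(alpha * increment^beta) / delta_t` — the new-tissue
#'   component of growth, ignoring maturation and the mark position.
#' * `mode = "field"`: what the field protocol measures — production above
#'   the reference mark only.  When the excised above-mark tissue was
#'   weighed (`above_mark_weight` present on every leaf) those measured
#'   weights are used, mirroring the protocol in which new growth between
#'   the reference frame and the staple is cut out and weighed; otherwise
#'   the above-mark production is projected allometrically as
#'   `biomass(length_end) - biomass(length_end - increment_above_mark)`.
#'
#' @inheritParams shoot_rate_allometric
#' @param mode `"formal"` or `"field"`.
#' @return Rate in g/day.
#' @export
shoot_rate_marking <- function(shoot, params, delta_t,
                               mode = c("field", "formal")) {
  if (!is.character(mode) || !all(mode %in% c("field", "formal"))) {
    zg_stop_usage('`mode` must be "field" or "formal"')
  }
  mode <- match.arg(mode)
  zg_check_number(delta_t, "delta_t", 0, strict = TRUE)
  params <- as_allometric_params(params)
  lv <- shoot$leaves
  if (mode == "formal") {
    return(sum(params$alpha * lv$increment^params$beta) / delta_t)
  }
  if (!any(is.na(lv$above_mark_weight))) {
    return(sum(lv$above_mark_weight) / delta_t)
  }
  above <- ab_increment(lv$length_end - lv$increment_above_mark,
                        lv$length_end, params)
  sum(above) / delta_t
}

#' Plastochrone interval from leaf-appearance counts
#'
#' Jacobs' ratio: the mean number of days per new leaf per shoot,
#' `(n_shoots * delta_t) / new_leaves`.
#'
#' @param n_marked Number of shoots scored for new leaves.
#' @param new_leaves Total new leaves that appeared on them over the
#'   interval; must be > 0 for the interval to be defined.
#' @param delta_t Interval length, days.
#' @return Plastochrone interval in days.
#' @examples
#' plastochrone_interval(40, 40, 14)  # one leaf per shoot per interval
#' @export
plastochrone_interval <- function(n_marked, new_leaves, delta_t) {
  zg_check_number(n_marked, "n_marked", 0, strict = TRUE)
  zg_check_number(delta_t, "delta_t", 0, strict = TRUE)
  zg_check_number(new_leaves, "new_leaves", 0)
  if (new_leaves == 0) {
    zg_stop(paste(
      "plastochrone interval is undefined: no leaf appearance was observed"),
      "zg_undefined_interval_error")
  }
  (n_marked * delta_t) / new_leaves
}

#' Plastochrone shoot growth rate
#'
#' The third-leaf convention: the dry weight of the leaf of rank 3 on the
#' retrieved shoot divided by the plastochrone interval.  Shoots lacking a
#' rank-3 leaf cannot contribute and raise a skip-shoot condition, which
#' [campaign_rates()] catches (the shoot is excluded from the campaign mean
#' and counted).
#'
#' @param shoot A [shoot_sample()].
#' @param p Plastochrone interval, days.
#' @return Rate in g/day.
#' @export
shoot_rate_plastochrone <- function(shoot, p) {
  zg_check_number(p, "p", 0, strict = TRUE)
  lv <- shoot$leaves
  i <- which(lv$rank == 3L)
  if (!length(i)) {
    zg_stop_skip(sprintf("shoot %s has no rank-3 leaf; excluded from plastochrone mean",
                         as.character(shoot$shoot_id)))
  }
  w3 <- lv$dry_weight_end[i]
  if (is.na(w3)) {
    zg_stop_skip(sprintf("shoot %s has no retrieval weight for its rank-3 leaf",
                         as.character(shoot$shoot_id)))
  }
  w3 / p
}

#' Campaign-mean growth rates for all four methods
#'
#' Computes the per-shoot rate vectors and their campaign means for the in
#' situ, leaf-marking, allometric, and plastochrone estimators.  Each mean
#' divides by the number of shoots actually contributing to that method:
#' shoots without a rank-3 leaf are excluded from the plastochrone mean
#' (their count is reported), and the in situ mean is `NA` when start
#' weights are unavailable.
#'
#' @param camp A [campaign()].
#' @param params An [allometric_params()] object.
#' @param marking_mode Passed to [shoot_rate_marking()].
#' @return An object of class `campaign_rates`: means `lg`, `lgm`, `lga`,
#'   `lgp`, the per-shoot vectors in `$shoots`, the plastochrone interval
#'   `p` used, and the number of shoots excluded from the plastochrone
#'   mean.
#' @export
campaign_rates <- function(camp, params, marking_mode = "field") {
  if (!inherits(camp, "campaign")) zg_stop_usage("`camp` must be a campaign")
  if (camp$n_retrieved == 0L) zg_stop_domain("empty campaign: no shoots retrieved")
  params <- as_allometric_params(params)
  p <- campaign_p(camp)

  lga_s <- vapply(camp$shoots, shoot_rate_allometric, numeric(1),
                  params = params, delta_t = camp$delta_t)
  lgm_s <- vapply(camp$shoots, shoot_rate_marking, numeric(1),
                  params = params, delta_t = camp$delta_t, mode = marking_mode)
  lg_s <- vapply(camp$shoots, function(s) {
    tryCatch(shoot_rate_in_situ(s, camp$delta_t),
             zg_unobservable_error = function(e) NA_real_)
  }, numeric(1))
  lgp_s <- vapply(camp$shoots, function(s) {
    tryCatch(shoot_rate_plastochrone(s, p),
             zg_skip_shoot = function(e) NA_real_)
  }, numeric(1))
  n_skipped <- sum(is.na(lgp_s))
  if (all(is.na(lgp_s))) {
    zg_stop_domain("no shoot in the campaign carries a usable rank-3 leaf")
  }

  structure(
    list(date = camp$date, delta_t = camp$delta_t, p = p,
         n_retrieved = camp$n_retrieved,
         lg = if (all(is.na(lg_s))) NA_real_ else mean(lg_s, na.rm = TRUE),
         lgm = mean(lgm_s), lga = mean(lga_s),
         lgp = mean(lgp_s, na.rm = TRUE),
         shoots = data.frame(
           shoot_id = vapply(camp$shoots, function(s) as.character(s$shoot_id),
                             character(1)),
           lg = lg_s, lgm = lgm_s, lga = lga_s, lgp = lgp_s),
         n_skipped_plastochrone = n_skipped,
         marking_mode = marking_mode),
    class = "campaign_rates")
}

#' @export
print.campaign_rates <- function(x, ...) {
  cat(sprintf(
    "<campaign_rates> %s (N = %d, p = %.3g d)\n  Lg  = %s g/d\n  Lgm = %.4g g/d\n  Lga = %.4g g/d\n  Lgp = %.4g g/d%s\n",
    format(x$date), x$n_retrieved, x$p,
    if (is.na(x$lg)) "unobservable" else sprintf("%.4g", x$lg),
    x$lgm, x$lga, x$lgp,
    if (x$n_skipped_plastochrone > 0)
      sprintf("  (%d shoots without rank-3 leaf excluded)",
              x$n_skipped_plastochrone) else ""))
  invisible(x)
}
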