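# CSV input/output for campaign-structured leaf records, YAML run
# configuration, and fixture export for the simulator.
#
# Leaf table schema (one row per leaf; headers carry unit suffixes and are
# required verbatim — no silent unit coercion):
#   campaign_date, delta_t_days, shoot_id, leaf_rank, length_start_mm,
#   length_end_mm, increment_mm, increment_above_mark_mm, dry_weight_end_g
# optional: dry_weight_start_g, above_mark_weight_g
# Campaign sidecar (one row per campaign):
#   campaign_date, delta_t_days, n_marked, new_leaves

leaf_table_required <- c("campaign_date", "delta_t_days", "shoot_id",
                         "leaf_rank", "length_start_mm", "length_end_mm",
                         "increment_mm", "increment_above_mark_mm",
                         "dry_weight_end_g")
leaf_table_optional <- c("dry_weight_start_g", "above_mark_weight_g")

#' Read campaign-structured leaf records from CSV
#'
#' Parses and validates a leaf table (plus optional campaign sidecar) into
#' a list of [campaign()] objects, campaigns ordered by date.  Violations
#' (missing columns, duplicate `(campaign_date, shoot_id, leaf_rank)` keys,
#' increments inconsistent with the length difference beyond 1e-9 mm) are
#' reported with the offending row numbers.
#'
#' @param path Path to the leaf table CSV.
#' @param campaigns_path Optional path to the campaign sidecar CSV carrying
#'   `n_marked` and `new_leaves`; without it the marked count defaults to
#'   the retrieved count and the plastochrone interval cannot be computed
#'   from leaf-appearance data.
#' @return A list of [campaign()] objects (empty, with a warning, for a
#'   header-only file).
#' @export
read_leaf_table <- function(path, campaigns_path = NULL) {
  if (!file.exists(path)) zg_stop_usage(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(leaf_table_required, names(df))
  if (length(missing)) {
    zg_stop_usage(sprintf("leaf table %s lacks required column(s): %s",
                          path, paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(leaf_table_required, leaf_table_optional))
  if (length(unknown)) {
    zg_stop_usage(sprintf(
      "leaf table %s has unrecognized column(s): %s (unit-suffixed headers are required)",
      path, paste(unknown, collapse = ", ")))
  }
  if (!nrow(df)) {
    warning(sprintf("leaf table %s is empty; returning no campaigns", path))
    return(list())
  }
  for (col in leaf_table_optional) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }

  bad <- which(abs(df$increment_mm -
                     (df$length_end_mm - df$length_start_mm)) > 1e-9)
  if (length(bad)) {
    zg_stop_domain(sprintf(
      "increment_mm != length_end_mm - length_start_mm in row(s): %s",
      paste(utils::head(bad, 20), collapse = ", ")))
  }
  key <- paste(df$campaign_date, df$shoot_id, df$leaf_rank)
  if (anyDuplicated(key)) {
    zg_stop_domain(sprintf(
      "duplicate (campaign_date, shoot_id, leaf_rank) key in row(s): %s",
      paste(utils::head(which(duplicated(key)), 20), collapse = ", ")))
  }

  sidecar <- NULL
  if (!is.null(campaigns_path)) {
    if (!file.exists(campaigns_path)) {
      zg_stop_usage(sprintf("no such file: %s", campaigns_path))
    }
    sidecar <- utils::read.csv(campaigns_path, stringsAsFactors = FALSE)
    need <- c("campaign_date", "delta_t_days", "n_marked", "new_leaves")
    if (length(setdiff(need, names(sidecar)))) {
      zg_stop_usage(sprintf("campaign sidecar %s needs columns: %s",
                            campaigns_path, paste(need, collapse = ", ")))
    }
  }

  dates <- sort(unique(df$campaign_date))
  lapply(dates, function(d) {
    sub <- df[df$campaign_date == d, , drop = FALSE]
    dt <- unique(sub$delta_t_days)
    if (length(dt) != 1L) {
      zg_stop_domain(sprintf("campaign %s has inconsistent delta_t_days", d))
    }
    shoots <- lapply(split(sub, sub$shoot_id), function(ss) {
      shoot_sample(ss$shoot_id[1], data.frame(
        rank = ss$leaf_rank,
        length_start = ss$length_start_mm,
        length_end = ss$length_end_mm,
        increment = ss$increment_mm,
        increment_above_mark = ss$increment_above_mark_mm,
        dry_weight_end = ss$dry_weight_end_g,
        dry_weight_start = ss$dry_weight_start_g,
        above_mark_weight = ss$above_mark_weight_g))
    })
    shoots <- shoots[order(names(shoots))]
    n_marked <- length(shoots)
    new_leaves <- NA_integer_
    if (!is.null(sidecar)) {
      row <- sidecar[sidecar$campaign_date == d, , drop = FALSE]
      if (nrow(row) == 1L) {
        n_marked <- row$n_marked
        new_leaves <- row$new_leaves
      }
    }
    p <- if (!is.na(new_leaves) && new_leaves > 0) {
      plastochrone_interval(length(shoots), new_leaves, dt)
    } else NULL
    campaign(date = d, delta_t = dt, shoots = unname(shoots),
             n_marked = n_marked, new_leaves = new_leaves, p = p)
  })
}

#' Write campaigns to the CSV leaf-table schema
#'
#' @param campaigns List of [campaign()] objects or a simulated season.
#' @param path Output path of the leaf table CSV.
#' @param campaigns_path Optional output path of the campaign sidecar.
#' @return Invisibly, the path(s) written.
#' @export
write_leaf_table <- function(campaigns, path, campaigns_path = NULL) {
  camps <- if (length(campaigns)) as_campaign_list(campaigns) else list()
  rows <- lapply(camps, function(cp) {
    do.call(rbind, lapply(cp$shoots, function(s) {
      lv <- s$leaves
      data.frame(
        campaign_date = format(cp$date),
        delta_t_days = cp$delta_t,
        shoot_id = as.character(s$shoot_id),
        leaf_rank = lv$rank,
        length_start_mm = lv$length_start,
        length_end_mm = lv$length_end,
        increment_mm = lv$increment,
        increment_above_mark_mm = lv$increment_above_mark,
        dry_weight_end_g = lv$dry_weight_end,
        dry_weight_start_g = lv$dry_weight_start,
        above_mark_weight_g = lv$above_mark_weight)
    }))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(c(leaf_table_required, leaf_table_optional))),
      c(leaf_table_required, leaf_table_optional)))
  write_csv_full_precision(df, path)

  paths <- path
  if (!is.null(campaigns_path)) {
    side <- if (length(camps)) do.call(rbind, lapply(camps, function(cp) {
      data.frame(campaign_date = format(cp$date),
                 delta_t_days = cp$delta_t,
                 n_marked = cp$n_marked,
                 new_leaves = cp$new_leaves)
    })) else data.frame(campaign_date = character(0), delta_t_days = numeric(0),
                        n_marked = integer(0), new_leaves = integer(0))
    write_csv_full_precision(side, campaigns_path)
    paths <- c(paths, campaigns_path)
  }
  invisible(paths)
}

# CSV writer preserving doubles to full precision (17 significant digits),
# so that write -> read round-trips are value-identical.
write_csv_full_precision <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    zg_stop_usage(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Export simulated campaigns as CSV fixtures
#'
#' Writes the leaf table, the campaign sidecar, and a ground-truth sidecar
#' (per-campaign true rate and plastochrone interval, per-shoot true
#' production) under `dir`.  The files round-trip losslessly through
#' [read_leaf_table()].
#'
#' @param sims A simulated season from [simulate_campaigns()] (or a plain
#'   list of campaigns, in which case no truth sidecar is written).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
export_fixtures <- function(sims, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) zg_stop_usage(sprintf("cannot create directory %s", dir))
  leaf_path <- file.path(dir, "leaves.csv")
  camp_path <- file.path(dir, "campaigns.csv")
  write_leaf_table(sims, leaf_path, camp_path)
  paths <- c(leaves = leaf_path, campaigns = camp_path)

  has_truth <- length(sims) &&
    all(vapply(sims, inherits, logical(1), "simulated_campaign"))
  if (has_truth) {
    truth <- do.call(rbind, lapply(sims, function(s) {
      data.frame(campaign_date = format(s$campaign$date),
                 p_true_days = s$truth$p_true,
                 lg_true_g_per_day = s$truth$lg_true)
    }))
    truth_path <- file.path(dir, "truth.csv")
    write_csv_full_precision(truth, truth_path)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

config_run_keys <- c("alpha", "beta", "fit_allometry", "marking_mode")

#' Load a YAML run configuration
#'
#' A flat key/value YAML file holding any [simulation_config()] field plus
#' the run options `alpha`, `beta` (the analysis parameters; default the
#' conventional 2e-5 and 1.3), `fit_allometry` (fit alpha/beta from the
#' data instead of using the fixed values; default `FALSE`) and
#' `marking_mode`.  Unknown keys are rejected by name; an empty (or
#' missing) file yields all defaults.
#'
#' @param path Path to the YAML file, or `NULL` for pure defaults.
#' @return A list with `$sim` (a [simulation_config()]) and `$run` (the run
#'   options).
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) zg_stop_usage(sprintf("no such file: %s", path))
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    if (!is.list(vals)) zg_stop_usage("config must be a YAML mapping")
  }
  sim_keys <- setdiff(names(formals(simulation_config)), "")
  unknown <- setdiff(names(vals), c(sim_keys, config_run_keys))
  if (length(unknown)) {
    zg_stop_usage(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  sim_vals <- vals[intersect(names(vals), sim_keys)]
  if (!is.null(sim_vals$leaves_per_shoot)) {
    sim_vals$leaves_per_shoot <- as.numeric(sim_vals$leaves_per_shoot)
  }
  if (!is.null(sim_vals$plastochrone_days)) {
    sim_vals$plastochrone_days <- as.numeric(sim_vals$plastochrone_days)
  }
  if (!is.null(sim_vals$true_params)) {
    sim_vals$true_params <- as_allometric_params(sim_vals$true_params)
  }
  sim <- tryCatch(do.call(simulation_config, sim_vals), error = function(e) {
    zg_stop_usage(sprintf("invalid config value: %s", conditionMessage(e)))
  })

  run <- list(alpha = 2e-5, beta = 1.3, fit_allometry = FALSE,
              marking_mode = "field")
  for (k in intersect(names(vals), config_run_keys)) run[[k]] <- vals[[k]]
  if (!is.logical(run$fit_allometry) || length(run$fit_allometry) != 1L) {
    zg_stop_usage("config key `fit_allometry` must be a single logical")
  }
  if (!run$marking_mode %in% c("field", "formal")) {
    zg_stop_usage('config key `marking_mode` must be "field" or "formal"')
  }
  zg_check_number(run$alpha, "alpha", 0, strict = TRUE)
  zg_check_number(run$beta, "beta", 0, strict = TRUE)
  list(sim = sim, run = run)
}
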