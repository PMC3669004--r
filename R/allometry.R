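# Leaf-level allometric machinery.
#
# Eelgrass leaf dry weight scales with leaf length as a power law
# w = alpha * l^beta (lengths in millimetres, weights in grams).  All
# growth-rate projections in the package are built from this law, its
# increment form alpha * l_end^beta * delta, and the split of an increment
# into new-tissue and maturation components.

#' Allometric parameters of the leaf length-to-weight power law
#'
#' Container for the normalization constant `alpha` and scaling exponent
#' `beta` of the leaf allometry `w = alpha * l^beta`, with `l` in
#' millimetres and `w` in grams dry weight.
#'
#' @param alpha Normalization constant, grams per millimetre^beta; must be
#'   positive.  For eelgrass leaf data in millimetres and grams,
#'   values near `2e-5` are typical.
#' @param beta Dimensionless scaling exponent; must be positive, and is
#'   slightly above 1 for eelgrass leaves (leaves thicken as they lengthen).
#' @return An object of class `allometric_params`.
#' @examples
#' allometric_params(2e-5, 1.3)
#' @export
allometric_params <- function(alpha, beta) {
  zg_check_number(alpha, "alpha", 0, strict = TRUE)
  zg_check_number(beta, "beta", 0, strict = TRUE)
  structure(list(alpha = alpha, beta = beta), class = "allometric_params")
}

#' @export
print.allometric_params <- function(x, ...) {
  cat(sprintf("<allometric_params> w = %g * l^%g  (l in mm, w in g)\n",
              x$alpha, x$beta))
  invisible(x)
}

as_allometric_params <- function(x) {
  if (inherits(x, "allometric_params")) return(x)
  if (is.list(x) && all(c("alpha", "beta") %in% names(x))) {
    return(allometric_params(x$alpha, x$beta))
  }
  if (is.numeric(x) && length(x) == 2L) {
    return(allometric_params(x[[1L]], x[[2L]]))
  }
  zg_stop_usage("cannot interpret `params` as allometric parameters")
}

#' One leaf on one retrieved shoot
#'
#' Validated record of a single leaf observed over a marking interval
#' `[t, t + delta_t]`: its rank on the shoot (1 = youngest, innermost),
#' lengths at marking and retrieval, the length increment and its portion
#' above the reference mark, and dry weights.  The start weight and the
#' measured dry weight of above-mark new tissue are optional: field data are
#' destructive at retrieval only, so start weights exist only for simulated
#' data, while the above-mark tissue weight exists when the new-growth piece
#' was excised and weighed (the classical marking protocol).
#'
#' @param rank Integer leaf position, 1 = youngest.
#' @param length_start,length_end Leaf length (mm) at marking and retrieval.
#' @param increment Length increment (mm) over the interval; defaults to
#'   `length_end - length_start` and must equal it when supplied.
#' @param increment_above_mark Portion of `increment` above the reference
#'   mark (mm); defaults to `increment`.
#' @param dry_weight_end Dry weight (g) at retrieval.
#' @param dry_weight_start Optional dry weight (g) at marking.
#' @param above_mark_weight Optional measured dry weight (g) of the new
#'   tissue produced above the mark.
#' @return An object of class `leaf_observation` (a named list).
#' @examples
#' leaf_observation(rank = 3, length_start = 80, length_end = 100,
#'                  dry_weight_end = 0.008)
#' @export
leaf_observation <- function(rank, length_start, length_end,
                             increment = NULL,
                             increment_above_mark = NULL,
                             dry_weight_end = NA_real_,
                             dry_weight_start = NA_real_,
                             above_mark_weight = NA_real_) {
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1 ||
      rank != as.integer(rank)) {
    zg_stop_usage("`rank` must be a positive integer")
  }
  zg_check_number(length_start, "length_start", 0)
  zg_check_number(length_end, "length_end", 0)
  if (is.null(increment)) increment <- length_end - length_start
  zg_check_number(increment, "increment", 0)
  if (abs(increment - (length_end - length_start)) > 1e-9) {
    zg_stop_domain(sprintf(
      "increment (%g) must equal length_end - length_start (%g)",
      increment, length_end - length_start))
  }
  if (increment > length_end + 1e-12) {
    zg_stop_domain("increment cannot exceed length_end")
  }
  if (is.null(increment_above_mark)) increment_above_mark <- increment
  zg_check_number(increment_above_mark, "increment_above_mark", 0)
  if (increment_above_mark > increment + 1e-9) {
    zg_stop_domain("increment_above_mark cannot exceed increment")
  }
  for (w in c(dry_weight_end = dry_weight_end,
              dry_weight_start = dry_weight_start,
              above_mark_weight = above_mark_weight)) {
    if (!is.na(w) && w < 0) zg_stop_domain("dry weights must be >= 0")
  }
  structure(
    list(rank = as.integer(rank),
         length_start = length_start,
         length_end = length_end,
         increment = increment,
         increment_above_mark = increment_above_mark,
         dry_weight_end = dry_weight_end,
         dry_weight_start = dry_weight_start,
         above_mark_weight = above_mark_weight),
    class = "leaf_observation")
}

#' @export
print.leaf_observation <- function(x, ...) {
  cat(sprintf(
    "<leaf_observation> rank %d: %g -> %g mm (+%g, %g above mark), w_end = %g g\n",
    x$rank, x$length_start, x$length_end, x$increment,
    x$increment_above_mark, x$dry_weight_end))
  invisible(x)
}

# Accept a leaf_observation, a one-row data frame, or a plain named list.
as_leaf_fields <- function(leaf) {
  if (inherits(leaf, "leaf_observation")) return(leaf)
  if (is.data.frame(leaf) && nrow(leaf) == 1L) leaf <- as.list(leaf)
  if (is.list(leaf) &&
      all(c("length_start", "length_end") %in% names(leaf))) {
    if (is.null(leaf$increment)) {
      leaf$increment <- leaf$length_end - leaf$length_start
    }
    return(leaf)
  }
  zg_stop_usage("`leaf` must be a leaf_observation (or equivalent record)")
}

#' Leaf biomass from length through the allometric law
#'
#' @param length Leaf length (mm); vectorized, all values must be >= 0.
#' @param params An [allometric_params()] object.
#' @return Dry weight(s) in grams, `alpha * length^beta`.
#' @examples
#' leaf_biomass(100, allometric_params(2e-5, 1.3))
#' @export
leaf_biomass <- function(length, params) {
  params <- as_allometric_params(params)
  if (any(!is.finite(length)) || any(length < 0)) {
    zg_stop_domain("`length` must be finite and >= 0")
  }
  params$alpha * length^params$beta
}

#' Fraction of final allometric biomass gained over the interval
#'
#' The delta factor `1 - (1 - increment / length_end)^beta` converts a
#' leaf's final allometric biomass into its biomass increment: growing
#' `increment` mm out of a final `length_end` mm means a fraction `delta`
#' of the final biomass `alpha * length_end^beta` was gained over the
#' interval.  Always lies in `[0, 1]`.
#'
#' @param increment Length increment (mm), `0 <= increment <= length_end`.
#' @param length_end Leaf length at the end of the interval (mm).
#' @param beta Scaling exponent of the allometric law.
#' @return The dimensionless factor, vectorized over the inputs.
#' @examples
#' delta_factor(20, 100, 1.3)  # 1 - 0.8^1.3
#' @export
delta_factor <- function(increment, length_end, beta) {
  zg_check_number(beta, "beta", 0, strict = TRUE)
  check_increment_pair(increment, length_end)
  lam <- lambda_raw(increment, length_end)
  1 - (1 - lam)^beta
}

#' Length-increment to final-length ratio
#'
#' `lambda = increment / length_end`, the proportion of the leaf's final
#' length that is new; `0` for an empty leaf (`length_end = 0` with zero
#' increment, the empty-leaf convention).
#'
#' @inheritParams delta_factor
#' @return Dimensionless ratio in `[0, 1]`, vectorized.
#' @export
lambda_ratio <- function(increment, length_end) {
  check_increment_pair(increment, length_end)
  lambda_raw(increment, length_end)
}

check_increment_pair <- function(increment, length_end) {
  if (any(!is.finite(increment)) || any(!is.finite(length_end))) {
    zg_stop_domain("`increment` and `length_end` must be finite")
  }
  if (any(increment < 0)) zg_stop_domain("`increment` must be >= 0")
  if (any(length_end < 0)) zg_stop_domain("`length_end` must be >= 0")
  if (any(increment > length_end + 1e-12)) {
    zg_stop_domain("`increment` cannot exceed `length_end`")
  }
  invisible(NULL)
}

# increment/length_end with the 0/0 -> 0 empty-leaf convention.
lambda_raw <- function(increment, length_end) {
  out <- ifelse(length_end > 0, increment / length_end, 0)
  pmin(pmax(out, 0), 1)
}

#' Allometric biomass increment of a leaf
#'
#' Projects a leaf's dry-weight gain over the interval from its lengths:
#' `alpha * length_end^beta * delta`, which is algebraically identical to
#' `leaf_biomass(length_end) - leaf_biomass(length_start)`.
#'
#' @param leaf A [leaf_observation()] (or equivalent record with
#'   `length_start`, `length_end`).
#' @param params An [allometric_params()] object.
#' @return Biomass increment in grams.
#' @examples
#' p <- allometric_params(2e-5, 1.3)
#' lf <- leaf_observation(1, 80, 100, dry_weight_end = 0.008)
#' biomass_increment_allometric(lf, p)
#' @export
biomass_increment_allometric <- function(leaf, params) {
  leaf <- as_leaf_fields(leaf)
  params <- as_allometric_params(params)
  d <- delta_factor(leaf$increment, leaf$length_end, params$beta)
  params$alpha * leaf$length_end^params$beta * d
}

# Vectorized core used by the estimators: increments from paired lengths.
ab_increment <- function(length_start, length_end, params) {
  params$alpha * (length_end^params$beta - length_start^params$beta)
}

#' Split a leaf's biomass increment into new tissue and maturation
#'
#' The allometric increment decomposes exactly as
#' `alpha * increment^beta` (the allometric biomass of the newly produced
#' length, "new tissue") plus
#' `alpha * length_end^beta * (delta - lambda^beta)` (the gain attributable
#' to pre-existing tissue growing heavier as the leaf lengthens,
#' "maturation").  The maturation term is nonnegative for `beta >= 1` and
#' vanishes identically at `beta = 1`.
#'
#' @inheritParams biomass_increment_allometric
#' @return A list with components `new_tissue` and `maturation` (grams).
#' @examples
#' p <- allometric_params(1, 2)
#' lf <- leaf_observation(1, 0.5, 1)
#' growth_decomposition(lf, p)  # new 0.25, maturation 0.5
#' @export
growth_decomposition <- function(leaf, params) {
  leaf <- as_leaf_fields(leaf)
  params <- as_allometric_params(params)
  d <- delta_factor(leaf$increment, leaf$length_end, params$beta)
  lam <- lambda_ratio(leaf$increment, leaf$length_end)
  new_tissue <- params$alpha * leaf$increment^params$beta
  maturation <- params$alpha * leaf$length_end^params$beta * (d - lam^params$beta)
  list(new_tissue = new_tissue, maturation = maturation)
}
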