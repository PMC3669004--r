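# Small fixtures built in code.

ref_params <- function() allometric_params(2e-5, 1.3)

# A hand-sized shoot with known lengths and exact allometric weights.
exact_shoot <- function(params = ref_params(), id = "s1") {
  lens <- data.frame(
    rank = 1:3,
    length_start = c(50, 200, 300),
    length_end = c(120, 250, 330))
  w_end <- leaf_biomass(lens$length_end, params)
  w_start <- leaf_biomass(lens$length_start, params)
  above <- w_end - w_start          # all growth above the mark
  shoot_sample(id, data.frame(
    lens,
    increment = lens$length_end - lens$length_start,
    increment_above_mark = lens$length_end - lens$length_start,
    dry_weight_end = w_end, dry_weight_start = w_start,
    above_mark_weight = above))
}

exact_campaign <- function(params = ref_params(), n_shoots = 3, p = 12,
                           delta_t = 14) {
  shoots <- lapply(seq_len(n_shoots), function(i)
    exact_shoot(params, id = paste0("s", i)))
  campaign("2000-05-01", delta_t, shoots, n_marked = n_shoots + 1,
           new_leaves = n_shoots, p = p)
}

# Random valid (length_start, length_end, alpha, beta) draws.
random_leaf_cases <- function(n, seed = 42) {
  set.seed(seed)
  le <- stats::runif(n, 0.01, 600)
  ls <- le * stats::runif(n)
  # a few boundary cases: empty leaf, whole leaf new, no growth
  le[1] <- 0; ls[1] <- 0
  ls[2] <- 0
  ls[3] <- le[3]
  data.frame(length_start = ls, length_end = le,
             alpha = 10^stats::runif(n, -6, -3),
             beta = stats::runif(n, 0.5, 3))
}

# Small, fast simulated season for structural tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_campaigns = 4, shoots_per_campaign = 12, seed = 99), list(...))
  do.call(simulation_config, args)
}
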