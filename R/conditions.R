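# Structured error helpers. Every user-facing failure carries a condition
# class so callers (and tests) can distinguish domain violations from usage
# mistakes without parsing messages.

zg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "zg_error"), call = call))
}

zg_stop_domain <- function(msg) zg_stop(msg, "zg_domain_error")
zg_stop_usage  <- function(msg) zg_stop(msg, "zg_usage_error")

# Raised when a shoot cannot contribute to an estimator (e.g. no rank-3
# leaf for the plastochrone method); campaign-level code catches this and
# excludes the shoot rather than failing the whole campaign.
zg_stop_skip <- function(msg) zg_stop(msg, c("zg_skip_shoot", "zg_domain_error"))

zg_check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    zg_stop_usage(sprintf("`%s` must be a single finite number", name))
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    zg_stop_domain(sprintf(
      "`%s` must be %s %s (got %g)", name, if (strict) ">" else ">=", lower, x
    ))
  }
  invisible(x)
}
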