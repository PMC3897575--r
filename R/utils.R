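# Internal helpers shared across modules.

# Absolute tolerance used when resolving ties at the acceptance-region tail
# thresholds: the defining inequalities are non-strict, so a cumulative
# probability that equals alpha/2 up to floating-point noise is treated as
# attaining it (wider regions, coverage preserved).
.TAIL_TOL <- 1e-12

# Classed errors so callers/tests can distinguish failure modes.
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "alleleCI_error", "error", "condition")))
}

.is_whole <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) <= tol * pmax(1, abs(x))
}

.check_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || !.is_whole(x) || x < min) {
    .err(sprintf("`%s` must be a single integer >= %d", name, min),
         "alleleCI_invalid_argument")
  }
  as.integer(round(x))
}

.check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    .err("`alpha` must be a single number in (0, 1)", "alleleCI_invalid_argument")
  }
  alpha
}
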