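#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp dnorm plogis rnorm runif sd quantile bw.nrd0 setNames
#' @importFrom utils read.csv write.csv
NULL

# Stop with a classed condition so callers can test error identity.
stop_dsdm <- function(msg, class) {
  stop(structure(
    class = c(class, "disjunctSDM_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_dsdm(sprintf("`%s` must be a single integer >= %s", name, min),
              "invalid_parameter")
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_dsdm(sprintf("`%s` must be a single positive number", name),
              "invalid_parameter")
  x
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible sub-seed for a named pipeline stage from a master seed.
# Keeps results independent across stages while remaining a pure function of
# (seed, stage). Stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483562L) + 1L
}
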