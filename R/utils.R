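#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Censored-normal draws: normal with the configured mean/SD, values beyond
# the feature's admissible range set to the bound. Keeps the sample mean at
# the configured mean (renormalized truncation would shift it) and
# reproduces the pile-up at the bounds seen in bounded features such as
# percentages of seven trials.
rcensnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

stop_pataka <- function(msg, class) {
  stop(structure(class = c(class, "pataka_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
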