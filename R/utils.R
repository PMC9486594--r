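# shared internal helpers: condition classes, seeded evaluation, logging

data_error <- function(msg) {
  stop(errorCondition(msg, class = c("permlmm_data_error", "permlmm_error")))
}

numeric_error <- function(msg) {
  stop(errorCondition(msg, class = c("permlmm_numeric_error", "permlmm_error")))
}

usage_error <- function(msg) {
  stop(errorCondition(msg, class = c("permlmm_usage_error", "permlmm_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    usage_error("'seed' must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a base seed; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %% 2147483629
}

log_msg <- function(...) {
  message("[permlmm] ", sprintf(...))
}

# population (biased) sample skewness
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
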