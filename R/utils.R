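## Internal helpers: error conditions and seed management.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("emgdiff_invalid_argument", "emgdiff_error")))
}

stop_with_class <- function(class, msg, data = NULL) {
  cond <- errorCondition(msg, class = c(class, "emgdiff_error"))
  if (!is.null(data)) cond$data <- data
  stop(cond)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_invalid(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    stop_invalid(name, " must be a single number in [", min, ", ", max, "]")
  }
  as.numeric(x)
}

## Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
## afterwards so seeded draws never perturb the global random stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

## Derive a deterministic sub-seed from a base seed and integer ids. Each
## (subject, condition, trial) gets its own stream so that enlarging a design
## does not perturb trials generated earlier. Mixing is a multiplicative
## congruential step mod 2^31-1; intermediate products stay below 2^53.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  x <- (as.double(seed) %% 2147483647) + 1
  for (i in ids) {
    x <- (x * 48271 + (as.double(i) + 1) * 104729) %% 2147483647
  }
  as.integer(x)
}
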