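## Shared builders for small, fast test fixtures (all generated in code).

## A scaled-down two-condition EMG design: 6 subjects x 6 trials, 4 channels,
## 80-sample windows. Same generative model as the full design, cheap enough
## for property loops.
small_cfg <- function(...) {
  args <- list(n_subjects = 6, trials_per_condition = 6, n_channels = 4,
               window_len = 80, planted_channels = c(1L, 3L))
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

small_tm <- function(cfg, grouping = "joint") {
  minmax_normalize(vectorize_dataset(gen_emg_dataset(cfg)), grouping = grouping)
}

## A toy trial matrix with a single informative feature column: subjects
## contribute trials of two classes whose means differ by `sep` only in
## column `signal_col`; all other columns are pure noise.
toy_trial_matrix <- function(n_subjects = 6, trials_per = 4, p = 10,
                             signal_col = 3, sep = 2, noise = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_subjects * trials_per * 2
  X <- matrix(rnorm(n * p, 0, noise), nrow = n)
  cls <- rep(rep(c("a", "b"), each = trials_per), times = n_subjects)
  X[, signal_col] <- X[, signal_col] + ifelse(cls == "a", 0, sep)
  meta <- data.frame(
    subject = rep(sprintf("S%02d", seq_len(n_subjects)), each = 2 * trials_per),
    trial = rep(seq_len(2 * trials_per), times = n_subjects),
    condition = cls, stringsAsFactors = FALSE)
  trial_matrix(X, meta)
}

## Independent brute-force posterior for a diagonal model (direct density
## evaluation, no log-space tricks).
posterior_oracle <- function(model, x) {
  f <- vapply(1:2, function(k) {
    prod(dnorm(x, model$mu[k, ], sqrt(model$var))) * model$priors[k]
  }, 0)
  f / sum(f)
}
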