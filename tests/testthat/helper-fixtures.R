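# Shared fixtures. Expensive simulated sessions are memoised in an
# environment so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

random_spd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(n) * scale
}

random_invertible <- function(n) {
  repeat {
    A <- matrix(rnorm(n * n), n)
    if (abs(det(A)) > 1e-3) return(A)
  }
}

# A small but complete simulated session, preprocessed and artifact-marked:
# 8 trials, 2 objects at 500 ms SOA would starve the subclass cells, so use
# 4 objects with 6 stimuli per sequence at a reduced sampling rate.
tiny_epochs <- function() {
  memo("tiny_epochs", {
    cfg <- session_config(n_trials = 8, n_objects = 4, soa = 0.5,
                          rate = 200, n_channels = 12, seed = 42)
    ses <- simulate_session(cfg)
    rec <- bandpass_and_resample(ses$recording)
    reject_artifacts(extract_epochs(rec, ses$schedule))
  })
}

# Fold-mean AUC of every variant on a session simulated from `cfg`.
session_auc <- function(cfg, variants, fraction = 1, k = 5L,
                        subclass_by = "object") {
  ses <- simulate_session(cfg)
  rec <- bandpass_and_resample(ses$recording)
  ep <- reject_artifacts(extract_epochs(rec, ses$schedule))
  res <- evaluate_variants(ep, variants, subclass_by, k = k,
                           fraction = fraction)
  tapply(res$auc, res$variant, mean)
}
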