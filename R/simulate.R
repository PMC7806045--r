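## Synthetic session simulator: reproduces the paradigm's schedule
## structure (trials x repetitions x per-object highlighting sequences) and
## generates 31-channel recordings with controllable per-object ERP
## heterogeneity, spatially correlated pink noise, and blink artifacts.

#' Simulator configuration
#'
#' Defaults follow the study design: 24 trials with the target balanced
#' over 4 candidate objects, 3 repetitions per trial, 3 s highlighting
#' sequences at 250 ms SOA with 100 ms laser-on stimuli, 31 channels
#' sampled at 1 kHz.
#'
#' @param n_trials number of trials.
#' @param n_repetitions repetitions per trial (each repetition highlights
#'   every candidate object once with a full sequence).
#' @param n_objects number of candidate objects.
#' @param soa stimulus-onset asynchrony in seconds (0.25 or 0.5).
#' @param sequence_duration duration of one per-object highlighting
#'   sequence in seconds; must be an integer multiple of `soa`.
#' @param stimulus_duration laser-on duration in seconds.
#' @param rate sampling rate in Hz.
#' @param n_channels number of EEG channels.
#' @param gains per-object multiplicative ERP gain (recycled to
#'   `n_objects`).
#' @param latency_shift_ms per-object ERP latency shift in milliseconds.
#' @param target_p3_amplitude amplitude of the target-specific parietal
#'   positivity around 300 ms, in microvolts.
#' @param initial_boost amplitude multiplier (>= 1) for the first stimulus
#'   of each sequence, emulating the larger response to the initial
#'   highlighting.
#' @param noise_scale per-channel RMS of the background noise in
#'   microvolts.
#' @param artifact_rate expected blink artifacts per minute.
#' @param inter_sequence_gap pause between sequences in seconds (robot
#'   repositioning proxy).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A list of class `"session_config"`.
#' @export
session_config <- function(n_trials = 24L, n_repetitions = 3L,
                           n_objects = 4L, soa = 0.25,
                           sequence_duration = 3, stimulus_duration = 0.1,
                           rate = 1000, n_channels = 31L,
                           gains = 1, latency_shift_ms = 0,
                           target_p3_amplitude = 5, initial_boost = 1.5,
                           noise_scale = 9, artifact_rate = 2,
                           inter_sequence_gap = 1, seed = 1L) {
  nstim <- sequence_duration / soa
  if (abs(nstim - round(nstim)) > 1e-9)
    stop("sequence_duration must be an integer multiple of soa")
  cfg <- list(n_trials = as.integer(n_trials),
              n_repetitions = as.integer(n_repetitions),
              n_objects = as.integer(n_objects), soa = soa,
              sequence_duration = sequence_duration,
              stimulus_duration = stimulus_duration, rate = rate,
              n_channels = as.integer(n_channels),
              gains = rep_len(gains, n_objects),
              latency_shift_ms = rep_len(latency_shift_ms, n_objects),
              target_p3_amplitude = target_p3_amplitude,
              initial_boost = initial_boost, noise_scale = noise_scale,
              artifact_rate = artifact_rate,
              inter_sequence_gap = inter_sequence_gap,
              seed = as.integer(seed))
  class(cfg) <- "session_config"
  cfg
}

#' Build the highlighting schedule of a simulated session
#'
#' Every trial consists of `n_repetitions` repetitions; in each repetition
#' every candidate object is highlighted in turn with a sequence of
#' `sequence_duration / soa` stimuli. Exactly one object is the target per
#' trial; targets are balanced across objects (the per-object trial counts
#' are equal whenever `n_trials` is divisible by `n_objects`), with the
#' trial order shuffled from the seed.
#'
#' @param cfg a [session_config()].
#' @return An [event_schedule()].
#' @export
build_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  nstim <- as.integer(round(cfg$sequence_duration / cfg$soa))
  set.seed(cfg$seed)
  targets <- sample(rep_len(seq_len(cfg$n_objects), cfg$n_trials))
  onset <- trial <- rep_ <- object <- qpos <- integer(0)
  rows <- vector("list", cfg$n_trials * cfg$n_repetitions * cfg$n_objects)
  cur <- 2.0                       # lead-in
  r <- 0L
  for (tr in seq_len(cfg$n_trials)) {
    for (rep_i in seq_len(cfg$n_repetitions)) {
      for (ob in seq_len(cfg$n_objects)) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          onset_s = cur + (seq_len(nstim) - 1L) * cfg$soa,
          trial = tr, repetition = rep_i, object = ob,
          seq_position = seq_len(nstim),
          is_target = ob == targets[tr])
        cur <- cur + nstim * cfg$soa + cfg$inter_sequence_gap
      }
    }
  }
  df <- do.call(rbind, rows)
  event_schedule(df$onset_s, df$trial, df$repetition, df$object,
                 df$seq_position, df$is_target)
}

#' ERP source templates used by the simulator
#'
#' The non-target response is a small biphasic deflection (N1/P2-like,
#' peaks near 120 and 200 ms); targets add a parietal positive bump
#' centered at 300 ms with ~80 ms width. Shapes are qualitative stand-ins
#' for laser-highlighting ERPs, not reproductions of any recorded
#' waveform.
#'
#' @param rate sampling rate in Hz.
#' @param p3_amplitude amplitude of the target bump in microvolts.
#' @return List with `nontarget` and `p3` source waveforms (microvolts) and
#'   their duration `length_s`.
#' @export
erp_templates <- function(rate, p3_amplitude = 5) {
  len <- 0.7
  t <- seq(0, len, by = 1 / rate)
  g <- function(mu, sd) exp(-0.5 * ((t - mu) / sd)^2)
  list(nontarget = -2.5 * g(0.12, 0.025) + 3.0 * g(0.20, 0.035),
       p3 = p3_amplitude * g(0.30, 0.040),
       length_s = len, times = t)
}

## Order-6 pinking IIR: six first-order shelving sections with poles
## log-spaced from 1 Hz to near Nyquist and zeros offset by half a
## spacing step, collapsed into one polynomial pair. The magnitude
## response approximates a 1/sqrt(f) amplitude (1/f power) slope above
## f_lo and is flat below it, so slow drifts do not dominate the RMS.
.pinking_filter <- function(rate, K = 6L, f_lo = 1) {
  f_hi <- rate / 2 * 0.8
  r <- (f_hi / f_lo)^(1 / K)
  fp <- f_lo * r^(seq_len(K) - 1)
  fz <- fp * sqrt(r)
  poles <- exp(-2 * pi * fp / rate)
  zeros <- exp(-2 * pi * fz / rate)
  polymul <- function(roots) Reduce(function(p, rt) c(p, 0) - c(0, rt * p),
                                    roots, init = 1)
  b <- polymul(zeros)
  a <- polymul(poles)
  list(b = b, a_rec = -a[-1])
}

## Fixed fictitious montage on a golden-angle spiral over the unit disc;
## row 1 of the returned list holds channel coordinates, plus the source
## projection patterns (fronto-central for the biphasic component,
## parietal for the target positivity, frontal for blinks).
.montage <- function(n_channels) {
  i <- seq_len(n_channels)
  rad <- sqrt((i - 0.5) / n_channels)
  th <- i * 2.399963
  pos <- cbind(x = rad * cos(th), y = rad * sin(th))
  pat <- function(cx, cy, w) {
    v <- exp(-((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2) / (2 * w^2))
    v / max(v)
  }
  list(pos = pos,
       erp = pat(0, 0.55, 0.55),     # fronto-central
       p3 = pat(0, -0.45, 0.55),     # parietal
       blink = pat(0, 0.95, 0.35))   # frontal
}

#' Generate a continuous recording for a schedule
#'
#' The signal is a linear superposition, over highlightings, of the source
#' templates of [erp_templates()] scaled by the object gain and the
#' initial-position boost and shifted by the object latency, projected
#' through fixed spatial patterns; plus spatially correlated pink noise and
#' Poisson-placed high-amplitude frontal blink artifacts. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [session_config()].
#' @param sched the schedule from [build_schedule()].
#' @return A [continuous_recording()] (`n_channels` x samples, microvolts).
#' @export
generate_recording <- function(cfg, sched) {
  stopifnot(inherits(cfg, "session_config"))
  validate_schedule(sched)
  set.seed(cfg$seed + 1L)
  rate <- cfg$rate
  tmpl <- erp_templates(rate, cfg$target_p3_amplitude)
  nsamp <- as.integer(round((max(sched$onset_s) + 3) * rate))
  mont <- .montage(cfg$n_channels)

  ## source time courses
  s_erp <- numeric(nsamp)
  s_p3 <- numeric(nsamp)
  L <- length(tmpl$nontarget)
  for (k in seq_len(nrow(sched))) {
    ob <- sched$object[k]
    shift <- round(cfg$latency_shift_ms[ob] / 1000 * rate)
    i0 <- round(sched$onset_s[k] * rate) + 1L + shift
    idx <- i0:(i0 + L - 1L)
    keep <- idx >= 1L & idx <= nsamp
    amp <- cfg$gains[ob] *
      (if (sched$seq_position[k] == 1L) cfg$initial_boost else 1)
    s_erp[idx[keep]] <- s_erp[idx[keep]] + amp * tmpl$nontarget[keep]
    if (sched$is_target[k])
      s_p3[idx[keep]] <- s_p3[idx[keep]] + amp * tmpl$p3[keep]
  }
  X <- outer(mont$erp, s_erp) + outer(mont$p3, s_p3)

  ## spatially correlated pink noise: white noise shaped by a pinking
  ## filter (log-spaced pole/zero shelves giving ~1/f power over the band
  ## of interest), then mixed through a smooth exponential spatial
  ## correlation over the montage
  if (cfg$noise_scale > 0) {
    nch <- cfg$n_channels
    pk <- .pinking_filter(rate)
    P <- matrix(0, nch, nsamp)
    for (ch in seq_len(nch)) {
      p <- .iir_filter(pk$b, pk$a_rec, rnorm(nsamp))
      P[ch, ] <- p / sd(p)
    }
    d <- as.matrix(dist(mont$pos))
    Lmix <- t(chol(exp(-d / 0.5)))
    N <- Lmix %*% P
    X <- X + N / apply(N, 1L, sd) * cfg$noise_scale
  }

  ## blink artifacts: ~400 ms frontal positive deflections > 100 uV
  if (cfg$artifact_rate > 0) {
    nb <- rpois(1L, cfg$artifact_rate * nsamp / rate / 60)
    if (nb > 0) {
      tb <- seq(0, 0.4, by = 1 / rate)
      bw <- 150 * exp(-0.5 * ((tb - 0.2) / 0.07)^2)
      at <- sort(round(runif(nb, 0, nsamp - length(bw))))
      for (a in at) {
        idx <- a + seq_along(bw)
        X[, idx] <- X[, idx] + outer(mont$blink, bw)
      }
    }
  }
  continuous_recording(X, rate)
}

#' Simulate a full session (schedule + recording)
#'
#' @param cfg a [session_config()].
#' @return List with `schedule` and `recording`.
#' @export
simulate_session <- function(cfg) {
  sched <- build_schedule(cfg)
  list(schedule = sched, recording = generate_recording(cfg, sched))
}

#' Named simulator presets for subclass heterogeneity
#'
#' `homogeneous`: identical per-object responses (all gains 1, no latency
#' shifts). `heterogeneous`: per-object gains 1.5, 1.2, 0.7, 0.5 and
#' latency shifts 0, 0, 10, 25 ms, mirroring a salient / less-salient
#' object split. All other parameters follow the [session_config()]
#' defaults.
#'
#' @param seed seed stored in both configs.
#' @param ... further overrides passed to [session_config()].
#' @return Named list of two [session_config()] objects.
#' @export
heterogeneity_presets <- function(seed = 1L, ...) {
  list(homogeneous = session_config(gains = 1, latency_shift_ms = 0,
                                    seed = seed, ...),
       heterogeneous = session_config(gains = c(1.5, 1.2, 0.7, 0.5),
                                      latency_shift_ms = c(0, 0, 10, 25),
                                      seed = seed, ...))
}
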