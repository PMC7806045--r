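## Segmentation and preprocessing: band-pass filtering, downsampling,
## epoching with baseline correction, and peak-to-peak artifact rejection.

## Zero-state IIR filtering y = (b/a) * x via compiled stats::filter calls:
## the moving-average part runs on a zero-padded input (so the implicit
## past is exactly zero -- replacing the NA head instead would inject a
## transient that near-unity poles amplify enormously), the autoregressive
## part as a recursive filter.
.iir_filter <- function(b, a_rec, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  w <- stats::filter(xp, b, method = "convolution",
                     sides = 1)[-seq_len(nb - 1L)]
  as.numeric(stats::filter(w, a_rec, method = "recursive"))
}

## One forward-backward (zero-phase) pass of the IIR filter b/a, with
## reflected edge padding to absorb filter transients.
.zero_phase <- function(b, a, x, pad) {
  n <- length(x)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  a_rec <- -a[-1]
  y <- rev(.iir_filter(b, a_rec, rev(.iir_filter(b, a_rec, xe))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter and downsample a recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward (zero
#' phase, preserving ERP latencies) and then decimates to `out_rate`. The
#' upper band edge must leave the output Nyquist frequency free, so the
#' band-pass itself provides the anti-aliasing. Event onsets are expressed
#' in seconds and are unaffected.
#'
#' @param rec a [continuous_recording()].
#' @param low,high band edges in Hz (defaults 0.5 and 16).
#' @param out_rate output sampling rate in Hz (default 100); must divide the
#'   input rate.
#' @return A filtered, downsampled [continuous_recording()].
#' @export
bandpass_and_resample <- function(rec, low = 0.5, high = 16, out_rate = 100) {
  stopifnot(inherits(rec, "continuous_recording"))
  rate <- rec$rate
  if (!(low > 0 && low < high && high < rate / 2))
    stop("require 0 < low < high < rate/2")
  if (out_rate > rate) stop("out_rate must not exceed the input rate")
  if (high >= out_rate / 2)
    stop("out_rate ", out_rate, " Hz violates Nyquist for the ", high,
         " Hz band edge")
  bf <- signal::butter(2, c(low, high) / (rate / 2), type = "pass")
  pad <- min(ncol(rec$data) - 1L, as.integer(round(3 * rate / low)))
  filt <- t(apply(rec$data, 1L, function(ch)
    .zero_phase(bf$b, bf$a, ch, pad)))
  dec <- rate / out_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("out_rate must divide the input rate (got ratio ", format(dec), ")")
  dec <- as.integer(round(dec))
  idx <- seq(1L, ncol(filt), by = dec)
  continuous_recording(filt[, idx, drop = FALSE], out_rate, rec$channel_names)
}

#' Extract baseline-corrected stimulus-locked windows
#'
#' For every schedule row a window spanning `window_s` (default `[0, 1]` s
#' relative to onset, inclusive at both ends, so 101 samples at 100 Hz) is
#' cut out and the per-channel mean over the preceding `baseline_s` interval
#' (default `[-0.2, 0)` s) is subtracted. Onsets are snapped to the nearest
#' sample. Events too close to the recording edges are dropped with a
#' warning.
#'
#' @param rec a preprocessed [continuous_recording()] (see
#'   [bandpass_and_resample()]).
#' @param sched an [event_schedule()].
#' @param window_s two-element numeric, window relative to onset in seconds.
#' @param baseline_s two-element numeric, baseline interval relative to
#'   onset; samples in `[baseline_s[1], baseline_s[2])`.
#' @return An [epoch_set()] whose schedule rows align with the retained
#'   windows.
#' @export
extract_epochs <- function(rec, sched, window_s = c(0, 1),
                           baseline_s = c(-0.2, 0)) {
  stopifnot(inherits(rec, "continuous_recording"))
  validate_schedule(sched)
  rate <- rec$rate
  nsamp <- ncol(rec$data)
  i0 <- round(sched$onset_s * rate) + 1L         # 1-based sample at onset
  w_lo <- as.integer(round(window_s[1] * rate))
  w_hi <- as.integer(round(window_s[2] * rate))
  b_lo <- as.integer(round(baseline_s[1] * rate))
  b_hi <- as.integer(round(baseline_s[2] * rate)) # exclusive upper edge
  ok <- (i0 + min(w_lo, b_lo)) >= 1L & (i0 + w_hi) <= nsamp
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: window extends beyond the recording")
  i0 <- i0[ok]
  K <- length(i0)
  nc <- nrow(rec$data)
  nt <- w_hi - w_lo + 1L
  win <- array(0, dim = c(K, nc, nt))
  for (k in seq_len(K)) {
    seg <- rec$data[, (i0[k] + w_lo):(i0[k] + w_hi), drop = FALSE]
    bas <- rec$data[, (i0[k] + b_lo):(i0[k] + b_hi - 1L), drop = FALSE]
    win[k, , ] <- seg - rowMeans(bas)
  }
  epoch_set(win, sched[ok, , drop = FALSE], rate,
            seq(w_lo, w_hi) / rate)
}

#' Mark artifact windows by peak-to-peak amplitude
#'
#' A window is rejected when its peak-to-peak amplitude strictly exceeds
#' `threshold` in any channel; a window at exactly the threshold is
#' retained. Rejected windows stay in the set but are excluded from model
#' fitting downstream.
#'
#' @param ep an [epoch_set()].
#' @param threshold peak-to-peak limit in microvolts (default 100).
#' @return The epoch set with an updated `rejected` mask.
#' @export
reject_artifacts <- function(ep, threshold = 100) {
  stopifnot(inherits(ep, "epoch_set"), threshold > 0)
  ptp <- apply(ep$windows, 1L, function(w)
    max(apply(w, 1L, function(ch) max(ch) - min(ch))))
  ep$rejected <- ptp > threshold
  ep
}

#' Drop rejected windows from an epoch set
#'
#' @param ep an [epoch_set()].
#' @return The epoch set restricted to non-rejected windows.
#' @export
retained <- function(ep) ep[!ep$rejected]

#' Class-mean ERP prototypes
#'
#' Euclidean (elementwise) means of the target and non-target training
#' windows; used as the constant prototype rows of the augmented windows.
#'
#' @param ep an [epoch_set()] of training data; rejected windows are
#'   excluded.
#' @return A list of class `"prototype_pair"` with `target_mean` and
#'   `nontarget_mean` (channels x times matrices).
#' @export
compute_prototypes <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  ep <- retained(ep)
  y <- ep$schedule$is_target
  if (!any(y) || !any(!y))
    stop("both target and non-target windows are required for prototypes")
  mean_of <- function(sel) {
    w <- ep$windows[sel, , , drop = FALSE]
    apply(w, c(2, 3), mean)
  }
  structure(list(target_mean = mean_of(y), nontarget_mean = mean_of(!y)),
            class = "prototype_pair")
}
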