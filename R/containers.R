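## Lightweight S3 containers shared across the package.

#' Construct a continuous multi-channel recording
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param rate sampling rate in Hz.
#' @param channel_names optional character vector of channel labels.
#' @return Object of class `"continuous_recording"`.
#' @export
continuous_recording <- function(data, rate, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a channels x samples numeric matrix")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the number of channels")
  structure(list(data = data, rate = rate, channel_names = channel_names),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Construct and validate a stimulus event schedule
#'
#' One row per highlighting event `k`. The position group (initial vs
#' subsequent) is derived from the sequence position: `initial` iff
#' `seq_position == 1`.
#'
#' @param onset_s stimulus onset times in seconds, strictly increasing.
#' @param trial trial identifier (integer); each trial has exactly one
#'   target object.
#' @param repetition repetition index within the trial.
#' @param object highlighted object id.
#' @param seq_position position of the stimulus within its highlighting
#'   sequence (1-based).
#' @param is_target logical: does the highlighted object equal the trial's
#'   goal object?
#' @return A data frame of class `"event_schedule"` with an additional
#'   derived `position_group` factor (`"initial"`/`"subsequent"`).
#' @export
event_schedule <- function(onset_s, trial, repetition, object, seq_position,
                           is_target) {
  df <- data.frame(onset_s = as.numeric(onset_s),
                   trial = as.integer(trial),
                   repetition = as.integer(repetition),
                   object = as.integer(object),
                   seq_position = as.integer(seq_position),
                   is_target = as.logical(is_target))
  df$position_group <- factor(ifelse(df$seq_position == 1L, "initial",
                                     "subsequent"),
                              levels = c("initial", "subsequent"))
  validate_schedule(df)
  class(df) <- c("event_schedule", "data.frame")
  df
}

#' Validate event-schedule invariants
#'
#' Checks strictly increasing onsets, uniqueness of onsets, and that every
#' trial has exactly one target object.
#'
#' @param df data frame with the schedule columns.
#' @return `df`, invisibly, on success; otherwise an error naming the
#'   offending rows.
#' @export
validate_schedule <- function(df) {
  need <- c("onset_s", "trial", "repetition", "object", "seq_position",
            "is_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule is missing required columns: ", paste(miss, collapse = ", "))
  d <- diff(df$onset_s)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop("onsets must be strictly increasing (violated at row ", bad, ")")
  }
  for (tr in unique(df$trial)) {
    tgt <- unique(df$object[df$trial == tr & df$is_target])
    if (length(tgt) != 1L)
      stop("trial ", tr, " must have exactly one target object, found ",
           length(tgt))
  }
  invisible(df)
}

#' Construct an epoch set
#'
#' @param windows K x n_channels x n_times numeric array (microvolts).
#' @param schedule [event_schedule()] rows aligned with the first array
#'   dimension.
#' @param rate sampling rate of the epoched data in Hz.
#' @param times vector of within-epoch sample times in seconds.
#' @param rejected logical vector marking artifact windows (see
#'   [reject_artifacts()]); rejected windows are excluded from all model
#'   fitting.
#' @return Object of class `"epoch_set"`.
#' @export
epoch_set <- function(windows, schedule, rate, times,
                      rejected = rep(FALSE, dim(windows)[1])) {
  stopifnot(length(dim(windows)) == 3L,
            dim(windows)[1] == nrow(schedule),
            dim(windows)[3] == length(times),
            length(rejected) == dim(windows)[1])
  structure(list(windows = windows, schedule = schedule, rate = rate,
                 times = times, rejected = rejected),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d windows (%d rejected), %d channels x %d samples @ %g Hz\n",
              dim(x$windows)[1], sum(x$rejected), dim(x$windows)[2],
              dim(x$windows)[3], x$rate))
  invisible(x)
}

#' Subset an epoch set by window index
#'
#' @param x an [epoch_set()].
#' @param i integer or logical index over windows.
#' @param ... ignored.
#' @return The subsetted `epoch_set`.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  epoch_set(x$windows[i, , , drop = FALSE], x$schedule[i, , drop = FALSE],
            x$rate, x$times, x$rejected[i])
}

## Subclass labels j(k) from a schedule under a given definition.
.subclass_labels <- function(schedule,
                             subclass_by = c("object", "position_group",
                                             "position")) {
  subclass_by <- match.arg(subclass_by)
  switch(subclass_by,
         object = as.character(schedule$object),
         position_group = as.character(schedule$position_group),
         position = as.character(schedule$seq_position))
}
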