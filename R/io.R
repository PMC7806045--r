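## Readers and writers: BrainVision triplets, a native RDS container,
## tabular event schedules, YAML run configuration and model files.

#' Write a recording as a BrainVision triplet
#'
#' Emits `<stem>.vhdr` (text header), `<stem>.vmrk` (markers; one Stimulus
#' marker per schedule row if a schedule is given) and `<stem>.eeg`
#' (multiplexed IEEE float32 binary, microvolts).
#'
#' @param rec a [continuous_recording()].
#' @param stem path without extension.
#' @param sched optional [event_schedule()] to emit as Stimulus markers.
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(rec, stem, sched = NULL) {
  stopifnot(inherits(rec, "continuous_recording"))
  base <- basename(stem)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "; generated by riemerp",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$data)),
           paste0("SamplingInterval=", format(1e6 / rec$rate)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)),
                   rec$channel_names))
  writeLines(hdr, paste0(stem, ".vhdr"))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", base, ".eeg"),
           "[Marker Infos]",
           "Mk1=New Segment,,1,1,0,0")
  if (!is.null(sched)) {
    pos <- round(sched$onset_s * rec$rate) + 1L
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_len(nrow(sched)) + 1L, sched$object, pos))
  }
  writeLines(mrk, paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

.parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  sec <- ""
  kv <- list(); chans <- character(0); res <- numeric(0); unit <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "[")) { sec <- ln; next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1, eq - 1)
    val <- substr(ln, eq + 1, nchar(ln))
    if (sec == "[Channel Infos]") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1]]
      chans <- c(chans, parts[1])
      res <- c(res, if (length(parts) >= 3 && nzchar(parts[3]))
        as.numeric(parts[3]) else 1)
      unit <- c(unit, if (length(parts) >= 4) parts[4] else "µV")
    } else kv[[key]] <- val
  }
  list(kv = kv, chans = chans, res = res, unit = unit)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed or vectorized binary layouts in IEEE float32 or
#' int16 (with per-channel resolution). Channels declared in volts are
#' rescaled to microvolts. Stimulus markers from the `.vmrk` file are
#' attached as attribute `"events"` (a data frame of onset seconds and
#' descriptions).
#'
#' @param path path to the `.vhdr` header; the data and marker files it
#'   names must sit next to it.
#' @return A [continuous_recording()] in microvolts.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop("header not found: ", path)
  h <- .parse_vhdr(path)
  dir <- dirname(path)
  datafile <- file.path(dir, h$kv[["DataFile"]])
  if (is.null(h$kv[["DataFile"]]) || !file.exists(datafile))
    stop("BrainVision data file missing: ", h$kv[["DataFile"]])
  nch <- as.integer(h$kv[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(h$kv[["SamplingInterval"]])
  fmt <- toupper(h$kv[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  orient <- toupper(h$kv[["DataOrientation"]] %||% "MULTIPLEXED")
  sz <- file.size(datafile)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L
  else if (fmt == "INT_16") 2L
  else stop("unsupported BinaryFormat: ", fmt)
  n_total <- sz / bytes
  if (n_total %% nch != 0)
    stop("data file length is not a multiple of the channel count; ",
         "header and data are inconsistent")
  nsamp <- as.integer(n_total / nch)
  con <- file(datafile, "rb")
  on.exit(close(con))
  raw_ <- if (bytes == 4L)
    readBin(con, numeric(), n = n_total, size = 4L, endian = "little")
  else
    readBin(con, integer(), n = n_total, size = 2L, signed = TRUE,
            endian = "little")
  X <- if (orient == "MULTIPLEXED") matrix(raw_, nrow = nch)
  else if (orient == "VECTORIZED") t(matrix(raw_, nrow = nsamp))
  else stop("unsupported DataOrientation: ", orient)
  X <- X * h$res
  isV <- h$unit %in% c("V", "v")
  if (any(isV)) X[isV, ] <- X[isV, , drop = FALSE] * 1e6
  rec <- continuous_recording(X, rate, h$chans)
  mfile <- file.path(dir, h$kv[["MarkerFile"]] %||% "")
  if (nzchar(h$kv[["MarkerFile"]] %||% "") && file.exists(mfile)) {
    ml <- grep("^Mk[0-9]+=", readLines(mfile, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    ev <- do.call(rbind, lapply(parts, function(p)
      if (length(p) >= 3 && p[1] != "New Segment")
        data.frame(onset_s = (as.numeric(p[3]) - 1) / rate,
                   type = p[1], description = p[2])
      else NULL))
    attr(rec, "events") <- ev
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a continuous recording
#'
#' @param path file path: a `.vhdr` for BrainVision or an `.rds` container
#'   written by [write_recording()].
#' @param format `"brainvision"`, `"container"`, or `"auto"` (by
#'   extension). EDF is not supported; convert to BrainVision first.
#' @return A [continuous_recording()] in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "brainvision",
                                            "container", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", rds = "container",
                     edf = "edf",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "edf")
    stop("EDF reading is not supported; convert the recording to a ",
         "BrainVision triplet or the native container")
  if (format == "brainvision") return(read_brainvision(path))
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$rate))
    stop("container does not hold a recording")
  if (!is.null(obj$n_samples) && obj$n_samples != ncol(obj$data))
    stop("container header declares ", obj$n_samples,
         " samples but the data hold ", ncol(obj$data))
  X <- obj$data
  if (identical(obj$unit, "V")) X <- X * 1e6
  continuous_recording(X, obj$rate, obj$channel_names)
}

#' Write a continuous recording
#'
#' @param rec a [continuous_recording()].
#' @param path output path (`.vhdr` stem semantics for BrainVision, `.rds`
#'   for the container).
#' @param format `"brainvision"` or `"container"`.
#' @param sched optional schedule, emitted as markers (BrainVision only).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("container", "brainvision"),
                            sched = NULL) {
  format <- match.arg(format)
  if (format == "brainvision") {
    write_brainvision(rec, sub("\\.vhdr$", "", path), sched)
  } else {
    saveRDS(list(schema = "riemerp/recording/1", data = rec$data,
                 rate = rec$rate, channel_names = rec$channel_names,
                 unit = "µV", n_samples = ncol(rec$data)), path)
  }
  invisible(path)
}

#' Read an event schedule from a tab-separated file
#'
#' Required columns: `onset_s`, `trial`, `repetition`, `object`,
#' `seq_position`, `is_target`. The position group is derived
#' (`initial` iff `seq_position == 1`) and all schedule invariants are
#' validated.
#'
#' @param path TSV file path.
#' @return An [event_schedule()].
#' @export
read_schedule <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset_s", "trial", "repetition", "object", "seq_position",
            "is_target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule file lacks column(s): ", paste(miss, collapse = ", "))
  event_schedule(df$onset_s, df$trial, df$repetition, df$object,
                 df$seq_position, as.logical(df$is_target))
}

#' Write an event schedule to a tab-separated file
#'
#' @param sched an [event_schedule()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  out <- sched[c("onset_s", "trial", "repetition", "object",
                 "seq_position", "is_target")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All preprocessing and evaluation defaults in one place: 0.5-16 Hz
#' band-pass, 100 Hz pipeline rate, `[0, 1]` s windows with `[-0.2, 0)` s
#' baseline, 100 uV peak-to-peak rejection, 5 chronological folds.
#'
#' @param ... overrides of the default fields.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(band_low = 0.5, band_high = 16, out_rate = 100,
              window_s = c(0, 1), baseline_s = c(-0.2, 0),
              reject_uV = 100, variant = "cts_reg_lda",
              subclass_by = "object", folds = 5L, fraction = 1.0,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ",
                        paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `"run_config"`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a `"run_config"`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write provenance information next to an output
#'
#' Every output directory gets the exact resolved configuration and the
#' package version, so results are reproducible from the files alone.
#'
#' @param dir output directory (created if needed).
#' @param cfg the resolved `"run_config"`.
#' @return The directory, invisibly.
#' @export
write_provenance <- function(dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(dir, "run_config.yaml"))
  writeLines(paste0("riemerp ", as.character(packageVersion("riemerp"))),
             file.path(dir, "VERSION"))
  invisible(dir)
}

#' Save / load a fitted pipeline model
#'
#' Single-file RDS container with a schema version tag.
#'
#' @param model a `"pipeline_model"`.
#' @param path file path.
#' @return For `load_pipeline`, the model.
#' @export
save_pipeline <- function(model, path) {
  stopifnot(inherits(model, "pipeline_model"))
  saveRDS(list(schema = "riemerp/pipeline_model/1", model = model), path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "riemerp/pipeline_model/1"))
    stop("not a riemerp pipeline model file")
  obj$model
}
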