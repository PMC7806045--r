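test_that("schedules have the paradigm's combinatorial structure", {
  cfg <- session_config(n_trials = 24, n_objects = 4, soa = 0.25, seed = 5)
  sched <- build_schedule(cfg)
  expect_equal(sort(unique(sched$seq_position)), 1:12)
  expect_equal(sum(sched$is_target), 864)
  expect_equal(sum(!sched$is_target), 2592)
  expect_true(all(diff(sched$onset_s) > 0))
  # targets balanced over objects: 6 trials each
  tgt <- unique(sched[sched$is_target, c("trial", "object")])$object
  expect_equal(as.integer(table(tgt)), rep(6L, 4))
  # position-group rule
  expect_equal(sched$position_group == "initial", sched$seq_position == 1)

  cfg2 <- session_config(soa = 0.5, seed = 5)
  expect_equal(max(build_schedule(cfg2)$seq_position), 6)
  expect_error(session_config(soa = 0.4), "integer multiple")

  # generic count law: targets = trials * reps * stimuli per sequence
  cfg3 <- session_config(n_trials = 6, n_repetitions = 2, n_objects = 3,
                         soa = 0.5, seed = 1)
  s3 <- build_schedule(cfg3)
  expect_equal(sum(s3$is_target), 6 * 2 * 6)
  expect_equal(sum(!s3$is_target), 2 * 6 * 2 * 6)
})

test_that("noise-free recordings reproduce the source templates", {
  # one stimulus per sequence isolates each response
  cfg <- session_config(n_trials = 2, n_repetitions = 1, n_objects = 2,
                        soa = 0.5, sequence_duration = 0.5, rate = 500,
                        n_channels = 6, noise_scale = 0, artifact_rate = 0,
                        initial_boost = 1, seed = 9)
  ses <- simulate_session(cfg)
  rec <- ses$recording
  tmpl <- erp_templates(cfg$rate, cfg$target_p3_amplitude)
  mont <- riemerp:::.montage(cfg$n_channels)
  k <- which(!ses$schedule$is_target)[1]
  i0 <- round(ses$schedule$onset_s[k] * cfg$rate) + 1
  seg <- rec$data[, i0:(i0 + length(tmpl$nontarget) - 1)]
  expect_equal(seg, outer(mont$erp, tmpl$nontarget), tolerance = 1e-10)
  kt <- which(ses$schedule$is_target)[1]
  i0t <- round(ses$schedule$onset_s[kt] * cfg$rate) + 1
  segt <- rec$data[, i0t:(i0t + length(tmpl$nontarget) - 1)]
  expect_equal(segt, outer(mont$erp, tmpl$nontarget) +
                 outer(mont$p3, tmpl$p3), tolerance = 1e-10)
})

test_that("simulation is reproducible from the seed", {
  cfg <- session_config(n_trials = 2, rate = 200, n_channels = 5, seed = 21)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$schedule, b$schedule)
  cfg2 <- cfg; cfg2$seed <- 22L
  c2 <- simulate_session(cfg2)
  expect_false(identical(a$recording$data, c2$recording$data))
})

test_that("superposition is linear in the schedule (noise-free)", {
  base <- session_config(n_trials = 2, n_repetitions = 1, n_objects = 2,
                         soa = 0.5, sequence_duration = 1, rate = 200,
                         n_channels = 4, noise_scale = 0,
                         artifact_rate = 0, seed = 3)
  sched <- build_schedule(base)
  full <- generate_recording(base, sched)
  parts <- lapply(unique(sched$trial), function(tr) {
    part <- sched[sched$trial == tr, ]
    class(part) <- c("event_schedule", "data.frame")
    generate_recording(base, part)$data
  })
  n <- min(vapply(parts, ncol, integer(1)), ncol(full$data))
  added <- Reduce(`+`, lapply(parts, function(p) p[, 1:n]))
  expect_equal(full$data[, 1:n], added, tolerance = 1e-12)
})

test_that("heterogeneity presets encode the intended object structure", {
  pr <- heterogeneity_presets(seed = 2)
  expect_equal(pr$homogeneous$gains, rep(1, 4))
  expect_equal(pr$heterogeneous$gains, c(1.5, 1.2, 0.7, 0.5))
  expect_equal(pr$heterogeneous$latency_shift_ms, c(0, 0, 10, 25))

  # noise-free grand averages follow the configured gains
  cfg <- pr$heterogeneous
  cfg$n_trials <- 4; cfg$rate <- 200; cfg$noise_scale <- 0
  cfg$artifact_rate <- 0
  ses <- simulate_session(cfg)
  rec <- bandpass_and_resample(ses$recording)
  ep <- extract_epochs(rec, ses$schedule)
  ga <- grand_average(ep)
  amp <- vapply(1:4, function(ob) {
    sel <- ga$groups$object == ob & ga$groups$class == "nt" &
      ga$groups$position_group == "subsequent"
    max(abs(ga$waveforms[[which(sel)]]))
  }, numeric(1))
  expect_equal(order(amp, decreasing = TRUE), order(cfg$gains,
                                                    decreasing = TRUE))
  # 3:1 non-target to target ratio in both presets
  expect_equal(sum(!ses$schedule$is_target) / sum(ses$schedule$is_target), 3)

  # homogeneous preset: identical per-object responses by construction
  cfgh <- pr$homogeneous
  cfgh$n_trials <- 4; cfgh$rate <- 200; cfgh$noise_scale <- 0
  cfgh$artifact_rate <- 0
  sesh <- simulate_session(cfgh)
  eph <- extract_epochs(bandpass_and_resample(sesh$recording),
                        sesh$schedule)
  gah <- grand_average(eph)
  waves <- lapply(1:4, function(ob) {
    sel <- gah$groups$object == ob & gah$groups$class == "nt" &
      gah$groups$position_group == "subsequent"
    gah$waveforms[[which(sel)]]
  })
  # identical up to band-pass edge transients at the session boundaries
  for (ob in 2:4)
    expect_lt(max(abs(waves[[ob]] - waves[[1]])),
              0.01 * max(abs(waves[[1]])))
})

test_that("zero target amplitude removes class information", {
  cfg <- session_config(n_trials = 5, n_objects = 4, soa = 0.5,
                        rate = 200, n_channels = 12,
                        target_p3_amplitude = 0, seed = 31)
  a <- session_auc(cfg, "ts_lda", k = 3)
  expect_gt(a, 0.3)
  expect_lt(a, 0.7)
})

test_that("blink artifacts exceed the rejection threshold", {
  cfg <- session_config(n_trials = 2, rate = 200, n_channels = 8,
                        noise_scale = 0, artifact_rate = 30, seed = 12)
  ses <- simulate_session(cfg)
  expect_gt(max(ses$recording$data), 100)
})
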