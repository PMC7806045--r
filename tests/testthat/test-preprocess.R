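make_rec <- function(data, rate = 1000) continuous_recording(data, rate)

test_that("band-pass removes DC, keeps 5 Hz and attenuates 30 Hz", {
  rate <- 1000
  t <- seq(0, 20, by = 1 / rate)
  dc <- make_rec(matrix(7, 1, length(t)), rate)
  out <- bandpass_and_resample(dc)
  expect_lt(max(abs(out$data)), 1e-4)   # > 90 dB DC suppression
  expect_equal(out$rate, 100)

  s5 <- make_rec(matrix(sin(2 * pi * 5 * t), 1), rate)
  o5 <- bandpass_and_resample(s5)
  mid <- o5$data[1, 500:1500]
  expect_lt(abs(max(mid) - 1), 0.05)

  s30 <- make_rec(matrix(sin(2 * pi * 30 * t), 1), rate)
  o30 <- bandpass_and_resample(s30)
  rms_out <- sd(o30$data[1, 500:1500])
  rms_in <- sd(sin(2 * pi * 30 * t))
  expect_lt(20 * log10(rms_out / rms_in), -20)
})

test_that("resampling guards Nyquist and integer decimation", {
  rec <- make_rec(matrix(rnorm(5000), 1), 1000)
  expect_error(bandpass_and_resample(rec, high = 60, out_rate = 100),
               "Nyquist")
  expect_error(bandpass_and_resample(rec, out_rate = 300), "divide")
})

test_that("epoch extraction yields 101-sample baseline-corrected windows", {
  rate <- 100
  n <- 3000
  sched <- event_schedule(onset_s = c(5, 8, 11), trial = c(1, 1, 1),
                          repetition = 1:3, object = c(1, 2, 1),
                          seq_position = c(1, 1, 2),
                          is_target = c(TRUE, FALSE, TRUE))
  # constant channel: removed entirely by baseline correction
  X <- matrix(7, 3, n)
  # impulse 0.30 s after the second onset on channel 2
  X[2, round(8 * rate) + 1 + 30] <- X[2, round(8 * rate) + 1 + 30] + 5
  ep <- extract_epochs(make_rec(X, rate), sched)
  expect_equal(dim(ep$windows), c(3, 3, 101))
  expect_equal(ep$windows[1, 1, ], rep(0, 101))
  w2 <- ep$windows[2, 2, ]
  expect_true(which.max(abs(w2)) == 31)    # sample index 30, 0-based
  expect_gt(w2[31], 4.9)

  # events too close to the recording edge are dropped with a warning
  sched_edge <- event_schedule(onset_s = c(0.05, 5), trial = c(1, 1),
                               repetition = c(1, 2), object = c(1, 1),
                               seq_position = c(1, 1),
                               is_target = c(TRUE, TRUE))
  expect_warning(ep2 <- extract_epochs(make_rec(X, rate), sched_edge),
                 "dropped")
  expect_equal(dim(ep2$windows)[1], 1)
})

test_that("baseline correction is idempotent", {
  rate <- 100
  set.seed(8)
  X <- matrix(rnorm(2 * 2000), 2)
  sched <- event_schedule(5, 1, 1, 1, 1, TRUE)
  ep1 <- extract_epochs(make_rec(X, rate), sched)
  # re-epoching the already-corrected window around its own start yields
  # the same window once the (zero-mean) baseline is subtracted again
  base <- rowMeans(X[, (501 - 20):500])
  manual <- X[, 501:601] - base
  expect_equal(ep1$windows[1, , ], manual)
})

test_that("artifact rejection uses a strict peak-to-peak threshold", {
  w <- array(0, dim = c(3, 2, 101))
  w[2, 1, 5] <- 150                       # spike: p2p 150
  w[3, 2, 1] <- 60; w[3, 2, 2] <- -40     # p2p exactly 100
  sched <- event_schedule(c(1, 2, 3), rep(1, 3), 1:3, c(1, 2, 1),
                          c(1, 1, 2), c(TRUE, FALSE, TRUE))
  ep <- reject_artifacts(epoch_set(w, sched, 100, seq(0, 1, 0.01)))
  expect_equal(ep$rejected, c(FALSE, TRUE, FALSE))
})

test_that("prototypes are class-wise Euclidean means", {
  W <- matrix(rnorm(2 * 101), 2)
  wins <- array(NA_real_, dim = c(4, 2, 101))
  wins[1, , ] <- W; wins[2, , ] <- W      # identical targets
  wins[3, , ] <- W; wins[4, , ] <- -W     # symmetric non-targets
  sched <- event_schedule(1:4, rep(1, 4), rep(1, 4), c(1, 1, 2, 2),
                          1:4, c(TRUE, TRUE, FALSE, FALSE))
  pr <- compute_prototypes(epoch_set(wins, sched, 100, seq(0, 1, 0.01)))
  expect_equal(pr$target_mean, W)
  expect_equal(pr$nontarget_mean, matrix(0, 2, 101))

  sched_t <- event_schedule(1:4, rep(1, 4), rep(1, 4), rep(1, 4),
                            1:4, rep(TRUE, 4))
  expect_error(compute_prototypes(
    epoch_set(wins, sched_t, 100, seq(0, 1, 0.01))), "both")
})

test_that("Ledoit-Wolf shrinkage is within [0, 1], SPD, and consistent", {
  set.seed(9)
  for (i in 1:100) {
    X <- matrix(rnorm(30 * 8), 30)
    lw <- ledoit_wolf(X)
    expect_gte(lw$shrinkage, 0)
    expect_lte(lw$shrinkage, 1)
    expect_gt(min(eigen(lw$sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # i.i.d. unit-variance noise converges to the identity
  lw <- ledoit_wolf(matrix(rnorm(20000 * 4), ncol = 4))
  expect_equal(lw$sigma, diag(4), tolerance = 0.05)
  # rank-1 data still give a strictly positive spectrum
  r1 <- tcrossprod(rnorm(50), rnorm(6))
  expect_gt(min(eigen(ledoit_wolf(r1)$sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("xDAWN returns the requested filters and recovers a planted pattern", {
  rate <- 100
  nt <- 101
  found <- logical(20)
  for (seed in 1:20) {
    set.seed(seed)
    nc <- 8
    a <- rnorm(nc); a <- a / sqrt(sum(a^2))   # planted spatial pattern
    erp <- 3 * sin(2 * pi * 3 * seq(0, 1, by = 1 / rate)) *
      exp(-((seq(0, 1, by = 1 / rate) - 0.3) / 0.2)^2)
    K <- 60
    wins <- array(rnorm(K * nc * nt, sd = 1), dim = c(K, nc, nt))
    y <- rep(c(TRUE, FALSE), K / 2)
    for (k in which(y)) wins[k, , ] <- wins[k, , ] + outer(a, erp)
    sched <- event_schedule(seq_len(K) * 2, rep(1:6, each = 10),
                            rep(1, K), rep(1:2, K / 2),
                            rep(1:10, 6), y)
    ep <- epoch_set(wins, sched, rate, seq(0, 1, by = 1 / rate))
    xd <- fit_xdawn(ep)
    expect_equal(dim(xd$Wt), c(2, nc))
    expect_equal(dim(xd$Wnt), c(2, nc))
    # forward model of the leading target filter vs the planted pattern
    Cx <- crossprod(matrix(aperm(ep$windows, c(3, 1, 2)), ncol = nc)) /
      (K * nt)
    pat <- Cx %*% xd$Wt[1, ]
    found[seed] <- abs(sum(pat * a)) / sqrt(sum(pat^2) * sum(a^2)) > 0.95
  }
  expect_gte(mean(found), 0.9)
})

test_that("xDAWN eigenvalues stay flat on noise-only data", {
  ratios <- numeric(5)
  for (seed in 1:5) {
    set.seed(100 + seed)
    K <- 60; nc <- 6; nt <- 101
    wins <- array(rnorm(K * nc * nt), dim = c(K, nc, nt))
    sched <- event_schedule(seq_len(K) * 2, rep(1:6, each = 10),
                            rep(1, K), rep(1:2, K / 2),
                            rep(1:10, 6), rep(c(TRUE, FALSE), K / 2))
    ep <- epoch_set(wins, sched, 100, seq(0, 1, 0.01))
    xd <- fit_xdawn(ep)
    ev <- xd$evals_t
    ratios[seed] <- ev[1] / median(ev)
  }
  expect_lt(mean(ratios), 2)
})

test_that("augmentation stacks prototypes over filtered windows", {
  ep <- tiny_epochs()
  tr <- retained(ep)
  pr <- compute_prototypes(tr)
  xd <- fit_xdawn(tr)
  X0 <- matrix(0, dim(tr$windows)[2], dim(tr$windows)[3])
  A0 <- augment_window(X0, pr, xd)
  expect_equal(dim(A0), c(8, dim(tr$windows)[3]))
  expect_equal(A0[5:8, ], matrix(0, 4, ncol(A0)))
  expect_equal(A0[1:2, ], xd$Wt %*% pr$target_mean)
  expect_equal(A0[3:4, ], xd$Wnt %*% pr$nontarget_mean)
  # prototype rows constant across distinct windows
  A1 <- augment_window(tr$windows[1, , ], pr, xd)
  A2 <- augment_window(tr$windows[2, , ], pr, xd)
  expect_equal(A1[1:4, ], A2[1:4, ])
  expect_false(isTRUE(all.equal(A1[5:8, ], A2[5:8, ])))
  # covariance of the augmented window is 8 x 8 and SPD
  S <- shrinkage_covariance(A1)
  expect_equal(dim(S), c(8, 8))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(augment_window(X0[1:3, ], pr, xd), "shape")
})
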