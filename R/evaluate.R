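## Evaluation protocol: chronological cross-validation at the trial level,
## the reduced (first-repetition) data condition, window-level AUC, grand
## averages, and paired pipeline comparison statistics.

#' Chronological fold assignment over trials
#'
#' Trials are ordered by their first onset and split into `k` contiguous
#' blocks of near-equal size; all windows of a trial share its fold, so no
#' trial straddles the train/test boundary and no test trial precedes
#' training data from a later time.
#'
#' @param sched an [event_schedule()].
#' @param k number of folds (default 5).
#' @return Integer fold id per schedule row, with the trial-level map in
#'   attribute `"trial_fold"`.
#' @export
chronological_folds <- function(sched, k = 5L) {
  first <- vapply(split(sched$onset_s, sched$trial), min, numeric(1))
  trials <- as.integer(names(sort(first)))
  n <- length(trials)
  if (n < k) stop("fewer trials (", n, ") than folds (", k, ")")
  fold_of_trial <- rep(seq_len(k), diff(round(seq(0, n, length.out = k + 1))))
  names(fold_of_trial) <- trials
  fold <- unname(fold_of_trial[as.character(sched$trial)])
  attr(fold, "trial_fold") <- fold_of_trial
  fold
}

#' Restrict a schedule to the first repetition of every trial
#'
#' The reduced-data condition: keeping only repetition 1 retains one third
#' of the windows of a three-repetition design while preserving per-object
#' class balance (the design is interleaved).
#'
#' @param sched an [event_schedule()].
#' @return Logical mask over schedule rows (`TRUE` = keep).
#' @export
reduced_data_view <- function(sched) {
  sched$repetition == 1L
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The probability that a uniformly drawn target window outscores a
#' uniformly drawn non-target window, ties counted one half; computed from
#' midranks.
#'
#' @param scores numeric decision values.
#' @param labels logical (or coercible), `TRUE` = target.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || !any(!y))
    stop("AUC needs both classes present")
  r <- rank(scores)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grand-average waveforms by object, sequence position group and class
#'
#' Elementwise mean window per group, together with the window counts the
#' averages are based on. By default averages are computed before artifact
#' rejection, matching how grand averages are usually reported.
#'
#' @param ep an [epoch_set()].
#' @param use_rejected include rejected windows (default TRUE).
#' @return List of class `"grand_average"`: `groups` (data frame with
#'   object, position_group, class and count) and `waveforms` (list of
#'   channels x times matrices, aligned with `groups` rows).
#' @export
grand_average <- function(ep, use_rejected = TRUE) {
  stopifnot(inherits(ep, "epoch_set"))
  if (!use_rejected) ep <- retained(ep)
  s <- ep$schedule
  key <- interaction(s$object, s$position_group, s$is_target, drop = TRUE)
  groups <- do.call(rbind, lapply(levels(key), function(lv) {
    sel <- key == lv
    data.frame(object = s$object[which(sel)[1]],
               position_group = as.character(s$position_group[which(sel)[1]]),
               class = if (s$is_target[which(sel)[1]]) "t" else "nt",
               count = sum(sel))
  }))
  waveforms <- lapply(levels(key), function(lv) {
    apply(ep$windows[key == lv, , , drop = FALSE], c(2, 3), mean)
  })
  structure(list(groups = groups, waveforms = waveforms, times = ep$times),
            class = "grand_average")
}

#' Run one pipeline through chronological cross-validation
#'
#' Fits the pipeline on the training trials of each fold and scores the
#' test-fold windows; prototypes, filters, references and classifiers see
#' training data only. Rejected windows are excluded from fitting and from
#' the reported AUC.
#'
#' @param ep a preprocessed, artifact-marked [epoch_set()] of a full
#'   session.
#' @param variant,subclass_by passed to [fit_pipeline()].
#' @param k number of chronological folds (default 5).
#' @param fraction `1.0` for the full data or `0.33` for the
#'   first-repetition-only condition.
#' @param pooled logical: also return the AUC over the pooled scores of all
#'   folds.
#' @param ... further arguments to [fit_pipeline()].
#' @return List of class `"cv_result"`: `fold_auc`, `mean_auc`,
#'   `pooled_auc`, `variant`, `fraction`.
#' @export
evaluate_session <- function(ep, variant = "ts_lda", subclass_by = "object",
                             k = 5L, fraction = 1.0, pooled = FALSE, ...) {
  stopifnot(inherits(ep, "epoch_set"))
  if (fraction < 1) ep <- ep[reduced_data_view(ep$schedule)]
  fold <- chronological_folds(ep$schedule, k)
  fold_auc <- numeric(k)
  all_scores <- numeric(0); all_y <- logical(0)
  for (f in seq_len(k)) {
    train <- ep[fold != f]
    test <- retained(ep[fold == f])
    model <- fit_pipeline(train, variant, subclass_by, ...)
    sc <- predict_window_scores(model, test)
    fold_auc[f] <- auc(sc, test$schedule$is_target)
    if (pooled) {
      all_scores <- c(all_scores, sc)
      all_y <- c(all_y, test$schedule$is_target)
    }
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 pooled_auc = if (pooled) auc(all_scores, all_y) else NA_real_,
                 variant = variant, fraction = fraction),
            class = "cv_result")
}

#' Cross-validate several pipeline variants on shared per-fold state
#'
#' Like [evaluate_session()] but fits all requested variants on each
#' training fold using one set of prototypes, filters and covariances
#' ([pipeline_shared()]), which is substantially faster than evaluating
#' the variants independently. Results are identical to per-variant runs.
#'
#' @inheritParams evaluate_session
#' @param variants character vector of pipeline variants.
#' @return Data frame with one row per variant x fold and the window AUC.
#' @export
evaluate_variants <- function(ep, variants = c("ts_lda", "sep_ts_lda",
                                               "cts_reg_lda"),
                              subclass_by = "object", k = 5L,
                              fraction = 1.0, ...) {
  stopifnot(inherits(ep, "epoch_set"))
  if (fraction < 1) ep <- ep[reduced_data_view(ep$schedule)]
  fold <- chronological_folds(ep$schedule, k)
  rows <- list()
  for (f in seq_len(k)) {
    train <- retained(ep[fold != f])
    test <- retained(ep[fold == f])
    shared <- pipeline_shared(train)
    test_covs <- epoch_covariances(test, shared$proto, shared$xd)
    for (v in variants) {
      model <- fit_pipeline(train, v, subclass_by, shared = shared, ...)
      sc <- score_with_covs(model, test_covs, test$schedule)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = v, fold = f,
                   auc = auc(sc, test$schedule$is_target))
    }
  }
  do.call(rbind, rows)
}

## Wilcoxon signed-rank with Pratt handling of zero differences and a
## tie-corrected normal approximation; used above the exact regime.
.wilcoxon_pratt <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  Wp <- sum(r[nz & d > 0])
  n <- length(d)
  mu <- (n * (n + 1) / 2 - sum(r[!nz])) / 2
  ties <- table(r)
  ## variance: full ranks minus the zero-rank block, with tie correction
  sig2 <- (n * (n + 1) * (2 * n + 1)) / 24 -
    sum(r[!nz]^2) / 4 -
    sum(ties^3 - ties) / 48
  z <- (Wp - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

#' Paired comparison of pipelines across participants
#'
#' Two-sided Wilcoxon signed-rank tests on per-participant AUC differences
#' (exact null for n <= 25 without zeros or ties, otherwise a normal
#' approximation with Pratt handling of zeros and tie correction), with
#' Holm-Bonferroni adjustment across the comparison family.
#'
#' @param ... one or more two-column comparisons: each argument is a list
#'   or data frame with elements `a` and `b`, paired per-participant AUC
#'   vectors. A single pair may also be given as
#'   `compare_pipelines(a = x, b = y)`.
#' @param alpha family significance level (default 0.05).
#' @return Data frame with one row per comparison: median paired
#'   difference, raw and Holm-adjusted p-values, and significance at
#'   `alpha`.
#' @export
compare_pipelines <- function(..., alpha = 0.05) {
  args <- list(...)
  if (!is.null(names(args)) && setequal(names(args), c("a", "b")))
    args <- list(args)
  res <- lapply(args, function(cmp) {
    a <- cmp$a; b <- cmp$b
    if (length(a) != length(b) || length(a) < 5L)
      stop("paired vectors of common length >= 5 are required")
    d <- a - b
    if (all(d == 0)) {
      return(data.frame(median_diff = 0, p = 1, note = "no difference"))
    }
    p <- if (length(d) <= 25L && !any(d == 0) &&
             !any(duplicated(abs(d)))) {
      stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    } else {
      .wilcoxon_pratt(d)
    }
    data.frame(median_diff = median(d), p = p, note = "")
  })
  out <- do.call(rbind, res)
  nm <- names(args)
  rownames(out) <- if (!is.null(nm) && all(nzchar(nm))) nm else NULL
  out$p_holm <- p.adjust(out$p, method = "holm")
  out$significant <- out$p_holm <= alpha
  out
}

#' Simulate-and-evaluate experiment matrix
#'
#' Runs the full preprocessing + decoding chain (band-pass to 100 Hz,
#' epoching, 100 uV rejection, pipeline fitting, chronological CV) for
#' every combination of pipeline variant, data fraction and simulated
#' participant seed under one simulator configuration.
#'
#' @param cfg a [session_config()]; its `seed` field is replaced by each
#'   entry of `seeds` in turn (one simulated participant per seed).
#' @param seeds integer vector of participant seeds.
#' @param variants pipeline variants to evaluate.
#' @param fractions data fractions (subset of `c(0.33, 1)`).
#' @param subclass_by subclass definition for the subclass-aware variants.
#' @param k CV folds.
#' @return Data frame with one row per participant x variant x fraction,
#'   holding the fold-mean AUC.
#' @export
run_experiment <- function(cfg, seeds,
                           variants = c("ts_lda", "sep_ts_lda",
                                        "cts_reg_lda"),
                           fractions = c(0.33, 1), subclass_by = "object",
                           k = 5L) {
  rows <- list()
  for (sd_ in seeds) {
    cfg$seed <- as.integer(sd_)
    ses <- simulate_session(cfg)
    rec <- bandpass_and_resample(ses$recording)
    ep <- reject_artifacts(extract_epochs(rec, ses$schedule))
    for (fr in fractions) {
      res <- evaluate_variants(ep, variants, subclass_by, k = k,
                               fraction = fr)
      for (v in variants) {
        rows[[length(rows) + 1L]] <-
          data.frame(seed = sd_, variant = v, fraction = fr,
                     mean_auc = mean(res$auc[res$variant == v]))
      }
    }
  }
  do.call(rbind, rows)
}
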