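## The three classification pipelines: pooled tangent-space LDA (TS+LDA),
## separate per-subclass classifiers (sep. TS+LDA), and parallel-transport
## centered, multi-target-shrinkage regularized LDA (cTS+reg-LDA).

#' Shrunk window covariances for an epoch set
#'
#' Augments every window with the fitted prototypes/filters and returns the
#' Ledoit-Wolf shrunk covariance of each augmented window.
#'
#' @param ep an [epoch_set()].
#' @param proto a `"prototype_pair"`.
#' @param xd an `"xdawn_model"`.
#' @return List of SPD matrices, one per window.
#' @export
epoch_covariances <- function(ep, proto, xd) {
  stopifnot(inherits(ep, "epoch_set"), inherits(proto, "prototype_pair"),
            inherits(xd, "xdawn_model"))
  proto_rows <- rbind(xd$Wt %*% proto$target_mean,
                      xd$Wnt %*% proto$nontarget_mean)
  arr <- .augmented_lw_covs_cpp(aperm(ep$windows, c(2, 3, 1)),
                                proto_rows, xd$Wt, xd$Wnt)
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' Project covariances to tangent-space feature vectors
#'
#' In `pooled` mode every covariance is log-mapped at the single reference
#' `references` (typically the training Frechet mean). In
#' `per_subclass_centered` mode each covariance is first parallel
#' transported to the identity using its subclass's reference from the
#' named list `references`, then log-mapped at the identity. Vectors use
#' the Frobenius-preserving vectorization of [tangent_vectorize()].
#'
#' @param covs list of SPD matrices.
#' @param references an SPD matrix (pooled) or a named list of SPD matrices
#'   keyed by subclass label (centered).
#' @param mode `"pooled"` or `"per_subclass_centered"`.
#' @param subclass character vector of subclass labels per covariance
#'   (centered mode only).
#' @return K x n(n+1)/2 feature matrix.
#' @export
featurize <- function(covs, references,
                      mode = c("pooled", "per_subclass_centered"),
                      subclass = NULL) {
  mode <- match.arg(mode)
  n <- nrow(covs[[1]])
  batch <- function(cc, ref) {
    .tangent_features_cpp(array(unlist(cc), dim = c(n, n, length(cc))),
                          .sym_check(ref, what = "reference"))
  }
  if (mode == "pooled") {
    feats <- batch(covs, references)
  } else {
    if (is.null(subclass) || length(subclass) != length(covs))
      stop("centered mode needs one subclass label per covariance")
    unknown <- setdiff(unique(subclass), names(references))
    if (length(unknown))
      stop("no reference for subclass(es): ", paste(unknown, collapse = ", "))
    ## transporting a subclass to the identity and taking the log map at I
    ## is the same whitening-log as a direct log map at the subclass
    ## reference, so both modes share the batched kernel
    feats <- matrix(NA_real_, length(covs), n * (n + 1) / 2)
    for (j in unique(subclass)) {
      sel <- subclass == j
      feats[sel, ] <- batch(covs[sel], references[[j]])
    }
  }
  feats
}

#' Precompute the variant-independent training state
#'
#' Prototypes, xDAWN filters, window covariances, the pooled Frechet mean
#' and the pooled fallback LDA are identical for all pipeline variants
#' fitted on the same training data; computing them once and passing the
#' result to [fit_pipeline()] (argument `shared`) avoids repeating the
#' work when several variants are compared.
#'
#' @param train an [epoch_set()] of retained training windows.
#' @param n_components_per_class xDAWN components per class.
#' @return List with `proto`, `xd`, `covs`, `Cm`, `lda_pooled`.
#' @export
pipeline_shared <- function(train, n_components_per_class = 2L) {
  proto <- compute_prototypes(train)
  xd <- fit_xdawn(train, n_components_per_class)
  covs <- epoch_covariances(train, proto, xd)
  Cm <- frechet_mean(covs)
  lda_pooled <- fit_lda(featurize(covs, Cm, "pooled"),
                        train$schedule$is_target)
  list(proto = proto, xd = xd, covs = covs, Cm = Cm,
       lda_pooled = lda_pooled)
}

.make_lda <- function(mu_t, mu_nt, Clda) {
  w <- solve(Clda, mu_t - mu_nt)
  structure(list(w = w, b = -sum(w * (mu_t + mu_nt)) / 2, mu_t = mu_t,
                 mu_nt = mu_nt, C_lda = Clda, shrinkage = NA_real_),
            class = "lda_model")
}

## Pooled within-class covariance of centered tangent vectors: every
## subclass x class cell is centered at its own mean, then one Ledoit-Wolf
## estimate over the pooled residuals.
.cellwise_scatter <- function(X, y, j_lab) {
  Xc <- X
  for (j in unique(j_lab)) for (cl in c(TRUE, FALSE)) {
    sel <- j_lab == j & y == cl
    if (sum(sel) > 0)
      Xc[sel, ] <- sweep(X[sel, , drop = FALSE], 2L,
                         colMeans(X[sel, , drop = FALSE]))
  }
  ledoit_wolf(Xc, center = FALSE)$sigma
}

#' Fit a tangent-space ERP classification pipeline
#'
#' Fits one of the three pipeline variants on the non-rejected windows of a
#' training epoch set:
#' \describe{
#'   \item{`ts_lda`}{one Frechet mean of all training covariances, one LDA
#'     on the pooled tangent vectors (subclasses ignored).}
#'   \item{`sep_ts_lda`}{per subclass, its own Frechet mean, tangent space
#'     and LDA, fitted only on that subclass's windows.}
#'   \item{`cts_reg_lda`}{each subclass is centered by parallel transport of
#'     its covariances to the identity; per-subclass LDA class means are
#'     replaced by multi-target-shrunk combinations across subclasses
#'     ([mts_weights()]), and the within-class covariance is pooled over all
#'     centered subclasses.}
#' }
#' Prototypes and xDAWN filters are fitted once on the pooled training data
#' and shared by all variants. A pooled `ts_lda` submodel is always fitted
#' alongside as the fallback for subclasses unseen at prediction time.
#'
#' @param ep training [epoch_set()]; rejected windows are excluded.
#' @param variant `"ts_lda"`, `"sep_ts_lda"` or `"cts_reg_lda"`.
#' @param subclass_by subclass definition: `"object"` (default),
#'   `"position_group"` or `"position"`.
#' @param mts logical; disable to force all MTS weights to zero
#'   (`cts_reg_lda` only).
#' @param pooled_scatter logical; use the pooled within-class covariance
#'   (default). `FALSE` gives per-subclass scatter, under which
#'   `cts_reg_lda` with `mts = FALSE` reproduces `sep_ts_lda` exactly.
#' @param n_components_per_class xDAWN components per class (default 2).
#' @param shared optional precomputed prototype/filter/covariance state
#'   from [pipeline_shared()], so several variants can be fitted on the
#'   same training fold without redoing the shared work.
#' @return Object of class `"pipeline_model"`.
#' @export
fit_pipeline <- function(ep,
                         variant = c("ts_lda", "sep_ts_lda", "cts_reg_lda"),
                         subclass_by = c("object", "position_group",
                                         "position"),
                         mts = TRUE, pooled_scatter = TRUE,
                         n_components_per_class = 2L, shared = NULL) {
  variant <- match.arg(variant)
  subclass_by <- match.arg(subclass_by)
  stopifnot(inherits(ep, "epoch_set"))
  train <- retained(ep)
  y <- train$schedule$is_target
  if (!any(y) || !any(!y))
    stop("training data must contain both classes")
  j_lab <- .subclass_labels(train$schedule, subclass_by)

  if (is.null(shared)) shared <- pipeline_shared(train, n_components_per_class)
  proto <- shared$proto
  xd <- shared$xd
  covs <- shared$covs
  Cm <- shared$Cm
  lda_pooled <- shared$lda_pooled

  refs <- NULL; ldas <- NULL; mts_w <- NULL
  if (variant != "ts_lda") {
    labs <- sort(unique(j_lab))
    for (j in labs) {
      yj <- y[j_lab == j]
      if (!any(yj) || !any(!yj))
        stop("subclass '", j, "' is missing one class; cannot fit ", variant)
    }
    refs <- lapply(labs, function(j) frechet_mean(covs[j_lab == j]))
    names(refs) <- labs
    if (variant == "sep_ts_lda") {
      ldas <- lapply(labs, function(j) {
        sel <- j_lab == j
        Xj <- featurize(covs[sel], refs[[j]], "pooled")
        fit_lda(Xj, y[sel])
      })
      names(ldas) <- labs
    } else {
      X <- featurize(covs, refs, "per_subclass_centered", subclass = j_lab)
      Cshared <- if (pooled_scatter) .cellwise_scatter(X, y, j_lab) else NULL
      ldas <- list(); mts_w <- list()
      pooled_mu <- list(t = colMeans(X[y, , drop = FALSE]),
                        nt = colMeans(X[!y, , drop = FALSE]))
      for (j in labs) {
        sel <- j_lab == j
        mu <- list(); wts <- list()
        for (i in c("t", "nt")) {
          cl <- if (i == "t") y else !y
          if (sum(sel & cl) < 2L) {
            warning("subclass '", j, "' has < 2 windows of class '", i,
                    "'; using the pooled class mean")
            mu[[i]] <- pooled_mu[[i]]
            wts[[i]] <- NULL
          } else if (mts && length(labs) > 1L) {
            wts[[i]] <- mts_weights(X, y, j_lab, j, i)
            mu[[i]] <- mts_shrunk_mean(X, y, j_lab, j, i, wts[[i]])
          } else {
            mu[[i]] <- colMeans(X[sel & cl, , drop = FALSE])
            wts[[i]] <- NULL
          }
        }
        Cj <- if (pooled_scatter) Cshared else {
          Xj <- X[sel, , drop = FALSE]
          yj <- y[sel]
          Xc <- Xj
          Xc[yj, ] <- sweep(Xj[yj, , drop = FALSE], 2L,
                            colMeans(Xj[yj, , drop = FALSE]))
          Xc[!yj, ] <- sweep(Xj[!yj, , drop = FALSE], 2L,
                             colMeans(Xj[!yj, , drop = FALSE]))
          ledoit_wolf(Xc, center = FALSE)$sigma
        }
        ldas[[j]] <- .make_lda(mu$t, mu$nt, Cj)
        mts_w[[j]] <- wts
      }
    }
  }
  structure(list(variant = variant, subclass_by = subclass_by,
                 proto = proto, xdawn = xd, Cm = Cm,
                 lda_pooled = lda_pooled, refs = refs, ldas = ldas,
                 mts = mts_w, mts_enabled = mts,
                 pooled_scatter = pooled_scatter),
            class = "pipeline_model")
}

#' @export
print.pipeline_model <- function(x, ...) {
  cat(sprintf("<pipeline_model> variant = %s, subclasses by %s (%s)\n",
              x$variant, x$subclass_by,
              if (is.null(x$refs)) "pooled"
              else paste(names(x$refs), collapse = ", ")))
  invisible(x)
}

#' Score windows with a fitted pipeline
#'
#' Each window's covariance is routed to its subclass's reference and
#' classifier (or the single pooled one for `ts_lda`); the returned LDA
#' decision values are higher for more target-like windows. Windows of a
#' subclass unseen during fitting fall back to the pooled model, with a
#' warning.
#'
#' @param model a fitted `"pipeline_model"`.
#' @param ep an [epoch_set()] to score (all windows are scored; apply
#'   [retained()] first to exclude artifacts).
#' @return Numeric vector of decision values aligned with the windows.
#' @export
predict_window_scores <- function(model, ep) {
  stopifnot(inherits(model, "pipeline_model"), inherits(ep, "epoch_set"))
  covs <- epoch_covariances(ep, model$proto, model$xdawn)
  score_with_covs(model, covs, ep$schedule)
}

#' Score precomputed window covariances with a fitted pipeline
#'
#' Covariance computation depends only on the shared prototypes and
#' filters, so when several variants fitted via [pipeline_shared()] score
#' the same test windows the covariances can be computed once with
#' [epoch_covariances()] and passed here.
#'
#' @param model a fitted `"pipeline_model"`.
#' @param covs list of SPD window covariances (from the model's own
#'   prototypes/filters).
#' @param sched the schedule rows aligned with `covs`.
#' @return Numeric decision values.
#' @export
score_with_covs <- function(model, covs, sched) {
  K <- length(covs)
  if (model$variant == "ts_lda") {
    return(predict(model$lda_pooled, featurize(covs, model$Cm, "pooled")))
  }
  j_lab <- .subclass_labels(sched, model$subclass_by)
  scores <- numeric(K)
  for (j in unique(j_lab)) {
    sel <- j_lab == j
    if (is.null(model$refs[[j]])) {
      warning("subclass '", j, "' was not seen during fitting; ",
              "falling back to the pooled classifier")
      scores[sel] <- predict(model$lda_pooled,
                             featurize(covs[sel], model$Cm, "pooled"))
    } else if (model$variant == "sep_ts_lda") {
      scores[sel] <- predict(model$ldas[[j]],
                             featurize(covs[sel], model$refs[[j]], "pooled"))
    } else {
      X <- featurize(covs[sel], model$refs[j], "per_subclass_centered",
                     subclass = rep(j, sum(sel)))
      scores[sel] <- predict(model$ldas[[j]], X)
    }
  }
  scores
}

#' Select the attended object of a trial from window scores
#'
#' Candidate objects are scored by the mean decision value of their windows
#' within the trial; the argmax wins and exact ties go to the lowest object
#' id. The mean (rather than the sum) keeps trials with rejected windows
#' comparable.
#'
#' @param scores decision values aligned with `sched` rows.
#' @param sched the corresponding [event_schedule()] rows.
#' @param trial trial id to decide; `NULL` (default) decides every trial.
#' @return Integer object id (or a named vector over trials).
#' @export
select_object <- function(scores, sched, trial = NULL) {
  stopifnot(length(scores) == nrow(sched))
  if (is.null(trial)) {
    trials <- unique(sched$trial)
    out <- vapply(trials, function(tr) select_object(scores, sched, tr),
                  integer(1))
    names(out) <- trials
    return(out)
  }
  sel <- sched$trial == trial & !is.na(scores)
  if (!any(sel)) stop("trial ", trial, " has no scored windows")
  cand <- sort(unique(sched$object[sched$trial == trial]))
  ms <- vapply(cand, function(ob) {
    s <- scores[sel & sched$object == ob]
    if (!length(s)) {
      warning("object ", ob, " has no scored windows in trial ", trial,
              "; excluded")
      -Inf
    } else mean(s)
  }, numeric(1))
  cand[which.max(ms)]   # which.max takes the first (lowest id) on ties
}
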