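#' Leave-one-out cross-validation splits
#'
#' @param n_subjects Number of subjects `N` (`>= 6`; fewer leaves too
#'   little for a robust per-edge fit).
#' @return A list of `N` splits, each `list(train, test)` with `train` of
#'   size `N - 1` excluding exactly the left-out index `test = k`.
#' @export
loo_splits <- function(n_subjects) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 6L) {
    stop("leave-one-out needs at least 6 subjects", call. = FALSE)
  }
  lapply(seq_len(n_subjects), function(k) {
    list(train = seq_len(n_subjects)[-k], test = k)
  })
}

#' Run the full CPM pipeline under leave-one-out cross-validation
#'
#' For each fold: screen edges on the `N - 1` training subjects
#' ([select_edges()]), fit the positive and negative summary regressions on
#' the training summary values, apply the fold's masks to the left-out
#' subject, and record its two predicted scores.  The left-out subject
#' never influences its own fold's selection or models.  Per-fold
#' association values of selected edges and the per-fold masks are retained
#' for [normalized_rank()] and [consistent_edges()].
#'
#' Folds in which a side selects no edges are *degenerate* on that side:
#' the prediction falls back to the training mean, the fold still counts
#' toward `N`, and the count is reported.
#'
#' @param cohort A [cohort()].
#' @param config A [cpm_config()].
#' @param verbose If `TRUE`, report each fold as it completes.
#' @return A `cpm_cv` object: `observed`, `pos_pred`, `neg_pred`
#'   (length-`N`), logical `N x E` matrices `pos_masks` / `neg_masks`,
#'   numeric `N x E` `fold_r` (association values of selected edges, 0
#'   elsewhere), per-fold `models`, `degenerate` counts per side,
#'   `subject_id`, `n_folds`, `n_rois`, and the `config`.
#' @export
run_cpm_loo <- function(cohort, config = cpm_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "cpm_cohort"), inherits(config, "cpm_config"))
  X <- cohort$edges
  y <- cohort$scores
  N <- nrow(X)
  E <- ncol(X)
  splits <- loo_splits(N)
  pos_masks <- neg_masks <- matrix(FALSE, N, E)
  fold_r <- matrix(0, N, E)
  pos_pred <- neg_pred <- numeric(N)
  models <- vector("list", N)
  degen <- c(positive = 0L, negative = 0L)
  for (sp in splits) {
    k <- sp$test
    tr <- sp$train
    sel <- withCallingHandlers(
      select_edges(X[tr, , drop = FALSE], y[tr], config),
      warning = function(w) {
        if (verbose) message("fold ", k, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tr_sum <- summary_values(X[tr, , drop = FALSE], sel,
                             summary = config$summary)
    pos_model <- suppressWarnings(
      fit_summary_model(tr_sum$pos_sum, y[tr], "positive"))
    neg_model <- suppressWarnings(
      fit_summary_model(tr_sum$neg_sum, y[tr], "negative"))
    te_sum <- summary_values(X[k, ], sel, summary = config$summary)
    pos_pred[k] <- predict_score(pos_model, te_sum$pos_sum)
    neg_pred[k] <- predict_score(neg_model, te_sum$neg_sum)
    pos_masks[k, ] <- sel$pos_mask
    neg_masks[k, ] <- sel$neg_mask
    any_sel <- sel$pos_mask | sel$neg_mask
    fold_r[k, any_sel] <- sel$r[any_sel]
    models[[k]] <- list(positive = pos_model, negative = neg_model)
    degen <- degen + c(pos_model$degenerate, neg_model$degenerate)
    if (verbose) {
      message(sprintf("fold %d/%d: %d pos, %d neg edges selected",
                      k, N, sum(sel$pos_mask), sum(sel$neg_mask)))
    }
  }
  if (any(degen > 0L)) {
    message("degenerate folds (mean-fallback predictions): ",
            degen[["positive"]], " positive, ",
            degen[["negative"]], " negative")
  }
  structure(list(observed = y, pos_pred = pos_pred, neg_pred = neg_pred,
                 pos_masks = pos_masks, neg_masks = neg_masks,
                 fold_r = fold_r, models = models, degenerate = degen,
                 subject_id = cohort$phenotype$subject_id,
                 n_folds = N, n_rois = cohort$n_rois, config = config),
            class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  ev_p <- suppressWarnings(evaluate_predictions(x$pos_pred, x$observed))
  ev_n <- suppressWarnings(evaluate_predictions(x$neg_pred, x$observed))
  cat(sprintf("CPM leave-one-out run: %d folds, %d edges (%s, p < %g)\n",
              x$n_folds, ncol(x$pos_masks), x$config$method, x$config$alpha))
  cat(sprintf("  positive model: r = %.3f, r^2 = %.3f, p = %.3g\n",
              ev_p$r, ev_p$r_squared, ev_p$p))
  cat(sprintf("  negative model: r = %.3f, r^2 = %.3f, p = %.3g\n",
              ev_n$r, ev_n$r_squared, ev_n$p))
  invisible(x)
}

#' Evaluate out-of-fold predictions against observed scores
#'
#' Pearson correlation of predicted versus observed scores, its square,
#' and the two-tailed t-based p-value -- the conventional headline numbers
#' of a CPM run.  If every fold was degenerate the predictions are
#' constant and the evaluation is `r = 0, p = 1` with a warning.
#'
#' @param predicted,observed Aligned numeric vectors (length `>= 3`);
#'   `observed` must be non-constant.
#' @return A `cpm_evaluation` list: `r`, `r_squared`, `p`, `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(observed) == 0) {
    stop("observed scores are constant", call. = FALSE)
  }
  if (stats::sd(predicted) == 0) {
    warning("constant predictions (all folds degenerate?); r set to 0",
            call. = FALSE)
    res <- list(r = 0, p = 1)
  } else {
    res <- pearson_association(predicted, observed)
  }
  structure(list(r = res$r, r_squared = res$r^2, p = res$p,
                 n = length(observed)),
            class = "cpm_evaluation")
}

#' @export
print.cpm_evaluation <- function(x, ...) {
  cat(sprintf("prediction evaluation (n = %d): r = %.3f, r^2 = %.3f, p = %.3g\n",
              x$n, x$r, x$r_squared, x$p))
  invisible(x)
}

#' Edges selected in every fold
#'
#' The strict cross-validation consistency rule: an edge belongs to the
#' reported network only if it was selected, on the given side, in all `N`
#' leave-one-out folds.
#'
#' @param run A `cpm_cv` from [run_cpm_loo()].
#' @param side `"positive"` or `"negative"`.
#' @return Logical edge mask of length `E`.
#' @export
consistent_edges <- function(run, side = c("positive", "negative")) {
  side <- match.arg(side)
  stopifnot(inherits(run, "cpm_cv"))
  masks <- if (side == "positive") run$pos_masks else run$neg_masks
  colSums(masks) == run$n_folds
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance two-tailed t-test computed from group means, SDs and
#' sizes (as used to compare cohort demographics), with the
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 First group summary statistics (`n1 >= 2`,
#'   `sd1 > 0`).
#' @param mean2,sd2,n2 Second group.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(!is.finite(c(mean1, sd1, n1, mean2, sd2, n2)))) {
    stop("non-finite inputs", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = two_tailed_p(tstat, df))
}
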