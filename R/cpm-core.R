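#' CPM configuration
#'
#' Collects the tunable parameters of the pipeline.  `alpha` is the raw
#' per-edge significance threshold of the screening step (no
#' multiple-testing correction is applied: the screen is deliberately a
#' bare threshold, with cross-validation providing the guard against
#' overfitting).  `method` picks the per-edge association estimator:
#' `"robust"` (Huber IRLS, the default) or `"pearson"`.  `summary` chooses
#' how selected edge weights are summed into the network summary value:
#' `"raw"` sums the signed weights of the selected edges; `"clipped"` keeps
#' only positive weights on the positive side and negative weights on the
#' negative side.
#'
#' @param alpha Per-edge significance threshold in `(0, 1]` (default 0.01).
#' @param method `"robust"` or `"pearson"`.
#' @param summary `"raw"` or `"clipped"`.
#' @param huber_c Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param irls_max_iter IRLS iteration cap (default 50).
#' @param irls_tol Convergence tolerance on the max coefficient change
#'   (default 1e-8).
#' @return A `cpm_config` list.
#' @export
cpm_config <- function(alpha = 0.01, method = c("robust", "pearson"),
                       summary = c("raw", "clipped"),
                       huber_c = 1.345, irls_max_iter = 50L,
                       irls_tol = 1e-8) {
  stopifnot(alpha > 0, alpha <= 1, huber_c > 0,
            irls_max_iter >= 1, irls_tol > 0)
  structure(list(alpha = alpha, method = match.arg(method),
                 summary = match.arg(summary), huber_c = huber_c,
                 irls_max_iter = as.integer(irls_max_iter),
                 irls_tol = irls_tol),
            class = "cpm_config")
}

two_tailed_p <- function(tstat, df) 2 * stats::pt(-abs(tstat), df)

#' Pearson association between one edge and the score
#'
#' Pearson correlation with the two-tailed p-value of the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (identical to the t-test of the simple-regression slope).  A constant
#' edge carries no association and returns `r = 0, p = 1` by convention.
#'
#' @param x Edge weights across subjects.
#' @param y Scores, non-constant, same length (`n >= 3`).
#' @return List with `r`, `p`, `slope`, `intercept`, `method = "pearson"`.
#' @export
pearson_association <- function(x, y) {
  check_xy(x, y, n_min = 3L)
  res <- edge_association(matrix(x, ncol = 1L), y, method = "pearson")
  list(r = res$r[1L], p = res$p[1L], slope = res$slope[1L],
       intercept = res$intercept[1L], method = "pearson")
}

#' Robust (Huber IRLS) association between one edge and the score
#'
#' Fits `y = a + b * x` by iteratively reweighted least squares with Huber
#' weights `w = min(1, c * s / |resid|)`, tuning constant `c` (default
#' 1.345) and scale `s = 1.4826 * median(|resid|)` re-estimated each
#' iteration; iteration stops when the largest coefficient change falls
#' below `tol` or after `max_iter` iterations (then the last iterate is
#' returned with a warning).  If the residual MAD is zero the fit is
#' exactly ordinary least squares.
#'
#' The p-value is the two-tailed t-test of the slope using the final
#' weighted covariance on `n - 2` degrees of freedom.  `r` is the weighted
#' Pearson correlation of `x` and `y` under the final IRLS weights, which
#' shares the slope's sign by construction.
#'
#' @param x Edge weights across subjects (`n >= 5`).
#' @param y Scores, same length.
#' @param huber_c,max_iter,tol IRLS controls; see [cpm_config()].
#' @return List with `r`, `p`, `slope`, `intercept`, `weights` (final IRLS
#'   weights in `(0, 1]`), `iterations`, `converged`, `method = "robust"`.
#' @export
robust_association <- function(x, y, huber_c = 1.345, max_iter = 50L,
                               tol = 1e-8) {
  check_xy(x, y, n_min = 5L)
  res <- edge_association(matrix(x, ncol = 1L), y, method = "robust",
                          huber_c = huber_c, max_iter = max_iter, tol = tol,
                          keep_weights = TRUE)
  list(r = res$r[1L], p = res$p[1L], slope = res$slope[1L],
       intercept = res$intercept[1L], weights = res$weights[, 1L],
       iterations = res$iterations, converged = res$converged[1L],
       method = "robust")
}

check_xy <- function(x, y, n_min) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < n_min) {
    stop("need at least ", n_min, " observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("y is constant", call. = FALSE)
  invisible(TRUE)
}

#' Per-edge association sweep over a training block
#'
#' Applies [pearson_association()] or [robust_association()] to every
#' column of an `N x E` edge-weight matrix against one score vector,
#' vectorized across edges (all edges share the IRLS iteration loop).
#' Constant edges get `r = 0, p = 1, slope = 0`.
#'
#' @param X Numeric `N x E` matrix of training edge weights.
#' @param y Numeric length-`N` score vector, non-constant.
#' @param method `"robust"` or `"pearson"`.
#' @param huber_c,max_iter,tol IRLS controls (robust method only).
#' @param keep_weights If `TRUE`, return the final `N x E` IRLS weight
#'   matrix (memory-heavy for large `E`; off by default).
#' @return List with numeric length-`E` vectors `r`, `p`, `slope`,
#'   `intercept`, logical `converged`, scalar `iterations`, and optionally
#'   `weights`.
#' @export
edge_association <- function(X, y, method = c("robust", "pearson"),
                             huber_c = 1.345, max_iter = 50L, tol = 1e-8,
                             keep_weights = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match nrow(X)", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant", call. = FALSE)
  if (method == "pearson") {
    return(pearson_sweep(X, y))
  }
  huber_sweep(X, y, huber_c = huber_c, max_iter = max_iter, tol = tol,
              keep_weights = keep_weights)
}

pearson_sweep <- function(X, y) {
  n <- nrow(X)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  xm <- colMeans(X)
  Xc <- X - rep(xm, each = n)
  sxx <- colSums(Xc^2)
  sxy <- colSums(Xc * yc)
  ok <- sxx > 0
  r <- slope <- numeric(ncol(X))
  r[ok] <- sxy[ok] / sqrt(sxx[ok] * syy)
  r <- pmin(1, pmax(-1, r))
  slope[ok] <- sxy[ok] / sxx[ok]
  p <- rep(1, ncol(X))
  denom <- 1 - r[ok]^2
  tt <- ifelse(denom > 0, r[ok] * sqrt((n - 2) / pmax(denom, 1e-300)), Inf)
  p[ok] <- ifelse(denom > 0, two_tailed_p(tt, n - 2), 0)
  list(r = r, p = p, slope = slope, intercept = mean(y) - slope * xm,
       converged = rep(TRUE, ncol(X)), iterations = 0L, method = "pearson")
}

# column medians via one radix sort (hot path of the IRLS sweep)
col_medians <- function(M) {
  n <- nrow(M)
  S <- matrix(M[order(rep.int(seq_len(ncol(M)), rep.int(n, ncol(M))), M)], n)
  if (n %% 2L) S[(n + 1L) %/% 2L, ] else (S[n %/% 2L, ] + S[n %/% 2L + 1L, ]) / 2
}

huber_sweep <- function(X, y, huber_c, max_iter, tol, keep_weights = FALSE) {
  n <- nrow(X)
  E <- ncol(X)
  if (n < 5L) stop("robust association needs n >= 5", call. = FALSE)
  W <- matrix(1, n, E)
  a <- b <- numeric(E)
  converged <- rep(FALSE, E)
  active <- seq_len(E)
  it <- 0L
  # edges leave the active set as their coefficients converge
  while (length(active) && it < max_iter) {
    it <- it + 1L
    Xa <- X[, active, drop = FALSE]
    Wa <- W[, active, drop = FALSE]
    sw <- colSums(Wa)
    xw <- colSums(Wa * Xa) / sw
    yw <- colSums(Wa * y) / sw
    Xc <- Xa - rep(xw, each = n)
    Yc <- y - rep(yw, each = n)
    sxx <- colSums(Wa * Xc^2)
    sxy <- colSums(Wa * Xc * Yc)
    ok <- sxx > 0
    b_new <- ifelse(ok, sxy / ifelse(ok, sxx, 1), 0)
    a_new <- yw - b_new * xw
    delta <- pmax(abs(b_new - b[active]), abs(a_new - a[active]))
    a[active] <- a_new
    b[active] <- b_new
    conv <- delta < tol
    converged[active[conv]] <- TRUE
    still <- which(!conv)
    if (length(still)) {
      idx <- active[still]
      resid <- y - (rep(a_new[still], each = n) +
                      X[, idx, drop = FALSE] * rep(b_new[still], each = n))
      s <- 1.4826 * col_medians(abs(resid))
      # zero residual MAD: keep unit weights, i.e. the OLS solution
      s[s == 0] <- Inf
      Wn <- pmin(huber_c * rep(s, each = n) / pmax(abs(resid), 1e-300), 1)
      dim(Wn) <- c(n, length(idx))
      W[, idx] <- Wn
    }
    active <- active[!conv]
  }
  if (!all(converged)) {
    warning(sum(!converged), " edge(s) did not converge within ", max_iter,
            " IRLS iterations; using last iterate", call. = FALSE)
  }
  # final weighted statistics
  sw <- colSums(W)
  xw <- colSums(W * X) / sw
  yw <- colSums(W * y) / sw
  Xc <- X - rep(xw, each = n)
  Yc <- y - rep(yw, each = n)
  sxx <- colSums(W * Xc^2)
  syy <- colSums(W * Yc^2)
  sxy <- colSums(W * Xc * Yc)
  ok <- sxx > 0
  r <- numeric(E)
  r[ok] <- sxy[ok] / sqrt(sxx[ok] * syy[ok])
  r <- pmin(1, pmax(-1, r))
  resid <- y - (rep(a, each = n) + X * rep(b, each = n))
  sigma2 <- colSums(W * resid^2) / (n - 2)
  p <- rep(1, E)
  se <- sqrt(sigma2[ok] / sxx[ok])
  tt <- ifelse(se > 0, b[ok] / se, sign(b[ok]) * Inf)
  p[ok] <- two_tailed_p(tt, n - 2)
  out <- list(r = r, p = p, slope = b, intercept = a, converged = converged,
              iterations = it, method = "robust")
  if (keep_weights) out$weights <- W
  out
}

#' Screen edges by association with the score and split by sign
#'
#' Runs the chosen per-edge association over a training block and applies
#' the raw significance threshold: edges with `p < alpha` are selected and
#' split by the sign of their association into the positive network
#' (`r > 0`) and the negative network (`r < 0`).  The two masks are
#' disjoint and exhaust the selected set (an exactly-zero `r` at `p <
#' alpha`, a measure-zero event, joins neither side).
#'
#' @param X Numeric `N x E` training edge-weight matrix (`N >= 5`).
#' @param y Training scores (non-constant).
#' @param config A [cpm_config()]; `alpha` and `method` are taken from it.
#' @return An `edge_selection` object: `r`, `p`, `alpha`, `method`,
#'   logical masks `pos_mask` and `neg_mask`.
#' @export
select_edges <- function(X, y, config = cpm_config()) {
  stopifnot(inherits(config, "cpm_config"))
  X <- as.matrix(X)
  if (nrow(X) < 5L) stop("need at least 5 training subjects", call. = FALSE)
  if (stats::sd(y) == 0) stop("training scores are constant", call. = FALSE)
  assoc <- edge_association(X, y, method = config$method,
                            huber_c = config$huber_c,
                            max_iter = config$irls_max_iter,
                            tol = config$irls_tol)
  sel <- assoc$p < config$alpha
  structure(list(r = assoc$r, p = assoc$p, alpha = config$alpha,
                 method = config$method,
                 pos_mask = sel & assoc$r > 0,
                 neg_mask = sel & assoc$r < 0),
            class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf(
    "edge selection (%s, p < %g): %d positive, %d negative of %d edges\n",
    x$method, x$alpha, sum(x$pos_mask), sum(x$neg_mask), length(x$r)))
  invisible(x)
}

#' Positive and negative network summary values
#'
#' Collapses a subject's selected edges into the two single-number
#' predictors of CPM: the sum of edge weights over the positive network and
#' over the negative network.  With `summary = "raw"` (default) the signed
#' weights are summed as-is; `"clipped"` keeps only the positive weights on
#' the positive side and only the negative weights on the negative side.
#' An empty network contributes exactly 0.
#'
#' @param edges A single edge vector, or an `N x E` matrix of them.
#' @param selection An `edge_selection` from [select_edges()].
#' @param summary `"raw"` or `"clipped"`.
#' @return For a vector input, a list `pos_sum`, `neg_sum`; for a matrix,
#'   a list of two length-`N` vectors.
#' @export
summary_values <- function(edges, selection, summary = c("raw", "clipped")) {
  summary <- match.arg(summary)
  stopifnot(inherits(selection, "edge_selection"))
  vec_in <- !is.matrix(edges)
  X <- if (vec_in) matrix(edges, nrow = 1L) else edges
  if (ncol(X) != length(selection$pos_mask)) {
    stop("edge vector length does not match selection masks", call. = FALSE)
  }
  P <- X[, selection$pos_mask, drop = FALSE]
  Ng <- X[, selection$neg_mask, drop = FALSE]
  if (summary == "clipped") {
    P <- pmax(P, 0)
    Ng <- pmin(Ng, 0)
  }
  pos_sum <- unname(rowSums(P))
  neg_sum <- unname(rowSums(Ng))
  if (vec_in) list(pos_sum = pos_sum[1L], neg_sum = neg_sum[1L])
  else list(pos_sum = pos_sum, neg_sum = neg_sum)
}

#' Fit the univariate summary-to-score regression
#'
#' Ordinary least-squares simple regression of the training scores on the
#' network summary values -- one model per network side.  When the summary
#' values are constant (e.g. no edges were ever selected) the model is
#' flagged degenerate and predicts the training mean.
#'
#' @param summaries Training summary values (length `n >= 3`).
#' @param y Training scores.
#' @param side `"positive"` or `"negative"` (bookkeeping label).
#' @return A `summary_model`: `slope`, `intercept`, `side`, `degenerate`.
#' @export
fit_summary_model <- function(summaries, y, side = c("positive", "negative")) {
  side <- match.arg(side)
  if (length(summaries) != length(y)) {
    stop("summaries and y must have equal length", call. = FALSE)
  }
  if (length(y) < 3L) stop("need at least 3 training points", call. = FALSE)
  if (stats::sd(summaries) == 0) {
    warning("constant summary values on the ", side,
            " side; falling back to the training mean", call. = FALSE)
    model <- list(slope = 0, intercept = mean(y), side = side,
                  degenerate = TRUE)
  } else {
    fit <- stats::lm(y ~ summaries)
    model <- list(slope = unname(stats::coef(fit)[2L]),
                  intercept = unname(stats::coef(fit)[1L]),
                  side = side, degenerate = FALSE)
  }
  structure(model, class = "summary_model")
}

#' Predict a score from a summary value
#'
#' `slope * summary + intercept`; a degenerate model returns the training
#' mean regardless of the summary.
#'
#' @param model A `summary_model` from [fit_summary_model()].
#' @param summary Summary value(s).
#' @return Predicted score(s), in score points.
#' @export
predict_score <- function(model, summary) {
  stopifnot(inherits(model, "summary_model"))
  if (model$degenerate) rep(model$intercept, length(summary))
  else model$slope * summary + model$intercept
}
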