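test_that("pearson association reproduces hand-computed values", {
  res <- pearson_association(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # sum of deviation products 3 over sqrt(5 * 5)
  res <- pearson_association(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6, tolerance = 1e-12)
  expect_equal(res$slope, 0.6)

  const <- pearson_association(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_equal(const$r, 0)
  expect_equal(const$p, 1)

  expect_error(pearson_association(1:2, 1:2), "at least 3")
  expect_error(pearson_association(1:4, 1:3), "equal length")
  expect_error(pearson_association(1:4, rep(1, 4)), "constant")
  expect_error(pearson_association(c(1, NA, 3), c(1, 2, 3)), "non-finite")
})

test_that("pearson r and p match cor.test across random draws", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    ct <- cor.test(x, y)
    res <- pearson_association(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("t-based p-values rank like the exact permutation test at n = 8", {
  perms <- all_perms(8)
  set.seed(17)
  x <- rnorm(8)
  p_t <- p_perm <- numeric(6)
  for (i in 1:6) {
    y <- 0.7 * (i - 1) * x + rnorm(8)
    r_obs <- cor(x, y)
    xs <- scale(x)[, 1]
    ys <- scale(y)[, 1]
    r_all <- as.vector(matrix(ys[perms], nrow(perms)) %*% xs) / 7
    p_perm[i] <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    p_t[i] <- pearson_association(x, y)$p
  }
  expect_gt(cor(p_t, p_perm, method = "spearman"), 0.99)
})

test_that("robust association agrees with OLS on clean data and resists outliers", {
  set.seed(8)
  x <- seq(0, 5, length.out = 30)
  y <- 2 * x + 1 + rnorm(30, sd = 1e-4)
  res <- robust_association(x, y)
  expect_equal(res$slope, 2, tolerance = 1e-3)
  expect_gt(res$r, 0.999)
  expect_lt(res$p, 1e-6)
  expect_true(res$converged)
  # Huber weights live in (0, 1] and the smallest residual gets weight 1
  expect_true(all(res$weights > 0 & res$weights <= 1))
  expect_equal(max(res$weights), 1)

  # one gross outlier: the robust slope stays near truth, OLS drifts more
  x2 <- 1:20
  y2 <- 2 * x2
  y2[20] <- y2[20] + 50 * sd(y2)
  rob <- robust_association(x2, y2)
  ols <- pearson_association(x2, y2)
  expect_lt(abs(rob$slope - 2) / 2, 0.1)
  expect_gt(abs(ols$slope - 2), abs(rob$slope - 2))
  expect_error(robust_association(1:4, c(1, 2, 3, 5)), "at least 5")
})

test_that("robust slope tracks MASS::rlm with the same Huber constant", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(60)
    y <- 3 - 1.5 * x + rt(60, df = 3)
    mine <- robust_association(x, y)
    ref <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = 1.345,
                     maxit = 100, acc = 1e-10)
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 5e-3)
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 5e-3)
  }
})

test_that("flipping the predictor flips r and keeps p for both methods", {
  set.seed(21)
  x <- rnorm(25)
  y <- 0.5 * x + rnorm(25)
  for (fn in list(pearson_association, robust_association)) {
    a <- fn(x, y)
    b <- fn(-x, y)
    expect_equal(b$r, -a$r, tolerance = 1e-10)
    expect_equal(b$p, a$p, tolerance = 1e-10)
  }
})

test_that("edge selection splits significant edges disjointly by sign", {
  g <- generate_cohort(synthetic_spec(n_subjects = 40, n_rois = 10, seed = 6))
  X <- g$cohort$edges
  y <- g$cohort$scores
  sel <- select_edges(X, y, cpm_config(alpha = 0.05, method = "pearson"))
  expect_false(any(sel$pos_mask & sel$neg_mask))
  expect_identical(sel$pos_mask | sel$neg_mask, sel$p < 0.05 & sel$r != 0)
  expect_true(all(sign(sel$r[sel$pos_mask]) == 1))
  expect_true(all(sign(sel$r[sel$neg_mask]) == -1))

  # a vacuous threshold selects every non-constant edge into exactly one side
  sel1 <- select_edges(X, y, cpm_config(alpha = 1, method = "pearson"))
  expect_true(all(xor(sel1$pos_mask, sel1$neg_mask)))

  expect_error(select_edges(X, rep(1, nrow(X))), "constant")
  expect_error(select_edges(X[1:4, ], y[1:4]), "at least 5")
})

test_that("selection masks are invariant to affine rescaling of the score", {
  g <- generate_cohort(synthetic_spec(n_subjects = 40, n_rois = 10, seed = 13))
  X <- g$cohort$edges
  y <- g$cohort$scores
  for (method in c("pearson", "robust")) {
    cfg <- cpm_config(method = method)
    s1 <- select_edges(X, y, cfg)
    s2 <- select_edges(X, 2.5 * y + 40, cfg)
    expect_identical(s1$pos_mask, s2$pos_mask)
    expect_identical(s1$neg_mask, s2$neg_mask)
  }
})

test_that("summary values sum the selected edges per side", {
  sel <- structure(list(r = c(0.5, -0.4, 0.6), p = c(0.001, 0.001, 0.001),
                        alpha = 0.01, method = "pearson",
                        pos_mask = c(TRUE, FALSE, TRUE),
                        neg_mask = c(FALSE, TRUE, FALSE)),
                   class = "edge_selection")
  w <- c(0.2, -0.1, 0.4)
  sv <- summary_values(w, sel)
  expect_equal(sv$pos_sum, 0.6)
  expect_equal(sv$neg_sum, -0.1)

  # empty mask yields exactly zero
  sel0 <- sel
  sel0$neg_mask <- rep(FALSE, 3)
  expect_identical(summary_values(w, sel0)$neg_sum, 0)

  # disjoint masks make the two sums additive over the union
  union_sum <- sum(w[sel$pos_mask | sel$neg_mask])
  expect_equal(sv$pos_sum + sv$neg_sum, union_sum)

  # linear in the edge vector for fixed masks
  w2 <- c(1, 2, -3)
  sv2 <- summary_values(w2, sel)
  svsum <- summary_values(3 * w + w2, sel)
  expect_equal(svsum$pos_sum, 3 * sv$pos_sum + sv2$pos_sum)
  expect_equal(svsum$neg_sum, 3 * sv$neg_sum + sv2$neg_sum)

  # clipped variant drops weights of the "wrong" sign instead of summing raw
  clip <- summary_values(c(0.2, 0.3, -0.4), sel, summary = "clipped")
  expect_equal(clip$pos_sum, 0.2)   # -0.4 on the positive side clipped out
  expect_equal(clip$neg_sum, 0)     # +0.3 on the negative side clipped out

  # matrix input returns per-subject vectors
  M <- rbind(w, w2)
  svm <- summary_values(M, sel)
  expect_equal(svm$pos_sum, c(0.6, -2))
})

test_that("summary model is exact OLS with a mean fallback when degenerate", {
  m <- fit_summary_model(c(1, 2, 3), c(3, 5, 7), side = "positive")
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_false(m$degenerate)
  expect_equal(predict_score(m, 3), 7)

  # residuals orthogonal to the predictor
  set.seed(4)
  s <- rnorm(20)
  y <- 100 + 5 * s + rnorm(20)
  fit <- fit_summary_model(s, y, "negative")
  resid <- y - predict_score(fit, s)
  expect_lt(abs(sum(resid * s)) / sum(abs(y) * abs(s)), 1e-8)

  # prediction is affine
  expect_equal(predict_score(fit, 1.2) + predict_score(fit, -0.7) -
                 predict_score(fit, 0),
               predict_score(fit, 0.5))

  expect_warning(dm <- fit_summary_model(rep(0, 5), c(99, 100, 101, 100, 100),
                                         "positive"),
                 "constant summary")
  expect_true(dm$degenerate)
  expect_equal(predict_score(dm, 123), 100)
  expect_equal(predict_score(dm, -5), 100)
  expect_error(fit_summary_model(1:2, 1:2), "at least 3")
})
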