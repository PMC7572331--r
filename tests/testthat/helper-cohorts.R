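# shared fixtures: all synthetic, built in code, seeded

# small cohort with no planted signal (no lower bound on N, unlike
# generate_null_cohort)
null_cohort_small <- function(n_subjects, n_rois, seed) {
  generate_cohort(synthetic_spec(
    n_subjects = n_subjects, n_rois = n_rois,
    n_pos_edges = 0, n_neg_edges = 0, effect = 0,
    outlier_fraction = 0, seed = seed))$cohort
}

# randomized cross-validation result with hand-built masks and association
# values, for ranking oracle/property tests
fake_cv_run <- function(n_folds, n_rois, seed, p_select = 0.3) {
  set.seed(seed)
  E <- n_edges(n_rois)
  pos <- matrix(stats::runif(n_folds * E) < p_select, n_folds, E)
  neg <- matrix(stats::runif(n_folds * E) < p_select, n_folds, E) & !pos
  r <- matrix(stats::runif(n_folds * E, -1, 1), n_folds, E)
  r[pos] <- abs(r[pos])
  r[neg] <- -abs(r[neg])
  structure(list(observed = stats::rnorm(n_folds),
                 pos_pred = stats::rnorm(n_folds),
                 neg_pred = stats::rnorm(n_folds),
                 pos_masks = pos, neg_masks = neg,
                 fold_r = r * (pos | neg), models = NULL,
                 degenerate = c(positive = 0L, negative = 0L),
                 subject_id = sprintf("S%03d", seq_len(n_folds)),
                 n_folds = n_folds, n_rois = n_rois,
                 config = cpm_config()),
            class = "cpm_cv")
}

# all n! permutations of 1..n, one per row (for exact permutation p-values)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep(k, nrow(p)), p + (p >= k))
  }))
}

# regression data whose residuals stay inside the Huber threshold, so the
# robust fit reduces exactly to OLS (|e| in [0.5, 1]: max/median < 1.994)
bounded_residual_data <- function(n, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  e <- sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 0.5, 1)
  list(x = x, y = 1 + 2 * x + e)
}
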