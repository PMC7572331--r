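#' Specification for a synthetic connectome cohort
#'
#' Defines the generative model behind [generate_cohort()]: a cohort of
#' symmetric, correlation-like connectomes in which a sparse set of planted
#' edges is linearly coupled to a simulated intelligence score, with both
#' coupling signs, optional gross corruption of recorded scores, and
#' everything driven by one RNG seed.
#'
#' Defaults emulate an adolescent IQ cohort (score 106.5 +/- 15.2 points)
#' with background edge variability `edge_noise_sd = 0.25`, a scale typical
#' of off-diagonal resting-state functional correlations.  The default
#' `effect` is calibrated so that each planted edge correlates ~0.4 with the
#' score in the population (see [effect_for_correlation()]).
#'
#' @param n_subjects Number of subjects `N`.
#' @param n_rois Number of ROIs `R`.
#' @param n_pos_edges,n_neg_edges Counts of planted positively / negatively
#'   coupled edges (disjoint, drawn uniformly without replacement).
#' @param effect Per-edge coupling magnitude `beta` (dimensionless) applied
#'   to the standardized score.
#' @param edge_noise_sd Standard deviation of background edge variation
#'   (pre-squashing).
#' @param score_mean,score_sd Mean and SD of the simulated score (points).
#' @param outlier_fraction Fraction of subjects whose *recorded* score is
#'   grossly corrupted (`0 <= f < 0.5`); the connectome stays clean.
#' @param outlier_shift Corruption magnitude in units of `score_sd`; signs
#'   alternate `+`, `-`, ... across corrupted subjects.
#' @param seed Integer RNG seed; identical specs give bit-identical cohorts.
#' @param target Which phenotype column records the score (`"fiq"`/`"viq"`).
#'   The simulated score is written to both IQ columns so either target can
#'   be analysed; `target` sets the cohort's default.
#' @return A `cpm_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 150, n_rois = 20,
                           n_pos_edges = 5, n_neg_edges = 5,
                           effect = effect_for_correlation(0.4, 0.25),
                           edge_noise_sd = 0.25,
                           score_mean = 106.5, score_sd = 15.2,
                           outlier_fraction = 0, outlier_shift = 5,
                           seed = 1, target = c("fiq", "viq")) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_rois = as.integer(n_rois),
               n_pos_edges = as.integer(n_pos_edges),
               n_neg_edges = as.integer(n_neg_edges),
               effect = effect, edge_noise_sd = edge_noise_sd,
               score_mean = score_mean, score_sd = score_sd,
               outlier_fraction = outlier_fraction,
               outlier_shift = outlier_shift,
               seed = as.integer(seed), target = match.arg(target))
  e_max <- n_edges(spec$n_rois)
  if (spec$n_subjects < 3L || spec$n_rois < 3L) {
    stop("need at least 3 subjects and 3 ROIs", call. = FALSE)
  }
  if (spec$n_pos_edges + spec$n_neg_edges > e_max) {
    stop("cannot plant ", spec$n_pos_edges + spec$n_neg_edges,
         " edges in a graph with ", e_max, " edges", call. = FALSE)
  }
  if (spec$outlier_fraction < 0 || spec$outlier_fraction >= 0.5) {
    stop("outlier_fraction must be in [0, 0.5)", call. = FALSE)
  }
  if (spec$effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (spec$edge_noise_sd <= 0) stop("edge_noise_sd must be > 0", call. = FALSE)
  if (spec$score_sd <= 0) stop("score_sd must be > 0", call. = FALSE)
  structure(spec, class = "cpm_synthetic_spec")
}

#' Coupling magnitude for a target edge-score correlation
#'
#' For the generator's linear model `w = beta * z + e`, with standardized
#' score `z` and background noise `e ~ Normal(0, sigma^2)`, the population
#' edge-score correlation is `beta / sqrt(beta^2 + sigma^2)`.  Inverting
#' gives `beta = rho * sigma / sqrt(1 - rho^2)`.  The `tanh` squashing
#' applied afterwards is close to the identity at these magnitudes, so the
#' realized correlation is only slightly attenuated.
#'
#' @param rho Target population correlation in `[0, 1)`.
#' @param edge_noise_sd Background edge noise SD `sigma`.
#' @return The coupling magnitude `beta`.
#' @export
effect_for_correlation <- function(rho, edge_noise_sd) {
  stopifnot(rho >= 0, rho < 1, edge_noise_sd > 0)
  rho * edge_noise_sd / sqrt(1 - rho^2)
}

#' Generate a synthetic connectome cohort with planted signal edges
#'
#' Generative model, in draw order: (1) planted positive then negative edge
#' indices, uniform without replacement; (2) latent scores
#' `y_i ~ Normal(score_mean, score_sd)`, standardized to `z_i` by the sample
#' mean and SD; (3) background edge weights
#' `w_ik ~ Normal(0, edge_noise_sd)`; (4) planted coupling
#' `w_ik <- w_ik +/- effect * z_i` (sign by planted set); (5) `tanh`
#' squashing so all weights lie in `(-1, 1)`; (6) gross corruption of
#' `floor(outlier_fraction * N)` randomly chosen recorded scores by
#' `+/- outlier_shift * score_sd` with alternating sign; (7) simulated ages.
#' Matrices are assembled symmetric with unit diagonal by construction.
#'
#' The squashed matrices are elementwise bounded and symmetric but not
#' guaranteed positive semidefinite; the CPM pipeline treats edges as
#' independent features and never relies on definiteness.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `cohort` (a [cohort()], whose `scores` are the
#'   possibly-corrupted *recorded* scores) and `truth` (a `cpm_ground_truth`
#'   list: `pos_edge_indices`, `neg_edge_indices`, `true_scores`,
#'   `outlier_ids`, and the spec).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "cpm_synthetic_spec"))
  set.seed(spec$seed)
  N <- spec$n_subjects
  E <- n_edges(spec$n_rois)
  n_plant <- spec$n_pos_edges + spec$n_neg_edges
  planted <- if (n_plant > 0L) sample.int(E, n_plant) else integer(0)
  pos_idx <- sort(planted[seq_len(spec$n_pos_edges)])
  neg_idx <- sort(planted[spec$n_pos_edges + seq_len(spec$n_neg_edges)])

  y_true <- stats::rnorm(N, spec$score_mean, spec$score_sd)
  z <- (y_true - mean(y_true)) / stats::sd(y_true)

  W <- matrix(stats::rnorm(N * E, 0, spec$edge_noise_sd), N, E)
  if (length(pos_idx)) W[, pos_idx] <- W[, pos_idx] + spec$effect * z
  if (length(neg_idx)) W[, neg_idx] <- W[, neg_idx] - spec$effect * z
  W <- tanh(W)

  y_rec <- y_true
  n_out <- floor(spec$outlier_fraction * N)
  out_subj <- integer(0)
  if (n_out > 0L) {
    out_subj <- sample.int(N, n_out)
    signs <- rep_len(c(1, -1), n_out)
    y_rec[out_subj] <- y_rec[out_subj] +
      signs * spec$outlier_shift * spec$score_sd
  }

  age <- stats::rnorm(N, 15.2, 3.7)
  ids <- sprintf("S%04d", seq_len(N))
  pheno <- data.frame(subject_id = ids, group = "NT", age = age,
                      fiq = y_rec, viq = y_rec, stringsAsFactors = FALSE)
  coh <- cohort(edges = W, phenotype = pheno, scores = y_rec,
                n_rois = spec$n_rois, target = spec$target)
  truth <- structure(list(pos_edge_indices = pos_idx,
                          neg_edge_indices = neg_idx,
                          true_scores = y_true,
                          outlier_ids = ids[sort(out_subj)],
                          spec = spec),
                     class = "cpm_ground_truth")
  list(cohort = coh, truth = truth)
}

#' Generate a pure-null cohort
#'
#' Shorthand for [generate_cohort()] with `effect = 0` and no outliers: no
#' edge carries any signal.  Used for type-I-error calibration of the edge
#' screen and for null behaviour of the full pipeline.
#'
#' @param n_subjects Number of subjects (`>= 10`).
#' @param n_rois Number of ROIs (`>= 3`).
#' @param seed RNG seed.
#' @return A [cohort()] object.
#' @export
generate_null_cohort <- function(n_subjects = 100, n_rois = 30, seed = 1) {
  stopifnot(n_subjects >= 10, n_rois >= 3)
  spec <- synthetic_spec(n_subjects = n_subjects, n_rois = n_rois,
                         n_pos_edges = 0, n_neg_edges = 0,
                         effect = 0, outlier_fraction = 0, seed = seed)
  generate_cohort(spec)$cohort
}

#' Write a cohort (and optional ground truth) to disk
#'
#' Writes one headerless connectome CSV per subject under
#' `dir/connectomes/`, a manifest TSV `dir/manifest.tsv` in the
#' [read_cohort()] dialect, and, when ground truth is supplied, a sidecar
#' `dir/ground_truth.tsv` listing planted `edge_index` (1-based, fixed edge
#' order) and `sign`, with the full generator spec as `key=value` pairs in
#' a header comment.  `read_cohort()` on the manifest round-trips scores
#' and edge weights to within 1e-12.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `cpm_ground_truth` from [generate_cohort()].
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "cpm_cohort"))
  conn_dir <- file.path(dir, "connectomes")
  dir.create(conn_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(conn_dir)) {
    stop("cannot create output directory: ", conn_dir, call. = FALSE)
  }
  ids <- cohort$phenotype$subject_id
  rel <- file.path("connectomes", paste0(ids, ".csv"))
  for (k in seq_along(ids)) {
    m <- unvectorize(cohort$edges[k, ], cohort$n_rois)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, rel[k]), sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  man <- data.frame(subject_id = ids, connectome_path = rel,
                    group = cohort$phenotype$group,
                    age = num_fmt(cohort$phenotype$age),
                    fiq = num_fmt(cohort$phenotype$fiq),
                    viq = num_fmt(cohort$phenotype$viq),
                    stringsAsFactors = FALSE)
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "cpm_ground_truth"))
    gt_path <- file.path(dir, "ground_truth.tsv")
    spec <- truth$spec
    spec_kv <- paste(sprintf("%s=%s",
                             setdiff(names(spec), "target"),
                             unlist(spec[setdiff(names(spec), "target")])),
                     collapse = " ")
    con <- file(gt_path, "w")
    on.exit(close(con))
    writeLines(paste0("# spec ", spec_kv), con)
    if (length(truth$outlier_ids)) {
      writeLines(paste0("# outlier_ids ",
                        paste(truth$outlier_ids, collapse = ",")), con)
    }
    gt <- data.frame(
      edge_index = c(truth$pos_edge_indices, truth$neg_edge_indices),
      sign = rep(c("positive", "negative"),
                 c(length(truth$pos_edge_indices),
                   length(truth$neg_edge_indices))))
    utils::write.table(gt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(manifest)
}

num_fmt <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, digits = 17, trim = TRUE, scientific = TRUE))
}
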