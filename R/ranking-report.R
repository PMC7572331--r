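#' Normalized rank of every edge across all leave-one-out folds
#'
#' Because the selected networks can differ from fold to fold, edges are
#' ranked by a selection-frequency-weighted mean absolute association:
#' for edge `k`,
#' `score(k) = sum over folds i of [selected_i(k)] * |r_i(k)| / N`,
#' where `[selected_i(k)]` indicates selection on the given side in fold
#' `i` and `r_i(k)` is that fold's association value.  Each selected edge
#' contributes exactly one term per fold, so scores lie in `[0, 1]`, equal
#' 0 iff the edge was never selected, and approach 1 only for edges
#' selected in every fold with near-perfect association.
#'
#' @param run A `cpm_cv` from [run_cpm_loo()].
#' @param side `"positive"` or `"negative"`; sides are ranked
#'   independently.
#' @return An `edge_ranking`: numeric `scores` (length `E`), integer
#'   `fold_counts`, `side`, `n_folds`.
#' @export
normalized_rank <- function(run, side = c("positive", "negative")) {
  side <- match.arg(side)
  stopifnot(inherits(run, "cpm_cv"))
  masks <- if (side == "positive") run$pos_masks else run$neg_masks
  scores <- colSums(masks * abs(run$fold_r)) / run$n_folds
  structure(list(scores = scores,
                 fold_counts = as.integer(colSums(masks)),
                 side = side, n_folds = run$n_folds),
            class = "edge_ranking")
}

#' Brute-force normalized-rank oracle for a single edge
#'
#' Recomputes one edge's normalized rank by an explicit loop over folds
#' and the stored per-fold selections.  Exists as an independent check of
#' [normalized_rank()]; the two must agree exactly.
#'
#' @param run A `cpm_cv`.
#' @param side `"positive"` or `"negative"`.
#' @param edge Edge index (1-based).
#' @return The edge's normalized rank score.
#' @export
rank_oracle <- function(run, side = c("positive", "negative"), edge) {
  side <- match.arg(side)
  stopifnot(inherits(run, "cpm_cv"),
            edge >= 1L, edge <= ncol(run$fold_r))
  masks <- if (side == "positive") run$pos_masks else run$neg_masks
  total <- 0
  for (i in seq_len(run$n_folds)) {
    if (masks[i, edge]) {
      total <- total + abs(run$fold_r[i, edge])
    }
  }
  total / run$n_folds
}

#' Top-k edges of a ranking as an ROI-pair table
#'
#' Orders edges by normalized-rank score, descending, breaking ties by
#' ascending edge index (deterministic reports), and returns the top `k`
#' with ROI display names.  Only edges with a nonzero score are eligible;
#' if fewer than `k` exist the table is truncated with a warning.
#'
#' @param ranking An `edge_ranking` from [normalized_rank()].
#' @param k Number of edges to report (default 5).
#' @param n_rois Number of ROIs of the underlying parcellation.
#' @param labels ROI names; defaults to AAL-116 when `n_rois == 116`.
#' @return Data frame with columns `rank`, `edge_index`, `roi_i`, `roi_j`,
#'   `score`, `folds_selected`.
#' @export
top_k_edges <- function(ranking, k = 5L, n_rois,
                        labels = default_labels(n_rois)) {
  stopifnot(inherits(ranking, "edge_ranking"), k >= 1L)
  if (n_edges(n_rois) != length(ranking$scores)) {
    stop("n_rois inconsistent with ranking length", call. = FALSE)
  }
  nz <- which(ranking$scores > 0)
  if (length(nz) < k) {
    warning("only ", length(nz), " edge(s) ever selected on the ",
            ranking$side, " side; truncating top-", k, " table",
            call. = FALSE)
  }
  ord <- nz[order(-ranking$scores[nz], nz)]
  top <- utils::head(ord, k)
  pairs <- edge_to_roi_pair(top, n_rois, labels)
  data.frame(rank = seq_along(top),
             edge_index = top,
             roi_i = pairs$roi_i,
             roi_j = pairs$roi_j,
             score = ranking$scores[top],
             folds_selected = ranking$fold_counts[top],
             stringsAsFactors = FALSE)
}

#' Write CPM run reports to a directory
#'
#' Writes, for each side: a top-edges CSV (`top_edges_<side>.csv`, header
#' `rank,edge_index,roi_i,roi_j,score,folds_selected`), a full per-edge
#' ranking CSV (`ranking_<side>.csv`), and an edge-list TSV
#' (`edge_list_<side>.tsv`, columns `roi_i  roi_j  score`, nonzero-score
#' edges only) consumable by connectogram/circular-graph tools.  Also
#' writes `predictions.csv` (subject, observed, both predictions) and
#' `evaluation.json` (r, r-squared, p per side plus degenerate-fold
#' counts).  Output is deterministic for a fixed run.
#'
#' @param run A `cpm_cv`.
#' @param out_dir Output directory (created if needed).
#' @param k Top-table size (default 5).
#' @param labels ROI names; AAL-116 by default for 116-ROI runs.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(run, out_dir, k = 5L,
                         labels = default_labels(run$n_rois)) {
  stopifnot(inherits(run, "cpm_cv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create report directory: ", out_dir, call. = FALSE)
  }
  paths <- c()
  eval_list <- list()
  for (side in c("positive", "negative")) {
    ranking <- normalized_rank(run, side)
    top <- suppressWarnings(top_k_edges(ranking, k, run$n_rois, labels))
    f_top <- file.path(out_dir, paste0("top_edges_", side, ".csv"))
    utils::write.csv(top, f_top, row.names = FALSE, quote = FALSE)

    full <- data.frame(edge_index = seq_along(ranking$scores),
                       score = ranking$scores,
                       folds_selected = ranking$fold_counts)
    f_rank <- file.path(out_dir, paste0("ranking_", side, ".csv"))
    utils::write.csv(full, f_rank, row.names = FALSE, quote = FALSE)

    nz <- which(ranking$scores > 0)
    pairs <- edge_to_roi_pair(nz, run$n_rois, labels)
    edge_list <- data.frame(roi_i = pairs$roi_i, roi_j = pairs$roi_j,
                            score = ranking$scores[nz])
    f_edges <- file.path(out_dir, paste0("edge_list_", side, ".tsv"))
    utils::write.table(edge_list, f_edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    pred <- if (side == "positive") run$pos_pred else run$neg_pred
    ev <- suppressWarnings(evaluate_predictions(pred, run$observed))
    eval_list[[side]] <- list(r = ev$r, r_squared = ev$r_squared, p = ev$p)
    paths <- c(paths, stats::setNames(c(f_top, f_rank, f_edges),
                                      paste0(c("top_", "ranking_", "edges_"),
                                             side)))
  }
  pred_df <- data.frame(subject_id = run$subject_id,
                        observed = run$observed,
                        pos_pred = run$pos_pred,
                        neg_pred = run$neg_pred)
  f_pred <- file.path(out_dir, "predictions.csv")
  utils::write.csv(pred_df, f_pred, row.names = FALSE, quote = FALSE)

  eval_list$degenerate_folds <- as.list(run$degenerate)
  eval_list$n_folds <- run$n_folds
  f_eval <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(eval_list, f_eval, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, predictions = f_pred, evaluation = f_eval)
  invisible(paths)
}
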