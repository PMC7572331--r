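#' Read a functional connectome matrix from a plain-text file
#'
#' Reads a square numeric matrix stored as headerless CSV or
#' whitespace-delimited text, validates it as a functional connectome
#' (symmetric, unit diagonal), and returns the symmetrized matrix.
#'
#' Connectomes are Pearson-correlation matrices between regional
#' time-series averages, so file round-trips can introduce last-digit
#' asymmetry.  Asymmetry up to `1e-6` is repaired by averaging
#' `(M + t(M)) / 2`; anything larger is treated as a corrupt file and
#' rejected, naming the worst cell.
#'
#' @param path Path to the matrix file (no header, one row per line;
#'   comma- or whitespace-delimited).
#' @param expect_rois Optional integer; if given, the matrix must be
#'   `expect_rois x expect_rois`.
#' @return A validated symmetric numeric matrix with unit diagonal.
#' @seealso [vectorize()], [read_cohort()]
#' @export
read_connectome <- function(path, expect_rois = NULL) {
  if (!file.exists(path)) {
    stop("connectome file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop("connectome file is not square: ", nrow(m), " x ", ncol(m),
         " in ", path, call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("connectome contains missing or non-finite entries: ", path,
         call. = FALSE)
  }
  if (!is.null(expect_rois) && nrow(m) != expect_rois) {
    stop("expected ", expect_rois, " ROIs but found ", nrow(m),
         " in ", path, call. = FALSE)
  }
  validate_connectome(m, context = path)
}

# Symmetry/diagonal validation shared by file reading and constructors.
# Asymmetry <= 1e-6 is symmetrized by averaging; beyond that it is an error.
validate_connectome <- function(m, context = "matrix") {
  asym <- abs(m - t(m))
  worst <- max(asym)
  if (worst > 1e-6) {
    cell <- which(asym == worst, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is asymmetric beyond tolerance (|M[%d,%d] - M[%d,%d]| = %g) in %s",
      cell[1L], cell[2L], cell[2L], cell[1L], worst, context), call. = FALSE)
  }
  m <- (m + t(m)) / 2
  dmax <- max(abs(diag(m) - 1))
  if (dmax > 1e-6) {
    stop(sprintf("diagonal deviates from 1 by %g in %s", dmax, context),
         call. = FALSE)
  }
  diag(m) <- 1
  m
}

#' Vectorize a connectome into its edge-weight vector
#'
#' Extracts the strict upper triangle of a symmetric `R x R` matrix in
#' row-major order -- `(1,2), (1,3), ..., (1,R), (2,3), ...` -- giving one
#' weight per unordered ROI pair.  This ordering is the package-wide edge
#' index convention used by every selection mask and ranking.
#'
#' @param m Symmetric numeric matrix (`R x R`).
#' @return Numeric vector of length `R * (R - 1) / 2`.
#' @export
#' @examples
#' m <- unvectorize(c(0.5, -0.2, 0), 3)
#' vectorize(m)  # 0.5 -0.2 0.0
vectorize <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), is.numeric(m))
  # row-major upper triangle of m == column-major lower triangle of t(m)
  t(m)[lower.tri(m)]
}

#' Rebuild a connectome matrix from an edge vector
#'
#' Inverse of [vectorize()]: places the edge weights back into the strict
#' upper and lower triangles and sets the diagonal to 1.
#'
#' @param edges Numeric vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois Number of ROIs `R`.
#' @return Symmetric `R x R` numeric matrix with unit diagonal.
#' @export
unvectorize <- function(edges, n_rois) {
  n_rois <- as.integer(n_rois)
  e_expect <- n_edges(n_rois)
  if (length(edges) != e_expect) {
    stop("edge vector has length ", length(edges), " but ", n_rois,
         " ROIs require ", e_expect, call. = FALSE)
  }
  m <- matrix(0, n_rois, n_rois)
  m[lower.tri(m)] <- edges
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Number of edges for a given parcellation size
#'
#' @param n_rois Number of ROIs.
#' @return `n_rois * (n_rois - 1) / 2`.
#' @export
n_edges <- function(n_rois) (as.integer(n_rois) * (as.integer(n_rois) - 1L)) %/% 2L

# (i, j) ROI index pair (1-based, i < j) for every edge, rows in edge order.
edge_roi_index <- function(n_rois) {
  idx <- which(lower.tri(matrix(FALSE, n_rois, n_rois)), arr.ind = TRUE)
  cbind(i = idx[, "col"], j = idx[, "row"])
}

#' Map edge indices to ROI-pair names
#'
#' Translates edge indices (under the fixed upper-triangle order, 1-based)
#' into the unordered pair of ROI display names, e.g. edge 1 of an AAL-116
#' connectome is `PreCG.L -- PreCG.R`.
#'
#' @param edge_index Integer vector of edge indices in `1..n_edges(n_rois)`.
#' @param n_rois Number of ROIs.
#' @param labels Character vector of `n_rois` ROI names; defaults to the
#'   AAL-116 abbreviations when `n_rois == 116`, otherwise `ROI1..ROIn`.
#' @return Data frame with columns `edge_index`, `roi_i`, `roi_j`
#'   (`i < j` under the atlas ordering).
#' @export
edge_to_roi_pair <- function(edge_index, n_rois,
                             labels = default_labels(n_rois)) {
  e_max <- n_edges(n_rois)
  edge_index <- as.integer(edge_index)
  if (any(edge_index < 1L | edge_index > e_max)) {
    stop("edge index out of range 1..", e_max, call. = FALSE)
  }
  if (length(labels) != n_rois) {
    stop("need exactly ", n_rois, " labels, got ", length(labels),
         call. = FALSE)
  }
  ij <- edge_roi_index(n_rois)[edge_index, , drop = FALSE]
  data.frame(edge_index = edge_index,
             roi_i = labels[ij[, "i"]],
             roi_j = labels[ij[, "j"]],
             stringsAsFactors = FALSE)
}

default_labels <- function(n_rois) {
  if (n_rois == 116L) aal116_labels() else paste0("ROI", seq_len(n_rois))
}

#' AAL-116 region labels
#'
#' The 116 region abbreviations of the automated anatomical labelling
#' (AAL) atlas in standard atlas order (1-116): paired cortical and
#' subcortical regions with `.L`/`.R` suffixes, the nine paired cerebellar
#' lobules (`Crus1.L` ... `C10.R`) and the eight vermis lobules
#' (`V12` ... `V10`).
#'
#' @return Character vector of length 116.
#' @export
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "conncpm",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$label[order(tab$index)]
}

#' Construct a cohort from edge data and phenotypes
#'
#' A cohort bundles the per-subject edge vectors of one population with the
#' phenotype table and the target behavioural score.  Prediction models are
#' population-specific, so a cohort must contain a single group.
#'
#' @param edges Numeric `N x E` matrix, one row of edge weights per subject.
#' @param phenotype Data frame with at least `subject_id` and `group`.
#' @param scores Numeric vector of target scores, aligned with rows; no
#'   missing values (exclusion happens before construction).
#' @param n_rois Number of ROIs `R` (so `E = R(R-1)/2`).
#' @param target Which score the cohort predicts: `"fiq"` or `"viq"`.
#' @return An object of class `cpm_cohort`.
#' @export
cohort <- function(edges, phenotype, scores, n_rois,
                   target = c("fiq", "viq")) {
  target <- match.arg(target)
  edges <- as.matrix(edges)
  n_rois <- as.integer(n_rois)
  stopifnot(is.numeric(edges), nrow(edges) == length(scores),
            nrow(edges) == nrow(phenotype),
            ncol(edges) == n_edges(n_rois))
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("cohort scores must be finite and non-missing", call. = FALSE)
  }
  if (anyDuplicated(phenotype$subject_id)) {
    stop("duplicate subject_id in cohort", call. = FALSE)
  }
  if (length(unique(phenotype$group)) > 1L) {
    stop("a cohort must contain a single group; got: ",
         paste(unique(phenotype$group), collapse = ", "), call. = FALSE)
  }
  structure(list(edges = edges, phenotype = phenotype,
                 scores = as.numeric(scores), n_rois = n_rois,
                 target = target),
            class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat(sprintf("CPM cohort: %d subjects (%s), %d ROIs, %d edges, target %s\n",
              nrow(x$edges), unique(x$phenotype$group), x$n_rois,
              ncol(x$edges), toupper(x$target)))
  cat(sprintf("  score: mean %.1f, sd %.1f\n",
              mean(x$scores), stats::sd(x$scores)))
  invisible(x)
}

#' Read a cohort from a manifest file
#'
#' Loads a tab-separated cohort manifest (columns `subject_id`,
#' `connectome_path`, `group`, `age`, `fiq`, `viq`; `NA` for missing),
#' reads and vectorizes every subject's connectome, and drops subjects
#' whose target score is missing.  Relative connectome paths are resolved
#' against the manifest's directory.  Subject order is preserved.
#'
#' @param manifest Path to the manifest TSV.
#' @param target `"fiq"` or `"viq"`; subjects missing this score are
#'   excluded (a subject missing VIQ still participates in FIQ analyses).
#' @param group Optional group to keep (`"ASD"` or `"NT"`); required when
#'   the manifest mixes groups, since models are population-specific.
#' @return A [cohort()] object.
#' @export
read_cohort <- function(manifest, target = c("fiq", "viq"), group = NULL) {
  target <- match.arg(target)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                           na.strings = "NA")
  need <- c("subject_id", "connectome_path", "group", "age", "fiq", "viq")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(man$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(man$subject_id[duplicated(man$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(group)) {
    man <- man[man$group == group, , drop = FALSE]
    if (!nrow(man)) stop("no subjects in group ", group, call. = FALSE)
  }
  if (length(unique(man$group)) > 1L) {
    stop("manifest mixes groups (", paste(unique(man$group), collapse = ", "),
         "); pass `group=` to select one population", call. = FALSE)
  }
  y <- man[[target]]
  n_excluded <- sum(is.na(y))
  if (n_excluded > 0L) {
    message("excluding ", n_excluded, " subject(s) with missing ",
            toupper(target))
    man <- man[!is.na(y), , drop = FALSE]
    y <- man[[target]]
  }
  if (!nrow(man)) {
    stop("cohort is empty after excluding missing ", toupper(target),
         call. = FALSE)
  }
  base_dir <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$connectome_path),
                  man$connectome_path,
                  file.path(base_dir, man$connectome_path))
  mats <- lapply(paths, read_connectome)
  rois <- vapply(mats, nrow, integer(1))
  if (length(unique(rois)) > 1L) {
    stop("mixed parcellation sizes in manifest: ",
         paste(sort(unique(rois)), collapse = ", "), call. = FALSE)
  }
  edges <- do.call(rbind, lapply(mats, vectorize))
  cohort(edges = edges,
         phenotype = man[, c("subject_id", "group", "age", "fiq", "viq")],
         scores = y, n_rois = rois[1L], target = target)
}
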