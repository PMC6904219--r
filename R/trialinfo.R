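#' Single-trial stimulus-specific information at perception
#'
#' For every perceptual trial, distances are computed from that trial's
#' activity pattern to every trial pattern in the *other* data fold
#' (cross-fold only, so trial and comparison noise are independent), using
#' the Mahalanobis metric under a shrunk noise covariance estimated from
#' training data. The distances are rank-correlated (Spearman) with the
#' trial's own binary model — distance 0 to patterns of the matching
#' stimulus, 1 to patterns of differing stimuli — and the correlation is
#' Fisher z-transformed. Informative trials have matching patterns closer
#' than differing ones, hence rho > 0 and z_info > 0.
#'
#' @param patterns Trials x ROI-voxels pattern matrix.
#' @param labels Per-trial stimulus ids.
#' @param fold Per-trial fold assignment (e.g. block parity); comparisons
#'   are restricted to trials of other folds.
#' @param cov \code{shrunk_covariance} (or covariance matrix) from training
#'   residuals.
#' @return data.frame of class \code{trial_information}: \code{trial_id},
#'   \code{z_info}, \code{phase}, \code{n_comparison_patterns}. Trials with
#'   no cross-fold comparisons or a degenerate model get \code{NA}.
#' @export
perception_trial_information <- function(patterns, labels, fold, cov) {
  n <- nrow(patterns)
  stopifnot(length(labels) == n, length(fold) == n)
  if (length(unique(labels)) < 2) {
    stop("need at least 2 distinct stimuli", call. = FALSE)
  }
  D <- mahalanobis_to_patterns(patterns, patterns, cov)
  z <- rep(NA_real_, n)
  n_comp <- integer(n)
  for (t in seq_len(n)) {
    other <- which(fold != fold[t])
    n_comp[t] <- length(other)
    if (length(other) < 3) next
    model <- as.numeric(labels[other] != labels[t])
    rho <- spearman_rho(D[t, other], model)
    if (!is.na(rho)) z[t] <- fisher_z(rho)
  }
  out <- data.frame(trial_id = seq_len(n), z_info = z, phase = "perception",
                    n_comparison_patterns = n_comp)
  class(out) <- c("trial_information", "data.frame")
  out
}

#' Single-trial reinstatement information at retrieval
#'
#' For every remembered retrieval trial, Mahalanobis distances (under the
#' shrunk training-data covariance, which supplies the discriminant
#' weighting) are computed from the single retrieval pattern to every
#' perception condition pattern, and rank-correlated with the binary model
#' that assigns 0 to perception patterns of the retrieved stimulus and 1 to
#' the rest; the Spearman rho is Fisher z-transformed. Trials that were not
#' remembered are excluded — their memory-related power and information
#' differences would otherwise masquerade as a trial-wise coupling.
#'
#' @param retrieval_patterns Remembered-and-forgotten retrieval trials x
#'   ROI-voxels matrix.
#' @param labels Per-retrieval-trial stimulus ids.
#' @param remembered Logical per retrieval trial.
#' @param perception_patterns List of condition x ROI-voxels matrices, one
#'   per perception fold (rows ordered by stimulus id), or a single matrix.
#' @param perception_labels Stimulus ids of the perception pattern rows (one
#'   fold's worth; recycled across folds).
#' @param cov \code{shrunk_covariance} or covariance matrix.
#' @param include_forgotten Also score forgotten trials (off the headline
#'   path; default \code{FALSE}).
#' @return data.frame of class \code{trial_information} with one row per
#'   scored trial.
#' @export
retrieval_trial_information <- function(retrieval_patterns, labels,
                                        remembered, perception_patterns,
                                        perception_labels,
                                        cov, include_forgotten = FALSE) {
  if (is.matrix(perception_patterns)) {
    perception_patterns <- list(perception_patterns)
  }
  n <- nrow(retrieval_patterns)
  stopifnot(length(labels) == n, length(remembered) == n)
  ref <- do.call(rbind, perception_patterns)
  ref_labels <- rep(perception_labels, length(perception_patterns))
  missing_stim <- setdiff(unique(labels), unique(ref_labels))
  if (length(missing_stim) > 0) {
    stop("no perception pattern for stimulus ",
         paste(missing_stim, collapse = ", "), call. = FALSE)
  }
  use <- if (include_forgotten) rep(TRUE, n) else remembered
  if (!any(use)) stop("no remembered trials to score", call. = FALSE)
  D <- mahalanobis_to_patterns(retrieval_patterns[use, , drop = FALSE],
                               ref, cov)
  idx <- which(use)
  z <- rep(NA_real_, length(idx))
  for (i in seq_along(idx)) {
    model <- as.numeric(ref_labels != labels[idx[i]])
    rho <- spearman_rho(D[i, ], model)
    if (!is.na(rho)) z[i] <- fisher_z(rho)
  }
  out <- data.frame(trial_id = idx, z_info = z, phase = "retrieval",
                    n_comparison_patterns = nrow(ref))
  class(out) <- c("trial_information", "data.frame")
  out
}

#' Maximum attainable Spearman correlation against a tied binary model
#'
#' The binary 0/1 trial model has heavy ties, which caps \code{|rho|} below
#' 1 even under perfect separation. For \code{m} zeros among \code{n}
#' entries, perfect separation puts the zeros at average rank
#' \code{(m + 1) / 2}, giving the closed-form ceiling returned here (the
#' Pearson correlation of average ranks under perfect ordering).
#'
#' @param n_match Number of model-0 (matching) entries.
#' @param n_diff Number of model-1 (differing) entries.
#' @return The tie-limited maximum Spearman rho.
#' @export
tie_limited_rho_max <- function(n_match, n_diff) {
  n <- n_match + n_diff
  model <- c(rep(0, n_match), rep(1, n_diff))
  perfect <- seq_len(n)  # any strictly increasing distances
  stats::cor(perfect, model, method = "spearman")
}
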