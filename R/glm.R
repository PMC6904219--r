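#' Canonical double-gamma haemodynamic response function
#'
#' The de-facto standard canonical HRF: a gamma density peaking at 6 s minus
#' a gamma density for the late undershoot at 16 s, scaled by a 1:6 ratio,
#' normalised to unit sum.
#'
#' @param t Time points in seconds (>= 0).
#' @param peak_s Delay of the response peak (default 6).
#' @param undershoot_s Delay of the undershoot (default 16).
#' @param ratio Response/undershoot amplitude ratio (default 6).
#' @return Numeric vector of HRF values at \code{t}.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    stats::dgamma(t, shape = undershoot_s, rate = 1) / ratio
  h / sum(h)
}

#' Build an HRF-convolved design matrix from a trial table
#'
#' Each event is modelled as a boxcar ("stick function" spanning the
#' stimulus duration) on a fine temporal grid (TR/16), convolved with the
#' canonical double-gamma HRF, and downsampled to volume onsets. In
#' \code{per_condition} mode events sharing a stimulus share a column; in
#' \code{per_trial} mode every trial gets its own column (least-squares-all
#' single-trial design). An intercept column is appended.
#'
#' @param table Trial table (rows used as given; subset phases/blocks first).
#' @param n_volumes Number of volumes in the run.
#' @param tr_s Repetition time in seconds.
#' @param mode \code{"per_condition"} or \code{"per_trial"}.
#' @param duration_s Event duration in seconds (default 3).
#' @param hrf Optional list of overrides passed to
#'   \code{\link{hrf_double_gamma}} (\code{peak_s}, \code{undershoot_s},
#'   \code{ratio}).
#' @param oversample Fine-grid factor (default 16 bins per TR).
#' @return A list of class \code{design_matrix} with \code{matrix}
#'   (volumes x regressors), \code{labels}, \code{dt_s}, \code{mode}.
#' @export
build_design_matrix <- function(table, n_volumes, tr_s,
                                mode = c("per_condition", "per_trial"),
                                duration_s = 3, hrf = list(),
                                oversample = 16) {
  mode <- match.arg(mode)
  scan_s <- n_volumes * tr_s
  if (any(table$onset_s < 0) || any(table$onset_s + duration_s > scan_s)) {
    stop("event onset + duration extends beyond the scan (",
         scan_s, " s)", call. = FALSE)
  }
  dt <- tr_s / oversample
  n_fine <- n_volumes * oversample
  h <- do.call(hrf_double_gamma,
               c(list(t = seq(0, 32, by = dt)), hrf))
  if (mode == "per_condition") {
    groups <- split(seq_len(nrow(table)), table$stimulus)
    labels <- paste0("stim_", names(groups))
  } else {
    groups <- as.list(seq_len(nrow(table)))
    labels <- paste0("trial_", table$trial_id %||% seq_len(nrow(table)))
  }
  X <- vapply(groups, function(rows) {
    box <- numeric(n_fine)
    for (r in rows) {
      i0 <- floor(table$onset_s[r] / dt) + 1
      i1 <- min(n_fine, floor((table$onset_s[r] + duration_s) / dt))
      box[i0:i1] <- box[i0:i1] + 1
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)]
    conv[seq(1, n_fine, by = oversample)]
  }, numeric(n_volumes))
  X <- cbind(X, intercept = 1)
  colnames(X) <- c(labels, "intercept")
  if (any(apply(X[, seq_along(labels), drop = FALSE], 2,
                function(col) all(col == 0)))) {
    stop("design contains an all-zero regressor", call. = FALSE)
  }
  structure(list(matrix = X, labels = colnames(X), dt_s = tr_s, mode = mode),
            class = "design_matrix")
}

#' Estimate activity patterns by ordinary least squares
#'
#' Fits the GLM \code{Y = X B + E} voxel-wise and returns the beta patterns
#' together with the residual time-series, which downstream covariance
#' shrinkage uses as its noise estimate.
#'
#' @param timeseries Numeric matrix, volumes x voxels.
#' @param design A \code{design_matrix}.
#' @return List with \code{patterns} (regressors x voxels, intercept row
#'   included, labelled), and \code{residuals} (volumes x voxels).
#' @export
estimate_betas <- function(timeseries, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$matrix
  if (nrow(X) != nrow(timeseries)) {
    stop("timeseries has ", nrow(timeseries), " volumes but design has ",
         nrow(X), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, timeseries)
  rownames(B) <- colnames(X)
  R <- timeseries - X %*% B
  list(patterns = B, residuals = R)
}
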