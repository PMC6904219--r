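#' Ledoit-Wolf shrinkage of a noise covariance towards its diagonal
#'
#' Estimates the voxel noise covariance from residual time-series and shrinks
#' it towards the diagonal target,
#' \code{Sigma* = (1 - lambda) S + lambda diag(S)}, with the analytically
#' optimal shrinkage weight (the ratio of the summed sampling variances of
#' the off-diagonal entries to their summed squares), clipped to
#' \code{[0, 1]}. The result is positive-definite even when there are fewer
#' residual samples than voxels, which is what makes the Mahalanobis
#' machinery usable inside small searchlights.
#'
#' @param residuals Numeric matrix, samples (time) x voxels.
#' @return List of class \code{shrunk_covariance} with \code{sigma},
#'   \code{lambda}, \code{source_df}.
#' @export
shrink_covariance <- function(residuals) {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  p <- ncol(residuals)
  if (n < 2) stop("need at least 2 residual samples", call. = FALSE)
  v <- apply(residuals, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance voxel(s): ", paste(which(v == 0), collapse = ", "),
         call. = FALSE)
  }
  m <- covariance_moments(residuals)
  shrink_from_moments(m, seq_len(p))
}

# sufficient statistics for diagonal-target shrinkage, computed once so
# searchlight-wise shrinkage can reuse submatrices
covariance_moments <- function(residuals) {
  n <- nrow(residuals)
  Xc <- sweep(residuals, 2, colMeans(residuals))
  S <- crossprod(Xc) / (n - 1)
  wbar <- crossprod(Xc) / n
  var_s <- n / (n - 1)^3 * (crossprod(Xc^2) - n * wbar^2)
  list(S = S, var_s = var_s, n = n)
}

# Ledoit-Wolf diagonal-target shrinkage restricted to voxel subset `idx`
shrink_from_moments <- function(m, idx) {
  S <- m$S[idx, idx, drop = FALSE]
  if (length(idx) == 1) {
    out <- list(sigma = S, lambda = 0, source_df = m$n - 1)
    class(out) <- "shrunk_covariance"
    return(out)
  }
  var_s <- m$var_s[idx, idx, drop = FALSE]
  off <- row(S) != col(S)
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(S)
  out <- list(sigma = sigma, lambda = lambda, source_df = m$n - 1)
  class(out) <- "shrunk_covariance"
  out
}

#' Cross-validated Mahalanobis (crossnobis) distance between conditions
#'
#' For conditions \code{j, k} measured independently in two folds A and B,
#' the cross-validated squared Mahalanobis distance is
#' \deqn{d(j,k) = (u_jA - u_kA)' \Sigma^{-1} (u_jB - u_kB),}
#' averaged over the two fold assignments (the two terms are algebraically
#' equal for a symmetric \eqn{\Sigma}). Because the two contrast estimates
#' carry independent noise, the expectation of \code{d} is zero when the
#' conditions do not differ, and \code{d} can be negative.
#'
#' @param fold_a,fold_b Condition x voxels pattern matrices from the two
#'   folds, with matching row order (same condition labels).
#' @param cov A \code{shrunk_covariance} (or a plain covariance matrix)
#'   matching the voxel dimension.
#' @return Symmetric condition x condition matrix of distances (diagonal is
#'   identically zero: the same-condition contrast vanishes).
#' @export
crossnobis_distance <- function(fold_a, fold_b, cov) {
  sigma <- if (inherits(cov, "shrunk_covariance")) cov$sigma else cov
  if (!all(dim(fold_a) == dim(fold_b))) {
    stop("fold pattern matrices must have identical dimensions", call. = FALSE)
  }
  if (!is.null(rownames(fold_a)) && !is.null(rownames(fold_b)) &&
      !identical(rownames(fold_a), rownames(fold_b))) {
    stop("condition labels differ across folds", call. = FALSE)
  }
  if (ncol(fold_a) != nrow(sigma)) {
    stop("covariance dimension does not match voxel count", call. = FALSE)
  }
  G <- fold_a %*% solve(sigma, t(fold_b))
  # d(j,k) = G_jj + G_kk - G_jk - G_kj, symmetrised over fold assignment
  g1 <- diag(G)
  D <- outer(g1, g1, "+") - G - t(G)
  (D + t(D)) / 2
}

#' Mahalanobis distances from single trials to comparison patterns
#'
#' Whitened (noise-normalised) Euclidean distances between each row of
#' \code{patterns} and each row of \code{reference}, using an
#' independently-estimated shrunk noise covariance. This is the
#' trial-resolved companion to \code{\link{crossnobis_distance}}: the
#' covariance (the discriminant weighting) comes from training data, the
#' patterns from held-out data.
#'
#' @param patterns Trials x voxels matrix.
#' @param reference Comparison patterns x voxels matrix.
#' @param cov \code{shrunk_covariance} or covariance matrix.
#' @return Trials x comparison-patterns matrix of squared Mahalanobis
#'   distances.
#' @export
mahalanobis_to_patterns <- function(patterns, reference, cov) {
  sigma <- if (inherits(cov, "shrunk_covariance")) cov$sigma else cov
  W <- chol(solve(sigma))
  Pw <- patterns %*% t(W)
  Rw <- reference %*% t(W)
  d2 <- outer(rowSums(Pw^2), rowSums(Rw^2), "+") - 2 * Pw %*% t(Rw)
  pmax(d2, 0)
}

#' Build a searchlight map on a regular voxel grid
#'
#' A searchlight at each in-mask voxel collects all in-mask voxels whose
#' centre lies within an inclusive Euclidean radius. The full-sphere member
#' count is derived analytically from the grid spacing (on the default
#' 3 x 3 x 4 mm grid a 10 mm radius holds 121 voxels); centres whose actual
#' member count falls below \code{min_fraction} of that full count (e.g.
#' searchlights protruding outside the brain) are discarded.
#'
#' @param mask 3-D logical array marking in-brain voxels.
#' @param spacing_mm Voxel spacing along the three axes (default
#'   \code{c(3, 3, 4)}).
#' @param radius_mm Searchlight radius (default 10).
#' @param min_fraction Minimum fraction of the full sphere a centre must
#'   retain (default 0.6).
#' @return List of class \code{searchlight_map}: \code{centres} (indices
#'   into the in-mask voxel list), \code{members} (list of in-mask voxel
#'   indices per centre), \code{full_count}, \code{radius_mm},
#'   \code{min_fraction}, \code{spacing_mm}, \code{mask},
#'   \code{voxel_index} (3-D array mapping grid position to in-mask index).
#' @export
build_searchlights <- function(mask, spacing_mm = c(3, 3, 4), radius_mm = 10,
                               min_fraction = 0.6) {
  stopifnot(length(dim(mask)) == 3, radius_mm > 0,
            min_fraction > 0, min_fraction <= 1)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  dims <- dim(mask)
  # analytic full-sphere stencil from the spacing
  rng <- floor(radius_mm / spacing_mm)
  off <- as.matrix(expand.grid(i = -rng[1]:rng[1], j = -rng[2]:rng[2],
                               k = -rng[3]:rng[3]))
  dist2 <- (off[, 1] * spacing_mm[1])^2 + (off[, 2] * spacing_mm[2])^2 +
    (off[, 3] * spacing_mm[3])^2
  off <- off[dist2 <= radius_mm^2, , drop = FALSE]
  full_count <- nrow(off)
  min_count <- ceiling(min_fraction * full_count)

  voxel_index <- array(NA_integer_, dims)
  voxel_index[mask] <- seq_len(sum(mask))
  grid <- which(mask, arr.ind = TRUE)
  n_vox <- nrow(grid)
  members <- vector("list", n_vox)
  keep <- logical(n_vox)
  for (v in seq_len(n_vox)) {
    pos <- sweep(off, 2, grid[v, ], "+")
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
      pos[, 2] >= 1 & pos[, 2] <= dims[2] &
      pos[, 3] >= 1 & pos[, 3] <= dims[3]
    idx <- voxel_index[pos[ok, , drop = FALSE]]
    idx <- idx[!is.na(idx)]
    members[[v]] <- sort(idx)
    keep[v] <- length(idx) >= min_count
  }
  structure(list(centres = which(keep), members = members[keep],
                 full_count = full_count, radius_mm = radius_mm,
                 min_fraction = min_fraction, spacing_mm = spacing_mm,
                 mask = mask, voxel_index = voxel_index),
            class = "searchlight_map")
}

#' Binary model representational dissimilarity matrix
#'
#' Hypothesised dissimilarity between pattern pairs: 0 where the two
#' patterns carry the same stimulus, 1 where they differ. Self-pairs are
#' excluded (\code{NA}). When a grouping (data fold, or task phase for the
#' reinstatement model) is supplied with \code{exclude_within_group = TRUE},
#' pairs inside the same group are also excluded, so that e.g. only
#' perception-retrieval comparisons remain in the reinstatement model.
#'
#' @param labels Per-pattern stimulus ids.
#' @param group Optional per-pattern grouping (fold or phase).
#' @param exclude_within_group Exclude same-group pairs (default \code{TRUE}
#'   when \code{group} is given).
#' @return n x n numeric matrix with entries 0/1 and \code{NA} for excluded
#'   pairs; class \code{model_rdm}.
#' @export
model_rdm <- function(labels, group = NULL,
                      exclude_within_group = !is.null(group)) {
  if (length(unique(labels)) < 2) {
    stop("all stimulus labels identical: model is degenerate", call. = FALSE)
  }
  M <- 1 - outer(labels, labels, "==")
  diag(M) <- NA
  if (!is.null(group) && exclude_within_group) {
    M[outer(group, group, "==")] <- NA
  }
  class(M) <- c("model_rdm", class(M))
  M
}

#' Searchlight map of stimulus-specific information
#'
#' At every searchlight centre: restrict the two folds' condition patterns
#' and the residuals to the member voxels, shrink the local noise
#' covariance, compute the crossnobis distance matrix, rank-correlate its
#' unique condition pairs (Spearman) against the binary model RDM, and store
#' the Fisher z of that correlation at the centre voxel. Higher z means the
#' local distance geometry matches the stimulus model better, i.e. more
#' stimulus-specific information.
#'
#' @param fold_a,fold_b Condition x voxels pattern matrices (voxels =
#'   in-mask voxels in \code{searchlights} order).
#' @param labels Condition stimulus ids (shared by both folds).
#' @param residuals Residual time-series (samples x voxels) for covariance
#'   estimation.
#' @param searchlights A \code{searchlight_map}.
#' @param include_diagonal Include the same-condition cross-fold pairs
#'   (identically-zero distances) in the correlation (default TRUE).
#' @return Numeric vector of Fisher z values, one per searchlight centre
#'   (named by centre voxel index); \code{NA} where the correlation is
#'   undefined.
#' @export
searchlight_information_map <- function(fold_a, fold_b, labels, residuals,
                                        searchlights,
                                        include_diagonal = TRUE) {
  stopifnot(inherits(searchlights, "searchlight_map"))
  n_cond <- nrow(fold_a)
  sel <- if (include_diagonal) {
    which(lower.tri(diag(n_cond), diag = TRUE))
  } else {
    which(lower.tri(diag(n_cond)))
  }
  model_full <- 1 - outer(labels, labels, "==")
  model_vec <- model_full[sel]
  if (length(model_vec) < 3 || stats::sd(model_vec) == 0) {
    stop("need at least 3 distance pairs and a non-constant model",
         call. = FALSE)
  }
  moments <- covariance_moments(residuals)
  z <- vapply(seq_along(searchlights$centres), function(ci) {
    vox <- searchlights$members[[ci]]
    cov <- shrink_from_moments(moments, vox)
    D <- crossnobis_distance(fold_a[, vox, drop = FALSE],
                             fold_b[, vox, drop = FALSE], cov)
    dv <- D[sel]
    rho <- spearman_rho(dv, model_vec)
    if (is.na(rho)) NA_real_ else fisher_z(rho)
  }, numeric(1))
  names(z) <- searchlights$centres
  z
}

#' Dilate a cluster of centre voxels into a searchlight-informed ROI
#'
#' Expands a set of centre voxels to the union of all voxels that belonged
#' to any searchlight centred inside the cluster — the voxels that actually
#' contributed to the cluster's statistic.
#'
#' @param cluster_voxels In-mask voxel indices of the cluster's centres.
#' @param searchlights A \code{searchlight_map}.
#' @return Sorted vector of in-mask voxel indices (a superset of the valid
#'   centres in \code{cluster_voxels}).
#' @export
dilate_roi <- function(cluster_voxels, searchlights) {
  stopifnot(inherits(searchlights, "searchlight_map"))
  if (length(cluster_voxels) == 0) {
    warning("empty cluster: ROI is empty")
    return(integer(0))
  }
  hit <- match(cluster_voxels, searchlights$centres)
  hit <- hit[!is.na(hit)]
  sort(unique(c(cluster_voxels, unlist(searchlights$members[hit]))))
}

#' Feature-space RSA for electrophysiological patterns
#'
#' Computes the Spearman correlation between every pair of trials across the
#' flattened spatiotemporal-spectral feature vector, Fisher z-transforms the
#' similarities, and contrasts same-stimulus against different-stimulus
#' pairs: the returned scalar (per participant) is mean(same) - mean(diff),
#' positive when trials of the same stimulus resemble each other more than
#' trials of different stimuli.
#'
#' @param features Trials x features numeric matrix (electrode x frequency x
#'   time features, flattened).
#' @param labels Per-trial stimulus ids.
#' @return List with \code{contrast} (scalar), \code{similarity} (trials x
#'   trials Fisher-z matrix), \code{n_same}, \code{n_diff}.
#' @export
eeg_feature_rsa <- function(features, labels) {
  stopifnot(nrow(features) == length(labels))
  if (min(table(labels)) < 2) {
    stop("need at least 2 trials per stimulus", call. = FALSE)
  }
  const <- apply(features, 1, function(x) stats::sd(x) == 0)
  S <- suppressWarnings(stats::cor(t(features), method = "spearman"))
  S[const, ] <- NA
  S[, const] <- NA
  Z <- fisher_z(S)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(Z)
  zs <- Z[ut & same]
  zd <- Z[ut & !same]
  list(contrast = mean(zs, na.rm = TRUE) - mean(zd, na.rm = TRUE),
       similarity = Z, n_same = sum(!is.na(zs)), n_diff = sum(!is.na(zd)))
}
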