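#' Per-participant regression linking power to trial information
#'
#' Ordinary least squares with stimulus-specific information (Fisher z per
#' trial) as the outcome and four z-scored predictors: post-stimulus
#' alpha/beta power plus the three confound regressors (pre-stimulus power,
#' BOLD amplitude, confidence rating). The per-regressor t-values
#' (beta / SE) standardise the effect across regressors and participants
#' and are what enters group-level inference. In \code{median_split} mode
#' the continuous post-power regressor is replaced by a 0/1 indicator of
#' above-median power.
#'
#' @param info Per-trial information (outcome); \code{NA}s drop the trial.
#' @param post_power,pre_power,bold_amplitude,confidence Per-trial
#'   predictors.
#' @param mode \code{"continuous"} (default) or \code{"median_split"}.
#' @return Object of class \code{link_regression}: \code{t_values} (named:
#'   post_power, pre_power, bold_amplitude, confidence),
#'   \code{coefficients}, \code{n_trials}, \code{n_dropped}, \code{mode}.
#' @export
fit_link_regression <- function(info, post_power, pre_power, bold_amplitude,
                                confidence,
                                mode = c("continuous", "median_split")) {
  mode <- match.arg(mode)
  dat <- data.frame(info = info, post_power = post_power,
                    pre_power = pre_power, bold_amplitude = bold_amplitude,
                    confidence = as.numeric(confidence))
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, ]
  n <- nrow(dat)
  if (n < 7) {
    stop("too few complete trials (", n, "): need at least 7", call. = FALSE)
  }
  if (anyDuplicated(dat) > 0) {
    warning("duplicated trials detected; t-values would be inflated")
  }
  post <- if (mode == "median_split") {
    as.numeric(dat$post_power > stats::median(dat$post_power))
  } else {
    zscore_vec(dat$post_power, "post_power")
  }
  X <- cbind(post_power = post,
             pre_power = zscore_vec(dat$pre_power, "pre_power"),
             bold_amplitude = zscore_vec(dat$bold_amplitude, "bold_amplitude"),
             confidence = zscore_vec(dat$confidence, "confidence"))
  if (kappa(cbind(1, X)) > 1e8) {
    stop("regressors are collinear (condition number > 1e8)", call. = FALSE)
  }
  fit <- stats::lm(dat$info ~ X)
  sm <- summary(fit)$coefficients
  rn <- sub("^X", "", rownames(sm))
  out <- list(t_values = stats::setNames(sm[-1, "t value"], rn[-1]),
              coefficients = stats::setNames(sm[-1, "Estimate"], rn[-1]),
              n_trials = n, n_dropped = n_dropped, mode = mode)
  class(out) <- "link_regression"
  out
}

#' @export
print.link_regression <- function(x, ...) {
  cat("Power-information link regression (", x$mode, ", ",
      x$n_trials, " trials", if (x$n_dropped > 0)
        paste0(", ", x$n_dropped, " dropped"), ")\n", sep = "")
  print(round(rbind(beta = x$coefficients, t = x$t_values), 3))
  invisible(x)
}

#' Sign-flip permutation one-sample t-test across participants
#'
#' Tests whether per-participant values (t-statistics or Fisher z) differ
#' from zero by randomly flipping the sign of each participant's value and
#' recomputing the group t-statistic. With 12 or fewer participants the
#' full set of 2^n sign assignments is enumerated (exact test); otherwise
#' \code{n_perm} random flips are drawn and the p-value uses the +1
#' correction, which keeps it valid at finite permutation counts.
#'
#' @param values Per-participant values.
#' @param tail \code{"left"}, \code{"right"}, or \code{"two"}.
#' @param n_perm Number of random sign flips (default 2000).
#' @param seed Integer seed for the sampled variant.
#' @param exhaustive Force (\code{TRUE}) or forbid (\code{FALSE}) the exact
#'   enumeration; default \code{NULL} enumerates when n <= 12. Forbidding it
#'   exists so the sampled estimator can be validated against the exact one.
#' @return List: \code{p}, \code{t_obs}, \code{mean_obs}, \code{n},
#'   \code{n_perm}, \code{exhaustive}.
#' @export
group_permutation_ttest <- function(values, tail = c("left", "right", "two"),
                                    n_perm = 2000, seed = 1,
                                    exhaustive = NULL) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n >= 2, n_perm >= 1)
  if (all(values == 0)) {
    warning("all values are zero; p = 1")
    return(list(p = 1, t_obs = 0, mean_obs = 0, n = n, n_perm = 0,
                exhaustive = TRUE))
  }
  ss <- sum(values^2)
  t_of_means <- function(m) {
    s2 <- (ss - n * m^2) / (n - 1)
    m / sqrt(s2 / n)
  }
  t_obs <- t_of_means(mean(values))
  if (exhaustive %||% (n <= 12)) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    m_perm <- as.vector(signs %*% values) / n
    t_perm <- t_of_means(m_perm)
    count <- switch(tail,
                    left = sum(t_perm <= t_obs),
                    right = sum(t_perm >= t_obs),
                    two = sum(abs(t_perm) >= abs(t_obs)))
    p <- count / nrow(signs)
    return(list(p = p, t_obs = t_obs, mean_obs = mean(values), n = n,
                n_perm = nrow(signs), exhaustive = TRUE))
  }
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  m_perm <- as.vector(signs %*% values) / n
  t_perm <- t_of_means(m_perm)
  count <- switch(tail,
                  left = sum(t_perm <= t_obs),
                  right = sum(t_perm >= t_obs),
                  two = sum(abs(t_perm) >= abs(t_obs)))
  list(p = (count + 1) / (n_perm + 1), t_obs = t_obs,
       mean_obs = mean(values), n = n, n_perm = n_perm, exhaustive = FALSE)
}

#' Orthogonal-neighbour adjacency for features on a regular lattice
#'
#' @param dims Integer vector of lattice dimensions (2-D time-frequency
#'   grids, 3-D voxel grids, ...). Features are indexed in array
#'   (column-major) order.
#' @return List of integer neighbour vectors, one per feature.
#' @export
lattice_adjacency <- function(dims) {
  nd <- length(dims)
  coords <- as.matrix(expand.grid(lapply(dims, seq_len)))
  n <- nrow(coords)
  idx <- array(seq_len(n), dims)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer(0)
    for (d in seq_len(nd)) {
      for (s in c(-1L, 1L)) {
        p <- coords[i, ]
        p[d] <- p[d] + s
        if (p[d] >= 1 && p[d] <= dims[d]) {
          nb <- c(nb, idx[matrix(p, 1)])
        }
      }
    }
    adj[[i]] <- nb
  }
  adj
}

# connected components of `nodes` (integer subset) under adjacency list
connected_components <- function(nodes, adjacency) {
  in_set <- logical(length(adjacency))
  in_set[nodes] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adjacency[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Cluster-based sign-flip permutation test over feature maps
#'
#' Family-wise inference over electrode, time-frequency or voxel features:
#' per-feature one-sample t-values are thresholded at the
#' \code{cluster_alpha} quantile of the t distribution, suprathreshold
#' features are grouped into connected clusters under the supplied
#' adjacency, and each cluster's summed t ("maxsum") is compared with the
#' permutation distribution of the maximal cluster sum obtained by flipping
#' participant signs.
#'
#' @param data Participants x features matrix.
#' @param adjacency Neighbour list as from \code{\link{lattice_adjacency}};
#'   features without neighbours form singleton clusters.
#' @param cluster_alpha Cluster-forming alpha (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 2000).
#' @param tail \code{"right"} (positive clusters), \code{"left"}, or
#'   \code{"two"}.
#' @param seed Integer seed.
#' @return Object of class \code{cluster_result}: \code{clusters} (list of
#'   \code{members}, \code{stat}, \code{p}), \code{t_values},
#'   \code{t_threshold}, \code{n_perm}.
#' @export
cluster_permutation_test <- function(data, adjacency, cluster_alpha = 0.05,
                                     n_perm = 2000,
                                     tail = c("right", "left", "two"),
                                     seed = 1) {
  tail <- match.arg(tail)
  n <- nrow(data)
  nf <- ncol(data)
  stopifnot(length(adjacency) == nf, n >= 2)
  df <- n - 1
  tcrit <- if (tail == "two") {
    stats::qt(1 - cluster_alpha / 2, df)
  } else {
    stats::qt(1 - cluster_alpha, df)
  }
  col_t <- function(X) {
    m <- colMeans(X)
    s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
    m / (s / sqrt(n))
  }
  # maximal cluster mass of one signed map
  max_mass <- function(tv) {
    mass <- 0
    pos <- if (tail != "left") which(tv > tcrit) else integer(0)
    neg <- if (tail != "right") which(tv < -tcrit) else integer(0)
    for (nodes in list(pos, neg)) {
      if (length(nodes) == 0) next
      for (comp in connected_components(nodes, adjacency)) {
        mass <- max(mass, abs(sum(tv[comp])))
      }
    }
    mass
  }
  t_obs <- col_t(data)
  obs_nodes <- switch(tail,
                      right = which(t_obs > tcrit),
                      left = which(t_obs < -tcrit),
                      two = which(abs(t_obs) > tcrit))
  obs_clusters <- if (length(obs_nodes) > 0) {
    connected_components(obs_nodes, adjacency)
  } else {
    list()
  }
  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    max_mass(col_t(data * flips))
  }, numeric(1))
  clusters <- lapply(obs_clusters, function(comp) {
    stat <- sum(t_obs[comp])
    list(members = comp, stat = stat,
         p = (sum(null_max >= abs(stat)) + 1) / (n_perm + 1))
  })
  structure(list(clusters = clusters, t_values = t_obs,
                 t_threshold = tcrit, n_perm = n_perm, tail = tail),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster permutation test (", x$tail, "-tailed, ", x$n_perm,
      " permutations, |t| > ", round(x$t_threshold, 3), ")\n", sep = "")
  if (length(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      cat(sprintf("  cluster %d: k = %d, sum(t) = %.2f, p = %.4f\n",
                  i, length(cl$members), cl$stat, cl$p))
    }
  }
  invisible(x)
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default-prior Bayes factor comparing the alternative (Cauchy prior with
#' scale \code{prior_scale} on the standardised effect size) against the
#' point null, computed from the one-sample t statistic by adaptive
#' numerical integration over the JZS mixing variable.
#'
#' @param values Per-participant values (used to compute t and n), or
#'   \code{NULL} if \code{t} and \code{n} are given directly.
#' @param t,n One-sample t statistic and sample size (alternative input).
#' @param prior_scale Cauchy prior scale r (default \code{sqrt(2)/2}, the
#'   conventional "medium" default).
#' @return BF10 (> 1 favours the alternative, < 1 the null).
#' @export
jzs_bayes_factor <- function(values = NULL, t = NULL, n = NULL,
                             prior_scale = sqrt(2) / 2) {
  stopifnot(prior_scale > 0)
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 2) stop("need at least 2 values", call. = FALSE)
    t <- mean(values) / (stats::sd(values) / sqrt(n))
  }
  stopifnot(is.finite(t), n >= 2)
  nu <- n - 1
  r <- prior_scale
  # integrand over u = log(g), g ~ inverse-gamma(1/2, r^2/2); evaluated in
  # log space so the tails underflow cleanly to zero
  integrand <- function(u) {
    g <- exp(u)
    lg <- -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
      log(r) - 0.5 * log(2 * pi) - 0.5 * u - r^2 / (2 * g)
    exp(lg)
  }
  num <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10,
                          stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value) || num$value <= 0) {
    stop("Bayes factor integration failed: ", num$message,
         " (value = ", num$value, ")", call. = FALSE)
  }
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  bf <- num$value / den
  attr(bf, "evidence") <- bf_evidence_label(bf)
  bf
}

# rule-of-thumb interpretation bands for BF10
bf_evidence_label <- function(bf) {
  b <- max(bf, 1 / bf)
  strength <- if (b < 3) "anecdotal" else if (b < 10) "moderate"
  else if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  dir <- if (bf >= 1) "for H1" else "for H0"
  paste(strength, dir)
}

#' Trial-wise correlation between spectral power and confidence
#'
#' Spearman rank correlation (the ratings are ordinal 1-4) between per-trial
#' power and confidence, Fisher z-transformed to an approximately normal
#' per-participant statistic. Group inference is done by passing the z
#' values to \code{\link{group_permutation_ttest}}.
#'
#' @param power Per-trial power values.
#' @param confidence Per-trial ordinal confidence ratings.
#' @return Fisher z of the Spearman correlation, or \code{NA} (with a
#'   warning) when confidence is constant.
#' @export
confidence_power_correlation <- function(power, confidence) {
  cc <- stats::complete.cases(power, confidence)
  power <- power[cc]; confidence <- confidence[cc]
  if (length(power) < 3) {
    stop("need at least 3 complete trials", call. = FALSE)
  }
  if (stats::sd(confidence) == 0) {
    warning("constant confidence: correlation undefined, participant flagged")
    return(NA_real_)
  }
  fisher_z(spearman_rho(power, as.numeric(confidence)))
}

#' Participant inclusion rule on memory outcome counts
#'
#' Participants need at least \code{min_trials} remembered and
#' \code{min_trials} forgotten trials to enter group analyses.
#'
#' @param remembered Logical vector of trial outcomes for one participant.
#' @param min_trials Minimum count per outcome (default 10).
#' @return \code{TRUE} if the participant is included.
#' @export
meets_inclusion_rule <- function(remembered, min_trials = 10) {
  sum(remembered) >= min_trials && sum(!remembered) >= min_trials
}

#' Attenuation of the observed power-fidelity correlation
#'
#' Simulates the restricted-variance regime: per-trial power is generated as
#' \code{-coupling * fidelity + noise} and the observed power-fidelity
#' correlation is tabulated against the SD of fidelity. As fidelity
#' variance shrinks, the observable correlation is attenuated towards zero
#' even though the generating coupling is unchanged — the closed form is
#' \code{coupling * sd_f / sqrt(coupling^2 sd_f^2 + noise_sd^2)}.
#' \code{observed_r} is the (sign-corrected) mean of the signed per-replicate
#' correlations, which is the unbiased estimate the closed form predicts;
#' \code{mean_abs_r} is also reported but carries the usual upward
#' magnitude bias when the true correlation is near zero.
#'
#' @param fidelity_sd Vector of fidelity SDs to scan (>= 0).
#' @param coupling Generating slope beta.
#' @param noise_sd SD of the additive power noise.
#' @param n_trials Trials per replicate.
#' @param n_reps Replicates per SD value.
#' @param seed Integer seed.
#' @return data.frame: \code{fidelity_sd}, \code{observed_r},
#'   \code{mean_abs_r}, \code{se}, \code{expected_r} (closed form),
#'   \code{n_reps}.
#' @export
attenuation_simulation <- function(fidelity_sd, coupling = 1, noise_sd = 1,
                                   n_trials = 100, n_reps = 100, seed = 1) {
  stopifnot(all(fidelity_sd >= 0))
  set.seed(seed)
  rows <- lapply(fidelity_sd, function(sf) {
    r <- vapply(seq_len(n_reps), function(i) {
      f <- stats::rnorm(n_trials, sd = sf)
      pw <- -coupling * f + stats::rnorm(n_trials, sd = noise_sd)
      if (sf == 0) 0 else stats::cor(f, pw)  # no variance, no correlation
    }, numeric(1))
    data.frame(fidelity_sd = sf, observed_r = -mean(r),
               mean_abs_r = mean(abs(r)),
               se = stats::sd(r) / sqrt(n_reps),
               expected_r = coupling * sf /
                 sqrt(coupling^2 * sf^2 + noise_sd^2),
               n_reps = n_reps)
  })
  do.call(rbind, rows)
}
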