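#' Null calibration of the searchlight information-map group test
#'
#' Repeatedly simulates groups of subjects whose fold-wise condition
#' patterns and residuals are pure Gaussian noise, maps stimulus
#' information with \code{\link{searchlight_information_map}}, applies a
#' voxelwise one-sample t-test across subjects at every searchlight centre,
#' and reports the rejection rate at \code{alpha} pooled over centres and
#' simulations. Under the null this should sit at the nominal level.
#'
#' @param n_sims Number of null group simulations.
#' @param n_subjects Subjects per simulation (default 24; small enough to be
#'   cheap, large enough for the t reference distribution to hold on the
#'   discrete per-subject z values).
#' @param mask_dims Mask dimensions (default \code{c(5, 5, 3)}).
#' @param radius_mm Searchlight radius (default 5).
#' @param n_stimuli Conditions per fold (default 4).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return List: \code{rate}, \code{n_tests}, \code{mean_z}.
#' @export
calibrate_information_map <- function(n_sims, n_subjects = 24,
                                      mask_dims = c(5, 5, 3), radius_mm = 5,
                                      n_stimuli = 4, alpha = 0.05, seed = 1) {
  mask <- array(TRUE, mask_dims)
  sl <- build_searchlights(mask, c(3, 3, 4), radius_mm = radius_mm,
                           min_fraction = 0.6)
  nv <- sum(mask)
  set.seed(seed)
  rej <- 0
  tot <- 0
  zsum <- 0
  for (s in seq_len(n_sims)) {
    zs <- vapply(seq_len(n_subjects), function(su) {
      fa <- matrix(stats::rnorm(n_stimuli * nv), n_stimuli)
      fb <- matrix(stats::rnorm(n_stimuli * nv), n_stimuli)
      res <- matrix(stats::rnorm(60 * nv), 60)
      searchlight_information_map(fa, fb, seq_len(n_stimuli), res, sl)
    }, numeric(length(sl$centres)))
    pv <- apply(zs, 1, function(v) stats::t.test(v)$p.value)
    rej <- rej + sum(pv <= alpha)
    tot <- tot + length(pv)
    zsum <- zsum + mean(zs)
  }
  list(rate = rej / tot, n_tests = tot, mean_z = zsum / n_sims)
}

#' Null calibration of the sign-flip group permutation test
#'
#' @param n_sims Number of null simulations (i.i.d. standard normal
#'   participant values).
#' @param n_subjects Participants per simulation (default 12: the exact
#'   enumeration branch).
#' @param alpha Test level (default 0.05).
#' @param tail Test tail (default two-sided).
#' @param seed Integer seed.
#' @return List: \code{rate}, \code{n_sims}.
#' @export
calibrate_group_test <- function(n_sims, n_subjects = 12, alpha = 0.05,
                                 tail = "two", seed = 1) {
  set.seed(seed)
  rej <- vapply(seq_len(n_sims), function(i) {
    group_permutation_ttest(stats::rnorm(n_subjects), tail = tail,
                            seed = i)$p <= alpha
  }, logical(1))
  list(rate = mean(rej), n_sims = n_sims)
}

#' Null family-wise calibration of the cluster permutation test
#'
#' @param n_sims Number of null simulations (feature maps of i.i.d. noise).
#' @param dims Feature lattice dimensions (default \code{c(8, 8)}).
#' @param n_subjects Participants per simulation (default 12).
#' @param n_perm Inner sign-flip permutations (default 250).
#' @param alpha Family-wise level (default 0.05).
#' @param seed Integer seed.
#' @return List: \code{rate} (fraction of simulations with any cluster
#'   p <= alpha), \code{n_sims}.
#' @export
calibrate_cluster_test <- function(n_sims, dims = c(8, 8), n_subjects = 12,
                                   n_perm = 250, alpha = 0.05, seed = 1) {
  adj <- lattice_adjacency(dims)
  set.seed(seed)
  seeds <- sample.int(1e6, n_sims)
  rej <- vapply(seq_len(n_sims), function(i) {
    d <- matrix(stats::rnorm(n_subjects * prod(dims)), n_subjects)
    cr <- cluster_permutation_test(d, adj, cluster_alpha = alpha,
                                   n_perm = n_perm, tail = "right",
                                   seed = seeds[i])
    ps <- vapply(cr$clusters, function(cl) cl$p, numeric(1))
    length(ps) > 0 && any(ps <= alpha)
  }, logical(1))
  list(rate = mean(rej), n_sims = n_sims)
}

#' Null calibration of the confidence-power correlation group test
#'
#' @param n_sims Number of null simulations.
#' @param n_subjects Participants per simulation (default 12).
#' @param n_trials Trials per participant (default 40).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @return List: \code{rate}, \code{n_sims}.
#' @export
calibrate_confidence_correlation <- function(n_sims, n_subjects = 12,
                                             n_trials = 40, alpha = 0.05,
                                             seed = 1) {
  set.seed(seed)
  rej <- vapply(seq_len(n_sims), function(i) {
    z <- vapply(seq_len(n_subjects), function(s) {
      confidence_power_correlation(stats::rnorm(n_trials),
                                   sample(1:4, n_trials, replace = TRUE))
    }, numeric(1))
    group_permutation_ttest(z, tail = "two", seed = i)$p <= alpha
  }, logical(1))
  list(rate = mean(rej), n_sims = n_sims)
}

#' Detection power of the end-to-end power-information link pipeline
#'
#' Replicates the full study simulation (patterns with latent fidelity →
#' single-trial information → coupled power → per-participant regression →
#' one-tailed group permutation test) and reports how often the group test
#' rejects at \code{alpha}. With the default moderate coupling this is the
#' pipeline's statistical power; with \code{coupling = 0} it is the
#' empirical false-positive rate.
#'
#' @param n_reps Number of replicate studies.
#' @param coupling Generating power-fidelity slope.
#' @param n_subjects Participants per study (default 21).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{simulate_link_participant}}.
#' @return List: \code{rate}, \code{p_values}.
#' @export
link_pipeline_power <- function(n_reps, coupling = 1, n_subjects = 21,
                                alpha = 0.05, seed = 1, ...) {
  set.seed(seed)
  rep_seeds <- sample.int(1e7, n_reps)
  ps <- vapply(seq_len(n_reps), function(r) {
    simulate_link_study(n_subjects = n_subjects, coupling = coupling,
                        seed = rep_seeds[r], ...)$p
  }, numeric(1))
  list(rate = mean(ps <= alpha), p_values = ps)
}
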