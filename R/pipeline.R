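#' Simulate one participant and run the single-trial link analysis
#'
#' Generates a participant with known ground truth and pushes the data
#' through the single-trial pipeline: per-trial retrieval patterns with
#' Beta-distributed latent fidelity, fold-wise perception condition
#' patterns, a shrunk noise covariance from simulated residuals, the
#' single-trial reinstatement information statistic, fidelity-coupled trial
#' power with nuisance series, and the per-participant four-regressor link
#' regression.
#'
#' @param n_trials Remembered retrieval trials.
#' @param n_voxels ROI size in voxels (default 60).
#' @param n_stimuli Number of stimuli (default 4).
#' @param separation Prototype separation (default 3).
#' @param pattern_noise_sd Voxel noise SD on trial patterns (default 1).
#' @param fidelity_mean,fidelity_sd Beta fidelity moments (defaults 0.5,
#'   0.2).
#' @param coupling Power-fidelity slope beta (default 1).
#' @param power_noise_sd Noise SD on post-stimulus power (default 0.35).
#' @param n_perception_reps Perception trials per stimulus per fold used as
#'   comparison patterns (default 12).
#' @param n_residual_samples Residual samples for covariance estimation
#'   (default 120).
#' @param seed Integer seed.
#' @return List: \code{regression} (a \code{link_regression}),
#'   \code{info} (trial information data.frame), \code{power} (trial power
#'   data.frame), \code{fidelity} (ground truth).
#' @export
simulate_link_participant <- function(n_trials = 100, n_voxels = 60,
                                      n_stimuli = 4, separation = 3,
                                      pattern_noise_sd = 1,
                                      fidelity_mean = 0.5, fidelity_sd = 0.2,
                                      coupling = 1, power_noise_sd = 0.35,
                                      n_perception_reps = 12,
                                      n_residual_samples = 120, seed = 1) {
  set.seed(seed)
  proto <- make_stimulus_prototypes(n_voxels, n_stimuli, separation,
                                    seed = seed)
  fidelity <- draw_fidelity(n_trials, fidelity_mean, fidelity_sd)
  labels <- rep_len(seq_len(n_stimuli), n_trials)
  patterns <- fidelity * proto[labels, , drop = FALSE] +
    matrix(stats::rnorm(n_trials * n_voxels, sd = pattern_noise_sd),
           n_trials)
  # trial-level perception comparison patterns, two folds: distances are
  # taken to every perception trial, not to condition averages
  perc_labels <- rep(seq_len(n_stimuli), n_perception_reps)
  perc <- lapply(1:2, function(f) {
    proto[perc_labels, , drop = FALSE] +
      matrix(stats::rnorm(length(perc_labels) * n_voxels,
                          sd = pattern_noise_sd), length(perc_labels))
  })
  resid <- matrix(stats::rnorm(n_residual_samples * n_voxels,
                               sd = pattern_noise_sd), n_residual_samples)
  cov <- shrink_covariance(resid)
  info <- retrieval_trial_information(patterns, labels,
                                      remembered = rep(TRUE, n_trials),
                                      perception_patterns = perc,
                                      perception_labels = perc_labels,
                                      cov = cov)
  power <- simulate_trial_power(fidelity, coupling = coupling,
                                noise_sd = power_noise_sd, seed = seed + 1)
  reg <- fit_link_regression(info$z_info, power$post_power, power$pre_power,
                             power$bold_amplitude, power$confidence)
  list(regression = reg, info = info, power = power, fidelity = fidelity)
}

#' Group-level power-information link analysis on simulated participants
#'
#' Runs \code{\link{simulate_link_participant}} for every participant,
#' collects the post-stimulus-power t-values, and tests them against zero
#' with the one-tailed (left: a negative coupling is predicted) sign-flip
#' permutation test.
#'
#' @param n_subjects Number of participants (default 21).
#' @param coupling Power-fidelity slope beta shared by all participants.
#' @param n_perm Permutations for the group test (default 2000).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{simulate_link_participant}}.
#' @return List: \code{p}, \code{t_values} (per participant, all four
#'   regressors), \code{group} (the permutation-test result).
#' @export
simulate_link_study <- function(n_subjects = 21, coupling = 1, n_perm = 2000,
                                seed = 1, ...) {
  set.seed(seed)
  subj_seeds <- sample.int(1e7, n_subjects)
  tv <- vapply(seq_len(n_subjects), function(s) {
    simulate_link_participant(coupling = coupling,
                              seed = subj_seeds[s], ...)$regression$t_values
  }, numeric(4))
  group <- group_permutation_ttest(tv["post_power", ], tail = "left",
                                   n_perm = n_perm, seed = seed)
  list(p = group$p, t_values = t(tv), group = group)
}
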