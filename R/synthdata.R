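#' Generate a balanced paired-associates trial table
#'
#' Builds the trial bookkeeping for a paired-associates study in which a
#' small set of dynamic stimuli is repeated many times: each block presents
#' every stimulus equally often at encoding and probes every pair once at
#' retrieval. Memory outcomes are drawn per pair; a trial counts as
#' "remembered" exactly when the response was correct and the confidence
#' rating exceeded 1 (i.e. the participant indicated it was not a guess).
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Encoding trials per block; must be divisible by
#'   \code{n_stimuli}.
#' @param n_stimuli Number of distinct stimuli (default 4).
#' @param memory_rate Probability that a pair is later remembered.
#' @param seed Integer seed; the table is reproducible given the seed.
#' @param soa_s Stimulus onset asynchrony in seconds (default 8, jittered by
#'   up to 2 s).
#' @return A data.frame of class \code{trial_table} with one row per trial
#'   and columns \code{trial_id}, \code{stimulus}, \code{phase}
#'   (\code{"encoding"}/\code{"retrieval"}), \code{block}, \code{modality},
#'   \code{confidence} (1-4), \code{correct}, \code{remembered},
#'   \code{onset_s}.
#' @examples
#' tab <- make_trial_table(4, 48, 4, memory_rate = 0.634, seed = 1)
#' table(tab$stimulus[tab$phase == "encoding"], tab$block[tab$phase == "encoding"])
#' @export
make_trial_table <- function(n_blocks, trials_per_block, n_stimuli = 4,
                             memory_rate = 0.634, seed = 1, soa_s = 8) {
  if (trials_per_block %% n_stimuli != 0) {
    stop("trials_per_block (", trials_per_block,
         ") must be divisible by n_stimuli (", n_stimuli,
         ") for a balanced design", call. = FALSE)
  }
  if (memory_rate < 0 || memory_rate > 1) {
    stop("memory_rate must be a probability in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  reps <- trials_per_block / n_stimuli
  blocks <- lapply(seq_len(n_blocks), function(b) {
    stim <- sample(rep(seq_len(n_stimuli), reps))
    remembered <- stats::runif(trials_per_block) < memory_rate
    confidence <- integer(trials_per_block)
    correct <- logical(trials_per_block)
    # remembered: correct and not a guess; forgotten: wrong answer, or a
    # correct guess at confidence 1
    confidence[remembered] <- sample(2:4, sum(remembered), replace = TRUE,
                                     prob = c(0.2, 0.35, 0.45))
    correct[remembered] <- TRUE
    nf <- sum(!remembered)
    if (nf > 0) {
      lucky <- stats::runif(nf) < 0.25
      correct[!remembered] <- lucky
      cf <- integer(nf)
      cf[lucky] <- 1L
      cf[!lucky] <- sample(1:4, sum(!lucky), replace = TRUE,
                           prob = c(0.45, 0.3, 0.15, 0.1))
      confidence[!remembered] <- cf
    }
    onset_enc <- (seq_len(trials_per_block) - 1) * soa_s +
      stats::runif(trials_per_block, 0, 2)
    onset_ret <- (seq_len(trials_per_block) - 1) * soa_s +
      stats::runif(trials_per_block, 0, 2)
    modality <- if (b %% 2 == 1) "visual" else "auditory"
    ret_order <- sample(trials_per_block)
    data.frame(
      stimulus = c(stim, stim[ret_order]),
      phase = rep(c("encoding", "retrieval"), each = trials_per_block),
      block = b,
      modality = modality,
      confidence = c(confidence, confidence[ret_order]),
      correct = c(correct, correct[ret_order]),
      remembered = c(remembered, remembered[ret_order]),
      onset_s = c(onset_enc, onset_ret),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  stopifnot(all(out$remembered == (out$correct & out$confidence > 1)))
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Construct equidistant stimulus prototype patterns
#'
#' Places \code{n_stimuli} prototype voxel patterns at the vertices of a
#' regular simplex embedded in voxel space: every row has the same norm and
#' every pairwise Euclidean distance equals \code{separation} exactly. The
#' simplex orientation is random (seeded) so no voxel is privileged.
#'
#' @param n_voxels Number of voxels (>= \code{n_stimuli}).
#' @param n_stimuli Number of prototypes.
#' @param separation Pairwise Euclidean distance between prototypes (>= 0).
#' @param seed Integer seed for the random orientation.
#' @return \code{n_stimuli x n_voxels} numeric matrix.
#' @export
make_stimulus_prototypes <- function(n_voxels, n_stimuli = 4, separation = 1,
                                     seed = 1) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (n_voxels < n_stimuli) {
    stop("need n_voxels >= n_stimuli to embed the simplex", call. = FALSE)
  }
  set.seed(seed)
  # orthonormal frame scaled so ||e_i - e_j|| = sqrt(2) becomes `separation`
  Q <- qr.Q(qr(matrix(stats::rnorm(n_voxels * n_stimuli), n_voxels)))
  t(Q) * separation / sqrt(2)
}

#' Bundle the ground-truth parameters of a simulated session
#'
#' @param prototypes Stimulus prototype matrix (stimuli x voxels).
#' @param fidelity Per-trial pattern fidelity in \code{[0, 1]}.
#' @param coupling Power-fidelity slope (beta >= 0 means higher fidelity goes
#'   with lower post-stimulus power).
#' @param noise_cov Voxel noise covariance (symmetric positive-definite), or
#'   a zero matrix for noiseless simulation.
#' @param aperiodic_slope True 1/f exponent of simulated electrophysiology.
#' @param osc_amplitude Amplitude of the injected oscillation.
#' @return A list of class \code{ground_truth}.
#' @export
ground_truth <- function(prototypes, fidelity, coupling = 0.5,
                         noise_cov = diag(ncol(prototypes)),
                         aperiodic_slope = 1, osc_amplitude = 1) {
  stopifnot(is.matrix(prototypes), is.matrix(noise_cov))
  if (any(fidelity < 0 | fidelity > 1)) {
    stop("fidelity must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(noise_cov) != ncol(prototypes) ||
      max(abs(noise_cov - t(noise_cov))) > 1e-8) {
    stop("noise_cov must be symmetric with dimension n_voxels", call. = FALSE)
  }
  if (any(noise_cov != 0) && min(eigen(noise_cov, TRUE, TRUE)$values) <= 0) {
    stop("noise_cov must be positive-definite (or all zero)", call. = FALSE)
  }
  structure(list(prototypes = prototypes, fidelity = fidelity,
                 coupling = coupling, noise_cov = noise_cov,
                 aperiodic_slope = aperiodic_slope,
                 osc_amplitude = osc_amplitude),
            class = "ground_truth")
}

#' Draw per-trial fidelities from a Beta distribution by moments
#'
#' Fidelity is bounded in \code{[0, 1]}; a Beta prior parameterised by mean
#' and standard deviation covers both the realistic moderate-variance regime
#' and the low-variance regime where observed power-information correlations
#' are strongly attenuated.
#'
#' @param n Number of trials.
#' @param mean,sd Target mean and standard deviation (must satisfy
#'   \code{sd^2 < mean * (1 - mean)}).
#' @param seed Optional integer seed.
#' @return Numeric vector of length \code{n}.
#' @export
draw_fidelity <- function(n, mean = 0.5, sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("sd too large for a Beta distribution with this mean", call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Exponential-decay spatial noise covariance on a voxel grid
#'
#' @param coords Voxel coordinates in mm (n_voxels x 3), or an integer count
#'   in which case a 1-D chain with unit spacing is used.
#' @param sigma Marginal noise SD per voxel.
#' @param range_mm Correlation e-folding distance in mm.
#' @return Positive-definite covariance matrix.
#' @export
make_noise_cov <- function(coords, sigma = 1, range_mm = 4) {
  if (is.numeric(coords) && length(coords) == 1) {
    coords <- cbind(seq_len(coords), 0, 0)
  }
  d <- as.matrix(stats::dist(coords))
  sigma^2 * exp(-d / range_mm)
}

#' Simulate a BOLD session with known per-trial patterns
#'
#' Forward model: each trial contributes its fidelity-scaled stimulus
#' prototype, placed under a boxcar of the stimulus duration convolved with
#' the canonical double-gamma HRF, plus temporally white, spatially
#' correlated Gaussian noise. The noiseless per-trial patterns
#' \code{fidelity * prototype} are returned so downstream estimators can be
#' validated against ground truth.
#'
#' @param table A \code{trial_table} (or subset of rows, e.g. one block's
#'   encoding trials).
#' @param truth A \code{ground_truth} object; \code{truth$fidelity} must have
#'   one entry per row of \code{table}.
#' @param tr_s Repetition time in seconds (default 2).
#' @param duration_s Event (video) duration in seconds (default 3).
#' @param hrf_params Optional list overriding \code{\link{hrf_double_gamma}}
#'   defaults.
#' @param seed Integer seed for the noise draw.
#' @return List with \code{timeseries} (volumes x voxels), \code{true_patterns}
#'   (trials x voxels), \code{design} (the per-trial \code{design_matrix}),
#'   and \code{table}.
#' @export
simulate_bold_session <- function(table, truth, tr_s = 2, duration_s = 3,
                                  hrf_params = list(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  n_trials <- nrow(table)
  if (length(truth$fidelity) != n_trials) {
    stop("truth$fidelity must have one value per trial", call. = FALSE)
  }
  if (anyDuplicated(table$onset_s)) {
    warning("duplicated onsets: per-trial regressors will be collinear")
  }
  n_voxels <- ncol(truth$prototypes)
  n_volumes <- ceiling((max(table$onset_s) + duration_s + 24) / tr_s)
  design <- build_design_matrix(table, n_volumes = n_volumes, tr_s = tr_s,
                                mode = "per_trial", duration_s = duration_s,
                                hrf = hrf_params)
  true_patterns <- truth$fidelity * truth$prototypes[table$stimulus, ,
                                                     drop = FALSE]
  Y <- design$matrix[, seq_len(n_trials), drop = FALSE] %*% true_patterns
  if (any(truth$noise_cov != 0)) {
    set.seed(seed)
    Y <- Y + rmvnorm_chol(n_volumes, truth$noise_cov)
  }
  list(timeseries = Y, true_patterns = true_patterns, design = design,
       table = table)
}

#' Simulate trial-wise spectral power coupled to pattern fidelity
#'
#' Generates the four per-trial series consumed by the power-information
#' regression: post-stimulus power follows
#' \code{a - beta * fidelity + gamma_c * confidence + gamma_b * bold + noise};
#' pre-stimulus power and BOLD amplitude are independent of fidelity by
#' construction; confidence is an ordinal 1-4 rating obtained by
#' quartile-thresholding a latent Gaussian correlated with fidelity.
#'
#' @param fidelity Per-trial fidelity values.
#' @param coupling Slope beta of the negative fidelity-to-power coupling.
#' @param noise_sd SD of the additive noise on post-stimulus power.
#' @param intercept Baseline power level \code{a}.
#' @param gamma_confidence,gamma_bold Nuisance coefficients (default 0).
#' @param confidence_fidelity_cor Latent correlation between fidelity and the
#'   confidence rating (default 0.3).
#' @param pre_sd,bold_sd SDs of pre-stimulus power and BOLD amplitude.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{post_power}, \code{pre_power},
#'   \code{bold_amplitude}, \code{confidence}; the generating coefficients
#'   are attached as attribute \code{"coefficients"}.
#' @export
simulate_trial_power <- function(fidelity, coupling = 0.5, noise_sd = 0.5,
                                 intercept = 0, gamma_confidence = 0,
                                 gamma_bold = 0,
                                 confidence_fidelity_cor = 0.3,
                                 pre_sd = 1, bold_sd = 1, seed = 1) {
  stopifnot(is.finite(coupling), noise_sd >= 0, pre_sd >= 0, bold_sd >= 0)
  set.seed(seed)
  n <- length(fidelity)
  fz <- if (stats::sd(fidelity) > 0) zscore_vec(fidelity) else rep(0, n)
  latent <- confidence_fidelity_cor * fz +
    sqrt(max(0, 1 - confidence_fidelity_cor^2)) * stats::rnorm(n)
  confidence <- as.integer(cut(latent,
    breaks = c(-Inf, stats::qnorm(c(0.25, 0.5, 0.75)), Inf), labels = FALSE))
  bold <- stats::rnorm(n, sd = bold_sd)
  pre <- stats::rnorm(n, sd = pre_sd)
  post <- intercept - coupling * fidelity + gamma_confidence * confidence +
    gamma_bold * bold + stats::rnorm(n, sd = noise_sd)
  out <- data.frame(post_power = post, pre_power = pre,
                    bold_amplitude = bold, confidence = confidence)
  attr(out, "coefficients") <- c(intercept = intercept, coupling = coupling,
                                 gamma_confidence = gamma_confidence,
                                 gamma_bold = gamma_bold, noise_sd = noise_sd)
  out
}

#' Simulate epoched electrophysiology with 1/f and oscillatory content
#'
#' Each epoch is coloured Gaussian noise with power spectral density
#' proportional to \code{f^(-slope)} — synthesised by shaping the discrete
#' Fourier transform of white noise (DC bin zeroed) — plus a sinusoid of
#' known frequency and amplitude with a random phase per trial.
#'
#' @param n_trials Number of epochs.
#' @param fs Sampling rate in Hz.
#' @param duration_s Epoch length in seconds.
#' @param slope Aperiodic exponent chi (PSD proportional to
#'   \code{f^(-chi)}); 0 gives white noise.
#' @param intercept log10 scale of the aperiodic PSD.
#' @param osc_freq Oscillation frequency in Hz (must be below Nyquist).
#' @param osc_amp Oscillation amplitude (0 disables it).
#' @param seed Integer seed.
#' @return \code{n_trials x n_samples} matrix with attributes \code{fs} and
#'   \code{times_s}.
#' @export
simulate_eeg_epochs <- function(n_trials, fs, duration_s, slope = 1,
                                intercept = 0, osc_freq = 10, osc_amp = 0,
                                seed = 1) {
  stopifnot(duration_s > 0, fs > 0)
  if (osc_amp != 0 && (osc_freq <= 0 || osc_freq >= fs / 2)) {
    stop("osc_freq must lie in (0, fs/2)", call. = FALSE)
  }
  set.seed(seed)
  n <- round(fs * duration_s)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # absolute frequency of each DFT bin
  shape <- sqrt(10^intercept) * ifelse(freqs > 0, freqs^(-slope / 2), 0)
  tt <- (seq_len(n) - 1) / fs
  epochs <- matrix(0, n_trials, n)
  for (i in seq_len(n_trials)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    if (osc_amp != 0) {
      x <- x + osc_amp * sin(2 * pi * osc_freq * tt + stats::runif(1, 0, 2 * pi))
    }
    epochs[i, ] <- x
  }
  attr(epochs, "fs") <- fs
  attr(epochs, "times_s") <- tt
  epochs
}
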