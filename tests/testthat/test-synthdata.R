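test_that("trial tables are balanced, rule-consistent and reproducible", {
  tab <- make_trial_table(4, 48, 4, memory_rate = 0.634, seed = 3)
  enc <- tab[tab$phase == "encoding", ]
  counts <- table(enc$stimulus, enc$block)
  expect_true(all(counts == 12))
  expect_identical(tab$remembered, tab$correct & tab$confidence > 1)
  for (b in unique(tab$block)) {
    for (ph in c("encoding", "retrieval")) {
      on <- tab$onset_s[tab$block == b & tab$phase == ph]
      expect_true(all(diff(on) > 0))
    }
  }
  expect_identical(tab, make_trial_table(4, 48, 4, memory_rate = 0.634,
                                         seed = 3))
  expect_false(identical(tab, make_trial_table(4, 48, 4,
                                               memory_rate = 0.634,
                                               seed = 4)))
})

test_that("memory_rate boundaries and divisibility are enforced", {
  all_rem <- make_trial_table(2, 16, 4, memory_rate = 1, seed = 1)
  expect_true(all(all_rem$remembered))
  expect_true(all(all_rem$confidence >= 2))
  none <- make_trial_table(2, 16, 4, memory_rate = 0, seed = 1)
  expect_true(all(!none$remembered))
  expect_error(make_trial_table(2, 50, 4), "divisible")
  expect_error(make_trial_table(2, 16, 4, memory_rate = 1.2), "probability")
})

test_that("remembered fraction matches the binomial closed form", {
  p <- 0.634
  n_tables <- 200
  frac <- vapply(seq_len(n_tables), function(s) {
    tab <- make_trial_table(4, 48, 4, memory_rate = p, seed = 1000 + s)
    mean(tab$remembered[tab$phase == "retrieval"])
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n_tables * 192))
  expect_lt(abs(mean(frac) - p), 4 * se)
})

test_that("prototypes form an equidistant equal-norm simplex", {
  P <- make_stimulus_prototypes(100, 4, separation = 2, seed = 5)
  d <- as.matrix(dist(P))
  expect_true(all(abs(d[upper.tri(d)] - 2) < 1e-9))
  norms <- sqrt(rowSums(P^2))
  expect_true(all(abs(norms - norms[1]) < 1e-9))
  expect_identical(P, make_stimulus_prototypes(100, 4, 2, seed = 5))
  P0 <- make_stimulus_prototypes(10, 4, separation = 0, seed = 1)
  expect_true(all(abs(P0) < 1e-12))
  expect_error(make_stimulus_prototypes(10, 4, separation = -1), ">= 0")
  expect_error(make_stimulus_prototypes(3, 4), "n_voxels")
})

test_that("noiseless BOLD simulation round-trips through the GLM", {
  tab <- make_trial_table(1, 16, 4, memory_rate = 1, seed = 2)
  enc <- tab[tab$phase == "encoding", ]
  proto <- make_stimulus_prototypes(12, 4, separation = 2, seed = 1)
  truth <- ground_truth(proto, fidelity = rep(1, 16),
                        noise_cov = matrix(0, 12, 12))
  sess <- simulate_bold_session(enc, truth, seed = 1)
  fit <- estimate_betas(sess$timeseries, sess$design)
  est <- fit$patterns[seq_len(16), ]
  expect_lt(max(abs(est - sess$true_patterns)), 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("BOLD forward model is linear in fidelity", {
  tab <- make_trial_table(1, 8, 4, memory_rate = 1, seed = 2)
  enc <- tab[tab$phase == "encoding", ]
  proto <- make_stimulus_prototypes(6, 4, 1, seed = 1)
  f <- seq(0.05, 0.5, length.out = 8)
  t1 <- ground_truth(proto, f, noise_cov = matrix(0, 6, 6))
  t2 <- ground_truth(proto, 2 * f, noise_cov = matrix(0, 6, 6))
  s1 <- simulate_bold_session(enc, t1, seed = 1)
  s2 <- simulate_bold_session(enc, t2, seed = 1)
  expect_equal(2 * s1$true_patterns, s2$true_patterns, tolerance = 1e-12)
  expect_equal(2 * s1$timeseries, s2$timeseries, tolerance = 1e-12)
  t0 <- ground_truth(proto, rep(0, 8), noise_cov = matrix(0, 6, 6))
  s0 <- simulate_bold_session(enc, t0, seed = 1)
  expect_true(all(s0$true_patterns == 0))
  expect_true(all(abs(s0$timeseries) < 1e-12))
})

test_that("duplicated onsets trigger a collinearity warning", {
  tab <- make_trial_table(1, 8, 4, memory_rate = 1, seed = 2)
  enc <- tab[tab$phase == "encoding", ]
  enc$onset_s[2] <- enc$onset_s[1]
  proto <- make_stimulus_prototypes(6, 4, 1, seed = 1)
  truth <- ground_truth(proto, rep(1, 8), noise_cov = matrix(0, 6, 6))
  expect_warning(simulate_bold_session(enc, truth, seed = 1), "collinear")
})

test_that("trial power follows the stated generating equation", {
  f <- draw_fidelity(50, 0.5, 0.2, seed = 1)
  p0 <- simulate_trial_power(f, coupling = 0, noise_sd = 0, seed = 2)
  expect_true(all(abs(p0$post_power - p0$post_power[1]) < 1e-12))
  p1 <- simulate_trial_power(f, coupling = 1, noise_sd = 0, seed = 2)
  expect_equal(cor(p1$post_power, f), -1, tolerance = 1e-12)
  # pre-stimulus power independent of fidelity by construction
  expect_lt(abs(cor(p1$pre_power, f)), 0.5)
})

test_that("OLS recovers the generating power-fidelity slope on average", {
  n_rep <- 300
  slopes <- vapply(seq_len(n_rep), function(i) {
    f <- draw_fidelity(200, 0.5, 0.2, seed = i)
    pw <- simulate_trial_power(f, coupling = 0.5, noise_sd = 0.5,
                               seed = 5000 + i)
    unname(coef(lm(pw$post_power ~ f))[2])
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - (-0.5)), 3 * mc_se)
})

test_that("confidence is ordinal and coupled to fidelity via the latent", {
  f <- draw_fidelity(4000, 0.5, 0.2, seed = 1)
  pw <- simulate_trial_power(f, confidence_fidelity_cor = 0.6, seed = 2)
  expect_true(all(pw$confidence %in% 1:4))
  expect_gt(cor(f, pw$confidence, method = "spearman"), 0.2)
})

test_that("simulated epochs have the requested spectral content", {
  ep <- simulate_eeg_epochs(2, 200, 10, slope = 0, osc_amp = 0, seed = 9)
  expect_identical(ep, simulate_eeg_epochs(2, 200, 10, slope = 0,
                                           osc_amp = 0, seed = 9))
  # white-noise limit: log-log PSD slope ~ 0
  ps <- welch_psd(ep[1, ], 200, seg_s = 1)
  sel <- ps$freqs_hz >= 1 & ps$freqs_hz <= 40
  sl <- unname(coef(lm(log10(ps$psd[sel]) ~ log10(ps$freqs_hz[sel])))[2])
  expect_lt(abs(sl), 0.25)
  expect_error(simulate_eeg_epochs(1, 100, 2, osc_freq = 60, osc_amp = 1),
               "osc_freq")
  # pure sinusoid: wavelet power peaks at the oscillation frequency
  ep2 <- simulate_eeg_epochs(1, 200, 6, slope = 1, intercept = -3,
                             osc_freq = 12, osc_amp = 2, seed = 4)
  tfr <- morlet_tfr(ep2, 200, freqs = seq(8, 30, 1))
  mid <- which.min(abs(tfr$times_s - 3))
  expect_equal(tfr$freqs_hz[which.max(tfr$power[1, , mid, 1])], 12)
})

test_that("generated voxel noise covariance converges to the target", {
  sigma <- make_noise_cov(cbind(1:8, 0, 0), sigma = 1.5, range_mm = 3)
  expect_true(all(eigen(sigma, TRUE, TRUE)$values > 0))
  err <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(11)
    X <- fidelitylink:::rmvnorm_chol(n, sigma)
    norm(cov(X) - sigma, "F")
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[3], 5)  # ~ 1/sqrt(n) shrinkage over 100x samples
})

test_that("ground truth validates its inputs", {
  proto <- make_stimulus_prototypes(6, 4, 1, seed = 1)
  expect_error(ground_truth(proto, fidelity = c(0.5, 1.2)), "\\[0, 1\\]")
  bad <- diag(6)
  bad[1, 2] <- 0.5  # asymmetric
  expect_error(ground_truth(proto, 0.5, noise_cov = bad), "symmetric")
  notpd <- matrix(1, 6, 6)
  expect_error(ground_truth(proto, 0.5, noise_cov = notpd),
               "positive-definite")
})
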