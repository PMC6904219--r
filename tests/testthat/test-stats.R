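test_that("link regression recovers a planted coupling and nulls nuisances", {
  f <- draw_fidelity(80, 0.5, 0.2, seed = 1)
  pw <- simulate_trial_power(f, coupling = 1, noise_sd = 0.01, seed = 2)
  reg <- fit_link_regression(f, pw$post_power, pw$pre_power,
                             pw$bold_amplitude, pw$confidence)
  expect_lt(reg$t_values["post_power"], -10)
  expect_true(all(abs(reg$t_values[c("pre_power", "bold_amplitude")]) < 3))
})

test_that("link regression t-values are affine-invariant in predictors", {
  set.seed(3)
  info <- rnorm(40)
  post <- rnorm(40); pre <- rnorm(40); bold <- rnorm(40)
  conf <- sample(1:4, 40, TRUE)
  r1 <- fit_link_regression(info, post, pre, bold, conf)
  r2 <- fit_link_regression(info, 100 * post - 7, pre / 3, bold + 5, conf)
  expect_equal(r1$t_values, r2$t_values, tolerance = 1e-9)
})

test_that("link regression guards degenerate inputs", {
  set.seed(4)
  info <- rnorm(20)
  post <- rnorm(20)
  expect_error(fit_link_regression(info, post, post, rnorm(20),
                                   sample(1:4, 20, TRUE)), "collinear")
  expect_error(fit_link_regression(rnorm(5), rnorm(5), rnorm(5), rnorm(5),
                                   c(1, 2, 3, 4, 1)), "too few")
  dup_info <- rep(rnorm(10), 2)
  dup_post <- rep(rnorm(10), 2)
  dup_pre <- rep(rnorm(10), 2)
  dup_bold <- rep(rnorm(10), 2)
  dup_conf <- rep(sample(1:4, 10, TRUE), 2)
  expect_warning(fit_link_regression(dup_info, dup_post, dup_pre, dup_bold,
                                     dup_conf), "duplicated")
})

test_that("median-split mode dichotomises the power regressor", {
  set.seed(5)
  f <- draw_fidelity(60, 0.5, 0.2)
  pw <- simulate_trial_power(f, coupling = 1, noise_sd = 0.1, seed = 6)
  reg <- fit_link_regression(f, pw$post_power, pw$pre_power,
                             pw$bold_amplitude, pw$confidence,
                             mode = "median_split")
  expect_equal(reg$mode, "median_split")
  expect_lt(reg$t_values["post_power"], -2)
})

test_that("null link-regression t-values follow the Student reference", {
  n <- 30
  n_sim <- 400
  tv <- vapply(seq_len(n_sim), function(i) {
    set.seed(i)
    fit_link_regression(rnorm(n), rnorm(n), rnorm(n), rnorm(n),
                        sample(1:4, n, TRUE))$t_values[["post_power"]]
  }, numeric(1))
  ks <- ks.test(tv, function(q) pt(q, df = n - 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("sign-flip group test is exact, seeded and tail-correct", {
  v <- c(-2, -1, -0.5, 0.5, 1, 2)  # perfectly symmetric
  expect_gte(group_permutation_ttest(v, "two")$p, 0.99)
  set.seed(7)
  v10 <- rnorm(10, mean = 0.8)
  ex <- group_permutation_ttest(v10, "right")
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 1024)
  # sampled variant agrees with the exhaustive enumeration within 2 MC SE
  v13 <- c(v10, rnorm(3, mean = 0.8))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 13)))
  t_of <- function(x) mean(x) / (sd(x) / sqrt(13))
  t_obs <- t_of(v13)
  t_perm <- apply(signs, 1, function(s) t_of(s * v13))
  p_exact <- mean(t_perm >= t_obs)
  ps <- group_permutation_ttest(v13, "right", n_perm = 4000, seed = 1)
  expect_false(ps$exhaustive)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(ps$p - p_exact), 2 * mc_se + 1 / 4001)
  expect_equal(ps$p,
               group_permutation_ttest(v13, "right", n_perm = 4000,
                                       seed = 1)$p)
  expect_warning(p0 <- group_permutation_ttest(rep(0, 5), "two"), "zero")
  expect_equal(p0$p, 1)
})

test_that("permutation p-values are valid at several alpha levels", {
  n_sim <- 400
  set.seed(8)
  ps <- vapply(seq_len(n_sim), function(i) {
    group_permutation_ttest(rnorm(14), "two", n_perm = 199, seed = i)$p
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1)) {
    se <- sqrt(a * (1 - a) / n_sim)
    expect_lte(mean(ps <= a), a + 2 * se)
  }
})

test_that("cluster test recovers a planted contiguous effect", {
  set.seed(9)
  adj <- lattice_adjacency(c(8, 8))
  patch <- as.vector(outer(3:5, (3:5 - 1) * 8, "+"))  # 3x3 block
  d <- matrix(rnorm(14 * 64), 14)
  d[, patch] <- d[, patch] + 1.5
  res <- cluster_permutation_test(d, adj, cluster_alpha = 0.05,
                                  n_perm = 500, tail = "right", seed = 1)
  ps <- vapply(res$clusters, function(cl) cl$p, numeric(1))
  expect_true(any(ps <= 0.05))
  best <- res$clusters[[which.min(ps)]]
  expect_gte(length(intersect(best$members, patch)), 8)
})

test_that("edgeless adjacency reduces to the max-statistic test", {
  set.seed(10)
  d <- matrix(rnorm(12 * 10), 12)
  d[, 4] <- d[, 4] + 1.6
  adj0 <- rep(list(integer(0)), 10)
  res <- cluster_permutation_test(d, adj0, cluster_alpha = 0.05,
                                  n_perm = 400, tail = "right", seed = 2)
  # direct max-single-feature permutation implementation
  tcrit <- qt(0.95, 11)
  col_t <- function(X) apply(X, 2, function(v) mean(v) / (sd(v) / sqrt(12)))
  t_obs <- col_t(d)
  set.seed(2)
  null_max <- replicate(400, {
    tv <- col_t(d * sample(c(-1, 1), 12, TRUE))
    max(c(0, tv[tv > tcrit]))
  })
  for (cl in res$clusters) {
    expect_length(cl$members, 1)
    p_direct <- (sum(null_max >= cl$stat) + 1) / 401
    # identical up to floating-point ties at the identity permutation
    expect_lt(abs(cl$p - p_direct), 1.5 / 401)
  }
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  for (case in list(c(0, 12), c(1.5, 20), c(3, 20), c(-2.2, 15))) {
    bf <- jzs_bayes_factor(t = case[1], n = case[2])
    expect_equal(as.numeric(bf), jzs_oracle(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("JZS Bayes factor has the symmetry and monotonicity of the prior", {
  expect_lt(jzs_bayes_factor(t = 0, n = 10), 1)
  expect_lt(jzs_bayes_factor(t = 0, n = 50), 1)
  set.seed(11)
  v <- rnorm(15, 0.5)
  expect_equal(as.numeric(jzs_bayes_factor(v)),
               as.numeric(jzs_bayes_factor(-v)), tolerance = 1e-9)
  grid <- seq(0, 6, by = 0.5)
  bfs <- vapply(grid, function(t) as.numeric(jzs_bayes_factor(t = t, n = 18)),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_match(attr(jzs_bayes_factor(t = 6, n = 18), "evidence"), "for H1")
})

test_that("confidence-power correlation is rank-based and guarded", {
  set.seed(12)
  pw <- rnorm(40)
  conf <- as.integer(cut(-pw, quantile(-pw, 0:4 / 4), include.lowest = TRUE))
  z <- confidence_power_correlation(pw, conf)
  expect_lt(z, -1)
  # monotone transform of power leaves z unchanged
  expect_equal(confidence_power_correlation(exp(pw), conf), z,
               tolerance = 1e-12)
  expect_warning(zc <- confidence_power_correlation(pw, rep(2, 40)),
                 "constant")
  expect_true(is.na(zc))
  expect_error(confidence_power_correlation(pw[1:2], conf[1:2]), "3 complete")
})

test_that("inclusion rule requires 10 remembered and 10 forgotten trials", {
  expect_true(meets_inclusion_rule(rep(c(TRUE, FALSE), 10)))
  expect_false(meets_inclusion_rule(c(rep(TRUE, 30), rep(FALSE, 9))))
  expect_false(meets_inclusion_rule(c(rep(TRUE, 9), rep(FALSE, 30))))
})

test_that("attenuation simulation matches the closed form and edge cases", {
  tab <- attenuation_simulation(c(0, 0.1, 0.3, 0.6), coupling = 1,
                                noise_sd = 1, n_trials = 200, n_reps = 150,
                                seed = 13)
  expect_equal(tab$observed_r[1], 0)
  for (i in 2:4) {
    expect_lt(abs(tab$observed_r[i] - tab$expected_r[i]), 2 * tab$se[i])
  }
  expect_true(all(diff(tab$observed_r) > 0))
  expect_identical(tab, attenuation_simulation(c(0, 0.1, 0.3, 0.6),
                                               coupling = 1, noise_sd = 1,
                                               n_trials = 200, n_reps = 150,
                                               seed = 13))
})
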