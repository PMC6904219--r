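# shared fixtures, all generated in code

# small all-TRUE voxel mask
tiny_mask <- function(dims = c(5, 5, 3)) array(TRUE, dims)

# brute-force crossnobis by the definition, looped pair by pair
crossnobis_bruteforce <- function(fold_a, fold_b, sigma) {
  n <- nrow(fold_a)
  D <- matrix(0, n, n)
  Si <- solve(sigma)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      da <- fold_a[j, ] - fold_a[k, ]
      db <- fold_b[j, ] - fold_b[k, ]
      D[j, k] <- (t(da) %*% Si %*% db + t(db) %*% Si %*% da) / 2
    }
  }
  D
}

# brute-force searchlight membership by explicit distance loops
searchlight_bruteforce <- function(mask, spacing, radius) {
  grid <- which(mask, arr.ind = TRUE)
  coords <- sweep(grid, 2, spacing, "*")
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    which(d <= radius)
  })
}

# correlated Gaussian draws for covariance fixtures
rmvnorm_chol_test <- function(n, sigma) {
  matrix(rnorm(n * nrow(sigma)), n) %*% chol(sigma)
}

# independent JZS oracle: composite Simpson on the g scale after the
# u = g / (1 + g) substitution, with a fine fixed grid
jzs_oracle <- function(t, n, r = sqrt(2) / 2, n_grid = 200001) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  f <- (1 + n * g)^(-0.5) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    r / sqrt(2 * pi) * g^(-3 / 2) * exp(-r^2 / (2 * g)) * jac
  h <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = n_grid)
  w[1] <- 1
  w[n_grid] <- 1
  num <- sum(w * f) * h / 3
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
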