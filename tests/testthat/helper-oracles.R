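# Brute-force Bayes factor by trapezoid integration of the Gaussian
# likelihood ratio over the effect size, on a +/- 8 tau grid. Independent of
# the closed form it checks.
bf_numeric_oracle <- function(y, z, sigma, tau, n_grid = 4001L) {
  si <- solve(sigma)
  quad <- function(r) drop(t(r) %*% si %*% r)
  lr <- function(beta) exp(-0.5 * (quad(y - beta * z) - quad(y)))
  grid <- seq(-8 * tau, 8 * tau, length.out = n_grid)
  f <- vapply(grid, function(b) lr(b) * stats::dnorm(b, 0, tau), 0)
  h <- diff(grid)[1]
  bf <- h * (sum(f) - (f[1] + f[n_grid]) / 2)
  log10(bf)
}

# random small BF instance with a well-conditioned covariance
random_bf_instance <- function(L) {
  A <- matrix(rnorm(L * L), L)
  sigma <- crossprod(A) / L + diag(0.5, L)
  list(y = rnorm(L), z = rnorm(L), sigma = sigma,
       tau = runif(1, 0.3, 2))
}

# projection removing the weighted-mean reference direction; the covariance
# null is identifiable only on this contrast space
contrast_projection <- function(w) diag(length(w)) - outer(rep(1, length(w)), w)

projected_frobenius_error <- function(model, omega_true) {
  w <- (1 / model$d) / sum(1 / model$d)
  P <- contrast_projection(w)
  sqrt(sum((P %*% (model$omega - omega_true) %*% t(P))^2))
}
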