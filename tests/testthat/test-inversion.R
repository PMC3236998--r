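# The inversion machinery is exercised on a coarse 1 Hz grid; the
# acceptance suite runs the full-resolution experiments.

noise_free_data <- simulate_observed_spectrum(priors, coarse_grid,
                                              noise_sd = 0)
noisy_data <- simulate_observed_spectrum(priors, coarse_grid, seed = 21)
prior <- nf_prior(priors)
mu0 <- prior$mean

test_that("prediction error vanishes on noise-free self-generated data", {
  e <- prediction_error(mu0, noise_free_data, priors)
  expect_equal(max(Mod(e)), 0)
  expect_true(all(Im(e) == 0))
})

test_that("a constant offset in the data appears as a constant residual", {
  d <- noise_free_data
  d$values <- d$values + 3e-6
  e <- prediction_error(mu0, d, priors)
  expect_equal(Re(e), rep(-3e-6, length(coarse_grid)), tolerance = 1e-12)
})

test_that("prediction error matches direct recomputation at random scalings", {
  set.seed(22)
  mu <- stats::rnorm(length(mu0), sd = 0.1)
  names(mu) <- names(mu0)
  e <- prediction_error(mu, noisy_data, priors)
  scaled <- apply_scalings(priors, mu)
  direct <- predict_spectrum(scaled, coarse_grid) +
    noise_spectrum(2 * pi * coarse_grid, scaled$observation$alpha_N,
                   scaled$observation$beta_N) -
    Re(noisy_data$values[, 1, 1])
  expect_equal(Re(e), direct, tolerance = 1e-12)
})

test_that("prediction error demands a shared frequency grid", {
  expect_error(prediction_error(mu0, noisy_data, priors,
                                freq_hz = coarse_grid + 0.1),
               "grids differ")
})

test_that("Gibbs energy has the stated value at a perfect fit", {
  em <- nf_error_model(lambda = 0)
  G <- gibbs_energy(mu0, noise_free_data, priors, prior, em)
  # -1/2 ln|Sigma| - 1/2 ln|Omega| with Sigma = I and Omega = (1/16) I
  expected <- -0.5 * 0 +
    0.5 * determinant(prior$precision, logarithm = TRUE)$modulus
  expect_equal(G, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Gibbs energy is quadratic in a single residual", {
  em <- nf_error_model(lambda = 0)
  e <- 0.4
  bump <- function(scale) {
    d <- noise_free_data
    d$values[5, 1, 1] <- d$values[5, 1, 1] - scale
    gibbs_energy(mu0, d, priors, prior, em)
  }
  expect_equal(bump(2 * e) - bump(e), -1.5 * e^2, tolerance = 1e-10)
})

test_that("Gibbs energy matches a dense-algebra evaluation", {
  set.seed(23)
  mu <- stats::rnorm(length(mu0), sd = 0.05)
  names(mu) <- names(mu0)
  lam <- 0.7
  em <- nf_error_model(lambda = lam)
  G <- gibbs_energy(mu, noisy_data, priors, prior, em)
  # brute force with explicit matrices
  e <- prediction_error(mu, noisy_data, priors)
  n <- length(e)
  Sigma <- diag(exp(-lam), n)
  Omega <- solve(prior$precision)
  rho <- mu - prior$mean
  brute <- -0.5 * drop(Re(e) %*% solve(Sigma) %*% Re(e)) -
    0.5 * drop(Im(e) %*% solve(Sigma) %*% Im(e)) -
    0.5 * drop(rho %*% solve(Omega) %*% rho) -
    0.5 * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * determinant(Omega, logarithm = TRUE)$modulus
  expect_equal(G, brute, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("real auto-spectra give the same energy through the complex path", {
  em <- nf_error_model(lambda = 1.3)
  set.seed(24)
  mu <- stats::rnorm(length(mu0), sd = 0.05)
  names(mu) <- names(mu0)
  G <- gibbs_energy(mu, noisy_data, priors, prior, em)
  e <- Re(prediction_error(mu, noisy_data, priors))  # real-only path
  expect_equal(max(abs(Im(prediction_error(mu, noisy_data, priors)))), 0)
  n <- length(e)
  G_real <- -0.5 * exp(em$lambda) * sum(e^2) -
    0.5 * (-n * em$lambda) +
    0.5 * determinant(prior$precision, logarithm = TRUE)$modulus -
    0.5 * drop((mu - prior$mean) %*% prior$precision %*% (mu - prior$mean))
  expect_equal(G, G_real, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("energy gradient vanishes at a stationary point", {
  em <- nf_error_model(lambda = 0)
  eg <- energy_gradients(mu0, noise_free_data, priors, prior, em)
  expect_lt(max(abs(eg$gradient)), 1e-8)
})

test_that("energy gradient matches finite differences of the Gibbs energy", {
  em <- nf_error_model(lambda = -log(mean(Re(prediction_error(
    mu0, noisy_data, priors))^2)))
  set.seed(25)
  mu <- stats::rnorm(length(mu0), sd = 0.03)
  names(mu) <- names(mu0)
  eg <- energy_gradients(mu, noisy_data, priors, prior, em)
  h <- 1e-4
  fd <- vapply(seq_along(mu), function(i) {
    up <- mu; up[i] <- up[i] + h
    dn <- mu; dn[i] <- dn[i] - h
    (gibbs_energy(up, noisy_data, priors, prior, em) -
       gibbs_energy(dn, noisy_data, priors, prior, em)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum((eg$gradient - fd)^2)) / sqrt(sum(fd^2)), 1e-4)
})

test_that("curvature equals the Gauss-Newton assembly from the Jacobian", {
  lam <- 0.4
  em <- nf_error_model(lambda = lam)
  eg <- energy_gradients(mu0, noisy_data, priors, prior, em)
  J <- eg$jacobian
  assembled <- -(crossprod(Re(J), exp(lam) * Re(J)) +
                   crossprod(Im(J), exp(lam) * Im(J)) + prior$precision)
  assembled <- (assembled + t(assembled)) / 2
  expect_equal(eg$curvature, assembled, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("hyperparameter update moment-matches the residual variance", {
  em0 <- nf_error_model(lambda = 0)
  em1 <- update_hyperparameters(mu0, noisy_data, priors, em0)
  e <- Re(prediction_error(mu0, noisy_data, priors))
  expect_equal(exp(-em1$lambda), mean(e^2), tolerance = 1e-12)
  # fixed point: a second application leaves lambda unchanged
  em2 <- update_hyperparameters(mu0, noisy_data, priors, em1)
  expect_equal(em2$lambda, em1$lambda)
  # doubling residuals quadruples the estimated error variance
  d2 <- noisy_data
  clean <- Re(noise_free_data$values[, 1, 1])
  d2$values <- array(clean + 2 * (Re(noisy_data$values[, 1, 1]) - clean),
                     dim = dim(noisy_data$values))
  em4 <- update_hyperparameters(mu0, d2, priors, em0)
  expect_equal(exp(-em4$lambda), 4 * exp(-em1$lambda), tolerance = 1e-10)
  # vanishing residuals hit the precision cap instead of diverging
  emc <- update_hyperparameters(mu0, noise_free_data, priors, em0, cap = 32)
  expect_equal(emc$lambda, 32)
})

test_that("a two-component error basis recovers a known variance mixture", {
  freq <- seq(0.5, 100, by = 0.1)
  pred <- nfdcm:::predict_sensor(priors, freq)
  n <- length(freq)
  half <- n %/% 2
  q1 <- c(rep(1, half), rep(0, n - half))
  v1 <- 1e-11; v2 <- 9e-11
  set.seed(26)
  noise <- stats::rnorm(n, sd = sqrt(ifelse(q1 == 1, v1, v2)))
  d <- spectral_data(freq, pred + noise, meta = "simulated")
  em <- nf_error_model(lambda = c(0, 0),
                       basis = list(diag(q1), diag(1 - q1)))
  em <- update_hyperparameters(prior$mean, d, priors, em)
  expect_equal(exp(-em$lambda[1]), v1, tolerance = 0.1)
  expect_equal(exp(-em$lambda[2]), v2, tolerance = 0.1)
})

test_that("inversion of noise-free prior-generated data recovers the priors", {
  post <- invert_model(noise_free_data, priors)
  expect_s3_class(post, "nf_posterior")
  expect_true(all(abs(post$mu) <= 0.05))
  accepted <- post$trace$F[post$trace$accepted]
  expect_true(all(diff(accepted) >= -1e-6))
})

test_that("free energy is monotone and the Laplace covariance is consistent", {
  post <- invert_model(noisy_data, priors)
  accepted <- post$trace$F[post$trace$accepted]
  expect_true(all(diff(accepted) >= -1e-6))
  # C must equal the negative inverse curvature at the optimum
  eg <- energy_gradients(post$mu, noisy_data, priors, prior,
                         post$error_model)
  expect_equal(post$C, solve(-eg$curvature), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("infinitely precise priors pin the posterior at the prior mean", {
  hard_prior <- nf_prior(priors, precision = 1e10)
  post <- invert_model(noisy_data, priors, prior = hard_prior)
  expect_lt(max(abs(post$mu)), 1e-4)
})

test_that("the transit-time scaling is recovered with a credible interval", {
  gen <- apply_scalings(priors, c(upsilon = 0.5))
  d <- simulate_observed_spectrum(gen, coarse_grid, seed = 27)
  post <- invert_model(d, priors)
  est <- post$mu[["upsilon"]]
  sd <- sqrt(post$C["upsilon", "upsilon"])
  expect_gt(0.5, est - 1.645 * sd)
  expect_lt(0.5, est + 1.645 * sd)
})
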