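# Shared fixtures: the standard prior parameter set, a coarse frequency grid
# for fast inversions, and a draw of mildly jittered stable parameter sets.

priors <- nf_params_default()

coarse_grid <- seq(1, 60, by = 1)

# Jitter every free parameter by a small log-normal scaling and keep only
# draws that pass the stability check on the coarse grid.
random_stable_params <- function(n, sd = 0.15, seed = 1) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    mu <- stats::rnorm(length(free_param_names(priors)), sd = sd)
    names(mu) <- free_param_names(priors)
    cand <- apply_scalings(priors, mu)
    ok <- tryCatch(check_stability(cand, coarse_grid,
                                   diagnostics = FALSE)$stable,
                   error = function(e) FALSE)
    if (ok) out[[length(out) + 1L]] <- cand
  }
  out
}

# Numerical Fourier transform of the delayed exponential kernel
# d(x, t) = (alpha/2) exp(-c|x|) delta(t - upsilon |x|): the time integral
# leaves integrand (alpha/2) exp(-c|x|) exp(-i omega upsilon |x|) exp(-i k x),
# integrated over x with truncation where the envelope is negligible.
# Composite Simpson on a grid resolving the fastest oscillation (the
# adaptive quadrature in stats::integrate struggles with hundreds of
# oscillation periods under a slowly decaying envelope).
kernel_transfer_quadrature <- function(alpha, c, upsilon, k, omega,
                                       tol = 1e-12) {
  X <- -log(tol) / max(c, 1e-6)
  # folding x < 0 onto x > 0 removes the |x| kink: the integrand on the
  # half-line is smooth, with two oscillation rates
  rate <- max(abs(omega * upsilon + k), abs(omega * upsilon - k), c)
  n <- 2L * ceiling(max(2e4, 100 * X * rate / (2 * pi)) / 2)
  x <- seq(0, X, length.out = n + 1L)
  fx <- (alpha / 2) * exp(-c * x) *
    (exp(-1i * (omega * upsilon + k) * x) +
       exp(-1i * (omega * upsilon - k) * x))
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = n - 1L)
  (h / 3) * (fx[1] + fx[n + 1L] + sum(w * fx[2:n]))
}
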