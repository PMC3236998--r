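test_that("simulation is deterministic given the seed and unbiased in expectation", {
  d1 <- simulate_observed_spectrum(priors, coarse_grid, seed = 41)
  d2 <- simulate_observed_spectrum(priors, coarse_grid, seed = 41)
  expect_identical(d1$values, d2$values)
  d3 <- simulate_observed_spectrum(priors, coarse_grid, seed = 42)
  expect_false(identical(d1$values, d3$values))
  # zero noise returns exactly source spectrum plus channel noise
  d0 <- simulate_observed_spectrum(priors, coarse_grid, noise_sd = 0)
  clean <- predict_spectrum(priors, coarse_grid) +
    noise_spectrum(2 * pi * coarse_grid, priors$observation$alpha_N,
                   priors$observation$beta_N)
  expect_equal(Re(d0$values[, 1, 1]), clean)
  # Monte-Carlo mean within ~3 standard errors at every frequency (3.5
  # allows for the multiplicity of 60 bins; seeds are spaced by a large
  # prime to avoid lattice artefacts of consecutive seeding)
  R <- 1000
  sd1 <- attr(d1, "noise_sd")
  draws <- vapply(seq_len(R), function(r) {
    Re(simulate_observed_spectrum(priors, coarse_grid,
                                  seed = 1000 + r * 104729)$values[, 1, 1])
  }, numeric(length(coarse_grid)))
  se <- sd1 / sqrt(R)
  expect_true(all(abs(rowMeans(draws) - clean) < 3.5 * se))
})

test_that("simulation leaves the caller's random stream untouched", {
  set.seed(43)
  before <- .Random.seed
  invisible(simulate_observed_spectrum(priors, coarse_grid, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("default noise level gives a peak signal-to-noise ratio of ten", {
  d <- simulate_observed_spectrum(priors, coarse_grid, seed = 44)
  clean <- predict_spectrum(priors, coarse_grid) +
    noise_spectrum(2 * pi * coarse_grid, priors$observation$alpha_N,
                   priors$observation$beta_N)
  expect_equal(attr(d, "noise_sd"), max(clean) / 10)
})

test_that("recovery experiment tracks moderate transit-time deviations", {
  rec <- recovery_experiment(scalings = c(-0.5, 0.5), seed = 50,
                             freq_hz = coarse_grid)
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$covered))
  expect_true(all(abs(rec$estimate - rec$true) < 0.15))
})

test_that("recovery experiment defaults reproduce the printed design", {
  # the sweep is -1..1; the sensitivity scans use -2.5..2.5
  expect_equal(formals(recovery_experiment)$scalings,
               quote(seq(-1, 1, length.out = 9)))
  expect_equal(eval(formals(sensitivity_scan)$log_range), c(-2.5, 2.5))
})

test_that("sensitivity scan reproduces the baseline at scaling zero", {
  sc1 <- sensitivity_scan("upsilon", n_steps = 1, log_range = c(0, 0),
                          freq_hz = coarse_grid)
  baseline <- nfdcm:::predict_sensor(priors, coarse_grid)
  expect_equal(as.vector(sc1$spectra[1, ]), baseline)
  sc <- sensitivity_scan("upsilon", n_steps = 11, freq_hz = coarse_grid)
  mid <- (length(sc$scalings) + 1) / 2
  expect_equal(sc$scalings[mid], 0)
  expect_equal(as.vector(sc$spectra[mid, ]), baseline)
  # unstable scalings are recorded, not dropped
  expect_equal(nrow(sc$spectra), 11L)
  expect_equal(length(sc$stable), 11L)
})

test_that("slow conduction concentrates spectral power at low frequencies", {
  # slowing conduction from the reference transit time moves power below
  # 15 Hz and pulls the spectral centroid down; the comparison starts at
  # the baseline because at vanishing transit time the model collapses to
  # the mass spectrum, whose alpha peak also sits at low frequency.
  sc <- sensitivity_scan("upsilon", n_steps = 11, freq_hz = coarse_grid)
  low_frac <- function(row) sum(row[coarse_grid <= 15]) / sum(row)
  centroid <- function(row) sum(coarse_grid * row) / sum(row)
  up <- which(sc$stable & sc$scalings >= 0)
  slowest <- max(up)   # largest transit time (slowest conduction)
  baseline <- min(up)
  expect_gt(low_frac(sc$spectra[slowest, ]),
            low_frac(sc$spectra[baseline, ]))
  cents <- apply(sc$spectra[up, ], 1, centroid)
  expect_true(all(diff(cents) < 0))
  # ... while at vanishing transit time the shape approaches the mass limit
  nrm <- function(x) x / sqrt(sum(x^2))
  gm <- mass_limit_spectrum(priors, coarse_grid) +
    noise_spectrum(2 * pi * coarse_grid, priors$observation$alpha_N,
                   priors$observation$beta_N)
  d_fast <- sqrt(sum((nrm(sc$spectra[min(which(sc$stable)), ]) - nrm(gm))^2))
  d_slow <- sqrt(sum((nrm(sc$spectra[slowest, ]) - nrm(gm))^2))
  expect_lt(d_fast, d_slow)
})

test_that("faster excitatory kinetics shift the spectral peak upward", {
  sc <- sensitivity_scan("kappa_e", n_steps = 9, log_range = c(-1, 1),
                         freq_hz = coarse_grid)
  ok <- which(sc$stable)
  peak_f <- vapply(ok, function(i) {
    coarse_grid[which.max(sc$spectra[i, ])]
  }, numeric(1))
  # direction-only check across the extremes of the stable range
  expect_gt(peak_f[length(peak_f)], peak_f[1])
})

test_that("scanning the connectivity extent drives the field toward mass-like spectra", {
  sc <- sensitivity_scan("c", n_steps = 5, log_range = c(-1, 2.5),
                         freq_hz = coarse_grid)
  gm <- mass_limit_spectrum(priors, coarse_grid) +
    noise_spectrum(2 * pi * coarse_grid, priors$observation$alpha_N,
                   priors$observation$beta_N)
  nrm <- function(x) x / sqrt(sum(x^2))
  ok <- which(sc$stable)
  d_short <- sqrt(sum((nrm(sc$spectra[max(ok), ]) - nrm(gm))^2))
  d_long <- sqrt(sum((nrm(sc$spectra[min(ok), ]) - nrm(gm))^2))
  expect_lt(d_short, d_long)
})
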