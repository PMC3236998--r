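# Synthetic-data generation and the validation experiments built on it.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate an observed single-channel spectrum
#'
#' Draws synthetic observed data from the generative model: predicted source
#' spectrum plus channel noise plus additive Gaussian observation error on
#' every frequency bin. The default error magnitude puts the signal-to-noise
#' ratio at the spectral peak at about ten.
#'
#' @param params an `nf_params` object (the generating model).
#' @param freq_hz frequency grid (Hz).
#' @param noise_sd standard deviation of the Gaussian observation error on
#'   each bin; default `NULL` uses one tenth of the peak of the noiseless
#'   sensor spectrum.
#' @param seed integer seed; the draw is deterministic given the seed and
#'   the caller's random-number state is left untouched.
#' @return a [spectral_data()] with `meta = "simulated"`; the noise level
#'   used is attached as attribute `noise_sd`.
#' @export
simulate_observed_spectrum <- function(params, freq_hz = default_freq_grid(),
                                       noise_sd = NULL, seed = 0) {
  st <- check_stability(params, freq_hz, diagnostics = FALSE)
  if (!st$stable) stop("unstable parameter set: cannot simulate")
  clean <- predict_sensor(params, freq_hz)
  if (is.null(noise_sd)) noise_sd <- max(clean) / 10
  stopifnot(noise_sd >= 0)
  eps <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(freq_hz), sd = noise_sd))
  } else {
    numeric(length(freq_hz))
  }
  out <- spectral_data(freq_hz, clean + eps, meta = "simulated")
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Transit-time recovery experiment
#'
#' Replicates the identifiability analysis for the transit time: for each
#' true log-scaling in `scalings`, data are simulated from the model with
#' the transit time scaled accordingly (all other parameters at their prior
#' expectations), the model is inverted from its priors, and the conditional
#' mean and 90% credible interval (mean +/- 1.645 posterior sd) of the
#' transit-time log-scaling are recorded.
#'
#' @param scalings true transit-time log-scalings (default: 9 values over
#'   -1..1, i.e. 37% to 272% of the prior transit time).
#' @param noise_sd observation-error sd passed to
#'   [simulate_observed_spectrum()] (default: peak SNR of ten).
#' @param seed base seed; replicate i uses `seed + i`.
#' @param params prior-scale parameter set.
#' @param freq_hz frequency grid.
#' @param settings inversion settings, see [invert_model()].
#' @return data frame with columns `true`, `estimate`, `sd`, `lower`,
#'   `upper`, `covered`, `F`.
#' @export
recovery_experiment <- function(scalings = seq(-1, 1, length.out = 9),
                                noise_sd = NULL, seed = 0,
                                params = nf_params_default(),
                                freq_hz = default_freq_grid(),
                                settings = list()) {
  rows <- lapply(seq_along(scalings), function(i) {
    s <- scalings[i]
    gen <- apply_scalings(params, c(upsilon = s))
    dat <- simulate_observed_spectrum(gen, freq_hz, noise_sd = noise_sd,
                                      seed = seed + i)
    post <- invert_model(dat, params, settings = settings)
    est <- post$mu[["upsilon"]]
    sd <- sqrt(post$C["upsilon", "upsilon"])
    data.frame(true = s, estimate = est, sd = sd,
               lower = est - 1.645 * sd, upper = est + 1.645 * sd,
               covered = (s >= est - 1.645 * sd) & (s <= est + 1.645 * sd),
               F = post$F)
  })
  do.call(rbind, rows)
}

#' Spectral sensitivity scan over one parameter
#'
#' Evaluates the predicted sensor spectrum while one parameter is swept over
#' a log-scaling range (all others at their prior expectations), emulating a
#' structural-stability analysis of the spectral predictions. Scalings whose
#' parameter set loses stability are retained in the output with `NA`
#' spectra and flagged, not dropped.
#'
#' @param param_name one of [free_param_names()], or `"c"` to scale all
#'   kernel decay constants together (the lateral-connectivity extent).
#' @param log_range length-2 numeric range of log-scalings (default
#'   -2.5..2.5, i.e. 8% to 1218%).
#' @param n_steps number of scalings (odd values place the baseline,
#'   scaling 0, exactly in the middle row).
#' @param params prior-scale parameter set.
#' @param freq_hz frequency grid.
#' @return object of class `nf_scan`: list with `scalings`, `freq_hz`,
#'   `spectra` (matrix, one row per scaling) and `stable` (logical vector).
#' @export
sensitivity_scan <- function(param_name, log_range = c(-2.5, 2.5),
                             n_steps = 11, params = nf_params_default(),
                             freq_hz = default_freq_grid()) {
  scannable <- c(free_param_names(params), "c")
  if (!param_name %in% scannable) {
    stop("param_name must be one of: ", paste(scannable, collapse = ", "))
  }
  scalings <- if (n_steps == 1) mean(log_range) else
    seq(log_range[1], log_range[2], length.out = n_steps)
  spectra <- matrix(NA_real_, n_steps, length(freq_hz),
                    dimnames = list(sprintf("%.3f", scalings), NULL))
  stable <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    mu <- if (param_name == "c") {
      c(c_13 = scalings[i], c_23 = scalings[i], c_31 = scalings[i])
    } else {
      stats::setNames(scalings[i], param_name)
    }
    ps <- apply_scalings(params, mu)
    st <- tryCatch(check_stability(ps, freq_hz, diagnostics = FALSE)$stable,
                   error = function(e) FALSE)
    stable[i] <- st
    if (st) {
      spectra[i, ] <- tryCatch(predict_sensor(ps, freq_hz),
                               error = function(e) rep(NA_real_,
                                                       length(freq_hz)))
    }
    if (anyNA(spectra[i, ])) stable[i] <- FALSE
  }
  structure(list(param = param_name, scalings = scalings, freq_hz = freq_hz,
                 spectra = spectra, stable = stable), class = "nf_scan")
}

#' @export
print.nf_scan <- function(x, ...) {
  cat(sprintf("sensitivity scan of %s: %d scalings in [%.2f, %.2f], %d stable\n",
              x$param, length(x$scalings), min(x$scalings), max(x$scalings),
              sum(x$stable)))
  invisible(x)
}

#' Field-versus-mass model selection on synthetic data
#'
#' The 2 x 2 model-selection design: data are simulated once under the field
#' model (transit time at its prior expectation) and once under the mass
#' model (transit time zero), and each dataset is inverted with both model
#' variants. The generating model should attain the higher free energy on
#' its own data; because the mass model is nested in the field model, the
#' margin on mass-generated data is expected to be much smaller than on
#' field-generated data.
#'
#' @inheritParams recovery_experiment
#' @return list with `F` (2 x 2 matrix, rows = generating model, columns =
#'   fitted model), `delta_field_data` (= F[field data, field fit] -
#'   F[field data, mass fit]), `delta_mass_data`, and the four posteriors.
#' @export
model_selection_2x2 <- function(params = nf_params_default(),
                                freq_hz = default_freq_grid(),
                                noise_sd = NULL, seed = 0,
                                settings = list()) {
  mass <- make_mass_variant(params)
  dat_field <- simulate_observed_spectrum(params, freq_hz,
                                          noise_sd = noise_sd, seed = seed)
  dat_mass <- simulate_observed_spectrum(mass, freq_hz,
                                         noise_sd = noise_sd,
                                         seed = seed + 1000L)
  fits <- list(
    field_field = invert_model(dat_field, params, settings = settings),
    field_mass = invert_model(dat_field, mass, settings = settings),
    mass_field = invert_model(dat_mass, params, settings = settings),
    mass_mass = invert_model(dat_mass, mass, settings = settings)
  )
  F <- matrix(c(fits$field_field$F, fits$field_mass$F,
                fits$mass_field$F, fits$mass_mass$F),
              2, 2, byrow = TRUE,
              dimnames = list(data = c("field", "mass"),
                              model = c("field", "mass")))
  list(F = F,
       delta_field_data = F["field", "field"] - F["field", "mass"],
       delta_mass_data = F["mass", "mass"] - F["mass", "field"],
       posteriors = fits)
}
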