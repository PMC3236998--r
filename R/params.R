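#' Model parameters for the Jansen-Rit neural field source
#'
#' Builds the full parameter set of a single-source, three-population
#' (stellate, inhibitory interneuron, pyramidal) neural field model. All
#' values are stored in internal units: rate constants in s^-1, the transit
#' time in seconds, kernel decay constants per normalized patch radius
#' (the patch radius `ell` is fixed to 1), potentials in mV.
#'
#' @param synaptic named list with elements `m_e`, `m_i` (maximum postsynaptic
#'   depolarization, mV), `kappa_e`, `kappa_i` (postsynaptic rate constants,
#'   s^-1), `r` (sigmoid slope, mV^-1) and `eta` (sigmoid inflection, mV).
#' @param spatial named list with kernel amplitudes `alpha_13`, `alpha_23`,
#'   `alpha_31`, `alpha_32`, decay constants `c_13`, `c_23`, `c_31`
#'   (per normalized length; the interneuron-to-pyramidal decay is tied to
#'   `c_31`), the transit time `upsilon` (s, centre to boundary) and the
#'   normalized patch radius `ell` (must be 1).
#' @param observation named list with lead-field amplitude `phi_1`, lead-field
#'   width `phi_2` (normalized length^2), input-spectrum coefficients
#'   `alpha_U` (white) and `beta_U` (pink), and channel-noise coefficients
#'   `alpha_N`, `beta_N`.
#' @param n_modes number of standing-wave modes retained in the modal sum.
#' @param mass_limit logical; when `TRUE` the model is evaluated in its
#'   neural-mass limit (effective transit time exactly zero) and the transit
#'   time is removed from the free-parameter set.
#'
#' @return an object of class `nf_params`.
#' @seealso [nf_params_default()] for the standard prior expectations.
#' @export
nf_params <- function(synaptic, spatial, observation, n_modes = 32L,
                      mass_limit = FALSE) {
  p <- structure(list(
    synaptic = synaptic,
    spatial = spatial,
    observation = observation,
    n_modes = as.integer(n_modes),
    mass_limit = isTRUE(mass_limit)
  ), class = "nf_params")
  validate_nf_params(p)
  p
}

#' Default parameter set (prior expectations)
#'
#' The standard prior expectations for the model: maximum depolarizations of
#' 8 and 32 mV, postsynaptic rate constants of 250 and 1000/28 s^-1
#' (time constants of 4 and 28 ms), kernel amplitudes 2000, 8000, 2000 and
#' 1000, a kernel decay constant of 0.32 per patch radius, a transit time of
#' 50 mm / 3 m s^-1 = 16.7 ms, sigmoid slope 0.54
#' with inflection at 0 mV, and a narrow Gaussian lead field of width 0.01.
#' Input and channel-noise spectra mix white and pink (1/omega) components;
#' the channel-noise floor is two orders of magnitude below the typical
#' source-spectrum peak.
#'
#' @return an `nf_params` object.
#' @export
nf_params_default <- function() {
  nf_params(
    synaptic = list(m_e = 8, m_i = 32, kappa_e = 250, kappa_i = 1000 / 28,
                    r = 0.54, eta = 0),
    spatial = list(alpha_13 = 2000, alpha_23 = 8000, alpha_31 = 2000,
                   alpha_32 = 1000, c_13 = 0.32, c_23 = 0.32, c_31 = 0.32,
                   upsilon = 0.05 / 3, ell = 1),
    observation = list(phi_1 = 1, phi_2 = 0.01, alpha_U = 1, beta_U = 1,
                       alpha_N = 2e-6, beta_N = 2e-6),
    n_modes = 32L,
    mass_limit = FALSE
  )
}

validate_nf_params <- function(p) {
  syn_req <- c("m_e", "m_i", "kappa_e", "kappa_i", "r", "eta")
  spa_req <- c("alpha_13", "alpha_23", "alpha_31", "alpha_32",
               "c_13", "c_23", "c_31", "upsilon", "ell")
  obs_req <- c("phi_1", "phi_2", "alpha_U", "beta_U", "alpha_N", "beta_N")
  miss <- c(setdiff(syn_req, names(p$synaptic)),
            setdiff(spa_req, names(p$spatial)),
            setdiff(obs_req, names(p$observation)))
  if (length(miss)) {
    stop("missing parameter fields: ", paste(miss, collapse = ", "))
  }
  syn <- p$synaptic; spa <- p$spatial; obs <- p$observation
  pos <- c(m_e = syn$m_e, m_i = syn$m_i, kappa_e = syn$kappa_e,
           kappa_i = syn$kappa_i, r = syn$r, phi_2 = obs$phi_2)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  nonneg <- c(alpha_13 = spa$alpha_13, alpha_23 = spa$alpha_23,
              alpha_31 = spa$alpha_31, alpha_32 = spa$alpha_32,
              c_13 = spa$c_13, c_23 = spa$c_23, c_31 = spa$c_31,
              upsilon = spa$upsilon,
              alpha_U = obs$alpha_U, beta_U = obs$beta_U,
              alpha_N = obs$alpha_N, beta_N = obs$beta_N)
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad)) {
    stop("parameter(s) must be nonnegative: ", paste(bad, collapse = ", "))
  }
  if (!isTRUE(all.equal(spa$ell, 1))) {
    stop("ell must be 1 (spatial quantities are expressed per patch radius)")
  }
  if (p$n_modes < 1L) stop("n_modes must be >= 1")
  invisible(p)
}

#' @export
print.nf_params <- function(x, ...) {
  cat("Jansen-Rit neural field parameters",
      if (x$mass_limit) "(neural-mass limit, transit time = 0)" else "",
      "\n")
  cat(sprintf("  synaptic:    m_e=%g m_i=%g mV; kappa_e=%g kappa_i=%g s^-1; r=%g eta=%g\n",
              x$synaptic$m_e, x$synaptic$m_i, x$synaptic$kappa_e,
              x$synaptic$kappa_i, x$synaptic$r, x$synaptic$eta))
  cat(sprintf("  spatial:     alpha=(%g, %g, %g, %g); c=(%g, %g, %g); upsilon=%.4g s\n",
              x$spatial$alpha_13, x$spatial$alpha_23, x$spatial$alpha_31,
              x$spatial$alpha_32, x$spatial$c_13, x$spatial$c_23,
              x$spatial$c_31, x$spatial$upsilon))
  cat(sprintf("  observation: phi=(%g, %g); input (%g, %g); channel noise (%g, %g)\n",
              x$observation$phi_1, x$observation$phi_2, x$observation$alpha_U,
              x$observation$beta_U, x$observation$alpha_N, x$observation$beta_N))
  cat(sprintf("  modal sum:   %d standing-wave modes\n", x$n_modes))
  invisible(x)
}

# Effective transit time: structurally zero in the mass limit.
effective_upsilon <- function(params) {
  if (params$mass_limit) 0 else params$spatial$upsilon
}

# Map from free-parameter names to (sublist, field) locations.
param_locations <- function() {
  list(
    m_e = c("synaptic", "m_e"), m_i = c("synaptic", "m_i"),
    kappa_e = c("synaptic", "kappa_e"), kappa_i = c("synaptic", "kappa_i"),
    r = c("synaptic", "r"),
    alpha_13 = c("spatial", "alpha_13"), alpha_23 = c("spatial", "alpha_23"),
    alpha_31 = c("spatial", "alpha_31"), alpha_32 = c("spatial", "alpha_32"),
    c_13 = c("spatial", "c_13"), c_23 = c("spatial", "c_23"),
    c_31 = c("spatial", "c_31"),
    upsilon = c("spatial", "upsilon"),
    phi_1 = c("observation", "phi_1"), phi_2 = c("observation", "phi_2"),
    alpha_U = c("observation", "alpha_U"), beta_U = c("observation", "beta_U"),
    alpha_N = c("observation", "alpha_N"), beta_N = c("observation", "beta_N")
  )
}

#' Names of the free (log-scale) parameters of a model
#'
#' Every free parameter theta_i is estimated through a log-scaling lambda_i
#' with theta_i = P_i exp(lambda_i), where P_i is the prior expectation held
#' in the `nf_params` object. The sigmoid inflection `eta` is a location
#' parameter (prior expectation 0) and is excluded; the gain is scaled
#' through the slope `r`. In the neural-mass limit the transit time is
#' structurally zero and is removed from the free set.
#'
#' @param params an `nf_params` object.
#' @return character vector of free parameter names.
#' @export
free_param_names <- function(params) {
  nm <- names(param_locations())
  if (params$mass_limit) nm <- setdiff(nm, "upsilon")
  nm
}

#' Apply log-scalings to a parameter set
#'
#' @param params an `nf_params` object holding the scale (prior) values.
#' @param mu named numeric vector of log-scalings; names must be a subset of
#'   [free_param_names()].
#' @return an `nf_params` object with each named parameter multiplied by
#'   `exp(mu)`.
#' @export
apply_scalings <- function(params, mu) {
  if (length(mu) == 0) return(params)
  if (is.null(names(mu)) || any(!nzchar(names(mu)))) {
    stop("mu must be a named vector of log-scalings")
  }
  loc <- param_locations()
  unknown <- setdiff(names(mu), free_param_names(params))
  if (length(unknown)) {
    stop("not free parameters of this model: ", paste(unknown, collapse = ", "))
  }
  for (nm in names(mu)) {
    l <- loc[[nm]]
    params[[l[1]]][[l[2]]] <- params[[l[1]]][[l[2]]] * exp(mu[[nm]])
  }
  validate_nf_params(params)
  params
}
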