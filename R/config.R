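#' Load a model/prior configuration
#'
#' Reads a YAML or JSON configuration (by file extension) in the printed
#' units of the parameter table -- depolarizations in mV, rate constants in
#' ms^-1, the kernel decay constant in mm^-1, the conduction velocity in
#' m/s, the patch radius in mm -- applies defaults for every missing field,
#' validates, and converts to the internal units (s^-1, normalized patch
#' radius, transit time in seconds) exactly once. An empty or absent
#' configuration yields the standard prior expectations of
#' [nf_params_default()].
#'
#' Recognized keys: `m_e`, `m_i` (mV), `kappa_e`, `kappa_i` (ms^-1),
#' `alpha_13`, `alpha_23`, `alpha_31`, `alpha_32`, `c` (kernel decay
#' constant, per normalized patch radius), `s` (m/s), `ell` (mm), `r`
#' (mV^-1), `eta` (mV), `phi_1`, `phi_2`, `alpha_U`, `beta_U`, `alpha_N`,
#' `beta_N`, `n_modes`, `freq_min`, `freq_max`, `freq_step` (Hz),
#' `prior_precision`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for all
#'   defaults.
#' @param overrides named list applied on top of the file contents.
#' @return list with `params` (an `nf_params`), `prior` (an [nf_prior()]),
#'   `freq_hz` (the frequency grid) and `config` (the effective raw
#'   configuration, in printed units).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    m_e = 8, m_i = 32,
    kappa_e = 1 / 4, kappa_i = 1 / 28,          # ms^-1
    alpha_13 = 2000, alpha_23 = 8000, alpha_31 = 2000, alpha_32 = 1000,
    c = 0.32,                                   # per patch radius
    s = 3,                                      # m/s
    ell = 50,                                   # mm
    r = 0.54, eta = 0,
    phi_1 = 1, phi_2 = 0.01,
    alpha_U = 1, beta_U = 1,
    alpha_N = 2e-6, beta_N = 2e-6,
    n_modes = 32,
    freq_min = 1, freq_max = 60, freq_step = 0.5,
    prior_precision = 16
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop("unsupported configuration format: .", ext))
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)

  num_fields <- setdiff(names(defaults), "n_modes")
  for (nm in num_fields) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        !is.finite(cfg[[nm]])) {
      stop("configuration field must be a finite number: ", nm)
    }
  }
  for (nm in c("m_e", "m_i", "kappa_e", "kappa_i", "r", "s", "ell",
               "c", "freq_step", "prior_precision")) {
    if (cfg[[nm]] <= 0) stop("configuration field must be positive: ", nm)
  }
  if (cfg$freq_min <= 0 || cfg$freq_max <= cfg$freq_min) {
    stop("configuration requires 0 < freq_min < freq_max")
  }

  # unit conversions, performed exactly once: rate constants ms^-1 -> s^-1;
  # transit time = radius / velocity, in seconds. The kernel decay constant
  # is already expressed per normalized patch radius.
  c_norm <- cfg$c
  upsilon <- (cfg$ell / 1000) / cfg$s
  params <- nf_params(
    synaptic = list(m_e = cfg$m_e, m_i = cfg$m_i,
                    kappa_e = cfg$kappa_e * 1000,
                    kappa_i = cfg$kappa_i * 1000,
                    r = cfg$r, eta = cfg$eta),
    spatial = list(alpha_13 = cfg$alpha_13, alpha_23 = cfg$alpha_23,
                   alpha_31 = cfg$alpha_31, alpha_32 = cfg$alpha_32,
                   c_13 = c_norm, c_23 = c_norm, c_31 = c_norm,
                   upsilon = upsilon, ell = 1),
    observation = list(phi_1 = cfg$phi_1, phi_2 = cfg$phi_2,
                       alpha_U = cfg$alpha_U, beta_U = cfg$beta_U,
                       alpha_N = cfg$alpha_N, beta_N = cfg$beta_N),
    n_modes = cfg$n_modes
  )
  list(params = params,
       prior = nf_prior(params, precision = cfg$prior_precision),
       freq_hz = seq(cfg$freq_min, cfg$freq_max, by = cfg$freq_step),
       config = cfg)
}

#' Write and read a posterior as JSON
#'
#' Serializes the conditional means, covariance, free energy, noise
#' hyperparameters, iteration trace, model label and settings, with a
#' provenance block (package version, data fingerprint).
#'
#' @param post an `nf_posterior`.
#' @param path file path.
#' @return `read_posterior` returns an `nf_posterior` (without the model's
#'   `nf_params`/`nf_prior` objects re-attached); `write_posterior` returns
#'   `path` invisibly.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "nf_posterior"))
  obj <- list(
    provenance = list(package = "nfdcm",
                      version = as.character(utils::packageVersion("nfdcm")),
                      data_fingerprint = as.list(post$data_fingerprint)),
    model = post$model,
    mu = as.list(post$mu),
    C = list(names = colnames(post$C), values = as.vector(post$C)),
    F = post$F,
    lambda = post$lambda,
    trace = post$trace,
    settings = post$settings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse posterior JSON: ",
                                           conditionMessage(e)))
  need <- c("mu", "C", "F", "lambda", "model")
  if (!all(need %in% names(obj))) {
    stop("posterior JSON is missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  if (is.null(obj$provenance$package) ||
      !identical(obj$provenance$package, "nfdcm")) {
    warning("posterior JSON has no recognizable provenance block")
  }
  p <- length(obj$C$names)
  C <- matrix(obj$C$values, p, p, dimnames = list(obj$C$names, obj$C$names))
  structure(list(mu = unlist(obj$mu), C = C, F = obj$F,
                 lambda = obj$lambda, trace = obj$trace,
                 model = obj$model, settings = obj$settings,
                 data_fingerprint = unlist(obj$provenance$data_fingerprint)),
            class = "nf_posterior")
}
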