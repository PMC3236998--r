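#' Sigmoid firing-rate function
#'
#' Maps average membrane depolarization to a normalized firing rate in (0,1):
#' `sigma(v) = 1 / (1 + exp(r * (eta - v)))`.
#'
#' @param v membrane potential (mV), vectorized.
#' @param r sigmoid slope (mV^-1), must be positive.
#' @param eta inflection potential (mV) at which half the maximum rate is
#'   reached.
#' @return firing rate(s) in (0, 1).
#' @export
sigmoid <- function(v, r, eta = 0) {
  stopifnot(r > 0)
  1 / (1 + exp(r * (eta - v)))
}

#' Gain of the sigmoid at the working point
#'
#' The linearization of the firing-rate function about the spatially
#' homogeneous working point v = 0 has slope
#' `gamma = r * exp(r * eta) / (1 + exp(r * eta))^2`,
#' which multiplies every connectivity kernel in the linearized model.
#' At the default slope and inflection (r = 0.54, eta = 0) the gain is
#' 0.54 / 4 = 0.135.
#'
#' @inheritParams sigmoid
#' @return the gain (mV^-1), a positive scalar.
#' @export
sigmoid_gain <- function(r, eta = 0) {
  stopifnot(r > 0)
  e <- exp(r * eta)
  r * e / (1 + e)^2
}

#' Spectral transfer of an exponential connectivity kernel with conduction delay
#'
#' The lateral-connectivity kernel `d(x, t) = (alpha/2) exp(-c|x|)
#' delta(t - upsilon |x|)` couples layers with a strength decaying
#' exponentially in distance and a delay proportional to distance
#' (`upsilon` is the inverse conduction velocity, i.e. the transit time per
#' unit patch radius). Its space-time Fourier transform is
#' \deqn{D(k, \omega) = \alpha (c + i \upsilon \omega) /
#'   (c^2 - \upsilon^2 \omega^2 + 2 i \upsilon c \omega + k^2).}
#'
#' @param alpha kernel amplitude (dimensionless connection strength).
#' @param c kernel decay constant (per normalized length).
#' @param upsilon transit time per unit length (s).
#' @param k spatial frequency (per normalized length).
#' @param omega angular temporal frequency (rad/s). `k` and `omega` are
#'   recycled against each other.
#' @return complex transfer value(s).
#' @export
kernel_transfer <- function(alpha, c, upsilon, k, omega) {
  den <- c^2 - upsilon^2 * omega^2 + 2i * upsilon * c * omega + k^2
  if (any(Mod(den) < 1e-300)) {
    stop("singular connectivity kernel: vanishing denominator at (k, omega)")
  }
  alpha * (c + 1i * upsilon * omega) / den
}

#' Spectral-domain lead field
#'
#' Gaussian sensor sensitivity profile over the patch, expressed over spatial
#' frequencies: `L(k) = phi_1 * exp(-phi_2 * pi^2 * k^2)`. It acts as a
#' spatial low-pass filter on the standing-wave modes; `phi_2 = 0` is an
#' ideal sensor weighting all modes equally by `phi_1`.
#'
#' @param k spatial frequency (per normalized length), vectorized.
#' @param phi_1 lead-field amplitude (a.u.).
#' @param phi_2 lead-field width (normalized length^2), nonnegative.
#' @return real weight(s).
#' @export
lead_field_weight <- function(k, phi_1, phi_2) {
  stopifnot(phi_2 >= 0)
  phi_1 * exp(-phi_2 * pi^2 * k^2)
}

#' Input and channel-noise spectral densities
#'
#' Both the neuronal input fluctuations and the channel noise are
#' parameterized as a mixture of a white (`alpha`) and a pink (`beta/omega`)
#' component. The input is spatially white: its spectrum does not depend on
#' spatial frequency.
#'
#' @param omega angular temporal frequency (rad/s), strictly positive when
#'   the pink coefficient is nonzero.
#' @param alpha white (flat) coefficient, nonnegative.
#' @param beta pink (1/omega) coefficient, nonnegative.
#' @return real spectral density value(s).
#' @export
input_spectrum <- function(omega, alpha, beta) {
  stopifnot(alpha >= 0, beta >= 0)
  if (beta > 0 && any(omega <= 0)) {
    stop("invalid frequency: pink component requires omega > 0")
  }
  alpha + if (beta > 0) beta / omega else 0 * omega
}

#' @rdname input_spectrum
#' @export
noise_spectrum <- function(omega, alpha, beta) {
  input_spectrum(omega, alpha, beta)
}
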