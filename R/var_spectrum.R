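#' Time-series container
#'
#' @param samples numeric matrix, time points in rows, channels in columns
#'   (a vector is treated as one channel).
#' @param fs sampling rate (Hz), positive.
#' @return object of class `nf_timeseries`.
#' @export
nf_timeseries <- function(samples, fs) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  stopifnot(is.numeric(samples), fs > 0)
  if (anyNA(samples)) stop("time series must not contain missing samples")
  structure(list(samples = samples, fs = fs), class = "nf_timeseries")
}

#' @export
print.nf_timeseries <- function(x, ...) {
  cat(sprintf("nf_timeseries: %d samples x %d channel(s) at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' Band-pass filter and down-sample a recording
#'
#' Mirrors the usual LFP acquisition chain: zero-phase Butterworth high- and
#' low-pass filtering (applied forward and backward, so the nominal
#' attenuation is doubled and no phase distortion is introduced), followed by
#' decimation to the target rate. With `band = NULL` and `target_fs` equal to
#' the input rate the series is returned untouched.
#'
#' @param ts an [nf_timeseries()].
#' @param band numeric length-2 vector, low/high pass-band edges in Hz, or
#'   `NULL` for no filtering. The upper edge must lie below the Nyquist
#'   frequency of `target_fs`.
#' @param target_fs output sampling rate (Hz); must divide the input rate.
#' @param order Butterworth order per section (default 6 for the low-pass,
#'   2 for the high-pass).
#' @return an `nf_timeseries` at `target_fs`.
#' @export
preprocess <- function(ts, band = c(0.6, 60), target_fs = ts$fs, order = 6) {
  stopifnot(inherits(ts, "nf_timeseries"))
  if (is.null(band) && target_fs == ts$fs) return(ts)
  x <- ts$samples
  if (!is.null(band)) {
    stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
    if (band[2] >= target_fs / 2) {
      stop("band exceeds the Nyquist frequency of target_fs")
    }
    lp <- signal::butter(order, band[2] / (ts$fs / 2), type = "low")
    x <- apply(x, 2, function(col) signal::filtfilt(lp, col))
    if (band[1] > 0) {
      hp <- signal::butter(2, band[1] / (ts$fs / 2), type = "high")
      x <- apply(x, 2, function(col) signal::filtfilt(hp, col))
    }
  }
  if (target_fs != ts$fs) {
    fac <- ts$fs / target_fs
    if (abs(fac - round(fac)) > 1e-9) {
      stop("target_fs must divide the input sampling rate")
    }
    x <- x[seq(1, nrow(x), by = round(fac)), , drop = FALSE]
  }
  nf_timeseries(x, target_fs)
}

#' Cross-spectral density by vector autoregression
#'
#' Fits a vector autoregression of the given order to the (mean-removed)
#' series by ordinary least squares and evaluates the parametric spectrum
#' \deqn{S(f) = H(f) \Sigma H(f)^* / f_s, \quad
#'   H(f) = (I - \sum_l A_l e^{-2\pi i f l / f_s})^{-1},}
#' where `A_l` are the lag matrices and `Sigma` the innovation covariance.
#' The density is two-sided, per Hz. Only relative spectral shape matters for
#' model inversion (input and noise amplitudes are free parameters), but the
#' convention is fixed and shared across the package.
#'
#' @param ts an [nf_timeseries()].
#' @param order autoregression order (default 8).
#' @param freq_hz frequency grid (Hz) at which to evaluate the spectrum;
#'   must lie below the Nyquist frequency.
#' @return a [spectral_data()] with `meta = "estimated"`.
#' @export
var_cross_spectrum <- function(ts, order = 8, freq_hz = default_freq_grid()) {
  stopifnot(inherits(ts, "nf_timeseries"), order >= 1)
  x <- ts$samples
  m <- ncol(x)
  if (nrow(x) < 10 * (order * m + 1)) {
    stop("time series too short for the requested model order")
  }
  if (any(freq_hz >= ts$fs / 2)) {
    stop("frequency grid exceeds the Nyquist frequency")
  }
  fit <- tryCatch(
    stats::ar.ols(x, aic = FALSE, order.max = order, demean = TRUE,
                  intercept = FALSE),
    error = function(e) stop("ill-conditioned autoregression: ",
                             conditionMessage(e)))
  A <- fit$ar                      # order x m x m (drops dims if m == 1)
  if (m == 1) A <- array(A, dim = c(order, 1, 1))
  Sigma <- matrix(fit$var.pred, m, m)
  vals <- array(NA_complex_, dim = c(length(freq_hz), m, m))
  for (fi in seq_along(freq_hz)) {
    z <- exp(-2i * pi * freq_hz[fi] / ts$fs * seq_len(order))
    Af <- diag(m) + 0i
    for (l in seq_len(order)) Af <- Af - A[l, , ] * z[l]
    H <- solve(Af)
    S <- H %*% Sigma %*% Conj(t(H)) / ts$fs
    # enforce exact Hermitian symmetry against rounding
    vals[fi, , ] <- (S + Conj(t(S))) / 2
  }
  spectral_data(freq_hz, vals, meta = "estimated")
}
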