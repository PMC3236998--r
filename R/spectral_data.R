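#' Cross-spectral data container
#'
#' Holds complex cross-spectral matrices on a temporal frequency grid. The
#' per-frequency matrix must be Hermitian with real diagonal (auto-spectra).
#' Single-channel data are stored as a 1 x 1 matrix per frequency.
#'
#' @param freq_hz frequency grid (Hz), strictly increasing and positive.
#' @param values complex array `n_freq x n_channel x n_channel`, or a vector
#'   of length `n_freq` for single-channel auto-spectra.
#' @param meta provenance string: `"estimated"`, `"simulated"` or
#'   `"predicted"`.
#' @param channels optional channel names.
#' @param allow_negative permit negative auto-spectral values (additive
#'   Gaussian observation error on simulated data can push bins below zero).
#'   Defaults to `TRUE` for `meta = "simulated"`.
#' @return an object of class `spectral_data`.
#' @export
spectral_data <- function(freq_hz, values, meta = c("estimated", "simulated",
                                                    "predicted"),
                          channels = NULL,
                          allow_negative = identical(meta[1], "simulated")) {
  meta <- match.arg(meta)
  if (is.null(dim(values))) {
    values <- array(as.complex(values), dim = c(length(values), 1L, 1L))
  }
  stopifnot(length(dim(values)) == 3L, dim(values)[2] == dim(values)[3],
            dim(values)[1] == length(freq_hz))
  if (is.unsorted(freq_hz, strictly = TRUE) || any(freq_hz <= 0)) {
    stop("freq_hz must be strictly increasing and positive")
  }
  m <- dim(values)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(m))
  x <- structure(list(freq_hz = freq_hz, values = values,
                      channels = channels, meta = meta),
                 class = "spectral_data")
  validate_spectral_data(x, allow_negative = allow_negative)
  x
}

validate_spectral_data <- function(x, allow_negative = FALSE) {
  v <- x$values
  n <- dim(v)[1]
  scale <- max(Mod(v), 1e-300)
  for (f in seq_len(n)) {
    S <- v[f, , , drop = TRUE]
    if (!is.matrix(S)) S <- matrix(S, 1, 1)
    if (max(Mod(S - Conj(t(S)))) > 1e-8 * scale) {
      stop(sprintf("cross-spectral matrix not Hermitian at %g Hz",
                   x$freq_hz[f]))
    }
  }
  d <- vapply(seq_len(dim(v)[2]), function(i) v[, i, i], complex(n))
  if (max(abs(Im(d))) > 1e-8 * scale) {
    stop("auto-spectra must be real")
  }
  if (!allow_negative && min(Re(d)) < -1e-12 * scale) {
    stop("auto-spectra must be nonnegative")
  }
  invisible(x)
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("spectral_data (%s): %d channel(s), %d frequencies (%g-%g Hz)\n",
              x$meta, dim(x$values)[2], length(x$freq_hz),
              min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

# Real single-channel auto-spectrum as a plain vector.
auto_spectrum <- function(x) {
  stopifnot(inherits(x, "spectral_data"))
  if (dim(x$values)[2] != 1L) {
    stop("single-channel data required")
  }
  Re(x$values[, 1, 1])
}

# Cheap fingerprint to detect posteriors fitted to different data.
data_fingerprint <- function(x) {
  v <- x$values
  c(n = length(v),
    sum_re = sum(Re(v)), sum_im = sum(Im(v)),
    sumsq = sum(Mod(v)^2), f1 = x$freq_hz[1],
    fn = x$freq_hz[length(x$freq_hz)])
}

#' Read and write cross-spectra as CSV
#'
#' Long-format CSV with columns `frequency_hz`, `channel_i`, `channel_j`,
#' `real`, `imag`; one row per frequency and channel pair. Values are written
#' with 17 significant digits so that a write/read round trip is
#' bit-identical.
#'
#' @param x a `spectral_data` object.
#' @param path file path.
#' @param meta provenance to attach on reading.
#' @return `read_spectra_csv` returns a `spectral_data`;
#'   `write_spectra_csv` returns `path` invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectral_data"))
  m <- dim(x$values)[2]
  pairs <- expand.grid(i = seq_len(m), j = seq_len(m))
  rows <- do.call(rbind, lapply(seq_along(x$freq_hz), function(f) {
    S <- matrix(x$values[f, , ], m, m)
    data.frame(frequency_hz = sprintf("%.17g", x$freq_hz[f]),
               channel_i = pairs$i, channel_j = pairs$j,
               real = sprintf("%.17g", Re(S[cbind(pairs$i, pairs$j)])),
               imag = sprintf("%.17g", Im(S[cbind(pairs$i, pairs$j)])))
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, meta = "estimated") {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("cannot parse spectra CSV: ",
                                          conditionMessage(e)))
  need <- c("frequency_hz", "channel_i", "channel_j", "real", "imag")
  if (!all(need %in% names(df))) {
    stop("spectra CSV must have columns: ", paste(need, collapse = ", "))
  }
  for (nm in need) {
    if (!is.numeric(df[[nm]])) stop("non-numeric column in spectra CSV: ", nm)
  }
  for (nm in c("frequency_hz", "real", "imag")) {
    df[[nm]] <- as.double(df[[nm]])
  }
  freq <- sort(unique(df$frequency_hz))
  m <- max(df$channel_i, df$channel_j)
  v <- array(NA_complex_, dim = c(length(freq), m, m))
  fi <- match(df$frequency_hz, freq)
  v[cbind(fi, df$channel_i, df$channel_j)] <- complex(real = df$real,
                                                      imaginary = df$imag)
  if (anyNA(v)) stop("spectra CSV is missing channel pairs at some frequencies")
  spectral_data(freq, v, meta = meta, allow_negative = TRUE)
}
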