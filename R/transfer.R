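# Spectral transfer functions of the three-population field model.
#
# Population order: 1 = excitatory stellate (input) cells, 2 = inhibitory
# interneurons, 3 = excitatory pyramidal (output) cells. The linearized
# second-order synaptic dynamics give, per spatial frequency k and angular
# frequency omega, the system matrix
#   M(k, omega) = 2 i omega B + B^2 - omega^2 I - J(k, omega)
# with B = diag(kappa_e, kappa_i, kappa_e) and J the coupling matrix below.

kernel_set <- function(k, omega, params) {
  spa <- params$spatial
  ups <- effective_upsilon(params)
  list(
    D13 = kernel_transfer(spa$alpha_13, spa$c_13, ups, k, omega),
    D23 = kernel_transfer(spa$alpha_23, spa$c_23, ups, k, omega),
    D31 = kernel_transfer(spa$alpha_31, spa$c_31, ups, k, omega),
    # interneuron-to-pyramidal kernel shares the decay constant c_31
    D32 = kernel_transfer(spa$alpha_32, spa$c_31, ups, k, omega)
  )
}

#' Coupling matrix J(k, omega)
#'
#' Assembles the 3 x 3 complex coupling matrix `J = A B D(k, omega) gamma`
#' combining maximum depolarizations (A), synaptic rate constants (B), the
#' connectivity-kernel transfer functions (D) and the sigmoid gain (gamma).
#' Its sparsity follows the microcircuit: pyramidal cells drive stellate
#' cells and interneurons (entries (1,3) and (2,3)), stellate cells excite
#' and interneurons inhibit pyramidal cells (entries (3,1) and (3,2), the
#' latter with negative sign).
#'
#' @param k spatial frequency (scalar).
#' @param omega angular temporal frequency (rad/s, scalar).
#' @param params an `nf_params` object.
#' @return a 3 x 3 complex matrix.
#' @export
coupling_matrix <- function(k, omega, params) {
  syn <- params$synaptic
  g <- sigmoid_gain(syn$r, syn$eta)
  D <- kernel_set(k, omega, params)
  J <- matrix(0 + 0i, 3, 3)
  J[1, 3] <- syn$m_e * syn$kappa_e * D$D13 * g
  J[2, 3] <- syn$m_i * syn$kappa_i * D$D23 * g
  J[3, 1] <- syn$m_e * syn$kappa_e * D$D31 * g
  J[3, 2] <- -syn$m_e * syn$kappa_e * D$D32 * g
  J
}

system_matrix <- function(k, omega, params) {
  syn <- params$synaptic
  B <- diag(c(syn$kappa_e, syn$kappa_i, syn$kappa_e))
  2i * omega * B + B %*% B - omega^2 * diag(3) - coupling_matrix(k, omega, params)
}

#' Transfer vector: response of the three populations to unit input
#'
#' Solves `M(k, omega) T = G` for the complex 3-vector of depolarization
#' perturbations per unit input fluctuation, where the input enters the
#' stellate population only, `G = (kappa_e m_e, 0, 0)`.
#'
#' @inheritParams coupling_matrix
#' @return list of class `transfer_eval` with elements `k`, `omega` and
#'   `value` (complex 3-vector).
#' @export
transfer_vector <- function(k, omega, params) {
  syn <- params$synaptic
  M <- system_matrix(k, omega, params)
  G <- c(syn$kappa_e * syn$m_e, 0, 0)
  v <- tryCatch(solve(M, G), error = function(e) {
    stop(sprintf("resonance/instability: singular system matrix at k=%g, omega=%g",
                 k, omega))
  })
  structure(list(k = k, omega = omega, value = v), class = "transfer_eval")
}

#' @export
print.transfer_eval <- function(x, ...) {
  cat(sprintf("transfer vector at k=%g, omega=%g rad/s\n", x$k, x$omega))
  print(x$value)
  invisible(x)
}

# Closed-form pyramidal component of the transfer function, vectorized over
# a frequency grid and a set of spatial modes. Returns a list with the
# (n_omega x n_k) complex matrix T3 and the determinant surrogate R (equal to
# det M(k, omega)), used for resonance diagnostics.
#
#   T3 = D31 gamma kappa_e^2 m_e^2 (kappa_i + i omega)^2 / R
#   R  = a_i a_e^2
#        + a_e m_e m_i kappa_e kappa_i D23 D32 gamma^2
#        - a_i m_e^2 kappa_e^2 D13 D31 gamma^2
# with a_e = (kappa_e + i omega)^2, a_i = (kappa_i + i omega)^2.
transfer_pyramidal <- function(omega, k, params) {
  syn <- params$synaptic
  g <- sigmoid_gain(syn$r, syn$eta)
  ke <- syn$kappa_e; ki <- syn$kappa_i
  me <- syn$m_e; mi <- syn$m_i
  a_e <- (ke + 1i * omega)^2
  a_i <- (ki + 1i * omega)^2
  ow <- matrix(omega, length(omega), length(k))
  kw <- matrix(k, length(omega), length(k), byrow = TRUE)
  D <- kernel_set(kw, ow, params)
  R <- a_i * a_e^2 +
    a_e * (me * mi * ke * ki * g^2) * D$D23 * D$D32 -
    a_i * (me^2 * ke^2 * g^2) * D$D13 * D$D31
  T3 <- (g * ke^2 * me^2) * D$D31 * a_i / R
  list(T3 = T3, R = R)
}
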