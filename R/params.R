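#' Local excitatory-inhibitory circuit parameters
#'
#' Container for the five mesoscopic constants of the spectral graph model:
#' the excitatory and inhibitory characteristic time constants of the
#' Gamma-shaped ensemble response kernels, and the three dimensionless neural
#' gains. The excitatory self-gain `g_ee` is pinned at 1 by convention so that
#' the remaining gains are identifiable; override it only for methodological
#' experiments.
#'
#' @param tau_e Excitatory characteristic time constant, seconds.
#' @param tau_i Inhibitory characteristic time constant, seconds.
#' @param g_ei Gain of the coupled (alternating) excitatory-inhibitory
#'   population, dimensionless.
#' @param g_ii Inhibitory self-gain, dimensionless.
#' @param g_ee Excitatory self-gain, dimensionless; fixed at 1 unless
#'   explicitly overridden.
#' @return An object of class `local_params`.
#' @examples
#' p <- local_params(tau_e = 0.012, tau_i = 0.003, g_ei = 0.4, g_ii = 0.5)
#' @export
local_params <- function(tau_e = 0.012, tau_i = 0.003, g_ei = 0.4,
                         g_ii = 0.5, g_ee = 1) {
  vals <- c(tau_e = tau_e, tau_i = tau_i, g_ei = g_ei, g_ii = g_ii,
            g_ee = g_ee)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all local circuit parameters must be finite and strictly positive")
  structure(as.list(vals), class = "local_params")
}

#' Macroscopic network parameters
#'
#' The three constants governing the long-range excitatory network: the graph
#' characteristic time constant, the global coupling constant scaling the
#' connectome, and the cortico-cortical conduction speed that converts
#' inter-regional distances into transmission delays.
#'
#' @param tau_G Graph characteristic time constant, seconds.
#' @param alpha Global coupling constant, dimensionless.
#' @param v Conduction speed, m/s. Distances in the connectome are in mm, so
#'   a delay is `d_jk / (1000 * v)` seconds.
#' @return An object of class `network_params`.
#' @export
network_params <- function(tau_G = 0.012, alpha = 0.8, v = 5) {
  vals <- c(tau_G = tau_G, alpha = alpha, v = v)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all network parameters must be finite and strictly positive")
  structure(as.list(vals), class = "network_params")
}

#' @export
print.local_params <- function(x, ...) {
  cat("Local circuit parameters:\n")
  cat(sprintf("  tau_e = %g s, tau_i = %g s\n", x$tau_e, x$tau_i))
  cat(sprintf("  g_ee = %g, g_ei = %g, g_ii = %g\n", x$g_ee, x$g_ei, x$g_ii))
  invisible(x)
}

#' @export
print.network_params <- function(x, ...) {
  cat("Network parameters:\n")
  cat(sprintf("  tau_G = %g s, alpha = %g, v = %g m/s\n",
              x$tau_G, x$alpha, x$v))
  invisible(x)
}

#' Default oscillation band edges, Hz
#'
#' Conventional electrophysiology band partition of the 2-45 Hz analysis
#' range: delta 2-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz.
#' Used by [find_spectral_peaks()] to label peaks; pass a modified copy to
#' change the partition.
#'
#' @return Named numeric vector of band upper edges.
#' @export
default_band_edges <- function() {
  c(delta = 4, theta = 8, alpha = 12, beta = 30, gamma = 45)
}

#' Default analysis frequency grid
#'
#' The model is analyzed over 2-45 Hz, the band-pass range of the resting
#' MEG spectra the model is designed for.
#'
#' @param by Grid spacing, Hz.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freqs <- function(by = 0.1) seq(2, 45, by = by)
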