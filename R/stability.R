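# Polynomial helpers on ascending-order coefficient vectors.
poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}
poly_linear <- function(r) c(r, 1)  # (s + r)

#' Characteristic polynomial of the local circuit
#'
#' The poles of the local transfer function are the roots of the determinant
#' `det(sI - A(s))`. Writing `t_e = 1/tau_e`, `t_i = 1/tau_i` and clearing
#' the kernel denominators by `(s + t_e)^4 (s + t_i)^4` yields the monic
#' degree-10 real polynomial
#' `[s (s+t_e)^2 + g_ee t_e^3] (s+t_i)^2 * [s (s+t_i)^2 + g_ii t_i^3]
#'  (s+t_e)^2 + g_ei^2 t_e^5 t_i^5`,
#' built here by exact coefficient convolution. In the decoupled limit
#' (`g_ei -> 0`) clearing denominators leaves spurious roots at
#' `s = -t_e, -t_i`; with coupled gains the constant cross term perturbs
#' them into ordinary (still damped) roots.
#'
#' @param params A [local_params()] object.
#' @return List of class `char_poly` with `coeffs` (descending degree,
#'   leading coefficient 1), `degree`, `t_e`, `t_i`.
#' @export
mesoscopic_char_poly <- function(params) {
  te <- 1 / params$tau_e
  ti <- 1 / params$tau_i
  # s (s + te)^2 + g_ee te^3, ascending
  b1 <- poly_mul(c(0, 1), poly_mul(poly_linear(te), poly_linear(te)))
  b1[1] <- b1[1] + params$g_ee * te^3
  q1 <- poly_mul(b1, poly_mul(poly_linear(ti), poly_linear(ti)))
  b2 <- poly_mul(c(0, 1), poly_mul(poly_linear(ti), poly_linear(ti)))
  b2[1] <- b2[1] + params$g_ii * ti^3
  q2 <- poly_mul(b2, poly_mul(poly_linear(te), poly_linear(te)))
  p <- poly_mul(q1, q2)
  p[1] <- p[1] + params$g_ei^2 * te^5 * ti^5
  coeffs <- rev(p) / p[length(p)]
  structure(list(coeffs = coeffs, degree = length(coeffs) - 1L,
                 t_e = te, t_i = ti), class = "char_poly")
}

# Roots of a real polynomial given descending coefficients, via the
# companion-matrix eigenvalues (more robust than polyroot at degree 10 with
# coefficients spanning many orders of magnitude).
poly_roots <- function(coeffs_desc) {
  c <- coeffs_desc / coeffs_desc[1]
  n <- length(c) - 1
  if (n == 0) return(complex(0))
  M <- matrix(0, n, n)
  if (n > 1) M[cbind(2:n, 1:(n - 1))] <- 1
  M[1, ] <- -c[2:(n + 1)]
  eigen(M, only.values = TRUE)$values
}

#' Poles and stability verdict of the local circuit
#'
#' Finds all 10 roots of the characteristic polynomial as companion-matrix
#' eigenvalues and classifies the circuit: `stable` if the largest real part
#' is below `-tol`, `limit_cycle` if within `tol` of zero, `unstable`
#' otherwise. Roots coinciding with the cleared kernel denominators at
#' `s = -1/tau_e, -1/tau_i` (present in the decoupled limit) are flagged
#' `spurious` and excluded from `max_real`.
#'
#' @param params A [local_params()] object.
#' @param tol Marginality tolerance on the largest real part, rad/s.
#' @return List of class `pole_set`: `roots`, `spurious` (logical per root),
#'   `max_real` (over non-spurious roots), `classification`, `tolerance`.
#' @export
mesoscopic_poles <- function(params, tol = 1e-6) {
  cp <- mesoscopic_char_poly(params)
  r <- poly_roots(cp$coeffs)
  spur <- (Mod(r + cp$t_e) < 1e-6 * cp$t_e & abs(Im(r)) < 1e-6 * cp$t_e) |
          (Mod(r + cp$t_i) < 1e-6 * cp$t_i & abs(Im(r)) < 1e-6 * cp$t_i)
  mr <- max(Re(r[!spur]))
  cls <- if (mr < -tol) "stable" else if (mr > tol) "unstable"
         else "limit_cycle"
  structure(list(roots = r, spurious = spur, max_real = mr,
                 classification = cls, tolerance = tol, char_poly = cp),
            class = "pole_set")
}

#' @export
print.pole_set <- function(x, ...) {
  cat(sprintf("Pole set: %d roots, max real part %.6g rad/s -> %s\n",
              length(x$roots), x$max_real, x$classification))
  invisible(x)
}

#' Routh-Hurwitz array and right-half-plane root count
#'
#' Builds the Routh array of a real polynomial (descending coefficients).
#' The number of sign changes in the first column equals the number of roots
#' with strictly positive real part. Zero first-column pivots are replaced by
#' a small epsilon (relative to the largest magnitude in that row); an
#' all-zero row (symmetric root constellation) is replaced by the derivative
#' of its auxiliary polynomial. Both fallbacks are flagged in the output.
#'
#' @param coeffs Real polynomial coefficients, descending degree; leading
#'   coefficient nonzero.
#' @return List with `array` (the Routh array), `sign_changes` (count of
#'   open-right-half-plane roots), and `degenerate` (`TRUE` when an epsilon
#'   or auxiliary-polynomial substitution occurred).
#' @export
routh_hurwitz <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (coeffs[1] == 0) stop("leading coefficient must be nonzero")
  n <- length(coeffs) - 1
  ncol <- ceiling((n + 1) / 2)
  A <- matrix(0, n + 1, ncol)
  r1 <- coeffs[seq(1, n + 1, 2)]
  r2 <- coeffs[seq(2, n + 1, 2)]
  A[1, seq_along(r1)] <- r1
  if (length(r2)) A[2, seq_along(r2)] <- r2
  degenerate <- FALSE
  if (n >= 1 && all(A[2, ] == 0)) { A[2, 1] <- .Machine$double.eps; degenerate <- TRUE }
  for (i in seq_len(n - 1) + 2) {
    if (all(A[i - 1, ] == 0)) {
      # auxiliary polynomial from row i-2 (degree n - i + 3), differentiate
      degenerate <- TRUE
      deg_aux <- n - (i - 3)
      powers <- seq(deg_aux, by = -2, length.out = ncol)
      A[i - 1, ] <- A[i - 2, ] * pmax(powers, 0)
    }
    piv <- A[i - 1, 1]
    if (piv == 0) {
      degenerate <- TRUE
      piv <- 1e-12 * max(abs(A[i - 1, ]), 1)
      A[i - 1, 1] <- piv
    }
    for (j in seq_len(ncol - 1)) {
      A[i, j] <- (A[i - 1, 1] * A[i - 2, j + 1] -
                  A[i - 2, 1] * A[i - 1, j + 1]) / A[i - 1, 1]
    }
  }
  first <- A[, 1]
  first <- first[first != 0]
  sc <- sum(diff(sign(first)) != 0)
  list(array = A, sign_changes = sc, degenerate = degenerate)
}

#' Critical coupled-population gain by bisection
#'
#' Locates the `g_ei` at which the local circuit transitions from damped to
#' growing oscillations (a conjugate pole pair crossing the imaginary axis)
#' by bisecting the sign of the maximum real pole part.
#'
#' @param g_ii Inhibitory gain held fixed.
#' @param tau_e,tau_i Time constants, seconds.
#' @param bracket Length-2 numeric straddling the transition.
#' @param tol Absolute bisection tolerance on `g_ei`.
#' @return The critical gain `g_ei*`.
#' @export
critical_gei <- function(g_ii = 0.5, tau_e = 0.012, tau_i = 0.003,
                         bracket = c(0.1, 1), tol = 1e-4) {
  maxre <- function(g) mesoscopic_poles(local_params(
    tau_e = tau_e, tau_i = tau_i, g_ei = g, g_ii = g_ii))$max_real
  lo <- bracket[1]; hi <- bracket[2]
  flo <- maxre(lo); fhi <- maxre(hi)
  if (sign(flo) == sign(fhi))
    stop(sprintf("bracket [%g, %g] does not straddle the transition ",
                 lo, hi), sprintf("(max real parts %.3g, %.3g)", flo, fhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(maxre(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Analytic stability of the uncoupled (alpha = 0) macroscopic subsystem
#'
#' With zero global coupling each region obeys a scalar delay-free equation
#' whose characteristic polynomial is the cubic
#' `s^3 + (2/tau_e) s^2 + (1/tau_e^2) s + 1/(tau_e^2 tau_G)`.
#' The Routh-Hurwitz condition for this cubic reduces to `2 tau_G > tau_e`.
#'
#' @param tau_e Excitatory time constant, seconds.
#' @param tau_G Graph time constant, seconds.
#' @return List: `stable` (logical, from the analytic inequality), `cubic`
#'   (descending coefficients, for cross-checking), `critical_ratio`
#'   (`tau_e / tau_G` at the boundary, always 2).
#' @export
alpha0_stability <- function(tau_e, tau_G) {
  if (tau_e <= 0 || tau_G <= 0) stop("time constants must be positive")
  cubic <- c(1, 2 / tau_e, 1 / tau_e^2, 1 / (tau_e^2 * tau_G))
  list(stable = 2 * tau_G > tau_e, cubic = cubic, critical_ratio = 2)
}

#' Coupling constant at which the undelayed Laplacian first loses rank
#'
#' Sweeps the eigenvalues of `C` to find the smallest `alpha > 0` with
#' `det(I - alpha C) = 0`, i.e. `1 / max Re-eigenvalue`. For any connected
#' row-degree-normalized (row-stochastic) connectivity matrix the Perron
#' eigenvalue is 1, so the boundary is exactly `alpha = 1`; beyond it the
#' mean of the network response grows without bound.
#'
#' @param conn A [connectome()] object (or a bare row-stochastic matrix).
#' @return The critical coupling constant.
#' @export
alpha_boundary <- function(conn) {
  C <- if (inherits(conn, "connectome")) conn$C else as.matrix(conn)
  ev <- eigen(C, only.values = TRUE)$values
  lam_max <- max(Re(ev))
  if (lam_max <= 0) stop("C has no positive eigenvalue; graph degenerate")
  if (sum(abs(Re(ev) - lam_max) < 1e-8 & abs(Im(ev)) < 1e-8) > 1)
    warning("leading eigenvalue not simple; graph may be disconnected")
  1 / lam_max
}
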