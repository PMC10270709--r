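#' Delay-weighted connectivity matrix
#'
#' At complex frequency `s`, long-range transmission along each edge is
#' phase-shifted by its conduction delay `d_jk / v`:
#' `C*(s) = [c_jk exp(-s d_jk / v)]` elementwise. At `s = 0` (or as
#' `v -> Inf`) this reduces to `C`; on the imaginary axis each factor has
#' unit modulus so `|C*| = C` elementwise.
#'
#' @param conn A [connectome()] object (distances in mm).
#' @param v Conduction speed, m/s (> 0).
#' @param s Complex Laplace variable, rad/s; `s = 2i * pi * f` for a real
#'   frequency `f` Hz.
#' @return Complex N x N matrix.
#' @export
delayed_connectivity <- function(conn, v, s) {
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
    stop("conduction speed v must be a single positive number")
  # distances are mm, speed m/s: delay in seconds is d / (1000 v)
  conn$C * exp(-s * conn$D / (1000 * v))
}

#' Complex graph Laplacian and its eigendecomposition
#'
#' Forms `L = I - alpha C*` and computes a general (non-Hermitian)
#' eigendecomposition `L = U Lambda U^{-1}`. The delayed matrix `C*` is not
#' normal, so the eigenvector matrix is not unitary; reconstruction and the
#' eigenmode expansion therefore use the matrix inverse of `U` rather than
#' its conjugate transpose.
#'
#' @param C_star Complex square matrix from [delayed_connectivity()].
#' @param alpha Global coupling constant.
#' @return List of class `network_operator` with `L`, eigenvalues `lambda`,
#'   eigenvectors `U`, and `U_inv`.
#' @export
complex_laplacian <- function(C_star, alpha) {
  C_star <- as.matrix(C_star)
  if (nrow(C_star) != ncol(C_star)) stop("C_star must be square")
  L <- diag(nrow(C_star)) - alpha * C_star
  e <- eigen(L)
  structure(list(L = L, lambda = e$values, U = e$vectors,
                 U_inv = solve(e$vectors), alpha = alpha),
            class = "network_operator")
}

# Frequency-domain input spectrum driving the macroscopic network.
#  sgm_local: the local circuit output H_local(s) * P(s) with P = 1
#  exp_decay: exp(-t) input, transform 1/(s + 1)
#  impulse:   unit impulse, transform 1
network_input <- function(input_kind, local, s) {
  switch(input_kind,
         sgm_local = local_transfer(local, s)$H_local,
         exp_decay = 1 / (s + 1),
         impulse   = 1 + 0i,
         stop("unknown input_kind: ", input_kind))
}

# Regional response vector at a single complex frequency.
# method "direct" solves (s I + Fe(s)/tau_G L(s)) X = input * 1;
# method "eigen" expands the same solution over the eigenmodes of L(s):
#   X = sum_k u_k [U^{-1} 1]_k input / (s + lambda_k Fe(s) / tau_G).
network_response_at <- function(local, net, conn, s, input_kind = "sgm_local",
                                method = c("eigen", "direct")) {
  method <- match.arg(method)
  Fe <- gamma_kernel_transform(local$tau_e, s)
  Cs <- delayed_connectivity(conn, net$v, s)
  u_in <- network_input(input_kind, local, s)
  rhs <- rep(u_in, conn$N)
  if (method == "direct") {
    L <- diag(conn$N) - net$alpha * Cs
    M <- s * diag(conn$N) + (Fe / net$tau_G) * L
    return(solve(M, rhs))
  }
  op <- complex_laplacian(Cs, net$alpha)
  denom <- s + op$lambda * Fe / net$tau_G
  if (any(Mod(denom) < 1e-14 * max(1, Mod(s))))
    stop("marginal mode: s + lambda_k Fe / tau_G vanishes at this frequency")
  proj <- op$U_inv %*% rhs
  as.vector(op$U %*% (proj / denom))
}

#' Closed-form regional frequency response of the macroscopic model
#'
#' Evaluates the steady-state network response on a real frequency grid. At
#' each frequency the delayed connectivity, complex Laplacian, and its
#' eigenmodes are formed, and the response of every region is the eigenmode
#' sum `X = sum_k u_k (U^{-1} 1)_k input(s) / (s + lambda_k Fe(s)/tau_G)`
#' with `s = 2 pi f i`. The equivalent direct linear solve of
#' `(sI + Fe L / tau_G) X = input` is available as a cross-check and is used
#' internally by the fitting routines.
#'
#' @param local A [local_params()] object.
#' @param net A [network_params()] object.
#' @param conn A [connectome()] object.
#' @param freqs Frequency grid, Hz.
#' @param input_kind One of `"sgm_local"` (local circuit output, the full
#'   model), `"exp_decay"` (`exp(-t)` damping input, transform
#'   `1/(i omega + 1)`), `"impulse"`.
#' @param method `"eigen"` (eigenmode sum, default) or `"direct"` (linear
#'   solve).
#' @return Object of class `regional_spectrum`: list with complex `X`
#'   (regions x frequencies), `freqs`, `input_kind`, `labels`.
#' @export
network_transfer <- function(local, net, conn, freqs = default_freqs(),
                             input_kind = c("sgm_local", "exp_decay",
                                            "impulse"),
                             method = c("eigen", "direct")) {
  input_kind <- match.arg(input_kind)
  method <- match.arg(method)
  if (length(freqs) == 0) stop("frequency grid is empty")
  X <- vapply(freqs, function(f)
    network_response_at(local, net, conn, 2i * pi * f, input_kind, method),
    complex(conn$N))
  X <- matrix(X, nrow = conn$N)
  structure(list(X = X, freqs = freqs, input_kind = input_kind,
                 labels = conn$labels), class = "regional_spectrum")
}

#' Convert a regional spectrum (or any response magnitude) to dB power
#'
#' `20 log10 |X|` elementwise. Zero magnitudes are floored at the smallest
#' positive double with a warning, so the result is always finite.
#'
#' @param spec A `regional_spectrum` from [network_transfer()], or a numeric
#'   or complex matrix of responses.
#' @return Numeric matrix of dB values (regions x frequencies).
#' @export
model_psd <- function(spec) {
  X <- if (inherits(spec, "regional_spectrum")) spec$X else spec
  m <- Mod(X)
  if (any(m == 0)) {
    warning("degenerate spectrum: zero magnitude floored before log")
    m[m == 0] <- .Machine$double.xmin
  }
  out <- 20 * log10(m)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' Primary-peak frequency map over a (tau_G, alpha) grid
#'
#' For each grid cell, checks macroscopic stability (coupling bound
#' `alpha < 1` and the numerically found oscillation boundary in `tau_G`) and,
#' where stable, records the frequency of the primary peak of the mean
#' cortical PSD computed with the `exp(-t)` input. Unstable cells are `NA`.
#'
#' @param local A [local_params()] object.
#' @param tau_G_grid,alpha_grid Numeric grids, seconds / dimensionless.
#' @param conn A [connectome()] object.
#' @param v Conduction speed, m/s.
#' @param freqs Frequency grid for the spectra, Hz.
#' @param min_prominence Peak prominence floor in dB passed to
#'   [find_spectral_peaks()]; the default 1 dB suppresses delay-interference
#'   ripples.
#' @return Matrix of primary-peak frequencies (Hz), rows indexed by
#'   `tau_G_grid`, columns by `alpha_grid`; `NA` marks unstable cells.
#' @export
peak_frequency_map <- function(local, tau_G_grid, alpha_grid, conn, v = 5,
                               freqs = default_freqs(), min_prominence = 1) {
  out <- matrix(NA_real_, length(tau_G_grid), length(alpha_grid),
                dimnames = list(signif(tau_G_grid, 6), signif(alpha_grid, 6)))
  for (j in seq_along(alpha_grid)) {
    a <- alpha_grid[j]
    if (a >= 1) next
    bd <- tryCatch(jw_boundary(local, a, conn, v)$tau_G_critical,
                   error = function(e) NA_real_)
    for (i in seq_along(tau_G_grid)) {
      tg <- tau_G_grid[i]
      if (!is.na(bd) && tg <= bd) next
      net <- network_params(tau_G = tg, alpha = a, v = v)
      spec <- network_transfer(local, net, conn, freqs,
                               input_kind = "exp_decay", method = "direct")
      psd <- model_psd(spec)
      mean_psd <- colMeans(psd[conn$cortical_mask, , drop = FALSE])
      pk <- find_spectral_peaks(mean_psd, freqs,
                                min_prominence = min_prominence)
      if (nrow(pk)) out[i, j] <- pk$freq[1]
    }
  }
  out
}
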