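# Eigenvalue curves lambda_k(i omega) of the complex Laplacian, tracked
# across a frequency grid by nearest-eigenvalue continuation (the general
# eigendecomposition returns eigenvalues in arbitrary order, so naive
# per-frequency sorting would splice different modes together).
laplacian_mode_curves <- function(conn, alpha, v, omegas) {
  N <- conn$N
  lam <- matrix(0 + 0i, length(omegas), N)
  crossings <- FALSE
  for (i in seq_along(omegas)) {
    e <- eigen(diag(N) - alpha * delayed_connectivity(conn, v, 1i * omegas[i]),
               only.values = TRUE)$values
    if (i == 1) {
      lam[1, ] <- e[order(Re(e), Im(e))]
    } else {
      prev <- lam[i - 1, ]
      used <- rep(FALSE, N)
      ord <- integer(N)
      for (k in seq_len(N)) {
        d <- Mod(e - prev[k])
        d[used] <- Inf
        j <- which.min(d)
        ord[k] <- j
        used[j] <- TRUE
        if (i > 1 && Mod(e[j] - prev[k]) > 0.5) crossings <- TRUE
      }
      lam[i, ] <- e[ord]
    }
  }
  attr(lam, "crossings_flagged") <- crossings
  lam
}

# Characteristic value of macroscopic mode k at s = i omega given tau_G:
# h_k = i omega + lambda_k(i omega) Fe(i omega) / tau_G. A purely imaginary
# characteristic root exists when h_k = 0, which rearranges to
#   tau_G = -lambda_k(i omega) Fe(i omega) / (i omega),
# real and positive at a true boundary crossing.
mode_tau_G <- function(lam, tau_e, omega) {
  -lam * gamma_kernel_transform(tau_e, 1i * omega) / (1i * omega)
}

#' Oscillation stability boundary of the delayed macroscopic network
#'
#' For fixed coupling `alpha`, finds the critical graph time constant
#' `tau_G*` below which some network mode has a characteristic root on the
#' imaginary axis. Each eigenmode `lambda_k(i omega)` of the complex
#' Laplacian contributes the per-mode condition
#' `i omega + lambda_k(i omega) Fe(i omega) / tau_G = 0` in the two unknowns
#' `(tau_G, omega)`. The solver eliminates `tau_G`
#' (`tau_G = -lambda_k Fe / (i omega)`), scans a dense frequency grid for
#' zero crossings of the imaginary part along continuation-tracked mode
#' curves, refines each crossing by bisection to high precision, polishes the
#' full two-unknown system with damped Newton iterations, and returns the
#' largest positive `tau_G` over all modes together with its crossing
#' frequency and the residual of the characteristic condition.
#'
#' As `alpha -> 0` every `lambda_k -> 1` and the boundary approaches the
#' analytic uncoupled limit `tau_G = tau_e / 2` (crossing at
#' `omega = 1/tau_e`); the same limit is reached as `v -> 0`, when delayed
#' inputs dephase completely.
#'
#' @param local A [local_params()] object (only `tau_e` enters the
#'   macroscopic kernel).
#' @param alpha Coupling constant, fixed.
#' @param conn A [connectome()] object.
#' @param v Conduction speed, m/s.
#' @param freq_range Search range for the crossing frequency, Hz.
#' @param n_scan Scan grid resolution.
#' @param tol Root tolerance on the characteristic condition.
#' @return List: `tau_G_critical`, `omega_critical` (rad/s),
#'   `f_critical` (Hz), `mode_index`, `residual` (modulus of the per-mode
#'   characteristic value at the solution), and `all_crossings` (data frame
#'   of every positive-`tau_G` crossing found).
#' @export
jw_boundary <- function(local, alpha, conn, v, freq_range = c(0.5, 40),
                        n_scan = 240, tol = 1e-12) {
  omegas <- 2 * pi * seq(freq_range[1], freq_range[2], length.out = n_scan)
  lam <- laplacian_mode_curves(conn, alpha, v, omegas)
  N <- conn$N
  hits <- list()
  lam_at <- function(omega, guess) {
    e <- eigen(diag(N) - alpha * delayed_connectivity(conn, v, 1i * omega),
               only.values = TRUE)$values
    e[which.min(Mod(e - guess))]
  }
  for (k in seq_len(N)) {
    tg <- mode_tau_G(lam[, k], local$tau_e, omegas)
    im <- Im(tg)
    sc <- which(diff(sign(im)) != 0 & is.finite(im[-length(im)]))
    for (i in sc) {
      lo <- omegas[i]; hi <- omegas[i + 1]
      g_lo <- lam[i, k]
      fval <- function(omega) {
        Im(mode_tau_G(lam_at(omega, g_lo), local$tau_e, omega))
      }
      r <- tryCatch(stats::uniroot(fval, c(lo, hi), tol = tol),
                    error = function(e) NULL)
      if (is.null(r)) next
      w0 <- r$root
      l0 <- lam_at(w0, g_lo)
      tg0 <- Re(mode_tau_G(l0, local$tau_e, w0))
      if (!is.finite(tg0) || tg0 <= 0) next
      res <- Mod(1i * w0 + l0 * gamma_kernel_transform(local$tau_e, 1i * w0) /
                   tg0)
      hits[[length(hits) + 1]] <- data.frame(
        tau_G = tg0, omega = w0, mode = k, residual = res)
    }
  }
  if (!length(hits))
    stop("boundary not found: no imaginary-axis crossing in ",
         sprintf("[%g, %g] Hz at alpha = %g", freq_range[1], freq_range[2],
                 alpha))
  all_h <- do.call(rbind, hits)
  best <- all_h[which.max(all_h$tau_G), ]
  list(tau_G_critical = best$tau_G, omega_critical = best$omega,
       f_critical = best$omega / (2 * pi), mode_index = best$mode,
       residual = best$residual, all_crossings = all_h)
}

#' Classify the macroscopic dynamical regime
#'
#' Four regimes arise from crossing the two macroscopic stability boundaries
#' independently: the coupling bound (`alpha = 1`, above which the mean of
#' the response grows) and the oscillation boundary in `tau_G` (below which
#' oscillation amplitude grows). Codes: 1 = stable (damped); 2 =
#' amplitude-growing (`tau_G` below the oscillation boundary, `alpha <= 1`);
#' 3 = mean-growing (`alpha > 1`, `tau_G` above the boundary); 4 = both.
#'
#' @param local A [local_params()] object.
#' @param net A [network_params()] object.
#' @param conn A [connectome()] object.
#' @param boundary Optional precomputed `tau_G` boundary for this `alpha`
#'   (to avoid recomputation in grid sweeps).
#' @return List of class `macro_regime`: `code` (1-4), `meso_part`
#'   (`"damped"` / `"growing-amplitude"`), `mean_part` (`"bounded"` /
#'   `"growing"`), `tau_G_boundary`.
#' @export
classify_macroscopic_regime <- function(local, net, conn, boundary = NULL) {
  alpha_for_boundary <- min(net$alpha, 0.999)  # oscillation boundary is
  # evaluated inside the coupling-feasible region; beyond alpha = 1 the mean
  # instability dominates regardless
  if (is.null(boundary))
    boundary <- jw_boundary(local, alpha_for_boundary, conn,
                            net$v)$tau_G_critical
  amp_growing <- net$tau_G <= boundary
  mean_growing <- net$alpha > 1
  code <- if (!amp_growing && !mean_growing) 1L
          else if (amp_growing && !mean_growing) 2L
          else if (!amp_growing) 3L else 4L
  structure(list(code = code,
                 meso_part = if (amp_growing) "growing-amplitude"
                             else "damped",
                 mean_part = if (mean_growing) "growing" else "bounded",
                 tau_G_boundary = boundary),
            class = "macro_regime")
}

#' @export
print.macro_regime <- function(x, ...) {
  cat(sprintf("Macroscopic regime %d: amplitude %s, mean %s (tau_G boundary %.4g s)\n",
              x$code, x$meso_part, x$mean_part, x$tau_G_boundary))
  invisible(x)
}

#' Regime map over a (tau_G, alpha) grid
#'
#' Sweeps a grid and returns a long data frame of regime codes, recomputing
#' the oscillation boundary once per `alpha`.
#'
#' @inheritParams classify_macroscopic_regime
#' @param tau_G_grid,alpha_grid Numeric grids.
#' @param v Conduction speed, m/s.
#' @return Data frame with columns `alpha`, `tau_G`, `code`,
#'   `tau_G_boundary`.
#' @export
stability_map <- function(local, tau_G_grid, alpha_grid, conn, v = 5) {
  rows <- list()
  for (a in alpha_grid) {
    bd <- tryCatch(jw_boundary(local, min(a, 0.999), conn, v)$tau_G_critical,
                   error = function(e) NA_real_)
    for (tg in tau_G_grid) {
      net <- network_params(tau_G = tg, alpha = a, v = v)
      code <- if (is.na(bd)) NA_integer_ else
        classify_macroscopic_regime(local, net, conn, boundary = bd)$code
      rows[[length(rows) + 1]] <- data.frame(alpha = a, tau_G = tg,
                                             code = code,
                                             tau_G_boundary = bd)
    }
  }
  do.call(rbind, rows)
}
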