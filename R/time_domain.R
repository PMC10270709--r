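#' Numerical inverse Laplace transform (de Hoog-Knight-Stokes)
#'
#' Inverts a Laplace-domain function on a positive time grid using the
#' de Hoog, Knight and Stokes accelerated Fourier series method: the Bromwich
#' integral is discretized on a shifted contour, and the resulting Fourier
#' series is summed as a continued fraction obtained from the
#' quotient-difference algorithm, with the standard remainder correction.
#' One contour (set by the largest requested time) serves the whole grid, so
#' `fn` is evaluated at `2M + 1` complex nodes regardless of the number of
#' time points.
#'
#' @param fn Function of a single complex `s` returning the transform value
#'   (complex scalar). Must be analytic to the right of all its poles.
#' @param t_grid Strictly positive times, seconds.
#' @param M Series order; `2M + 1` transform evaluations (default 80).
#' @param alpha Estimated rightmost pole real part (contour shift); 0 works
#'   for stable and marginally unstable transforms.
#' @param tol Target accuracy controlling the contour offset.
#' @return Numeric vector of time-domain values; entries where the
#'   acceleration overflowed are `NA`.
#' @examples
#' t <- seq(0.01, 0.3, 0.01)
#' max(abs(inverse_laplace(function(s) 1 / (s + 10), t) - exp(-10 * t)))
#' @export
inverse_laplace <- function(fn, t_grid, M = 80, alpha = 0, tol = 1e-9) {
  if (any(t_grid <= 0)) stop("t_grid must be strictly positive")
  bigT <- 2 * max(t_grid)
  gamma <- alpha - log(tol) / (2 * bigT)
  s_nodes <- gamma + 1i * pi * (0:(2 * M)) / bigT
  a <- vapply(s_nodes, fn, complex(1))
  a[1] <- a[1] / 2
  d <- dehoog_cf_coeffs(a, M)
  vapply(t_grid, function(t) dehoog_eval(d, t, bigT, gamma, M), numeric(1))
}

# Quotient-difference algorithm: continued-fraction coefficients d_0..d_2M
# from the 2M+1 (half-weighted first) Fourier coefficients.
dehoog_cf_coeffs <- function(a, M) {
  n <- 2 * M + 1
  e <- matrix(0 + 0i, n, M + 1)
  q <- matrix(0 + 0i, n, M + 1)
  q[1:(n - 1), 2] <- a[2:n] / a[1:(n - 1)]
  for (r in 2:(M + 1)) {
    len <- 2 * (M - r + 1) + 1
    e[1:len, r] <- q[2:(len + 1), r] - q[1:len, r] + e[2:(len + 1), r - 1]
    if (r < M + 1) {
      rq <- r + 1
      lq <- 2 * (M - rq + 1) + 2
      q[1:lq, rq] <- q[2:(lq + 1), rq - 1] * e[2:(lq + 1), rq - 1] /
        e[1:lq, rq - 1]
    }
  }
  d <- complex(n)
  d[1] <- a[1]
  d[seq(2, 2 * M, 2)] <- -q[1, 2:(M + 1)]
  d[seq(3, n, 2)] <- -e[1, 2:(M + 1)]
  d
}

dehoog_eval <- function(d, t, bigT, gamma, M) {
  z <- exp(1i * pi * t / bigT)
  n <- 2 * M + 1
  A <- complex(n + 1); B <- complex(n + 1)
  A[1] <- 0; B[1] <- 1
  A[2] <- d[1]; B[2] <- 1
  for (k in 3:(n + 1)) {
    A[k] <- A[k - 1] + d[k - 1] * z * A[k - 2]
    B[k] <- B[k - 1] + d[k - 1] * z * B[k - 2]
  }
  h2M <- (1 + z * (d[n - 1] - d[n])) / 2
  R2M <- -h2M * (1 - sqrt(1 + z * d[n] / h2M^2))
  A[n + 1] <- A[n] + R2M * A[n - 1]
  B[n + 1] <- B[n] + R2M * B[n - 1]
  val <- exp(gamma * t) / bigT * Re(A[n + 1] / B[n + 1])
  if (!is.finite(val)) NA_real_ else val
}

# Default simulation horizon: numerical Laplace inversion of resonant
# transforms is reliable only over a short transient window.
default_t_grid <- function() seq(0.001, 0.3, by = 0.001)

#' Impulse-response simulation of the model
#'
#' Inverts the model transfer functions on a time grid. Levels:
#' `"meso"` inverts the local circuit responses `H_e(s)`, `H_i(s)` to a unit
#' impulse of the noise input; `"macro_only"` replaces the macroscopic
#' input (`x_e + x_i`) itself by an impulse, isolating the network kernel;
#' `"macro_meso"` drives the full cascade (local circuit with impulse noise
#' input feeding the network). Macroscopic levels return one trajectory per
#' region.
#'
#' @param level `"meso"`, `"macro_only"`, or `"macro_meso"`.
#' @param local A [local_params()] object.
#' @param net A [network_params()] object (macroscopic levels only).
#' @param conn A [connectome()] object (macroscopic levels only).
#' @param t_grid Positive times, seconds; default 1 ms steps to 0.3 s.
#' @param M de Hoog series order; escalated automatically once on failure.
#' @param alpha_shift Contour shift passed to [inverse_laplace()]; raise it
#'   for strongly unstable parameter sets.
#' @return Object of class `time_series`: list with `t`, `y` (matrix, one
#'   column per trajectory), `input_kind = "impulse"`, `level`,
#'   `reliable_until`.
#' @export
simulate_impulse <- function(level = c("meso", "macro_only", "macro_meso"),
                             local, net = NULL, conn = NULL,
                             t_grid = default_t_grid(), M = 80,
                             alpha_shift = NULL) {
  level <- match.arg(level)
  if (level != "meso" && (is.null(net) || is.null(conn)))
    stop("macroscopic simulation needs net and conn")
  if (is.null(alpha_shift)) {
    alpha_shift <- if (level == "meso")
      max(0, mesoscopic_poles(local)$max_real) else 0
  }
  if (level == "meso") {
    ye <- inverse_laplace(function(s) local_transfer(local, s)$H_e, t_grid,
                          M = M, alpha = alpha_shift)
    yi <- inverse_laplace(function(s) local_transfer(local, s)$H_i, t_grid,
                          M = M, alpha = alpha_shift)
    y <- cbind(x_e = ye, x_i = yi)
  } else {
    input_kind <- if (level == "macro_only") "impulse" else "sgm_local"
    bigT <- 2 * max(t_grid)
    gamma <- alpha_shift - log(1e-9) / (2 * bigT)
    s_nodes <- gamma + 1i * pi * (0:(2 * M)) / bigT
    vals <- vapply(s_nodes, function(s)
      network_response_at(local, net, conn, s, input_kind, "direct"),
      complex(conn$N))
    vals <- matrix(vals, nrow = conn$N)
    y <- vapply(seq_len(conn$N), function(k) {
      a <- vals[k, ]; a[1] <- a[1] / 2
      d <- dehoog_cf_coeffs(a, M)
      vapply(t_grid, function(t) dehoog_eval(d, t, bigT, gamma, M),
             numeric(1))
    }, numeric(length(t_grid)))
    colnames(y) <- conn$labels
  }
  reliable <- if (any(is.na(y))) t_grid[max(1, min(which(rowSums(is.na(y)) >
                                                           0)) - 1)]
              else max(t_grid)
  structure(list(t = t_grid, y = y, input_kind = "impulse", level = level,
                 reliable_until = reliable), class = "time_series")
}

#' Noise-driven simulation by spectral synthesis
#'
#' For a linear time-invariant system driven by Gaussian white noise, the
#' stationary output is synthesized directly in the frequency domain: the
#' transfer function is sampled on the FFT grid, multiplied by complex
#' Gaussian noise with flat expected power, Hermitian-symmetrized, and
#' inverse-transformed. This is statistically equivalent to filtering a
#' white-noise path through the system and avoids long-horizon numerical
#' Laplace inversion.
#'
#' @inheritParams simulate_impulse
#' @param duration Record length, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; fully determines the noise draw.
#' @param force Simulate even when the parameters are unstable (the
#'   stationary synthesis is then not meaningful; default refuses).
#' @return A `time_series` object with `input_kind = "noise"`.
#' @export
simulate_noise <- function(level = c("meso", "macro_meso"), local,
                           net = NULL, conn = NULL, duration = 2, fs = 600,
                           seed = 1, force = FALSE) {
  level <- match.arg(level)
  if (!force && mesoscopic_poles(local)$classification == "unstable")
    stop("local circuit parameters are unstable; pass force = TRUE to ",
         "synthesize anyway")
  n <- round(duration * fs)
  fgrid <- seq_len(floor(n / 2)) * fs / n  # positive FFT frequencies
  H <- if (level == "meso") {
    matrix(vapply(fgrid, function(f)
      local_transfer(local, 2i * pi * f)$H_local, complex(1)), nrow = 1)
  } else {
    if (is.null(net) || is.null(conn))
      stop("macroscopic simulation needs net and conn")
    vapply(fgrid, function(f)
      network_response_at(local, net, conn, 2i * pi * f, "sgm_local",
                          "direct"), complex(conn$N))
  }
  H <- matrix(H, ncol = length(fgrid))
  set.seed(seed)
  y <- t(apply(H, 1, function(h) {
    noise <- complex(real = stats::rnorm(length(fgrid)),
                     imaginary = stats::rnorm(length(fgrid))) / sqrt(2)
    pos <- h * noise
    spec <- complex(n)
    spec[2:(length(fgrid) + 1)] <- pos
    spec[n:(n - length(fgrid) + 1)] <- Conj(pos)
    if (n %% 2 == 0) spec[length(fgrid) + 1] <- Re(pos[length(fgrid)])
    Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  }))
  tgrid <- seq_len(n) / fs
  structure(list(t = tgrid, y = t(y), input_kind = "noise", level = level,
                 fs = fs, seed = seed, reliable_until = max(tgrid)),
            class = "time_series")
}

#' Classify the shape of an impulse trajectory
#'
#' Separates the oscillation envelope from the running mean and classifies
#' each trend. The running mean is a moving average over one oscillation
#' period (estimated from zero-crossing spacing of the detrended signal);
#' the envelope is a log-linear regression through the absolute extrema of
#' the detrended signal. A relative change of more than `threshold`
#' (default 2 percent) per period classifies growth or decay; within the
#' band, the envelope counts as a limit cycle and the mean as bounded.
#'
#' @param ts A `time_series` from [simulate_impulse()] (first trajectory is
#'   used unless `column` is given) or a numeric vector with attribute-free
#'   sampling given via `t`.
#' @param column Which trajectory column to classify.
#' @param threshold Relative per-period change separating trends.
#' @return One of `"damped"`, `"limit_cycle"`, `"growing_amplitude"`,
#'   `"growing_mean"`, `"growing_both"`, or `"indeterminate"` (fewer than 5
#'   usable extrema).
#' @export
classify_trajectory <- function(ts, column = 1, threshold = 0.02) {
  if (inherits(ts, "time_series")) {
    t <- ts$t; y <- ts$y[, column]
    keep <- t <= ts$reliable_until & is.finite(y)
    t <- t[keep]; y <- y[keep]
  } else stop("ts must be a time_series object")
  n <- length(y)
  if (n < 10) return("indeterminate")
  dt <- mean(diff(t))
  # dominant oscillation period from the periodogram of the linearly
  # detrended record
  ylin <- stats::residuals(stats::lm(y ~ t))
  amps <- Mod(stats::fft(ylin))[2:floor(n / 2)]
  f0 <- which.max(amps) / (n * dt)
  if (f0 <= 0) return("indeterminate")
  period <- 1 / f0
  ex_raw <- which(diff(sign(diff(y))) != 0) + 1L
  ex_lin <- which(diff(sign(diff(ylin))) != 0) + 1L
  ex_lin <- ex_lin[abs(ylin[ex_lin]) > 1e-10 * max(abs(ylin))]
  ex <- if (length(ex_raw) >= length(ex_lin)) ex_raw else ex_lin
  # refine the coarse periodogram estimate (resolution 1/T) with the
  # half-period spacing of consecutive extrema; when strong growth or decay
  # dominates the periodogram the spacing estimate replaces it outright
  span <- max(t) - t[1]
  sp <- diff(t[ex])
  sp_near <- sp[sp > 0.25 * period & sp < period]
  if (length(sp_near) >= 3) {
    period <- 2 * stats::median(sp_near)
  } else if (period > span / 3 && length(sp) >= 3) {
    period <- 2 * stats::median(sp)
  }
  period_ok <- period <= span / 2.5
  have_osc <- length(ex) >= 5 && period_ok
  # midline and amplitude of the oscillation in one-period windows sliding
  # by half a period
  if (!period_ok) period <- span / 6  # windowing scale for trend-only records
  half <- period / 2
  centers <- seq(t[1] + half, max(t) - half, by = half)
  if (length(centers) < 3) return("indeterminate")
  stats_w <- vapply(centers, function(ct) {
    sel <- t >= ct - half & t <= ct + half
    yw <- y[sel]; tw <- t[sel]
    # midline from the window-local linear fit; oscillation amplitude as
    # the half-range of the window
    tc <- tw - ct
    fit <- stats::lm(yw ~ tc)
    c(unname(stats::coef(fit)[1]), (max(yw) - min(yw)) / 2)
  }, numeric(2))
  m_b <- stats_w[1, ]; a_b <- stats_w[2, ]
  # the first window still carries faster secondary transients; drop it
  # when enough windows remain
  use <- if (length(centers) >= 4) -1L else seq_along(centers)
  ct_u <- centers[use]; m_u <- m_b[use]; a_u <- a_b[use]
  if (any(a_u <= 0)) return("indeterminate")
  mean_fit <- stats::lm(m_u ~ ct_u)
  mean_rate <- stats::coef(mean_fit)[2] * period / max(a_u)
  # demand a consistent upward midline, not phase-mismatch ripple
  mean_growing <- mean_rate > threshold &&
    suppressWarnings(stats::cor(ct_u, m_u, method = "spearman")) > 0.7
  # with too few oscillation extrema the envelope cannot be judged, but an
  # unambiguous midline climb still identifies mean growth
  if (!have_osc) {
    return(if (isTRUE(mean_growing)) "growing_mean" else "indeterminate")
  }
  # the asymptotic amplitude trend lives in the tail: with several modes of
  # comparable decay the early envelope can be non-monotone (decay of a
  # transient followed by growth of the dominant mode), so regress over the
  # final stretch of the record when enough windows remain there
  tail_start <- t[1] + max(period, 0.4 * (max(t) - t[1]))
  tail_sel <- ct_u >= tail_start
  if (sum(tail_sel) >= 3) {
    ct_a <- ct_u[tail_sel]; a_a <- a_u[tail_sel]
  } else {
    ct_a <- ct_u; a_a <- a_u
  }
  amp_fit <- stats::lm(log(a_a) ~ ct_a)
  amp_rate <- exp(stats::coef(amp_fit)[2] * period) - 1
  amp <- if (amp_rate > threshold) "growing"
         else if (amp_rate < -threshold) "damped" else "limit_cycle"
  if (mean_growing && amp == "growing") return("growing_both")
  if (mean_growing) return("growing_mean")
  if (amp == "growing") return("growing_amplitude")
  if (amp == "damped") return("damped")
  "limit_cycle"
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series (%s, %s): %d trajectories, %d samples, reliable to %.3g s\n",
              x$level, x$input_kind, ncol(x$y), length(x$t),
              x$reliable_until))
  invisible(x)
}

#' Write trajectories as TSV
#'
#' Time column plus one column per trajectory/region.
#'
#' @param ts A `time_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_time_series <- function(ts, path) {
  df <- data.frame(time = ts$t, ts$y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
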