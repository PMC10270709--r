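#' Estimation bounds and initial guesses for static spectrum fitting
#'
#' Box bounds and the three standard initial guesses for the seven free
#' parameters (the excitatory self-gain stays pinned at 1). An initial guess
#' outside its own bound (the inhibitory time constant's first guess) is
#' clipped to the nearest bound with a warning when used.
#'
#' @return List with `lower`, `upper` (named numeric vectors over
#'   `tau_e, tau_i, alpha, v, g_ei, g_ii, tau_G`) and `init` (3-row matrix
#'   of initial guesses).
#' @export
static_fit_bounds <- function() {
  nm <- c("tau_e", "tau_i", "alpha", "v", "g_ei", "g_ii", "tau_G")
  lower <- c(0.005, 0.005, 0.1, 5, 0.001, 1, 0.005)
  upper <- c(0.02, 0.02, 1, 20, 0.8, 2.5, 0.02)
  init <- rbind(c(0.012, 0.003, 1, 5, 0.2, 1, 0.006),
                c(0.018, 0.01, 0.5, 10, 0.1, 1.5, 0.01),
                c(0.006, 0.018, 0.1, 18, 0.3, 0.5, 0.018))
  names(lower) <- names(upper) <- colnames(init) <- nm
  list(lower = lower, upper = upper, init = init)
}

#' Estimation bounds for dynamic (windowed) fitting
#'
#' Only the coupling constant and the two free neural gains vary across
#' windows; time constants and conduction speed are frozen at their static
#' estimates.
#'
#' @return Same structure as [static_fit_bounds()] over
#'   `alpha, g_ei, g_ii`.
#' @export
dynamic_fit_bounds <- function() {
  nm <- c("alpha", "g_ei", "g_ii")
  lower <- c(0.1, 0.001, 1)
  upper <- c(1, 0.8, 2.5)
  init <- rbind(c(1, 0.2, 1), c(0.5, 0.1, 1.5), c(0.1, 0.3, 1))
  names(lower) <- names(upper) <- colnames(init) <- nm
  list(lower = lower, upper = upper, init = init)
}

#' Mean Pearson correlation between modeled and observed spectra
#'
#' Pearson's r is computed per region across frequencies and averaged
#' (unweighted) over the masked cortical regions. A region whose observed or
#' modeled spectrum has zero variance across frequencies is excluded with a
#' warning. Invariant to any common affine rescaling of either PSD.
#'
#' @param model Modeled PSD, regions x frequencies, dB.
#' @param obs Observed PSD, same shape.
#' @param cortical_mask Logical vector over regions (default: all).
#' @return Mean r over included regions, with per-region values in
#'   attribute `"r_per_region"` (NA for excluded regions).
#' @export
pearson_objective <- function(model, obs, cortical_mask = NULL) {
  model <- as.matrix(model); obs <- as.matrix(obs)
  if (!all(dim(model) == dim(obs)))
    stop("model and observed PSD shapes differ")
  if (ncol(model) < 2) stop("need at least 2 frequency points")
  if (is.null(cortical_mask)) cortical_mask <- rep(TRUE, nrow(model))
  r <- rep(NA_real_, nrow(model))
  for (k in which(cortical_mask)) {
    if (stats::sd(model[k, ]) == 0 || stats::sd(obs[k, ]) == 0) {
      warning(sprintf("region %d has zero spectral variance; excluded", k))
      next
    }
    r[k] <- stats::cor(model[k, ], obs[k, ])
  }
  out <- mean(r[cortical_mask], na.rm = TRUE)
  attr(out, "r_per_region") <- r
  out
}

# Seeded annealing global optimizer over a box, in the dual-annealing
# mold: Cauchy-distributed visiting moves whose scale shrinks with a slow
# logarithmic schedule, Metropolis acceptance with a fast 1/iter
# temperature, and bounded quasi-Newton local-search phases (from the
# initial guess and from the best visited point; the box widths serve as
# parameter scales, since the coordinates span three orders of magnitude).
# Minimizes fn.
dual_anneal <- function(fn, lower, upper, x0 = NULL, maxiter = 500,
                        polish = TRUE, t0 = 0.3) {
  d <- length(lower)
  range <- upper - lower
  x <- if (is.null(x0)) lower + stats::runif(d) * range
       else pmin(pmax(x0, lower), upper)
  f <- fn(x)
  best <- x; fbest <- f; evals <- 1L
  local_search <- function(from) {
    tryCatch(
      stats::optim(from, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 300, parscale = range,
                                  factr = 1e7)),
      error = function(e) NULL)
  }
  if (polish) {
    op <- local_search(x)
    if (!is.null(op)) {
      evals <- evals + op$counts[1]
      if (op$value < fbest) { best <- op$par; fbest <- op$value }
    }
  }
  for (it in seq_len(maxiter)) {
    tv <- 1 / log(it + exp(1))
    ta <- t0 / it
    prop <- x + 0.1 * range * tv * tan(pi * (stats::runif(d) - 0.5))
    prop <- pmin(pmax(prop, lower), upper)
    fp <- fn(prop); evals <- evals + 1L
    if (fp < f || stats::runif(1) < exp(-(fp - f) / ta)) {
      x <- prop; f <- fp
    }
    if (fp < fbest) { best <- prop; fbest <- fp }
  }
  if (polish) {
    op <- local_search(best)
    if (!is.null(op)) {
      evals <- evals + op$counts[1]
      if (op$value < fbest) { best <- op$par; fbest <- op$value }
    }
  }
  list(par = best, value = fbest, evals = evals)
}

fit_param_sets <- function(x) {
  list(local = local_params(tau_e = x[["tau_e"]], tau_i = x[["tau_i"]],
                            g_ei = x[["g_ei"]], g_ii = x[["g_ii"]]),
       net = network_params(tau_G = x[["tau_G"]], alpha = x[["alpha"]],
                            v = x[["v"]]))
}

#' Fit static model parameters to an observed PSD
#'
#' Maximizes the mean cortical Pearson correlation between the modeled and
#' observed spectra over the seven free parameters, using the seeded
#' annealing optimizer once per initial guess (three standard guesses);
#' the best-scoring run wins. The excitatory self-gain is pinned at 1.
#'
#' @param obs_psd Observed PSD, regions x frequencies, dB.
#' @param conn A [connectome()] matching the PSD rows.
#' @param freqs Frequency grid of the PSD columns, Hz.
#' @param bounds Bounds/guesses from [static_fit_bounds()].
#' @param seed Integer seed for the optimizer.
#' @param maxiter Annealing iterations per guess (default 500).
#' @return List of class `fit_result`: `local`, `net` (fitted parameter
#'   objects), `r_mean`, `r_per_region`, `par` (named vector),
#'   `optimizer_meta` (per-guess scores, chosen guess, seed, evaluations).
#' @export
fit_static <- function(obs_psd, conn, freqs, bounds = static_fit_bounds(),
                       seed = 1, maxiter = 500) {
  obs_psd <- as.matrix(obs_psd)
  if (nrow(obs_psd) != conn$N)
    stop("observed PSD rows do not match connectome regions")
  objective <- function(x) {
    names(x) <- names(bounds$lower)
    ps <- fit_param_sets(x)
    sp <- network_transfer(ps$local, ps$net, conn, freqs,
                           input_kind = "sgm_local", method = "direct")
    -suppressWarnings(
      as.numeric(pearson_objective(model_psd(sp), obs_psd,
                                   conn$cortical_mask)))
  }
  runs <- vector("list", nrow(bounds$init))
  for (g in seq_len(nrow(bounds$init))) {
    x0 <- bounds$init[g, ]
    clip <- x0 < bounds$lower | x0 > bounds$upper
    if (any(clip)) {
      warning(sprintf("initial guess %d outside bounds for %s; clipped",
                      g, paste(names(bounds$lower)[clip], collapse = ", ")))
      x0 <- pmin(pmax(x0, bounds$lower), bounds$upper)
    }
    set.seed(seed + g)
    runs[[g]] <- dual_anneal(objective, bounds$lower, bounds$upper,
                             x0 = x0, maxiter = maxiter)
  }
  scores <- vapply(runs, function(r) -r$value, numeric(1))
  winner <- which.max(scores)
  par <- runs[[winner]]$par
  names(par) <- names(bounds$lower)
  ps <- fit_param_sets(par)
  sp <- network_transfer(ps$local, ps$net, conn, freqs,
                         input_kind = "sgm_local", method = "direct")
  r <- suppressWarnings(pearson_objective(model_psd(sp), obs_psd,
                                          conn$cortical_mask))
  structure(list(local = ps$local, net = ps$net, par = par,
                 r_mean = as.numeric(r),
                 r_per_region = attr(r, "r_per_region"),
                 optimizer_meta = list(scores = scores,
                                       chosen_guess = winner, seed = seed,
                                       maxiter = maxiter,
                                       evals = runs[[winner]]$evals)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Static fit: mean cortical r = %.4f (guess %d of %d)\n",
              x$r_mean, x$optimizer_meta$chosen_guess,
              length(x$optimizer_meta$scores)))
  print(round(x$par, 5))
  invisible(x)
}

#' Fit time-varying parameters to windowed spectra
#'
#' Per window, re-estimates only the coupling constant and the two free
#' gains, with the time constants and conduction speed frozen at the static
#' fit. Windows are fitted independently with the standard guesses; a
#' failed window is recorded and does not abort the sequence.
#'
#' @param windows List of PSD matrices (regions x frequencies, dB), one per
#'   window, as produced by [synth_dynamic_windows()] or [morlet_tfr()].
#' @param static_fit A `fit_result` supplying the frozen parameters.
#' @param conn A [connectome()].
#' @param freqs Frequency grid, Hz.
#' @param bounds Bounds from [dynamic_fit_bounds()].
#' @param seed Integer seed.
#' @param maxiter Annealing iterations per guess per window.
#' @return List of class `dynamic_fit_result`: `params` (data frame of
#'   per-window `alpha`, `g_ei`, `g_ii`, `r`), `alpha_switch_count`,
#'   `frozen`, `window_times`.
#' @export
fit_dynamic <- function(windows, static_fit, conn, freqs,
                        bounds = dynamic_fit_bounds(), seed = 1,
                        maxiter = 200) {
  frozen <- list(tau_e = static_fit$local$tau_e,
                 tau_i = static_fit$local$tau_i,
                 tau_G = static_fit$net$tau_G, v = static_fit$net$v)
  fit_one <- function(obs_psd, sub_seed) {
    objective <- function(x) {
      loc <- local_params(tau_e = frozen$tau_e, tau_i = frozen$tau_i,
                          g_ei = x[2], g_ii = x[3])
      net <- network_params(tau_G = frozen$tau_G, alpha = x[1],
                            v = frozen$v)
      sp <- network_transfer(loc, net, conn, freqs,
                             input_kind = "sgm_local", method = "direct")
      -suppressWarnings(
        as.numeric(pearson_objective(model_psd(sp), obs_psd,
                                     conn$cortical_mask)))
    }
    best <- NULL
    for (g in seq_len(nrow(bounds$init))) {
      set.seed(sub_seed + g)
      run <- dual_anneal(objective, bounds$lower, bounds$upper,
                         x0 = bounds$init[g, ], maxiter = maxiter)
      if (is.null(best) || run$value < best$value) best <- run
    }
    best
  }
  rows <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    run <- tryCatch(fit_one(as.matrix(windows[[w]]), seed + 1000L * w),
                    error = function(e) e)
    if (inherits(run, "error")) {
      warning(sprintf("window %d fit failed: %s", w,
                      conditionMessage(run)))
      rows[[w]] <- data.frame(alpha = NA_real_, g_ei = NA_real_,
                              g_ii = NA_real_, r = NA_real_)
    } else {
      rows[[w]] <- data.frame(alpha = run$par[1], g_ei = run$par[2],
                              g_ii = run$par[3], r = -run$value)
    }
  }
  params <- do.call(rbind, rows)
  structure(list(params = params,
                 alpha_switch_count = count_switches(params$alpha),
                 frozen = frozen,
                 window_times = 5 * (seq_along(windows) - 0.5)),
            class = "dynamic_fit_result")
}

#' Count abrupt switches in a per-window parameter series
#'
#' @param series Numeric per-window values.
#' @param threshold Consecutive-difference magnitude that counts as a
#'   switch (strictly greater; default 0.5).
#' @return Integer switch count.
#' @export
count_switches <- function(series, threshold = 0.5) {
  if (length(series) < 2) stop("need at least two windows")
  sum(abs(diff(series)) > threshold, na.rm = TRUE)
}

#' Four-code stability timeline from a dynamic fit
#'
#' Per window, the local circuit's stability is evaluated at that window's
#' gains (with frozen time constants) and the coupling constant is compared
#' to the instability bound: code 1 = locally stable and `alpha` below the
#' bound; 2 = stable, `alpha` at the bound; 3 = unstable, below; 4 =
#' unstable, at the bound. "At the bound" means within `1e-6` of the active
#' upper bound when the bound caps estimation at 1, or `alpha >= 1` under a
#' relaxed bound.
#'
#' @param dyn A `dynamic_fit_result`.
#' @param alpha_upper The active upper bound used in estimation (default 1).
#' @return Integer vector of codes, one per window (NA for failed windows).
#' @export
stability_timeline <- function(dyn, alpha_upper = 1) {
  vapply(seq_len(nrow(dyn$params)), function(w) {
    p <- dyn$params[w, ]
    if (any(is.na(p[c("alpha", "g_ei", "g_ii")]))) return(NA_integer_)
    loc <- local_params(tau_e = dyn$frozen$tau_e, tau_i = dyn$frozen$tau_i,
                        g_ei = p$g_ei, g_ii = p$g_ii)
    meso_stable <- mesoscopic_poles(loc)$classification != "unstable"
    at_bound <- if (alpha_upper > 1) p$alpha >= 1
                else p$alpha >= alpha_upper - 1e-6
    if (meso_stable && !at_bound) 1L
    else if (meso_stable) 2L
    else if (!at_bound) 3L
    else 4L
  }, integer(1))
}

#' Compare dynamic and static goodness of fit
#'
#' Applies Fisher's z transform (`atanh`) to the paired per-window
#' correlations and runs a one-sided paired t-test of the hypothesis that
#' dynamic parameters fit better than static ones. Correlations at exactly
#' 1 in magnitude are clipped to `1 - 1e-12` with a warning.
#'
#' @param r_static Per-window correlations under the static parameters.
#' @param r_dynamic Per-window correlations under the per-window parameters.
#' @return List: `t` (paired t statistic), `p` (one-sided p-value),
#'   `df`, `mean_z_gain` (mean Fisher-z improvement).
#' @export
compare_static_dynamic <- function(r_static, r_dynamic) {
  if (length(r_static) != length(r_dynamic))
    stop("paired samples must have equal length")
  clip <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlation magnitude 1 clipped before Fisher z")
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    }
    r
  }
  zs <- atanh(clip(r_static))
  zd <- atanh(clip(r_dynamic))
  if (all(zd == zs)) return(list(t = 0, p = 0.5,
                                 df = length(zs) - 1, mean_z_gain = 0))
  tt <- stats::t.test(zd, zs, paired = TRUE, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_z_gain = mean(zd - zs))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Continuous wavelet transform with complex Morlet wavelets, one scale per
#' analysis frequency with width `w * fs / (2 pi f)` samples, power averaged
#' in non-overlapping windows and converted to dB. With the conventional
#' electrophysiological default `fs = 600` Hz the widths follow the same
#' per-frequency rule as the standard Python implementation.
#'
#' @param x Numeric time series (one region).
#' @param fs Sampling rate, Hz (default 600).
#' @param w Wavelet shape parameter (default 600).
#' @param freqs Analysis frequencies, Hz.
#' @param window_s Averaging window length, seconds (default 5).
#' @return List of class `tfr`: `power_db` (windows x frequencies),
#'   `window_times` (centers, s), `freqs`, `fs`, `w`.
#' @export
morlet_tfr <- function(x, fs = 600, w = 600, freqs = default_freqs(1),
                       window_s = 5) {
  n <- length(x)
  if (window_s * fs > n)
    stop("window longer than the record")
  n_win <- floor(n / (window_s * fs))
  win_id <- rep(seq_len(n_win), each = window_s * fs)
  pow <- matrix(NA_real_, n_win, length(freqs))
  xf <- stats::fft(c(x, numeric(n)))  # zero-padded once for all scales
  for (j in seq_along(freqs)) {
    s <- w * fs / (2 * pi * freqs[j])
    L <- min(2 * floor(5 * s) + 1, 2 * n - 1)
    k <- seq(-(L - 1) / 2, (L - 1) / 2)
    wav <- pi^-0.25 / sqrt(s) * exp(1i * w * k / s - (k / s)^2 / 2)
    kf <- stats::fft(c(wav, complex(2 * n - L)))
    conv <- stats::fft(xf * kf, inverse = TRUE) / (2 * n)
    cwt <- conv[(L - 1) / 2 + seq_len(n)]
    p <- Mod(cwt)^2
    pow[, j] <- tapply(p[seq_along(win_id)], win_id, mean)
  }
  structure(list(power_db = 10 * log10(pow),
                 window_times = window_s * (seq_len(n_win) - 0.5),
                 freqs = freqs, fs = fs, w = w), class = "tfr")
}
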