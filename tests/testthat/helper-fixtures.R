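# Shared fixtures, built once per test run and memoised: connectome
# generation and boundary searches are deterministic but not free.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

ref_local <- function() local_params(tau_e = 0.012, tau_i = 0.003,
                                     g_ei = 0.4, g_ii = 0.5)

conn_small <- function() fixture("conn_small", function()
  synth_connectome(synth_spec(N = 12, density = 0.5, seed = 3)))

conn_mid <- function() fixture("conn_mid", function()
  synth_connectome(synth_spec(N = 16, density = 0.4, seed = 7)))

conn_full <- function() fixture("conn_full", function()
  synth_connectome(synth_spec(seed = 7)))

# Static-recovery experiment shared by the fitting acceptance checks:
# noise-free spectra from the mid-size connectome at the default truth.
static_recovery <- function() fixture("static_recovery", function() {
  spec <- synth_spec(N = 16, density = 0.4, seed = 7)
  conn <- conn_mid()
  out <- synth_static_psd(spec, conn)
  fit <- suppressWarnings(
    fit_static(out$psd, conn, out$freqs, seed = 42, maxiter = 80))
  list(spec = spec, conn = conn, out = out, fit = fit,
       truth = c(tau_e = 0.012, tau_i = 0.01, alpha = 0.5, v = 10,
                 g_ei = 0.3, g_ii = 1.5, tau_G = 0.01))
})

# Dynamic-recovery experiment with a planted alpha jump, shared by the
# switch-count and static-vs-dynamic comparison checks.
dynamic_recovery <- function() fixture("dynamic_recovery", function() {
  wt <- data.frame(alpha = c(rep(0.3, 5), rep(0.9, 7)),
                   g_ei = rep(0.3, 12), g_ii = rep(1.5, 12))
  spec <- synth_spec(N = 16, density = 0.4, seed = 7, window_truths = wt)
  conn <- conn_mid()
  dynw <- synth_dynamic_windows(spec, conn)
  static_fit <- static_recovery()$fit
  dyn <- suppressWarnings(
    fit_dynamic(dynw$windows, static_fit, conn, dynw$freqs, seed = 5,
                maxiter = 40))
  list(spec = spec, conn = conn, dynw = dynw, dyn = dyn,
       static_fit = static_fit)
})

# Envelope decay rate of an impulse trajectory: log-linear regression over
# extrema after the first oscillation period (independent of
# classify_trajectory internals).
envelope_slope <- function(ts, column = 1) {
  t <- ts$t; y <- ts$y[, column]
  ex <- which(diff(sign(diff(y))) != 0) + 1L
  amps <- Mod(stats::fft(y - mean(y)))[2:floor(length(y) / 2)]
  period <- (length(y) * mean(diff(t))) / which.max(amps)
  ex <- ex[t[ex] > t[1] + period]
  unname(stats::coef(stats::lm(log(abs(y[ex])) ~ t[ex]))[2])
}

random_local_in_bounds <- function() {
  local_params(tau_e = stats::runif(1, 0.005, 0.02),
               tau_i = stats::runif(1, 0.005, 0.02),
               g_ei = stats::runif(1, 0.001, 0.8),
               g_ii = stats::runif(1, 1, 2.5))
}
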