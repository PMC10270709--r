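#' Write a PSD matrix as TSV
#'
#' Region-by-frequency table: first column `region`, remaining columns the
#' frequency grid in Hz (header row).
#'
#' @param psd Numeric matrix, regions x frequencies, dB.
#' @param freqs Frequency grid, Hz.
#' @param path Output path.
#' @param labels Region labels (default from rownames or `R1...RN`).
#' @return Invisibly, `path`.
#' @export
write_psd <- function(psd, freqs, path, labels = NULL) {
  psd <- as.matrix(psd)
  if (ncol(psd) != length(freqs))
    stop("PSD columns do not match frequency grid")
  if (is.null(labels))
    labels <- if (!is.null(rownames(psd))) rownames(psd)
              else paste0("R", seq_len(nrow(psd)))
  df <- data.frame(region = labels, psd, check.names = FALSE)
  colnames(df) <- c("region", format(freqs, trim = TRUE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PSD matrix from TSV
#'
#' @param path TSV written by [write_psd()].
#' @return List: `psd` (matrix with region rownames), `freqs` (parsed from
#'   the header).
#' @export
read_psd <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  freqs <- as.numeric(colnames(m))
  if (any(is.na(freqs)))
    stop("PSD header is not a numeric frequency grid")
  list(psd = unname(m) + 0, freqs = freqs, labels = as.character(labels))
}

#' Run configuration round-trip through JSON
#'
#' A flat named list of paths, parameter values, grids, seeds, and
#' tolerances. Unknown keys are rejected so typos fail loudly.
#'
#' @param overrides Named list overriding defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    connectome_csv = NULL, distance_csv = NULL, mask_csv = NULL,
    psd_tsv = NULL, out_dir = ".",
    tau_e = 0.012, tau_i = 0.003, g_ei = 0.4, g_ii = 0.5,
    tau_G = 0.012, alpha = 0.8, v = 5,
    freq_min = 2, freq_max = 45, freq_step = 0.1,
    seed = 1, maxiter = 500, marginal_tol = 1e-6)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
read_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

config_freqs <- function(config) {
  seq(config$freq_min, config$freq_max, by = config$freq_step)
}

#' Multitaper PSD estimate of a raw time series
#'
#' Sine-taper multitaper spectral estimate (Riedel-Sidorenko family) with
#' the number of tapers matching a Thomson time-bandwidth product of 4
#' (k = 7 tapers by default). Offered as a convenience for turning raw
#' recordings into the dB spectra the fitting routines consume; the
#' synthetic generators bypass it.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate, Hz.
#' @param k Number of sine tapers.
#' @param freqs Frequencies (Hz) at which to interpolate the estimate.
#' @return List: `psd_db` at `freqs`, `raw` (full-grid estimate), `fgrid`.
#' @export
psd_multitaper <- function(x, fs, k = 7, freqs = default_freqs(1)) {
  n <- length(x)
  x <- x - mean(x)
  tgrid <- seq_len(n)
  est <- 0
  for (j in seq_len(k)) {
    taper <- sqrt(2 / (n + 1)) * sin(pi * j * tgrid / (n + 1))
    est <- est + Mod(stats::fft(x * taper))^2
  }
  est <- est / k / fs
  fgrid <- (seq_len(n) - 1) * fs / n
  keep <- fgrid <= fs / 2
  psd <- stats::approx(fgrid[keep], est[keep], xout = freqs)$y
  list(psd_db = 10 * log10(psd), raw = est[keep], fgrid = fgrid[keep])
}
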