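#' Specification for synthetic model data
#'
#' Describes a synthetic study: connectome geometry, ground-truth model
#' parameters, PSD noise level, and optional per-window parameter
#' trajectories for dynamic experiments. The generators are fully
#' deterministic under `seed`; the PSD noise uses a separate stream
#' (`seed + 1e5`) so two specs differing only in noise share the same
#' underlying connectome and noiseless spectra.
#'
#' @param N Number of regions (default 86, the whole-brain atlas size
#'   used throughout; 68 cortical).
#' @param density Fraction of region pairs connected (default 0.3).
#' @param distance_scale Maximum inter-regional distance, mm (default 150,
#'   spanning realistic cortical fiber lengths).
#' @param seed Integer seed.
#' @param local,net Ground-truth [local_params()] and [network_params()].
#'   Defaults are mid-range values inside the estimation bounds.
#' @param noise_db Standard deviation of iid Gaussian noise added to the
#'   PSD, dB (default 0 = noiseless).
#' @param window_truths Optional data frame with columns `alpha`, `g_ei`,
#'   `g_ii`, one row per 5-s window, for dynamic generation.
#' @param graph One of `"geometric"` (distance-thresholded random geometric
#'   graph with Gaussian-magnitude weights, giving distance-correlated
#'   connectivity like tractography) or `"erdos_renyi"`.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(N = 86, density = 0.3, distance_scale = 150,
                       seed = 1,
                       local = local_params(tau_e = 0.012, tau_i = 0.01,
                                            g_ei = 0.3, g_ii = 1.5),
                       net = network_params(tau_G = 0.01, alpha = 0.5,
                                            v = 10),
                       noise_db = 0, window_truths = NULL,
                       graph = c("geometric", "erdos_renyi")) {
  graph <- match.arg(graph)
  if (N < 2) stop("need at least two regions")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  structure(list(N = N, density = density,
                 distance_scale = distance_scale, seed = as.integer(seed),
                 local = local, net = net, noise_db = noise_db,
                 window_truths = window_truths, graph = graph),
            class = "synth_spec")
}

# Connectivity and distances from random 3-D coordinates; weights are
# absolute Gaussian draws on edges retained by a distance threshold chosen
# to hit the requested density.
synth_connectome_once <- function(spec, seed) {
  set.seed(seed)
  N <- spec$N
  xyz <- matrix(stats::runif(3 * N), N, 3)
  D <- as.matrix(stats::dist(xyz))
  D <- D / max(D) * spec$distance_scale
  W <- abs(matrix(stats::rnorm(N * N), N, N))
  W <- (W + t(W)) / 2
  if (spec$graph == "geometric") {
    thr <- stats::quantile(D[upper.tri(D)], spec$density)
    W[D > thr] <- 0
  } else {
    keep <- matrix(stats::runif(N * N) < spec$density, N, N)
    keep <- keep | t(keep)
    W[!keep] <- 0
  }
  diag(W) <- 0
  n_cort <- round(0.79 * N)  # 68-of-86 cortical fraction
  mask <- c(rep(TRUE, n_cort), rep(FALSE, N - n_cort))
  connectome(W, D, labels = sprintf("region_%03d", seq_len(N)),
             cortical_mask = mask)
}

graph_connected <- function(C) {
  A <- (C + t(C)) > 0
  reached <- logical(nrow(A)); reached[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

#' Generate a synthetic connectome
#'
#' Random geometric (or Erdos-Renyi) graph with nonnegative symmetric
#' weights, distances from random 3-D coordinates scaled to realistic
#' cortical fiber lengths, rows normalized by row degree, and a cortical
#' mask covering about 79 percent of regions. Disconnected draws are
#' regenerated with an incremented sub-seed (bounded retries).
#'
#' @param spec A [synth_spec()].
#' @return A [connectome()] object.
#' @export
synth_connectome <- function(spec) {
  for (try in 0:24) {
    conn <- synth_connectome_once(spec, spec$seed + try)
    if (graph_connected(conn$C)) return(conn)
  }
  stop("could not generate a connected graph in 25 attempts; ",
       "raise density")
}

#' Generate a synthetic observed static PSD with known truth
#'
#' Runs the forward model at the ground-truth parameters over the frequency
#' grid, converts to dB, and adds iid Gaussian noise of `noise_db` dB from
#' a noise stream separated from the structural seed.
#'
#' @param spec A [synth_spec()] (truth must be stable: local circuit stable
#'   and `alpha < 1`; refused otherwise).
#' @param conn A [connectome()] from [synth_connectome()] (regenerated from
#'   `spec` if omitted).
#' @param freqs Frequency grid, Hz.
#' @return List: `psd` (regions x frequencies dB matrix), `freqs`, `truth`
#'   (list of `local`, `net`), `conn`.
#' @export
synth_static_psd <- function(spec, conn = NULL, freqs = default_freqs(1)) {
  if (is.null(conn)) conn <- synth_connectome(spec)
  if (mesoscopic_poles(spec$local)$classification == "unstable")
    stop("ground-truth local circuit is unstable; refusing to generate")
  if (spec$net$alpha >= 1)
    stop("ground-truth alpha >= 1 is macroscopically unstable; refusing")
  sp <- network_transfer(spec$local, spec$net, conn, freqs,
                         input_kind = "sgm_local", method = "direct")
  psd <- model_psd(sp)
  if (spec$noise_db > 0) {
    set.seed(spec$seed + 100000L)
    psd <- psd + matrix(stats::rnorm(length(psd), sd = spec$noise_db),
                        nrow = nrow(psd))
  }
  rownames(psd) <- conn$labels
  list(psd = psd, freqs = freqs, truth = list(local = spec$local,
                                              net = spec$net), conn = conn)
}

#' Generate synthetic windowed spectra with per-window ground truth
#'
#' Emulates the 5-second time-frequency windows of a 1-minute recording:
#' each window's PSD is generated from that window's `(alpha, g_ei, g_ii)`
#' truth with the remaining parameters frozen at the static truth. Supports
#' planted jumps in `alpha` for switch-counting experiments.
#'
#' @param spec A [synth_spec()] whose `window_truths` data frame supplies
#'   one row per window (default: 12 constant-truth windows, a 60-s record
#'   at 5 s).
#' @param conn Optional precomputed connectome.
#' @param freqs Frequency grid, Hz.
#' @return List: `windows` (list of regions x frequencies dB matrices),
#'   `window_times` (window centers, s), `truths` (data frame), `freqs`,
#'   `conn`, `frozen` (the static truth parameters).
#' @export
synth_dynamic_windows <- function(spec, conn = NULL,
                                  freqs = default_freqs(1)) {
  if (is.null(conn)) conn <- synth_connectome(spec)
  wt <- spec$window_truths
  if (is.null(wt))
    wt <- data.frame(alpha = rep(spec$net$alpha, 12),
                     g_ei = rep(spec$local$g_ei, 12),
                     g_ii = rep(spec$local$g_ii, 12))
  windows <- vector("list", nrow(wt))
  for (w in seq_len(nrow(wt))) {
    loc_w <- local_params(tau_e = spec$local$tau_e,
                          tau_i = spec$local$tau_i,
                          g_ei = wt$g_ei[w], g_ii = wt$g_ii[w])
    if (mesoscopic_poles(loc_w)$classification == "unstable")
      stop(sprintf("window %d truth is locally unstable; refusing", w))
    net_w <- network_params(tau_G = spec$net$tau_G, alpha = wt$alpha[w],
                            v = spec$net$v)
    sp <- network_transfer(loc_w, net_w, conn, freqs,
                           input_kind = "sgm_local", method = "direct")
    psd <- model_psd(sp)
    if (spec$noise_db > 0) {
      set.seed(spec$seed + 100000L + w)
      psd <- psd + matrix(stats::rnorm(length(psd), sd = spec$noise_db),
                          nrow = nrow(psd))
    }
    rownames(psd) <- conn$labels
    windows[[w]] <- psd
  }
  list(windows = windows,
       window_times = 5 * (seq_len(nrow(wt)) - 0.5),
       truths = wt, freqs = freqs, conn = conn,
       frozen = list(local = spec$local, net = spec$net))
}
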