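---
title: "The spectral graph model: spectra, stability, and windowed fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spectral graph model: spectra, stability, and windowed fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralgm)
```

## The model and its assumptions

`spectralgm` implements a linear, hierarchical model of whole-brain
electrophysiological activity. Its two levels are deliberately asymmetric:

* **Local circuit.** One excitatory and one inhibitory population per
  region, identical across regions. Every interaction — self-decay and
  cross-coupling — is filtered through a Gamma-shaped ensemble response
  kernel `f(t) = (t/τ²)e^{−t/τ}` whose Laplace transform
  `F(s) = (1/τ²)/(s+1/τ)²` has unit DC gain. Nonlinear (sigmoidal)
  neural-mass dynamics are linearized into constant gains `g_ee` (pinned at
  1 for identifiability), `g_ei`, `g_ii`. Both populations receive the same
  white-noise drive.
* **Network.** Only long-range *excitatory* signals couple regions, with no
  feedback from the network level to the local level. Coupling is the
  row-degree-normalized structural connectivity `C` with per-edge
  conduction delays `d_jk/v`; at angular frequency ω this becomes the
  delayed matrix `C*(ω) = [c_jk e^{−iω d_jk/v}]` and the complex Laplacian
  `L(ω) = I − αC*(ω)`.

Linearity buys three things the package is organized around: a closed-form
frequency response, an algebraic stability theory, and tractable parameter
estimation from spectra (no time-domain integration inside the objective).

The regional response is computed two ways, and the equivalence is a
standing invariant of the test suite: the direct solve of
`(iωI + F_e L/τ_G) X = H_local P 1` and the eigenmode expansion over
`L = U Λ U⁻¹`. The delayed `C*` is not a normal matrix, so its eigenvector
matrix is not unitary; the expansion therefore uses the matrix inverse of
`U` (an oblique projector), not the conjugate transpose, and the direct
solve is treated as normative whenever the two could disagree.

## Sign conventions in the local circuit

The flattened forms of the local equations admit more than one reading of
where the kernels and signs sit in the cross-coupling terms. The package
fixes the convention from the state matrix whose determinant carries the
constant cross term `g_ei² t_e⁵ t_i⁵` (with `t = 1/τ`):

    A(s) = [ −g_ee F_e/τ_e      +g_ei F_e F_i/τ_e ]
           [ −g_ei F_e F_i/τ_i  −g_ii F_i/τ_i     ]

This choice is not arbitrary: it is the unique reading that reproduces the
model's documented reference behavior — a damped/growing transition of the
local circuit at `g_ei ≈ 0.52` (for `g_ii = 0.5`, `τ_e = 12` ms,
`τ_i = 3` ms) and a primary-alpha/secondary-beta peak pair at
`g_ei = 0.25`, `g_ii = 1.5`, `τ_e = 10` ms, `τ_i = 5` ms. The
alternative parse (kernel-free cross terms) yields a degree-6
characteristic polynomial with no transition below `g_ei = 3`.

## Parameters

| parameter | meaning | default | estimation box |
|---|---|---|---|
| `tau_e` | excitatory kernel time constant (s) | 0.012 | [0.005, 0.02] |
| `tau_i` | inhibitory kernel time constant (s) | 0.003 | [0.005, 0.02] |
| `g_ei` | cross-population gain (–) | 0.4 | [0.001, 0.8] |
| `g_ii` | inhibitory self-gain (–) | 0.5 | [1, 2.5] |
| `g_ee` | excitatory self-gain (–) | 1 (pinned) | — |
| `tau_G` | graph time constant (s) | 0.012 | [0.005, 0.02] |
| `alpha` | global coupling (–) | 0.8 | [0.1, 1] |
| `v` | conduction speed (m/s) | 5 | [5, 20] |

Defaults are the stability-analysis reference values; note that the
reference `tau_i = 0.003` s (and the first `tau_i` initial guess) sits
below the estimation box — the estimation routines clip out-of-box guesses
to the nearest bound with a warning rather than silently widening the box.
Distances are in millimeters, so a delay is `d/(1000 v)` seconds; at
`v = 5` m/s a 150 mm fiber contributes a 30 ms delay, commensurate with
`tau_G` — which is exactly why delays shape the network spectrum.

## Stability machinery

**Local.** Clearing kernel denominators turns the pole condition into a
monic degree-10 real polynomial, built by exact coefficient convolution and
solved by companion-matrix eigenvalues (`polyroot`'s accuracy degrades with
coefficients spanning fifteen orders of magnitude). Classification uses a
marginality tolerance of `1e-6` rad/s on the largest real part: below
−tol stable, within ±tol limit cycle, above unstable. The Routh–Hurwitz
array is implemented as the independent second judgment (zero pivots by
epsilon substitution, all-zero rows by the auxiliary-polynomial
derivative), and the test suite checks both methods agree on random
parameter draws and random polynomials against a companion-matrix oracle.
In the decoupled limit `g_ei → 0` the cleared denominators leave genuine
roots at `−1/τ_e`, `−1/τ_i`; these are flagged `spurious` and excluded from
the verdict. For `g_ei > 0` the constant cross term moves them off those
points, so typically no root is flagged.

**Network.** Two independent boundaries:

* `alpha_boundary()`: for connected row-stochastic `C` the Perron
  eigenvalue is 1, so `det(I − αC)` first vanishes at `α = 1` exactly.
  Beyond it the *mean* of the response grows.
* `jw_boundary()`: the oscillation boundary in `τ_G` at fixed `α`. Each
  Laplacian mode contributes the scalar condition
  `iω + λ_k(iω) F_e(iω)/τ_G = 0` in the unknowns `(τ_G, ω)`. Rather than a
  two-dimensional root search from blind initial guesses — which needs a
  guess near the true root to converge — the package eliminates
  `τ_G = −λ_k(iω)F_e(iω)/(iω)` and scans `Im τ_G(ω) = 0` along mode curves
  tracked across frequency by nearest-eigenvalue continuation, refining
  each crossing by `uniroot` at `1e-12` tolerance. The largest positive
  crossing over all modes is the boundary; the residual of the determinant
  condition at the solution is returned and must be ≤ 1e-10 in the tests.
  Two analytic limits anchor it: as `α → 0`, `τ_G* → τ_e/2` with crossing
  frequency `1/τ_e` (the uncoupled cubic's boundary, Routh condition
  `2τ_G > τ_e`); and as delays dephase (`v → 0` at small α) the same limit
  reappears. At finite region count the dephased limit is only approximate
  for large α, because the eigenvalues of a random-phase matrix do not
  collapse to 1 — the package tests it at `α = 0.1` within 10 %.

Four regimes follow from crossing the two boundaries independently:
1 stable, 2 amplitude-growing (low `τ_G`), 3 mean-growing (`α > 1`),
4 both. `classify_macroscopic_regime()` evaluates the oscillation boundary
just inside the coupling-feasible region (`α` capped at 0.999) since
beyond `α = 1` the mean instability is decisive anyway.

## Time domain

Transients come from numerical inversion of the Laplace-domain solution by
the de Hoog–Knight–Stokes method: the Bromwich integral discretized on a
shifted contour, summed as a quotient-difference continued fraction with
the standard remainder correction. One contour serves a whole time grid, so
a macroscopic simulation costs `2M+1` linear solves regardless of the
number of time points. The series order defaults to `M = 80`, which
reproduces closed-form pairs to ~1e-6 (exponentials) and ~3e-7 (sinusoids)
on (0, 0.3] s; the default horizon is 0.3 s at 1 ms because inversion of
resonant transforms degrades at long horizons, especially near limit
cycles. For clearly unstable parameter sets the contour shift should be
set at or above the dominant growth rate (`simulate_impulse()` does this
automatically for the local level).

Noise-driven records are synthesized in the frequency domain — transfer
function × complex Gaussian noise of flat expected power, Hermitian
symmetrization, inverse FFT — which for a linear time-invariant system is
statistically equivalent to filtering a white-noise path and avoids
long-horizon inversion entirely. The synthesis is seed-deterministic, and a
smoothed periodogram of a long record correlates with `|H|²` above 0.95 in
the tests.

`classify_trajectory()` mirrors how the regimes are read off simulation
panels: it estimates the oscillation period (periodogram, refined by
extrema spacing, which also rescues records whose periodogram is dominated
by strong growth), slides one-period windows by half a period, and takes
each window's local linear fit as the midline and half-range as the
amplitude. The amplitude trend is a log-linear regression weighted toward
the tail of the record, because early windows carry transients of faster
modes (with several modes of comparable decay the early envelope can even
be non-monotone). A relative change of more than 2 % per period in either
statistic classifies growth/decay; within the band the envelope counts as
a limit cycle and the mean as bounded. Records with fewer than five
extrema are `indeterminate` — except that an unambiguous monotone midline
climb is still reported as `growing_mean`, since in the mean-growing
regime the oscillation has often damped away entirely within the window.
This classifier is a heuristic for short transients; it is validated
against pole-based verdicts on random circuits whose dominant mode is
actually expressed in the window (dominant-pole residue large enough to be
visible), and it is not intended for signals whose asymptotics lie outside
the simulated horizon.

## Fitting

The objective is the mean over cortical regions of Pearson's r between
modeled and observed dB spectra across 2–45 Hz — a shape criterion,
invariant to per-region affine rescaling, so absolute power calibration is
irrelevant. Optimization is a seeded annealer in the dual-annealing mold:
Cauchy-distributed visiting moves with a slow cooling schedule, Metropolis
acceptance on a fast `1/iter` temperature, and bounded quasi-Newton
local-search phases from the initial guess and from the best visited point.
Because the seven parameters span three orders of magnitude
(time constants ~0.01, speeds ~10), the box widths are used as parameter
scales in the local search; without that scaling the quasi-Newton phase
stalls far from the optimum. Three standard initial guesses are run and the
best mean-r wins; `maxiter` defaults to 500 annealing steps per guess.

Windowed (dynamic) fitting re-estimates only `(α, g_ei, g_ii)` per 5-s
window — gains and coupling are the quantities plausibly dynamic at
seconds timescale — with time constants and speed frozen at the static
estimates. Windows are fitted independently (no warm-starting from the
previous window, so a fit failure or a genuine jump in one window cannot
drag its neighbors). Switch counting applies a strict `> 0.5` threshold to
consecutive differences of `α`. The four-code stability timeline combines
the local verdict at each window's gains with whether `α` sits at its
upper bound ("at the bound" means within `1e-6` of the active bound when
the bound is 1, and `α ≥ 1` under a relaxed bound). The static-vs-dynamic
comparison Fisher-z transforms both correlation series and applies a
one-sided paired t-test.

The Morlet time-frequency utility uses per-frequency widths `w·fs/(2πf)`
samples. The conventional shape parameter `w = 600` is kept as the default
for compatibility with the windowed-fitting pipeline it feeds; note that at
600 the effective kernels are many seconds long, so a 5-s window resolves
slow amplitude changes but smears fast ones — the unit tests check the
localization of a pure tone and the 6 dB step of an amplitude doubling
between the first and last windows of a 60-s record.

## Synthetic data

Generators stand in for the empirical inputs, with the seed fully
determining every draw:

* `synth_connectome()`: random geometric graph (distance-thresholded, so
  connectivity correlates with distance as in tractography), symmetric
  nonnegative Gaussian-magnitude weights, rows normalized by row degree,
  distances from random 3-D coordinates scaled to ≤150 mm, cortical mask
  covering 79 % of regions (the 68-of-86 atlas proportion), N = 86 by
  default. An Erdős–Rényi family is available for comparison. Disconnected
  draws are regenerated with an incremented sub-seed.
* `synth_static_psd()` / `synth_dynamic_windows()`: forward spectra at
  ground-truth parameters (refusing locally unstable truths and `α ≥ 1`),
  plus optional iid Gaussian noise in dB on a noise stream separated from
  the structural seed, so changing the noise level never changes the
  connectome. Dynamic generation plants per-window `(α, g_ei, g_ii)`
  trajectories, including abrupt jumps for switch-count experiments.

What the generators do **not** emulate: heavy-tailed tractography weight
distributions, community/hemispheric structure, beamformer leakage between
regions, and non-Gaussian measurement noise. Passing recovery tests on
these fixtures demonstrates the estimation machinery is correct and
well-conditioned, not that real MEG spectra identify the parameters
equally well. One visible consequence: with the quasi-uniform synthetic
weights, the exp(−t)-input network spectrum shows its prominent alpha-band
peak in the stable band near the oscillation boundary at low coupling,
whereas heavy-tailed template connectomes express it over more of the
stable wedge.

## Problem sizes and numerical choices

The test-suite experiments use sizes chosen to make each property sharp:
equivalence of the eigenmode sum and direct solve on 10–20-node
connectomes at 1e-8; boundary and regime checks on 12- and 86-node
connectomes; static recovery on a 16-node connectome with a 1-Hz grid
(all seven free parameters recovered within 10 %, mean r > 0.99, from
noise-free spectra, fixed seeds); dynamic recovery of a planted
`α: 0.3 → 0.9` jump across twelve 5-s windows (per-window parameters
within 10 %, `α` within 0.05, switch count exact); and the Fisher-z
comparison on the same planted-drift experiment. Peak detection exposes a
topographic-prominence floor (default 0, i.e. every strict local maximum;
the network maps use 0.5–1 dB) because finite connectomes produce
dB-scale delay-interference ripple that a strict neighbor test would count
as peaks. Degenerate inputs are handled explicitly: zero spectra magnitude
is floored before the log with a warning, zero-variance regions are
excluded from the objective with a warning, zero-degree connectome rows
stay all-zero and are flagged by the validator, and ties in peak ranking
break toward the lower frequency.

## Known limitations

* The oscillation boundary is numerical; its location depends on the scan
  range and mode tracking, and agreement with any published boundary can
  only be as good as that approximation (symbolic manipulation of an
  86×86 delayed determinant is infeasible).
* Trajectory classification within a short window cannot see modes whose
  residues keep them below the transient floor; such parameter sets are
  reported honestly as what the window shows. Separately, the
  double-precision series inversion loses accuracy beyond roughly 0.4 s
  for strongly growing resonant transforms (the quotient-difference
  acceleration was designed for extended-precision arithmetic), so
  classification experiments stay inside that horizon.
* The model itself is linear: no multistability, no amplitude saturation;
  noise acts purely as a spectral filter. Regionally varying local
  parameters and sensor-space (lead-field) modeling are out of scope.
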