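test_that("characteristic polynomial is monic of degree 10 and matches an
          evaluation-interpolation oracle", {
  p <- ref_local()
  cp <- mesoscopic_char_poly(p)
  expect_identical(cp$degree, 10L)
  expect_identical(cp$coeffs[1], 1)
  # oracle: evaluate the rational determinant times the cleared denominator
  # at 11 points and interpolate the degree-10 polynomial
  te <- 1 / p$tau_e; ti <- 1 / p$tau_i
  sc <- 300
  z_pts <- seq(-1.5, 1.5, length.out = 11)
  s_pts <- sc * z_pts
  det_val <- function(s) {
    Fe <- gamma_kernel_transform(p$tau_e, s)
    Fi <- gamma_kernel_transform(p$tau_i, s)
    ((s + p$g_ee * Fe / p$tau_e) * (s + p$g_ii * Fi / p$tau_i) +
       p$g_ei^2 / (p$tau_e * p$tau_i) * (Fe * Fi)^2) *
      (s + te)^4 * (s + ti)^4
  }
  V <- outer(z_pts, 0:10, `^`)
  coef_z <- solve(V, vapply(s_pts, det_val, numeric(1)))
  expect_equal(rev(cp$coeffs) * sc^(0:10), unname(coef_z),
               tolerance = 1e-8)
})

test_that("with no cross coupling the root set is the union of the two
          uncoupled factors", {
  p <- local_params(tau_e = 0.01, tau_i = 0.004, g_ei = 1e-300, g_ii = 1.4)
  cp <- mesoscopic_char_poly(p)
  r <- sort(Re(spectralgm:::poly_roots(cp$coeffs)))
  te <- 1 / p$tau_e; ti <- 1 / p$tau_i
  q1 <- spectralgm:::poly_mul(
    {b <- spectralgm:::poly_mul(c(0, 1), c(te^2, 2 * te, 1))
     b[1] <- b[1] + te^3; b}, c(ti^2, 2 * ti, 1))
  q2 <- spectralgm:::poly_mul(
    {b <- spectralgm:::poly_mul(c(0, 1), c(ti^2, 2 * ti, 1))
     b[1] <- b[1] + p$g_ii * ti^3; b}, c(te^2, 2 * te, 1))
  ref <- sort(Re(c(spectralgm:::poly_roots(rev(q1)),
                   spectralgm:::poly_roots(rev(q2)))))
  expect_equal(r, ref, tolerance = 1e-6)
})

test_that("pole classification reproduces the reference stable, borderline,
          and unstable gain settings, with one conjugate pair crossing", {
  stable <- mesoscopic_poles(ref_local())
  expect_identical(stable$classification, "stable")
  unstable <- mesoscopic_poles(local_params(0.012, 0.003, 1.0, 0.5))
  expect_identical(unstable$classification, "unstable")
  rhp <- unstable$roots[Re(unstable$roots) > 0]
  expect_identical(length(rhp), 2L)
  expect_gt(abs(Im(rhp[1])), 1)  # oscillatory instability, not monotone
  expect_equal(sort(Im(rhp)), sort(-Im(rhp)), tolerance = 1e-8)
  # with coupled gains the constant cross term perturbs the cleared
  # kernel roots away from -1/tau; none should be flagged spurious
  expect_identical(sum(stable$spurious), 0L)
  # in the decoupled limit the cleared-denominator roots reappear exactly
  dec <- mesoscopic_poles(local_params(0.01, 0.004, 1e-300, 1.4))
  expect_identical(sum(dec$spurious), 4L)
  expect_true(all(Re(dec$roots[dec$spurious]) < 0))
})

test_that("Routh-Hurwitz counts right-half-plane roots, matching the
          companion-matrix oracle on random polynomials", {
  expect_identical(routh_hurwitz(c(1, 6, 11, 6))$sign_changes, 0L + 0L)
  set.seed(404)
  for (i in 1:200) {
    deg <- sample(3:10, 1)
    roots_re <- stats::runif(deg, -5, 5)
    # build a real polynomial from random real roots (exact RHP count)
    coef <- 1
    for (r in roots_re) coef <- spectralgm:::poly_mul(coef, c(-r, 1))
    n_rhp <- sum(roots_re > 0)
    rh <- routh_hurwitz(rev(coef))
    expect_identical(rh$sign_changes, n_rhp)
  }
  # complex-conjugate pairs as well
  for (i in 1:50) {
    re <- stats::runif(3, -4, 4); im <- stats::runif(3, 0.5, 5)
    coef <- 1
    for (j in 1:3)
      coef <- spectralgm:::poly_mul(coef, c(re[j]^2 + im[j]^2, -2 * re[j], 1))
    rh <- routh_hurwitz(rev(coef))
    expect_identical(rh$sign_changes, 2L * sum(re > 0))
  }
})

test_that("mesoscopic classification is identical whether judged by pole
          real parts or by Routh-Hurwitz sign changes", {
  set.seed(505)
  for (i in 1:100) {
    p <- random_local_in_bounds()
    ps <- mesoscopic_poles(p)
    rh <- routh_hurwitz(mesoscopic_char_poly(p)$coeffs)
    if (abs(ps$max_real) > 1e-3) {  # away from the marginal band
      expect_identical(ps$classification == "unstable",
                       rh$sign_changes > 0)
    }
  }
})

test_that("bisection locates the borderline-stable cross gain near 0.52 and
          honors its bracketing contract", {
  g_star <- critical_gei(g_ii = 0.5, tau_e = 0.012, tau_i = 0.003,
                         bracket = c(0.4, 1))
  expect_equal(g_star, 0.52, tolerance = 0.02)
  below <- mesoscopic_poles(local_params(0.012, 0.003, g_star - 1e-3, 0.5))
  above <- mesoscopic_poles(local_params(0.012, 0.003, g_star + 1e-3, 0.5))
  expect_lt(below$max_real, 0)
  expect_gt(above$max_real, 0)
  # grid-scan oracle at 1e-4 steps around the bisection result
  grid <- seq(g_star - 0.002, g_star + 0.002, 1e-4)
  flips <- vapply(grid, function(g)
    mesoscopic_poles(local_params(0.012, 0.003, g, 0.5))$max_real > 0,
    logical(1))
  g_scan <- grid[min(which(flips))]
  expect_lt(abs(g_scan - g_star), 2e-4)
  expect_error(critical_gei(bracket = c(0.1, 0.2)), "straddle")
})

test_that("uncoupled macroscopic cubic is stable exactly when twice the
          graph time constant exceeds the excitatory one", {
  expect_true(alpha0_stability(0.012, 0.012)$stable)
  expect_false(alpha0_stability(0.012, 0.005)$stable)
  expect_identical(alpha0_stability(0.012, 0.01)$critical_ratio, 2)
  # cubic cross-checks: Routh array and a purely imaginary pair exactly at
  # the boundary
  st <- alpha0_stability(0.012, 0.012)
  expect_identical(routh_hurwitz(st$cubic)$sign_changes, 0L)
  un <- alpha0_stability(0.012, 0.005)
  expect_gt(routh_hurwitz(un$cubic)$sign_changes, 0L)
  bd <- alpha0_stability(0.012, 0.006)   # tau_G = tau_e / 2
  r <- spectralgm:::poly_roots(bd$cubic)
  on_axis <- r[abs(Re(r)) < 1e-6 * max(Mod(r))]
  expect_identical(length(on_axis), 2L)
  expect_equal(sort(Im(on_axis)), c(-1, 1) / 0.012, tolerance = 1e-6)
})

test_that("coupling boundary is exactly 1 for connected row-stochastic
          connectivity", {
  expect_equal(alpha_boundary(matrix(c(0, 1, 1, 0), 2)), 1)
  expect_lt(abs(alpha_boundary(conn_small()) - 1), 1e-10)
  set.seed(606)
  conn10 <- synth_connectome(synth_spec(N = 10, density = 0.6, seed = 77))
  expect_lt(abs(alpha_boundary(conn10) - 1), 1e-10)
  # eigenvalue-sweep oracle: smallest alpha with a singular I - alpha C
  alphas <- seq(0.5, 1.5, 1e-3)
  dets <- vapply(alphas, function(a)
    min(Mod(eigen(diag(10) - a * conn10$C, only.values = TRUE)$values)),
    numeric(1))
  expect_equal(alphas[which.min(dets)], 1, tolerance = 2e-3)
})

test_that("jw boundary recovers the analytic uncoupled limit, the dephased
          slow-conduction limit, and satisfies the determinant condition", {
  conn <- conn_small()
  local <- ref_local()
  b0 <- jw_boundary(local, 1e-8, conn, 5)
  expect_equal(b0$tau_G_critical, local$tau_e / 2, tolerance = 1e-6)
  expect_equal(b0$omega_critical, 1 / local$tau_e, tolerance = 1e-4)
  bv <- jw_boundary(local, 0.1, conn, 1e-4)
  expect_equal(bv$tau_G_critical, local$tau_e / 2, tolerance = 0.1)
  b <- jw_boundary(local, 0.5, conn, 5)
  expect_lt(b$residual, 1e-9)
  # plug-in residual of the full determinant at the returned point
  s <- 1i * b$omega_critical
  Fe <- gamma_kernel_transform(local$tau_e, s)
  M <- (s + Fe / b$tau_G_critical) * diag(conn$N) -
    (0.5 / b$tau_G_critical) * Fe * delayed_connectivity(conn, 5, s)
  expect_lt(min(Mod(eigen(M, only.values = TRUE)$values)),
            1e-8 * max(Mod(M)))
})

test_that("determinant of the macroscopic stability matrix factorizes over
          the Laplacian eigenmodes", {
  conn <- synth_connectome(synth_spec(N = 8, density = 0.6, seed = 55))
  local <- ref_local()
  tau_G <- 0.01; alpha <- 0.6; v <- 5
  for (f in c(4, 11, 23)) {
    s <- 2i * pi * f
    Fe <- gamma_kernel_transform(local$tau_e, s)
    Cs <- delayed_connectivity(conn, v, s)
    M <- (s + Fe / tau_G) * diag(conn$N) - (alpha / tau_G) * Fe * Cs
    lam <- eigen(diag(conn$N) - alpha * Cs, only.values = TRUE)$values
    lhs <- prod(eigen(M, only.values = TRUE)$values)
    rhs <- prod(s + lam * Fe / tau_G)
    expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-8)
  }
})

test_that("macroscopic regimes split on the coupling bound and the
          oscillation boundary", {
  conn <- conn_full()
  local <- ref_local()
  bd8 <- fixture("bd_full_08", function()
    jw_boundary(local_params(0.012, 0.003, 0.4, 0.5), 0.8, conn,
                5)$tau_G_critical)
  cases <- list(list(0.012, 0.8, 1L), list(0.012, 1.1, 3L),
                list(0.005, 0.1, 2L), list(0.005, 1.1, 4L))
  for (cs in cases) {
    net <- network_params(tau_G = cs[[1]], alpha = cs[[2]], v = 5)
    r <- classify_macroscopic_regime(local, net, conn)
    expect_identical(r$code, cs[[3]])
  }
  expect_gt(0.012, bd8)  # the stable case really sits above the boundary
})

test_that("parameters just above the numerical boundary give a damped
          dominant characteristic root and just below a growing one", {
  conn <- conn_small()
  local <- ref_local()
  alpha <- 0.5
  b <- jw_boundary(local, alpha, conn, 5)
  # Newton iteration on the per-mode scalar characteristic equation
  # g(s) = s + lambda(s) Fe(s) / tau_G, tracking the boundary mode from
  # its crossing eigenvalue by nearest-eigenvalue continuation
  dominant_root <- function(tau_G) {
    lam_near <- function(s, guess) {
      e <- eigen(diag(conn$N) -
                   alpha * delayed_connectivity(conn, 5, s),
                 only.values = TRUE)$values
      e[which.min(Mod(e - guess))]
    }
    s <- 1i * b$omega_critical
    lam_star <- -1i * b$omega_critical * b$tau_G_critical /
      gamma_kernel_transform(local$tau_e, s)
    guess <- lam_near(s, lam_star)
    g <- function(s, guess)
      s + lam_near(s, guess) * gamma_kernel_transform(local$tau_e, s) / tau_G
    for (it in 1:60) {
      gv <- g(s, guess)
      h <- 1e-7 * max(1, Mod(s))
      dg <- (g(s + h, guess) - gv) / h
      step <- gv / dg
      s <- s - step
      guess <- lam_near(s, guess)
      if (Mod(step) < 1e-12 * max(1, Mod(s))) break
    }
    s
  }
  above <- dominant_root(b$tau_G_critical * 1.1)
  below <- dominant_root(b$tau_G_critical * 0.9)
  expect_lt(Re(above), 0)
  expect_gt(Re(below), 0)
})
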