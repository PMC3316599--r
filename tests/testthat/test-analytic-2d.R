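test_that("radius density: normalisation, mode, Fokker-Planck oracle", {
  set.seed(11)
  for (k in 1:5) {
    p <- analytic_params(0, runif(1, 0.03, 0.8))
    expect_equal(integrate(function(R) radius_pdf(R, p), 0, Inf,
                           rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  }
  p <- analytic_params(0, 0.04)
  mode <- optimize(function(R) -radius_pdf(R, p), c(0.2, 0.8))$minimum
  expect_lt(abs(mode - 0.5), 1e-3)
  expect_equal(radius_pdf(c(-0.2, 0), p), c(0, 0))
  # radial Fokker-Planck integration (reflecting at 0) as oracle
  for (pars in list(c(20, 0.1), c(1, 0.12), c(60, 0.05))) {
    lam <- pars[1]; eps <- pars[2]
    o <- fp_steady_oracle(K = lam * eps^2, gam = 2 * lam, cc = 0.5,
                          a = 0, b = 1.4)
    pp <- analytic_params(0, eps)
    L1 <- sum(abs(radius_pdf(o$z, pp) - o$W)[-c(1, length(o$z))]) * o$h
    expect_lt(L1, 1e-3)
  }
})

test_that("in-disc density: uniform limit, normalisation, special function", {
  expect_error(animal_conditional_pdf_2d(0.1, -1, 2), "positive")
  r <- seq(0, 0.59, length.out = 60)
  u <- animal_conditional_pdf_2d(r, 0.6, 0)
  expect_true(all(abs(u - 1 / (pi * 0.36)) < 1e-12))
  set.seed(21)
  for (k in 1:8) {
    R <- runif(1, 0.2, 1.5); b <- runif(1, 0, 10)
    tot <- integrate(function(s) 2 * pi * s * animal_conditional_pdf_2d(s, R, b),
                     0, R, rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-6)
    # closed-form normalising function vs brute-force quadrature
    brute <- integrate(function(s) exp(-b * s) * s, 0, R,
                       rel.tol = 1e-12)$value
    expect_lt(abs(ho_norm_2d(b, R) - brute) / brute, 1e-8)
  }
})

test_that("in-disc density matches a confined biased lattice walker", {
  set.seed(31)
  R_sites <- 50; beta <- 4
  L <- 2 * R_sites               # disc radius = 0.5 L
  pw <- 0.5 + beta / (4 * L)     # same kernel inversion as the simulator
  xy <- terriforage:::cpp_walker_disc(R_sites, pw, 1e5, 20L, 40000L)
  rr <- sqrt(xy[, 1]^2 + xy[, 2]^2) / L
  grid <- seq(0, 0.5, length.out = 401)
  dens <- 2 * pi * grid * animal_conditional_pdf_2d(grid, 0.5, beta)
  cdf <- cdf_from_density(grid, dens)
  jitter <- runif(length(rr), -0.25, 0.25) / L
  expect_lt(ks_distance(pmax(rr + jitter, 0), cdf), 0.03)
})

test_that("2D marginal: normalisation, tails, near-CP growth", {
  set.seed(41)
  for (k in 1:4) {
    p <- analytic_params(runif(1, 0, 6), runif(1, 0.05, 0.4))
    tot <- integrate(function(s) 2 * pi * s * marginal_pdf_2d(s, p), 0, 3,
                     rel.tol = 1e-8)$value
    expect_equal(tot, 1, tolerance = 1e-5)
  }
  # strong drift: sharp tail-off
  ph <- analytic_params(12, 0.05)
  expect_lt(marginal_pdf_2d(0.9, ph), 1e-3 * marginal_pdf_2d(0.05, ph))
  # strongly fluctuating border: density per unit area grows without bound
  # towards the CP (small nascent territories pile their mass there)
  pf <- analytic_params(0, 0.5)
  qs <- marginal_pdf_2d(c(0.001, 0.01, 0.05, 0.3), pf)
  expect_true(all(diff(qs) < 0))
  expect_gt(qs[1] / qs[4], 10)
})

test_that("radius MSD relation: limits, monotonicity, quadrature identity", {
  expect_lt(radius_msd_from_params(eps = 1e-5), 1e-9)
  eg <- c(0.03, 0.1, 0.25, 0.5, 1, 2)
  v <- radius_msd_from_params(eps = eg)
  expect_true(all(diff(v) > 0))
  for (e in c(0.08, 0.3, 0.9)) {
    quad <- integrate(function(R) (R - 0.5)^2 * radius_pdf(R, analytic_params(0, e)),
                      0, Inf, rel.tol = 1e-12)$value
    expect_lt(abs(quad - radius_msd_from_params(eps = e)), 1e-8)
  }
  expect_equal(eps_from_radius_msd(v[3]), 0.25, tolerance = 1e-8)
})

test_that("relocation sampling: reproducibility and distributional match", {
  p <- analytic_params(3, 0.12)
  expect_equal(nrow(sample_relocations(p, 0)), 0)
  s1 <- sample_relocations(p, 200, seed = 5)
  s2 <- sample_relocations(p, 200, seed = 5)
  expect_identical(s1, s2)
  big <- sample_relocations(p, 1e4, seed = 9, L = 250, cp = c(30, -40))
  r <- sqrt((big$x - 30)^2 + (big$y + 40)^2) / 250
  ks <- ks_distance(r, radial_cdf_2d(p))
  expect_lt(ks, 1.63 / sqrt(1e4))   # 1% critical value
  # angles are uniform
  th <- atan2(big$y + 40, big$x - 30)
  expect_lt(ks_distance(th, function(q) (q + pi) / (2 * pi)), 1.63 / 100)
})
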