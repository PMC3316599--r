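test_that("mass radius: uniform-disc closed form and support limit", {
  for (a in c(0.5, 1, 2)) {
    unif <- function(r) ifelse(r <= a, 1 / (pi * a^2), 0)
    expect_equal(mass_radius(unif, 0.95, upper = a), a * sqrt(0.95),
                 tolerance = 1e-8)
    expect_equal(mass_radius(unif, 1, upper = a), a, tolerance = 1e-6)
  }
})

test_that("home-range radius shrinks with drift and flags buffer zones", {
  r95 <- vapply(c(1, 3, 6, 10), function(b)
    mcp_radius(analytic_params(b, 0.08))$R95, numeric(1))
  expect_true(all(diff(r95) < 0))
  hr_lo <- mcp_radius(analytic_params(8, 0.05))
  expect_true(hr_lo$R95 < 0.5 && hr_lo$buffer_zone)
  expect_equal(hr_lo$exclusive_fraction, 1)
  hr_hi <- mcp_radius(analytic_params(0.5, 0.15))
  expect_true(hr_hi$R95 > 0.5)
  expect_false(hr_hi$buffer_zone)
  expect_lt(hr_hi$exclusive_fraction, 1)
})

test_that("exclusive area fraction: geometry against Monte-Carlo", {
  expect_equal(exclusive_area_fraction(0.4), 1)
  expect_equal(exclusive_area_fraction(0.5), 1)
  # continuity just above contact
  expect_gt(exclusive_area_fraction(0.501), 0.999)
  # monotone non-increasing
  rs <- seq(0.45, 0.95, by = 0.05)
  fr <- exclusive_area_fraction(rs)
  expect_true(all(diff(fr) <= 1e-12))
  # lens formula (and polar integration beyond it) vs Monte-Carlo, 0.2 pp
  for (R in c(0.33, 0.52, 0.56, 0.62, 0.75, 0.9)) {
    expect_lt(abs(exclusive_area_fraction(R) - mc_exclusive_fraction(R)),
              0.002)
  }
})

test_that("sigmoid summaries recover known curves and beat straight lines", {
  set.seed(14)
  x <- seq(0, 10, length.out = 12)
  truth <- c(A = 0.3, B = 0.62, x0 = 4, s = 1.2)
  y <- truth["A"] + (truth["B"] - truth["A"]) /
    (1 + exp(-(x - truth["x0"]) / truth["s"])) + rnorm(12, 0, 1e-4)
  fit <- fit_sigmoid(x, y)
  expect_equal(unname(fit$coefficients["A"]), 0.3, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["B"]), 0.62, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["x0"]), 4, tolerance = 0.05)
  expect_true(all(diff(fit$fitted) > 0))
  line_rss <- sqrt(sum(resid(lm(y ~ x))^2))
  expect_lte(fit$residual_norm, line_rss)
  expect_error(fit_sigmoid(x, rep(1, 12)), "flat")
})

test_that("allometric mapping composes and inverts consistently", {
  map <- synthetic_calibration_map()
  tab0 <- exclusive_fraction_vs_mass(map, masses = c(1, 10, 100),
                                     exponent = 0, f_ref = 0.9)
  # exponent 0: constant target fraction, constant Z per beta
  for (b in unique(tab0$beta))
    expect_lt(diff(range(tab0$Z[tab0$beta == b & tab0$attainable])), 1e-4)
  # a monotone exponent gives a monotone Z column
  tab <- exclusive_fraction_vs_mass(map, masses = c(1, 5, 25),
                                    exponent = -0.05, f_ref = 0.97,
                                    betas = 2)
  zc <- tab$Z[tab$attainable]
  if (length(zc) >= 2) expect_true(all(diff(zc) > 0) || all(diff(zc) < 0))
  # round trip: the Z that realises a fraction is recovered by inversion
  frac_of <- function(b, Z) {
    ln <- terriforage:::interp_line(map, b)
    eps <- eps_from_radius_msd(exp(ln$intercept + ln$slope * log(Z)))
    mcp_radius(analytic_params(b, eps))$exclusive_fraction
  }
  f_target <- frac_of(2, 6)
  tab2 <- exclusive_fraction_vs_mass(map, masses = 1, exponent = 0,
                                     f_ref = f_target, betas = 2)
  expect_equal(tab2$Z[1], 6, tolerance = 1e-3)
  # unattainable targets are flagged, not errors
  tab3 <- exclusive_fraction_vs_mass(map, masses = 1, exponent = 0,
                                     f_ref = 0.2, betas = 2)
  expect_false(tab3$attainable[1])
})

test_that("analytic mass radius agrees with empirical draws and hull MCP", {
  p <- analytic_params(4, 0.1)
  R95 <- mcp_radius(p)$R95
  d <- sample_relocations(p, 4000, seed = 33)
  r <- sqrt(d$x^2 + d$y^2)
  emp <- unname(quantile(r, 0.95))
  expect_lt(abs(emp - R95), 2 * 0.02)
  h <- mcp_hull(d$x, d$y, 0.95)
  expect_gt(nrow(h$hull), 4)
  expect_lt(abs(h$area - pi * R95^2) / (pi * R95^2), 0.35)
})
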