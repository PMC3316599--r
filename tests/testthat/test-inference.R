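make_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

test_that("relocation reader validates, drops and sorts", {
  f <- make_csv(data.frame(animal_id = 1, x = c(0, 1, 2), y = c(0, 0, 1),
                           t = 1:3))
  d <- read_relocations(f)
  expect_equal(nrow(d), 3)
  expect_equal(length(unique(d$animal_id)), 1)

  f2 <- make_csv(data.frame(animal_id = 1, x = c(0, NaN, 2), y = c(0, 0, 1),
                            t = 1:3))
  expect_message(d2 <- read_relocations(f2), "dropped 1")
  expect_equal(nrow(d2), 2)

  f3 <- make_csv(data.frame(animal_id = 1, x = 1:3, y = 1:3, t = c(3, 1, 2)))
  expect_warning(d3 <- read_relocations(f3), "out of order")
  expect_false(is.unsorted(d3$t))

  f4 <- make_csv(data.frame(animal_id = 1, x = 1:3, t = 1:3))
  expect_error(read_relocations(f4), "missing column.*y")
  f5 <- tempfile(fileext = ".csv")
  writeLines("animal_id,x,y,t", f5)
  expect_error(read_relocations(f5), "empty")
})

test_that("CP and spacing estimation", {
  set.seed(3)
  d <- tibble::tibble(animal_id = 1L, x = 3 + rnorm(400, 0, 0.5),
                      y = 4 + rnorm(400, 0, 0.5), t = 1:400)
  est <- estimate_cp_and_L(d, L = 1)
  se <- 0.5 * sqrt(pi / 2) / sqrt(400)
  expect_lt(abs(est$cp$x - 3), 2.5 * se + 0.02)
  expect_lt(abs(est$cp$y - 4), 2.5 * se + 0.02)
  # two animals 500 apart define L
  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, animal_id = 2L, x = x + 500))
  expect_equal(estimate_cp_and_L(d2)$L, 500, tolerance = 0.01)
  expect_error(estimate_cp_and_L(d), "user-supplied")
  # explicit CP overrides the estimate exactly
  ov <- estimate_cp_and_L(d, cp = c(9, 9), L = 1)
  expect_equal(c(ov$cp$x, ov$cp$y), c(9, 9))
})

test_that("animal-MSD saturation gate distinguishes data regimes", {
  set.seed(4)
  p <- analytic_params(2, 0.1)
  stationary <- sample_relocations(p, 1500, seed = 9)
  s1 <- check_msd_saturation(stationary, cp = c(0, 0))
  expect_true(s1$saturated)
  # an unbiased random walk never saturates
  rw <- tibble::tibble(animal_id = 1L, x = cumsum(rnorm(1500)),
                       y = cumsum(rnorm(1500)), t = 1:1500)
  s2 <- check_msd_saturation(rw)
  expect_false(s2$saturated)
  expect_match(s2$guidance, "not saturated")
  # constant position: saturated with zero MSD
  cst <- tibble::tibble(animal_id = 1L, x = 5, y = 5, t = 1:200)
  s3 <- check_msd_saturation(cst)
  expect_true(s3$saturated)
  expect_equal(s3$per_animal$msd_level, 0)
  expect_error(check_msd_saturation(cst[1:10, ]), "fewer than")
})

test_that("likelihood agrees with brute-force quadrature of the density", {
  p <- analytic_params(2.5, 0.12)
  r <- c(0.05, 0.2, 0.41, 0.55)
  got <- -terriforage:::marginal_nll(c(2.5, 0.12), r)
  want <- sum(vapply(r, function(ri) {
    q <- integrate(function(R) radius_pdf(R, p) *
                     exp(-p$beta * ri) / (2 * pi * ho_norm_2d(p$beta, R)),
                   ri, 0.5 + 0.12 * sqrt(log(1e18)), rel.tol = 1e-12)$value
    log(2 * pi * ri) + log(q)
  }, numeric(1)))
  expect_lt(abs(got - want), 1e-6)
})

test_that("fit invariances and tidy methods", {
  p <- analytic_params(2, 0.1)
  d <- sample_relocations(p, 1200, seed = 12)
  f1 <- fit_marginal(d, cp = c(0, 0), L = 1)
  dd <- dplyr::bind_rows(d, d)
  f2 <- fit_marginal(dd, cp = c(0, 0), L = 1)
  expect_equal(f2$beta_hat, f1$beta_hat, tolerance = 1e-3)
  expect_equal(f2$eps_hat, f1$eps_hat, tolerance = 1e-3)

  td <- tidy(f1)
  expect_equal(td$term, c("beta", "eps", "eps2"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(f1)
  expect_equal(gl$nobs, 1200)
  expect_true(gl$ks < 0.1)
})

test_that("scent-time inference refuses bad inputs and propagates scale", {
  map <- synthetic_calibration_map()
  p <- analytic_params(3, 0.1)
  d <- sample_relocations(p, 1500, seed = 21)
  fit <- fit_marginal(d, cp = c(0, 0), L = 1)
  expect_error(infer_active_scent_time(fit, map, D = NULL, rho = 1),
               "must be supplied")
  res <- infer_active_scent_time(fit, map, D = 0.25, rho = 1 / 224)
  expect_gt(res$T_AS, 0)
  expect_true(res$T_AS_interval[1] < res$T_AS &&
                res$T_AS < res$T_AS_interval[2])
  # doubling rho halves K2 and therefore T_AS at fixed Z
  res2 <- infer_active_scent_time(fit, map, D = 0.25, rho = 2 / 224)
  expect_equal(res2$T_AS, res$T_AS / 2, tolerance = 1e-10)
  td <- tidy(res)
  expect_true("T_AS" %in% td$term)
  # refusal on non-saturating data
  expect_error(infer_active_scent_time(fit, map, D = 0.25, rho = 1,
                                       saturation = list(saturated = FALSE,
                                                         guidance = "x")),
               "not saturated")
})
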