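test_that("configuration validates lattice/CP commensurability", {
  cfg <- sim_config(dimension = 1, n_animals = 2, cp_spacing = 10,
                    lattice_spacing = 1, seed = 1)
  expect_equal(cfg$n_sites, 20L)
  expect_equal(cfg$cp_sites, c(0L, 10L))
  expect_error(sim_config(dimension = 1, cp_spacing = 10.5),
               "incommensurable 1D")
  expect_error(sim_config(dimension = 2, cp_spacing = 15),
               "incommensurable 2D")
  expect_error(sim_config(dimension = 2, n_animals = 7),
               "incommensurable 2D CP layout")
  expect_error(sim_config(bias_p = 0.3), "bias_p")
  expect_error(sim_config(active_scent_time = -1), "active_scent_time")
})

test_that("initial state: animals on their CPs, empty scent, hexagonal CPs", {
  st <- init_state(sim_config(dimension = 1, cp_spacing = 10, seed = 1))
  expect_equal(st$positions$x, c(0, 10))
  expect_equal(nrow(st$scent), 0)
  expect_equal(st$time, 0)

  cfg <- sim_config(dimension = 2, seed = 1)
  st2 <- init_state(cfg)
  expect_equal(nrow(st2$positions), 30)
  expect_equal(nrow(dplyr::distinct(st2$positions[, c("x", "y")])), 30)
  # pairwise nearest-CP distance close to L on the torus
  nn <- vapply(seq_len(30), function(i) {
    dx <- abs(cfg$cp_x - cfg$cp_x[i]); dx <- pmin(dx, cfg$nx - dx)
    dy <- abs(cfg$cp_y - cfg$cp_y[i]); dy <- pmin(dy, cfg$ny - dy)
    min(sqrt(dx^2 + dy^2)[-i])
  }, numeric(1))
  expect_true(all(abs(nn - cfg$cp_spacing) / cfg$cp_spacing < 0.15))
})

test_that("2D movement kernel: symmetry, neutrality, normalisation, drift", {
  expect_equal(move_probabilities_2d(c(3, 4), c(3, 4), 0.9),
               setNames(rep(0.25, 4), c("+x", "-x", "+y", "-y")))
  expect_equal(unname(move_probabilities_2d(c(7, -2), c(1, 5), 0.5)),
               rep(0.25, 4))
  set.seed(42)
  for (k in 1:25) {
    pos <- runif(2, -50, 50); cp <- runif(2, -50, 50); p <- runif(1, 0.5, 1)
    pr <- move_probabilities_2d(pos, cp, p)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
    # expected step points towards the CP and is invariant under rescaling
    drift <- c(pr["+x"] - pr["-x"], pr["+y"] - pr["-y"])
    u <- (cp - pos) / sqrt(sum((cp - pos)^2))
    expect_gt(sum(drift * u), 0)
    pr2 <- move_probabilities_2d(pos, pos + 7.3 * (cp - pos), p)
    expect_equal(unname(pr2), unname(pr), tolerance = 1e-12)
  }
})

test_that("runs are bit-reproducible given the seed", {
  cfg <- sim_config(dimension = 1, cp_spacing = 10, active_scent_time = 60,
                    t_max = 300, record_every = 5, seed = 71)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
  cfg2 <- sim_config(dimension = 2, active_scent_time = 300, bias_p = 0.55,
                     t_max = 300, record_every = 20, seed = 5)
  expect_identical(run_simulation(cfg2)$borders, run_simulation(cfg2)$borders)
})

test_that("exclusion invariants hold on evolved states", {
  cfg <- sim_config(dimension = 2, active_scent_time = 2000, bias_p = 0.53,
                    t_max = 2500, record_every = 50, seed = 13)
  rec <- run_simulation(cfg)
  ow <- rec$state$scent_owner
  # ownership is single-valued by construction; every animal stands on a
  # site whose active scent, if any, is its own
  for (i in seq_len(cfg$n_animals)) {
    o <- ow[rec$state$final_x[i] + 1, rec$state$final_y[i] + 1]
    expect_true(is.na(o) || o == i)
  }
  # territories (active-scent site sets) are pairwise disjoint
  expect_true(all(table(ow[!is.na(ow)]) > 0))
  expect_lte(sum(!is.na(ow)), cfg$nx * cfg$ny)
})

test_that("scent exclusion blocks moves and expiry releases them", {
  # T_AS = 0 disables the interaction entirely: free biased walkers
  cfg <- sim_config(dimension = 1, cp_spacing = 10, active_scent_time = 0,
                    t_max = 100, record_every = 5, seed = 2)
  rec <- run_simulation(cfg)
  expect_true(all(is.na(rec$state$scent_owner)))
  # occupied sites always hold the occupant's fresh scent, so two animals
  # can never meet on a site
  cfg2 <- sim_config(dimension = 1, cp_spacing = 5, active_scent_time = 1e7,
                     t_max = 2000, record_every = 1, seed = 3)
  rec2 <- run_simulation(cfg2)
  pos <- tidyr::pivot_wider(rec2$positions[, c("time", "animal", "x")],
                            names_from = animal, values_from = x)
  gap <- abs(pos$`1` - pos$`2`)
  expect_true(all(pmin(gap, 10 - gap) >= 1))
})

test_that("free-walker MSD matches the lattice diffusion constant", {
  # T_AS = 0, bias off: slope of the per-animal MSD is 2 D t (1D)
  cfg <- sim_config(dimension = 1, n_animals = 2, cp_spacing = 50,
                    active_scent_time = 0, t_max = 1e4, record_every = 500,
                    seed = 1)
  d <- dplyr::bind_rows(lapply(1:500, function(s) {
    cfg$seed <- s
    r <- run_simulation(cfg)
    p <- r$positions
    p$replicate <- s
    p
  }))
  m <- compute_msd(d, x_unwrapped, time = time, series = animal,
                   replicate = replicate, reference = "initial")
  D <- dimensionless_parameters(cfg)$D
  slope <- unname(coef(lm(msd ~ time, data = m))[2])
  expect_lt(abs(slope - 2 * D) / (2 * D), 0.05)
})

test_that("1D border extraction follows the midpoint-of-gap definition", {
  own <- rep(NA_integer_, 20)
  own[4:8] <- 1L   # sites 3..7 (0-based)
  own[11:16] <- 2L # sites 10..15
  b <- extract_borders_1d(own)
  expect_equal(sort(b$position), c(8.5, 19))
  # juxtaposed blocks: empty gap, border on the half-integer between them
  own2 <- c(rep(1L, 8), rep(2L, 12))
  b2 <- extract_borders_1d(own2)
  expect_true(7.5 %in% b2$position)
  # an animal with no active scent: undefined border flag
  own3 <- rep(NA_integer_, 20); own3[4:8] <- 1L
  b3 <- extract_borders_1d(own3)
  expect_false(attr(b3, "defined"))
})

test_that("symmetric initial growth puts 1D borders at the midpoints on average", {
  # the first-contact point of any single run is stochastic; the symmetry
  # of the initial condition shows in the ensemble mean border position
  cfg <- sim_config(dimension = 1, cp_spacing = 20, active_scent_time = 1e5,
                    t_max = 3000, record_every = 50, seed = 10)
  dev <- vapply(1:24, function(s) {
    cfg$seed <- s
    rec <- run_simulation(cfg, record_positions = FALSE)
    b <- rec$borders[rec$borders$defined & rec$borders$time > 1500, ]
    # signed deviation from the nearer arc midpoint (10 or 30, ring of 40)
    m <- b$position %% 40
    mean(ifelse(abs(m - 10) < abs(m - 30), m - 10, m - 30))
  }, numeric(1))
  expect_lt(abs(mean(dev)), 2)
})

test_that("2D radial profile: disc geometry and ray-count consistency", {
  own <- matrix(NA_integer_, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 21)^2 + (j - 21)^2 <= 25) own[i, j] <- 1L
  pr <- extract_radius_profile_2d(own, cp = c(20, 20), animal_id = 1,
                                  n_rays = 8)
  expect_true(all(abs(pr$radius - 5) <= 1))
  pr4 <- extract_radius_profile_2d(own, cp = c(20, 20), animal_id = 1,
                                   n_rays = 4)
  expect_equal(pr4$radius, pr$radius[c(1, 3, 5, 7)])
  # mean ray radius approximates sqrt(area / pi) for convex territories
  for (ab in list(c(6, 6), c(9, 5), c(12, 7))) {
    own2 <- matrix(NA_integer_, 60, 60)
    for (i in 1:60) for (j in 1:60)
      if (((i - 31) / ab[1])^2 + ((j - 31) / ab[2])^2 <= 1) own2[i, j] <- 1L
    area <- sum(!is.na(own2))
    pr2 <- extract_radius_profile_2d(own2, c(30, 30), 1, n_rays = 32)
    expect_lt(abs(mean(pr2$radius) - sqrt(area / pi)), 1)
  }
  # no territory at all: flagged
  pr0 <- extract_radius_profile_2d(matrix(NA_integer_, 10, 10), c(5, 5), 1)
  expect_true(attr(pr0, "flagged"))
})
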