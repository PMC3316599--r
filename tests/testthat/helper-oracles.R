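# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own evaluation paths.

# Finite-volume integration of the Fokker-Planck equation
#   dW/dt = K W_zz + d/dz [ gam (z - cc) W ]
# with zero-flux (reflecting) walls at a and b, run to steady state.
fp_steady_oracle <- function(K, gam, cc, a, b, n = 401, max_it = 3e5) {
  h <- (b - a) / (n - 1)
  z <- seq(a, b, length.out = n)
  zi <- (z[-1] + z[-n]) / 2
  dt <- 0.2 * min(h^2 / K, h / (max(abs(gam * (zi - cc))) + 1e-12))
  W <- rep(1 / (b - a), n)
  for (it in seq_len(max_it)) {
    J <- -K * diff(W) / h - gam * (zi - cc) * (W[-1] + W[-n]) / 2
    dW <- -diff(c(0, J, 0)) / h
    W2 <- W + dt * dW
    if (it %% 2000 == 0 && max(abs(W2 - W)) / dt < 1e-9) {
      W <- W2
      break
    }
    W <- W2
  }
  W <- W / sum((W[-1] + W[-n]) / 2 * h)
  list(z = z, W = W, h = h)
}

# Monte-Carlo estimate of the exclusive area fraction of a disc of radius R
# surrounded by six unit-distance discs of the same radius.
mc_exclusive_fraction <- function(R, n = 1e6, seed = 1) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n)) * R
  x <- rr * cos(th); y <- rr * sin(th)
  covered <- rep(FALSE, n)
  for (k in 0:5) {
    cx <- cos(k * pi / 3); cy <- sin(k * pi / 3)
    covered <- covered | ((x - cx)^2 + (y - cy)^2 <= R^2)
  }
  mean(!covered)
}

# ensemble of 1D border records at the subdiffusion/saturation study
# conditions (ring of 100 sites, Z set via the active scent time)
run_border_ensemble_1d <- function(beta, n_rep, t_max = 1e5, tas = 5000,
                                   seed0 = 0, record_every = 100) {
  cfg <- sim_config(dimension = 1, n_animals = 2, cp_spacing = 50,
                    active_scent_time = tas,
                    bias_p = bias_p_for_beta(beta, 50, 1, 1),
                    t_max = t_max, record_every = record_every, seed = 1)
  dplyr::bind_rows(lapply(seq_len(n_rep), function(s) {
    cfg$seed <- seed0 + s
    r <- run_simulation(cfg, record_positions = FALSE)
    b <- r$borders
    b$replicate <- s
    b
  }))
}

border_msd_1d_curve <- function(ens, reference = "initial") {
  compute_msd(ens[ens$defined, ], position, time = time, series = border,
              replicate = replicate, reference = reference, scale = 50)
}

# a small synthetic calibration map with known straight lines, for unit
# tests of the lookup/mapping layer (the simulation-built maps are tested
# in the acceptance suite)
synthetic_calibration_map <- function(intercepts = c(-2.2, -2.8),
                                      slopes = c(-1.2, -1.0),
                                      betas = c(2, 4),
                                      Zs = c(2, 4, 8, 16)) {
  grid <- expand.grid(beta = betas, Z = Zs)
  ln <- tibble::tibble(beta = betas, beta_key = betas,
                       intercept = intercepts, slope = slopes,
                       sigma = 0.05, n = length(Zs))
  grid$msd_sat <- exp(ln$intercept[match(grid$beta, ln$beta)] +
                        ln$slope[match(grid$beta, ln$beta)] * log(grid$Z))
  grid$stderr <- grid$msd_sat * 0.02
  grid$beta_fit <- grid$beta
  grid$saturated <- TRUE
  grid$n_rep <- 10L
  structure(list(grid = tibble::as_tibble(grid), lines = ln, inverse = NULL,
                 meta = list(dimension = 2, estimator = "ray",
                             cp_spacing = 16, Z_range = range(Zs),
                             beta_range = range(betas),
                             replicates = 10, seed = 1)),
            class = "calibration_map")
}
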