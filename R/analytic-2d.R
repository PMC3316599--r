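# Reduced adiabatic analytic model in 2D.
#
# The territory is a disc with the CP at its centre; border movement is
# modelled by fluctuations of the territory radius R (dimensionless, units
# of the CP spacing L; mean radius 1/2). The animal inside a disc of fixed
# radius follows the 2D Holgate-Okubo localising tendency: density per unit
# area proportional to exp(-beta r), rotationally symmetric. All radial
# densities are per unit area; the 2 pi r measure is always explicit.

# upper radius cutoff where the radius density tail falls below `tail`
radius_cutoff <- function(eps, tail = 1e-12) 0.5 + eps * sqrt(log(1 / tail)) + 1e-9

#' Territory radius density (2D)
#'
#' Steady state of the radius Fokker-Planck model: a Gaussian of width `eps`
#' centred on the mean radius 1/2, reflected at R = 0 so the radius stays
#' positive:
#' `P(R) = [exp(-(R - 1/2)^2 / eps^2) + exp(-(R + 1/2)^2 / eps^2)] /
#' (sqrt(pi) eps)`. The normalisation over (0, Inf) is exact.
#'
#' @param R dimensionless radius value(s).
#' @param params an [analytic_params()] (only `eps` is used).
#' @return density values (0 for R <= 0).
#' @export
radius_pdf <- function(R, params) {
  eps <- params$eps
  out <- numeric(length(R))
  ok <- R > 0
  out[ok] <- (exp(-(R[ok] - 0.5)^2 / eps^2) + exp(-(R[ok] + 0.5)^2 / eps^2)) /
    (sqrt(pi) * eps)
  out
}

#' Normalising function of the in-disc Holgate-Okubo density
#'
#' The function `psi(beta, R) = \int_0^R exp(-beta r) r dr`, i.e. the
#' normalising integral of the exponential localising-tendency density over
#' a disc of radius R (up to the factor 2 pi). Evaluated in closed form,
#' `psi = (1 - (1 + beta R) exp(-beta R)) / beta^2`, with the `beta = 0`
#' limit `R^2 / 2`.
#'
#' @param beta drift strength (>= 0).
#' @param R disc radius (> 0).
#' @return the normalising integral.
#' @export
ho_norm_2d <- function(beta, R) {
  stopifnot(all(R > 0), beta >= 0)
  if (beta == 0) return(R^2 / 2)
  x <- beta * R
  # series for small x to avoid cancellation in 1 - (1 + x) e^{-x}
  small <- x < 1e-4
  out <- numeric(length(x))
  out[!small] <- (1 - (1 + x[!small]) * exp(-x[!small])) / beta^2
  out[small] <- (x[small]^2 / 2 - x[small]^3 / 3 + x[small]^4 / 8) / beta^2
  out
}

#' Animal density inside a disc territory (2D Holgate-Okubo)
#'
#' Density per unit area of an animal performing diffusion with
#' constant-magnitude drift `beta` towards the CP at the centre of a disc of
#' radius `R`: proportional to `exp(-beta r)` inside the disc, zero outside,
#' rotationally symmetric. Satisfies
#' `\int_0^R 2 pi r pdf(r) dr = 1`.
#'
#' @param r radial distance(s) from the CP (>= 0).
#' @param R territory radius (> 0).
#' @param beta drift strength (>= 0).
#' @return density per unit area.
#' @export
animal_conditional_pdf_2d <- function(r, R, beta) {
  if (R <= 0) stop("territory radius must be positive", call. = FALSE)
  stopifnot(beta >= 0, all(r >= 0))
  out <- numeric(length(r))
  ok <- r <= R
  out[ok] <- exp(-beta * r[ok]) / (2 * pi * ho_norm_2d(beta, R))
  out
}

#' Joint density of territory radius and animal position (2D)
#'
#' Adiabatic product `P(R) * phi(r | R)` gated so the animal lies inside the
#' territory (r < R). Density with respect to `dR` times the 2D area
#' measure `2 pi r dr`.
#'
#' @param R,r radius and radial animal coordinate (recycled).
#' @param params [analytic_params()].
#' @return joint density values.
#' @export
joint_pdf_2d <- function(R, r, params) {
  n <- max(length(R), length(r))
  R <- rep_len(R, n); r <- rep_len(r, n)
  out <- numeric(n)
  ok <- R > 0 & r >= 0 & r < R
  if (any(ok))
    out[ok] <- radius_pdf(R[ok], params) *
      vapply(which(ok), function(i)
        animal_conditional_pdf_2d(r[i], R[i], params$beta), numeric(1))
  out
}

#' Marginal space-use density of the animal (2D)
#'
#' The stationary marginal per unit area at radial distance `r` from the CP,
#' integrating the joint density over all territory radii `R > r`. The outer
#' integral is truncated where the radius density tail falls below `tail`.
#' Normalised so `\int_0^Inf 2 pi r q(r) dr = 1`. The density grows without
#' bound towards the CP whenever the border fluctuates (`eps > 0`), because
#' arbitrarily small territories carry all their mass near the CP; the
#' divergence is integrable under the 2D measure. With a frozen border
#' (`eps -> 0`) the value at the CP is finite.
#'
#' @param r radial distance(s) (>= 0).
#' @param params [analytic_params()].
#' @param n_nodes Gauss-Legendre order of the radius integral.
#' @param tail radius-density truncation bound.
#' @return density per unit area.
#' @export
marginal_pdf_2d <- function(r, params, n_nodes = 64, tail = 1e-12) {
  beta <- params$beta; eps <- params$eps
  Rmax <- radius_cutoff(eps, tail)
  g <- pracma::gaussLegendre(n_nodes, 0, 1)
  out <- numeric(length(r))
  ok <- is.finite(r) & r >= 0
  if (!any(ok)) return(out)
  rr <- r[ok]
  lo <- pmax(rr, 1e-12)
  # upper limit covers the radius-density tail even beyond the nominal
  # cutoff, so the density is positive (if tiny) wherever data can fall
  hi <- pmax(Rmax, lo + eps * sqrt(log(1 / tail)))
  # the integrand carries a 1/R^2 spike just above R = r (small nascent
  # territories): resolve it with a log-spaced inner panel before the
  # linear panel that covers the Gaussian radius peak
  mid <- pmin(lo * 16, hi * 0.5)
  mid <- pmax(mid, lo * (1 + 1e-9))
  Xa <- exp(outer(log(mid) - log(lo), g$x, `*`) + log(lo))
  Wa <- outer(log(mid) - log(lo), g$w, `*`) * Xa
  Xb <- outer(hi - mid, g$x, `*`) + mid
  Wb <- outer(hi - mid, g$w, `*`)
  X <- cbind(Xa, Xb)
  W <- cbind(Wa, Wb)
  P <- radius_pdf(X, params)
  if (beta == 0) {
    phi <- 1 / (pi * X^2)
  } else {
    xb <- beta * X
    psi <- ifelse(xb < 1e-4, xb^2 / 2 - xb^3 / 3 + xb^4 / 8,
                  1 - (1 + xb) * exp(-xb)) / beta^2
    phi <- exp(-beta * rr) / (2 * pi * psi)
  }
  out[ok] <- rowSums(W * P * phi)
  out
}

#' Saturation MSD of the territory radius
#'
#' The stationary mean square displacement of the territory radius about its
#' mean 1/2, i.e. the variance-like second moment `E[(R - 1/2)^2]` of the
#' radius density, in units of L^2. Closed form via the folded-normal
#' moments (`R` is distributed as `|X|` with `X ~ N(1/2, eps^2/2)`):
#' `msd = sigma^2 + 4 mu^2 Phi(-mu/sigma) - 4 mu sigma phi(mu/sigma)` with
#' `mu = 1/2`, `sigma = eps / sqrt(2)`. Its small-`eps` limit is
#' `eps^2 / 2`; it is the analytic-model analogue of the simulation border
#' MSD and is the quantity the inference programme equates with the
#' calibration surface. `eps_from_radius_msd()` inverts it.
#'
#' @param params [analytic_params()] (or give `eps` directly).
#' @param eps alternative to `params`.
#' @return dimensionless saturation MSD.
#' @export
radius_msd_from_params <- function(params = NULL, eps = NULL) {
  if (is.null(eps)) eps <- params$eps
  mu <- 0.5
  sigma <- eps / sqrt(2)
  sigma^2 + 4 * mu^2 * pnorm(-mu / sigma) - 4 * mu * sigma * dnorm(mu / sigma)
}

#' @rdname radius_msd_from_params
#' @param msd dimensionless saturation radius MSD (> 0).
#' @export
eps_from_radius_msd <- function(msd) {
  vapply(msd, function(m) {
    stopifnot(m > 0)
    uniroot(function(e) radius_msd_from_params(eps = e) - m,
            c(1e-6, 50), tol = 1e-12, extendInt = "upX")$root
  }, numeric(1))
}

#' Draw synthetic relocations from the 2D marginal
#'
#' I.i.d. draws from the stationary 2D marginal by inverse-CDF sampling on
#' the radial coordinate (uniform angle), useful as analytic telemetry
#' fixtures for the inference pipeline. Coordinates are returned in length
#' units of `L` around `cp`.
#'
#' @param params [analytic_params()].
#' @param n number of fixes (>= 0).
#' @param seed optional integer seed (set for reproducible fixtures).
#' @param L CP spacing used to scale to dimensional units.
#' @param cp centre (length-2) of the territory.
#' @param animal_id id written into the output.
#' @param grid_n resolution of the inverse-CDF grid.
#' @return tibble with `animal_id`, `x`, `y`, `t`.
#' @export
sample_relocations <- function(params, n, seed = NULL, L = 1, cp = c(0, 0),
                               animal_id = 1L, grid_n = 2048) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(tibble::tibble(animal_id = integer(), x = numeric(),
                          y = numeric(), t = numeric()))
  Rmax <- radius_cutoff(params$eps)
  rg <- seq(0, Rmax, length.out = grid_n)
  dens <- 2 * pi * rg * marginal_pdf_2d(rg, params)
  cdf <- cumsum((dens[-1] + dens[-grid_n]) / 2 * diff(rg))
  cdf <- c(0, cdf / cdf[grid_n - 1])
  # strictly increasing section for inversion
  keep <- c(TRUE, diff(cdf) > 0)
  inv <- approxfun(cdf[keep], rg[keep], rule = 2)
  r <- inv(runif(n)) * L
  th <- runif(n, 0, 2 * pi)
  tibble::tibble(animal_id = as.integer(animal_id),
                 x = cp[1] + r * cos(th), y = cp[2] + r * sin(th),
                 t = as.numeric(seq_len(n)))
}

#' Radial cumulative distribution of the 2D marginal
#'
#' `F(r) = \int_0^r 2 pi s q(s) ds`, returned as a function usable in
#' goodness-of-fit tests.
#'
#' @param params [analytic_params()].
#' @param grid_n grid resolution.
#' @return a function r -> F(r).
#' @export
radial_cdf_2d <- function(params, grid_n = 2048) {
  Rmax <- radius_cutoff(params$eps)
  rg <- seq(0, Rmax, length.out = grid_n)
  dens <- 2 * pi * rg * marginal_pdf_2d(rg, params)
  cdf <- c(0, cumsum((dens[-1] + dens[-grid_n]) / 2 * diff(rg)))
  cdf <- pmin(cdf / max(cdf), 1)
  f <- approxfun(rg, cdf, rule = 2)
  function(r) f(pmin(pmax(r, 0), Rmax))
}
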