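# Comparison with the reaction-diffusion (RD) territory model.
#
# The RD model of central-place territoriality (Moorcroft-Lewis, with the
# over-marking response set to zero: the animals here are counter-markers)
# has, in dimensionless form on [0, 1] with the two CPs at the ends, the
# steady state u(x) = C [1 - tanh(kappa C (x - 1/2))] for the left animal,
# v(x) = u(1 - x) for the right, and scent densities proportional to the
# animal densities. The probability conservation condition int_0^1 u = 1
# fixes the free constant C (analytically C = 1; the package solves for it
# numerically by bracketed root finding, as a check of the printed form).
# kappa is the single dimensionless parameter, a product of five
# dimensional ones, which is why the RD model cannot separate scent-mark
# longevity from movement parameters the way the mechanistic model can.

#' Steady state of the reaction-diffusion territory model
#'
#' @param kappa dimensionless advection strength (> 0).
#' @param n_grid evaluation grid size on the unit interval.
#' @return an `rd_solution` tibble with columns `x`, `u`, `v` (left/right
#'   animal densities) and `s_u`, `s_v` (scent densities, normalised to the
#'   animal densities); attributes `kappa` and `C`.
#' @export
rd_steady_state <- function(kappa, n_grid = 2048) {
  stopifnot(kappa > 0, n_grid >= 16)
  u_of <- function(C) function(x) C * (1 - tanh(kappa * C * (x - 0.5)))
  mass <- function(C) integrate(u_of(C), 0, 1, rel.tol = 1e-12,
                                subdivisions = 500L)$value - 1
  lo <- 1e-6; hi <- 10
  if (mass(lo) * mass(hi) > 0)
    stop("conservation root not bracketed on [", lo, ", ", hi, "]",
         call. = FALSE)
  C <- uniroot(mass, c(lo, hi), tol = 1e-12)$root
  x <- (seq_len(n_grid) - 0.5) / n_grid
  u <- u_of(C)(x)
  out <- tibble::tibble(x = x, u = u, v = rev(u), s_u = u, s_v = rev(u))
  attr(out, "kappa") <- kappa
  attr(out, "C") <- C
  class(out) <- c("rd_solution", class(out))
  out
}

# L2 objective between the RD left-animal density and the half-territory
# marginal of the mechanistic model, on a shared midpoint grid; `q` may be
# precomputed since it does not depend on kappa
rd_l2_objective <- function(kappa, beta, eps, n_grid = 2048, q = NULL) {
  x <- (seq_len(n_grid) - 0.5) / n_grid
  u <- rd_steady_state(kappa, n_grid)$u
  if (is.null(q)) q <- reduced_marginal_half(x, beta, eps)
  mean((u - q)^2)
}

#' Best-fit RD parameter for a mechanistic parameter pair
#'
#' Minimises the integrated squared difference between the RD animal
#' density and the pinned-border half-territory marginal of the mechanistic
#' model over `kappa` (golden-section search on log kappa).
#'
#' @param beta,eps mechanistic model parameters.
#' @param interval kappa search bracket.
#' @param n_grid shared evaluation grid.
#' @return list with `kappa`, `objective`, and the bracket-endpoint
#'   objectives (minimiser certificate).
#' @export
best_fit_kappa <- function(beta, eps, interval = c(1e-2, 1e3), n_grid = 2048) {
  x <- (seq_len(n_grid) - 0.5) / n_grid
  q <- reduced_marginal_half(x, beta, eps)
  f <- function(lk) rd_l2_objective(exp(lk), beta, eps, n_grid, q = q)
  op <- optimize(f, log(interval), tol = 1e-8)
  ends <- c(f(log(interval[1])), f(log(interval[2])))
  if (max(ends) - op$objective < 1e-15)
    stop("flat objective over the kappa bracket", call. = FALSE)
  list(kappa = exp(op$minimum), objective = op$objective,
       objective_at_bracket = ends)
}

#' Best-fit mechanistic parameters for an RD parameter
#'
#' Minimises the same L2 objective over the drift strength `beta` with the
#' border spread fixed small (`eps = 0.01` by default; low spread always
#' fits the RD curve at least as well and does not move the best-fit
#' `beta`).
#'
#' @param kappa RD parameter (> 0).
#' @param eps fixed (small) border-spread parameter.
#' @param interval beta search bracket.
#' @param n_grid shared evaluation grid.
#' @return list with `beta`, `eps`, `objective` and bracket-endpoint
#'   objectives.
#' @export
best_fit_beta_eps <- function(kappa, eps = 0.01, interval = c(1e-3, 60),
                              n_grid = 2048) {
  stopifnot(kappa > 0, eps > 0)
  u <- rd_steady_state(kappa, n_grid)$u
  x <- (seq_len(n_grid) - 0.5) / n_grid
  f <- function(lb) mean((u - reduced_marginal_half(x, exp(lb), eps))^2)
  op <- optimize(f, log(interval), tol = 1e-8)
  ends <- c(f(log(interval[1])), f(log(interval[2])))
  if (max(ends) - op$objective < 1e-15)
    stop("flat objective over the beta bracket", call. = FALSE)
  list(beta = exp(op$minimum), eps = eps, objective = op$objective,
       objective_at_bracket = ends)
}
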