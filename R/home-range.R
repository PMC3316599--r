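#' Probability-mass home-range radius
#'
#' `mass_radius()` finds the radius enclosing a given probability mass of a
#' rotationally symmetric planar density (bracketing bisection on the
#' cumulative radial mass, to 1e-8 absolute). `mcp_radius()` applies it to
#' the stationary 2D marginal of the territorial model: the analytic
#' operationalisation of the 95% minimum-convex-polygon home range, since
#' the MCP of arbitrarily many i.i.d. fixes from a rotationally symmetric
#' density converges to a probability-mass contour.
#'
#' @param pdf_r radial density per unit area (function of r).
#' @param level probability mass in (0, 1].
#' @param upper upper bracket for the search (support radius).
#' @return the mass radius.
#' @examples
#' # uniform disc of radius a: R_95 = a * sqrt(0.95)
#' a <- 2
#' mass_radius(function(r) ifelse(r <= a, 1 / (pi * a^2), 0), 0.95, upper = a)
#' @export
mass_radius <- function(pdf_r, level = 0.95, upper) {
  stopifnot(level > 0, level <= 1, upper > 0)
  g <- pracma::gaussLegendre(200, 0, 1)
  mass <- function(R) sum(R * g$w * 2 * pi * (R * g$x) * pdf_r(R * g$x))
  total <- mass(upper)
  target <- level * total          # level = 1 returns the support radius
  lo <- 0; hi <- upper
  while (hi - lo > 1e-9 * max(1, upper)) {
    mid <- (lo + hi) / 2
    if (mass(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @rdname mass_radius
#' @param params an [analytic_params()].
#' @return `mcp_radius`: a `home_range` list with `R95` (units of L),
#'   `buffer_zone` (TRUE when `R95 < 1/2`, i.e. a gap opens between
#'   adjacent territories) and `exclusive_fraction`.
#' @export
mcp_radius <- function(params, level = 0.95) {
  upper <- radius_cutoff(params$eps)
  R95 <- mass_radius(function(r) marginal_pdf_2d(r, params), level, upper)
  structure(list(R95 = R95, level = level,
                 buffer_zone = R95 < 0.5,
                 exclusive_fraction = exclusive_area_fraction(R95),
                 beta = params$beta, eps = params$eps),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat("<home_range> R", x$level * 100, " = ", signif(x$R95, 5),
      " L;  buffer zone: ", x$buffer_zone,
      ";  exclusive fraction: ", signif(x$exclusive_fraction, 4), "\n",
      sep = "")
  invisible(x)
}

#' Exclusive area fraction of a hexagonally packed home range
#'
#' Fraction of a home-range disc of radius `R` (units of the CP spacing)
#' not overlapped by the six identical discs centred on the hexagonal
#' neighbour CPs at unit distance. Disjoint discs (`R <= 1/2`) give 1. For
#' `R < 1/sqrt(3)` the overlaps are pairwise-disjoint and the circle-circle
#' lens formula is exact; beyond that triple overlaps appear and the
#' fraction is computed by exact polar integration of the exclusive region
#' (12-fold symmetry), which remains deterministic.
#'
#' @param R home-range radius in (0, 1).
#' @return fraction in `[0, 1]`.
#' @export
exclusive_area_fraction <- function(R) {
  vapply(R, function(R1) {
    stopifnot(R1 > 0, R1 < 1)
    if (R1 <= 0.5) return(1)
    if (R1 < 1 / sqrt(3)) {
      lens <- 2 * R1^2 * acos(1 / (2 * R1)) - 0.5 * sqrt(4 * R1^2 - 1)
      return(max(0, 1 - 6 * lens / (pi * R1^2)))
    }
    # polar integration over one 30-degree sector (12-fold symmetry):
    # along bearing theta the exclusive extent ends where the ray enters the
    # nearest neighbour disc: rho^2 - 2 rho cos(theta_k) + 1 - R^2 = 0
    g <- pracma::gaussLegendre(200, 0, pi / 6)
    th_nb <- (0:5) * pi / 3
    rho_ex <- vapply(g$x, function(th) {
      r_in <- suppressWarnings(vapply(th_nb, function(tn) {
        ct <- cos(th - tn)
        disc <- ct^2 + R1^2 - 1
        if (disc <= 0) Inf else ct - sqrt(disc)
      }, numeric(1)))
      min(R1, r_in[r_in > 0], Inf)
    }, numeric(1))
    area <- 12 * sum(g$w * rho_ex^2 / 2)
    max(0, min(1, area / (pi * R1^2)))
  }, numeric(1))
}

#' Sigmoid summary of home-range radius against drift strength
#'
#' Least-squares fit of the 4-coefficient sigmoid
#' `y = A + (B - A) / (1 + exp(-(x - x0) / s))` to a home-range radius
#' curve (one curve per Z in practice).
#'
#' @param x,y data (>= 6 points).
#' @return list with `coefficients` (A, B, x0, s), `residual_norm`,
#'   `fitted` and the `nls` fit object.
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 6)
  if (diff(range(y)) < 1e-12 * max(abs(y), 1))
    stop("degenerate (flat) curve: sigmoid is unidentifiable", call. = FALSE)
  ord <- order(x); x <- x[ord]; y <- y[ord]
  start <- list(A = y[1], B = y[length(y)], x0 = median(x),
                s = diff(range(x)) / 4 * sign(y[length(y)] - y[1] + 1e-12))
  fit <- minpack.lm::nlsLM(y ~ A + (B - A) / (1 + exp(-(x - x0) / s)),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- coef(fit)
  list(coefficients = co, residual_norm = sqrt(sum(resid(fit)^2)),
       fitted = fitted(fit), fit = fit)
}

#' Map an allometric exclusive-area law onto the scent-time ratio
#'
#' Composes a user-supplied allometric law for the exclusive area fraction,
#' `fraction = f_ref * (mass / mass_ref)^exponent`, with the model geometry
#' and a calibration surface: each target fraction is inverted to a
#' home-range radius, then (at each calibrated drift strength `beta`) to
#' the `Z = T_AS / K2` ratio that realises it. No allometric exponent is
#' built in; the caller supplies it.
#'
#' @param calibration a `calibration_map`.
#' @param masses mass grid (arbitrary units).
#' @param exponent allometric exponent of the fraction-mass law.
#' @param f_ref fraction at `mass_ref`.
#' @param mass_ref reference mass (default: first of `masses`).
#' @param betas drift strengths at which to invert (default: the
#'   calibrated betas).
#' @param level home-range mass level.
#' @return long tibble: `mass`, `target_fraction`, `beta`, `Z`,
#'   `attainable` (rows outside the calibrated range are flagged, Z = NA).
#' @export
exclusive_fraction_vs_mass <- function(calibration, masses, exponent,
                                       f_ref = 0.8, mass_ref = masses[1],
                                       betas = NULL, level = 0.95) {
  stopifnot(all(masses > 0), f_ref > 0, f_ref <= 1)
  if (is.null(betas))
    betas <- unique(calibration$lines$beta[!is.na(calibration$lines$slope)])
  zr <- calibration$meta$Z_range
  frac_of_Z <- function(beta, Z) {
    ln <- interp_line(calibration, beta)
    msd <- exp(ln$intercept + ln$slope * log(Z))
    eps <- eps_from_radius_msd(msd)
    mcp_radius(analytic_params(beta, eps), level)$exclusive_fraction
  }
  rows <- list()
  for (m in masses) {
    target <- min(f_ref * (m / mass_ref)^exponent, 1)
    for (b in betas) {
      f_lo <- frac_of_Z(b, zr[1]); f_hi <- frac_of_Z(b, zr[2])
      rng <- sort(c(f_lo, f_hi))
      if (target < rng[1] - 1e-9 || target > rng[2] + 1e-9) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          mass = m, target_fraction = target, beta = b, Z = NA_real_,
          attainable = FALSE)
        next
      }
      Z <- if (abs(f_hi - f_lo) < 1e-12) zr[1] else
        uniroot(function(z) frac_of_Z(b, z) - target, zr, tol = 1e-7)$root
      rows[[length(rows) + 1]] <- tibble::tibble(
        mass = m, target_fraction = target, beta = b, Z = Z,
        attainable = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Empirical minimum convex polygon home range
#'
#' The data-work counterpart of the analytic mass radius: peels the
#' `1 - level` fraction of fixes farthest from the centroid and returns the
#' convex hull and its area.
#'
#' @param x,y fix coordinates.
#' @param level retained fraction.
#' @return list with `hull` (tibble of vertices) and `area`.
#' @export
mcp_hull <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  keep <- d <= quantile(d, level)
  h <- grDevices::chull(x[keep], y[keep])
  hx <- x[keep][h]; hy <- y[keep][h]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  list(hull = tibble::tibble(x = hx, y = hy), area = area)
}
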