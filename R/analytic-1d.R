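# Reduced adiabatic analytic model in 1D.
#
# Coordinates are dimensionless: the focal animal's CP sits at 0, the
# conspecific CPs at -1 and +1 (all lengths divided by the CP spacing L).
# The left border z1 lives on (-1, 0), the right border z2 on (0, 1). The
# border distributions are method-of-images sums of Gaussians of width
# parameter eps (exp(-x^2/eps^2) convention; free-space variance eps^2/2)
# centred on the midpoints -1/2 and +1/2, reflected at the CPs. The animal
# inside fixed borders follows the Holgate-Okubo localising tendency with
# dimensionless drift strength beta = v L / D, giving an exponential
# conditional density.

#' Parameters of the reduced analytic models
#'
#' @param beta dimensionless drift strength towards the CP (`v L / D`,
#'   `>= 0`).
#' @param eps dimensionless border-spread parameter (> 0): the single
#'   parameter into which the border generalised diffusion constant `K_b`
#'   and the territory-size restoring rate `lambda` collapse at steady
#'   state, `eps^2 = K_b / lambda`. The steady border density is (up to
#'   image terms) a Gaussian `exp(-(z + 1/2)^2 / eps^2)`.
#' @param K_b,lambda optional dimensional pair for transient border work;
#'   if both are given they must satisfy `eps^2 = K_b / lambda`.
#' @return an `analytic_params` list.
#' @export
analytic_params <- function(beta, eps, K_b = NULL, lambda = NULL) {
  stopifnot(beta >= 0, eps > 0)
  if (!is.null(lambda)) stopifnot(lambda > 0)
  if (!is.null(K_b)) stopifnot(K_b >= 0)
  if (!is.null(K_b) && !is.null(lambda) && abs(K_b / lambda - eps^2) > 1e-8 * eps^2)
    stop("inconsistent (K_b, lambda): eps^2 must equal K_b / lambda", call. = FALSE)
  structure(list(beta = beta, eps = eps, K_b = K_b, lambda = lambda),
            class = "analytic_params")
}

# number of image pairs needed for an absolute tail below `tail`
n_images_needed <- function(sd2, tail = 1e-12) {
  # terms at distance d contribute < exp(-d^2 / (2 sd2)); solve for d
  d <- sqrt(max(2 * sd2 * log(1 / tail), 0)) + 2
  max(2L, as.integer(ceiling(d / 2)) + 1L)
}

# image-series density on (-1, 0) for a Gaussian of variance s2 centred at m,
# reflected at the CPs 0 and -1 (image families {m + 2n} and {-m + 2n})
image_series <- function(z, m, s2, tail = 1e-12) {
  N <- n_images_needed(s2, tail)
  out <- numeric(length(z))
  for (n in -N:N)
    out <- out + exp(-(z - m - 2 * n)^2 / (2 * s2)) +
      exp(-(z + m - 2 * n)^2 / (2 * s2))
  out / sqrt(2 * pi * s2)
}

#' Steady-state territory border density (1D)
#'
#' Image-series steady state of the border Fokker-Planck model: a Gaussian
#' of width `eps` centred on the inter-CP midpoint, reflected at the CPs so
#' the border cannot cross them. The left border is supported on (-1, 0),
#' the right border on (0, 1); outside its support the density is 0 by
#' contract. The series is truncated adaptively with an absolute tail below
#' `tail`.
#'
#' @param z dimensionless border position(s).
#' @param params an [analytic_params()] (only `eps` is used).
#' @param side `"left"` or `"right"`.
#' @param tail certified truncation tail bound.
#' @return density values.
#' @export
border_pdf <- function(z, params, side = c("left", "right"), tail = 1e-12) {
  side <- match.arg(side)
  eps <- params$eps
  zz <- if (side == "right") -z else z
  out <- numeric(length(z))
  ok <- zz > -1 & zz < 0
  out[ok] <- image_series(zz[ok], m = -0.5, s2 = eps^2 / 2, tail = tail)
  out
}

#' Transient territory border density (1D)
#'
#' Time-dependent border density from a point initial condition at `z0`,
#' under border diffusion constant `K_b` and restoring rate `lambda`
#' (Ornstein-Uhlenbeck relaxation towards the midpoint: mean
#' `m(t) = -1/2 + (z0 + 1/2) exp(-2 lambda t)`, variance
#' `s^2(t) = (K_b / (2 lambda)) (1 - exp(-4 lambda t))`), with the CPs at
#' -1 and 0 handled by the method of images. Two algebraically equivalent
#' representations are available: the image series, and its Poisson-summation
#' (cosine series) resummation; they agree to machine precision and the
#' `t -> Inf` limit is [border_pdf()].
#'
#' @param z dimensionless position(s) on (-1, 0) (left border coordinates).
#' @param t time (> 0).
#' @param params [analytic_params()] carrying `K_b` and `lambda`.
#' @param z0 initial border position in (-1, 0); defaults to the midpoint.
#' @param representation `"images"` or `"poisson"`.
#' @param tail truncation tail bound.
#' @return density values on (-1, 0).
#' @export
border_pdf_transient <- function(z, t, params, z0 = -0.5,
                                 representation = c("images", "poisson"),
                                 tail = 1e-12) {
  representation <- match.arg(representation)
  if (is.null(params$K_b) || is.null(params$lambda))
    stop("transient border densities need `K_b` and `lambda` in the params",
         call. = FALSE)
  stopifnot(t > 0, z0 > -1, z0 < 0)
  lam <- params$lambda
  m <- -0.5 + (z0 + 0.5) * exp(-2 * lam * t)
  s2 <- params$K_b / (2 * lam) * (1 - exp(-4 * lam * t))
  out <- numeric(length(z))
  ok <- z > -1 & z < 0
  if (representation == "images") {
    out[ok] <- image_series(z[ok], m = m, s2 = s2, tail = tail)
  } else {
    # Poisson summation of the two image families:
    # W(z) = 1 + 2 sum_k exp(-pi^2 k^2 s^2 / 2) cos(pi k z) cos(pi k m)
    kmax <- max(3L, ceiling(sqrt(2 * log(1 / tail)) / (pi * sqrt(s2))))
    if (kmax > 1e6) stop("Poisson representation truncation budget exceeded ",
                         "(needs k_max = ", kmax, "); achieved tail bound ",
                         signif(exp(-pi^2 * 1e12 * s2 / 2), 3), call. = FALSE)
    k <- seq_len(kmax)
    w <- exp(-pi^2 * k^2 * s2 / 2) * cos(pi * k * m)
    out[ok] <- 1 + 2 * as.vector(cos(pi * outer(z[ok], k)) %*% w)
  }
  out
}

#' Animal density inside fixed borders (1D Holgate-Okubo)
#'
#' Steady state of diffusion with constant-magnitude drift `beta` towards
#' the CP at 0, confined between borders `z1 < 0 < z2`: proportional to
#' `exp(-beta |z|)`, normalised in closed form on `(z1, z2)` and zero
#' outside. `beta = 0` gives the uniform density.
#'
#' @param z position(s).
#' @param z1,z2 border positions, `z1 < 0 < z2`.
#' @param beta dimensionless drift strength (>= 0).
#' @return density values.
#' @export
animal_conditional_pdf <- function(z, z1, z2, beta) {
  if (z1 >= z2) stop("need z1 < z2", call. = FALSE)
  stopifnot(z1 < 0, z2 > 0, beta >= 0)
  out <- numeric(length(z))
  ok <- z > z1 & z < z2
  if (beta == 0) out[ok] <- 1 / (z2 - z1)
  else out[ok] <- beta * exp(-beta * abs(z[ok])) /
      (2 - exp(beta * z1) - exp(-beta * z2))
  out
}

#' Joint density of the two borders and the animal (1D)
#'
#' Adiabatic product form: left border density times right border density
#' times the conditional animal density, gated by Heaviside factors so the
#' animal lies strictly between the borders.
#'
#' @param z1,z2,z border and animal positions (recycled to common length).
#' @param params [analytic_params()].
#' @return joint density values.
#' @export
joint_pdf <- function(z1, z2, z, params) {
  n <- max(length(z1), length(z2), length(z))
  z1 <- rep_len(z1, n); z2 <- rep_len(z2, n); z <- rep_len(z, n)
  out <- numeric(n)
  ok <- z1 > -1 & z1 < 0 & z2 > 0 & z2 < 1 & z > z1 & z < z2
  if (any(ok)) {
    cond <- vapply(which(ok), function(i)
      animal_conditional_pdf(z[i], z1[i], z2[i], params$beta), numeric(1))
    out[ok] <- border_pdf(z1[ok], params, "left") *
      border_pdf(z2[ok], params, "right") * cond
  }
  out
}

#' Marginal space-use density of the animal (1D)
#'
#' The long-time marginal obtained by integrating the joint density over all
#' border positions: the stationary utilisation distribution of a territorial
#' central-place forager on (-1, 1). It vanishes at the conspecific CPs
#' z = -1 and z = 1, where the animal cannot tread.
#'
#' @param z position(s) in (-1, 1).
#' @param params [analytic_params()].
#' @param n_nodes Gauss-Legendre panel order for each border integral.
#' @return density values.
#' @export
marginal_pdf_1d <- function(z, params, n_nodes = 48) {
  beta <- params$beta
  eps <- params$eps
  g <- pracma::gaussLegendre(n_nodes, 0, 1)   # reference nodes on (0, 1)
  # node/weight pair for one border integral; for narrow border densities
  # the integration runs in the scaled variable (border = mid + eps * u)
  border_nodes <- function(lo, hi, mid, side) {
    if (eps < 0.08) {
      ulo <- max(-8, (lo - mid) / eps); uhi <- min(8, (hi - mid) / eps)
      if (ulo >= uhi) return(NULL)
      gu <- pracma::gaussLegendre(n_nodes, ulo, uhi)
      list(x = mid + eps * gu$x, w = gu$w * exp(-gu$x^2) / sqrt(pi))
    } else {
      gx <- lo + (hi - lo) * g$x
      list(x = gx, w = (hi - lo) * g$w * border_pdf(gx, params, side))
    }
  }
  vapply(z, function(zz) {
    if (zz <= -1 || zz >= 1) return(0)
    n1 <- border_nodes(-1, min(zz, 0), -0.5, "left")
    n2 <- border_nodes(max(zz, 0), 1, 0.5, "right")
    if (is.null(n1) || is.null(n2)) return(0)
    if (beta == 0) {
      inv <- outer(n1$x, n2$x, function(a, b) 1 / (b - a))
    } else {
      inv <- beta * exp(-beta * abs(zz)) /
        outer(n1$x, n2$x, function(a, b) 2 - exp(beta * a) - exp(-beta * b))
    }
    as.numeric(n1$w %*% inv %*% n2$w)
  }, numeric(1))
}

#' Half-territory marginal with one border pinned (1D reduced model)
#'
#' `reduced_marginal_half()` evaluates the marginal of the animal on the
#' right-hand half of its territory when the left border is pinned at the CP
#' by a Dirac mass: `q(z) = beta exp(-beta z) \int_z^1 C2(z2) /
#' (1 - exp(-beta z2)) dz2` on (0, 1). This is the form compared with the
#' reaction-diffusion territory model. `reduced_marginal_limit()` is its
#' one-parameter collapse `beta -> 0`, which evaluates in closed series form
#' through the cosine integral Ci:
#' `q(z) = ln(1/z) + 2 sum_j (-1)^j exp(-pi^2 j^2 eps^2) [Ci(2 pi j) -
#' Ci(2 pi j z)]`.
#'
#' @param z position(s) in (0, 1).
#' @param beta drift strength (>= 0).
#' @param eps border-spread parameter (> 0).
#' @param n_nodes Gauss-Legendre order for the border integral.
#' @return density values on (0, 1).
#' @export
reduced_marginal_half <- function(z, beta, eps, n_nodes = 64) {
  stopifnot(eps > 0, beta >= 0)
  params <- analytic_params(beta, eps)
  g <- pracma::gaussLegendre(n_nodes, 0, 1)
  kernel <- function(x) {
    if (beta < 1e-8) 1 / x else 1 / (-expm1(-beta * x))
  }
  pref <- function(zz) {
    if (beta < 1e-8) rep(1, length(zz)) else beta * exp(-beta * zz)
  }
  inner <- numeric(length(z))
  inside <- z > 0 & z < 1
  if (eps < 0.08) {
    # the border density is a near-Gaussian spike at 1/2 (image terms are
    # below 1e-17 here); integrate in the scaled variable z2 = 1/2 + eps u.
    # Below the spike the inner integral is a constant.
    uhi <- min(8, 0.5 / eps)
    g0 <- pracma::gaussLegendre(n_nodes, -8, uhi)
    w0 <- g0$w * exp(-g0$x^2) / sqrt(pi)
    I0 <- sum(w0 * kernel(0.5 + eps * g0$x))
    low <- inside & z <= 0.5 - 8 * eps
    inner[low] <- I0
    spike <- inside & !low & z < 0.5 + uhi * eps
    inner[spike] <- vapply(z[spike], function(zz) {
      gu <- pracma::gaussLegendre(n_nodes, (zz - 0.5) / eps, uhi)
      sum(gu$w * exp(-gu$x^2) / sqrt(pi) * kernel(0.5 + eps * gu$x))
    }, numeric(1))
  } else {
    # integrate in log(z2): the kernel behaves like 1/z2 near the CP
    inner[inside] <- vapply(z[inside], function(zz) {
      u <- log(zz) * (1 - g$x)          # nodes from log(zz) to 0
      x <- exp(u)
      sum(-log(zz) * g$w * x * border_pdf(x, params, "right") * kernel(x))
    }, numeric(1))
  }
  out <- numeric(length(z))
  out[inside] <- pref(z[inside]) * inner[inside]
  out
}

#' @rdname reduced_marginal_half
#' @export
reduced_marginal_limit <- function(z, eps) {
  stopifnot(eps > 0)
  jmax <- min(5000L, max(5L, ceiling(2.5 / eps) + 10L))
  j <- seq_len(jmax)
  damp <- (-1)^j * exp(-pi^2 * j^2 * eps^2)
  ci_2pij <- vapply(2 * pi * j, pracma::Ci, numeric(1))
  vapply(z, function(zz) {
    if (zz <= 0 || zz >= 1) return(0)
    ci_z <- vapply(2 * pi * j * zz, pracma::Ci, numeric(1))
    log(1 / zz) + 2 * sum(damp * (ci_2pij - ci_z))
  }, numeric(1))
}

#' Saturation border MSD implied by the border-spread parameter (1D)
#'
#' The stationary mean square displacement of a territory border about its
#' mean position (the inter-CP midpoint), computed by quadrature of the
#' image-series border density. This is the 1D analogue of the
#' radius-variance relation used by the inference programme in 2D; its
#' small-`eps` limit is `eps^2 / 2`. `eps_from_border_msd_1d()` inverts it.
#'
#' @param eps border-spread parameter (> 0).
#' @return dimensionless saturation MSD (units of L^2).
#' @export
border_msd_1d <- function(eps) {
  vapply(eps, function(e) {
    p <- analytic_params(0, e)
    integrate(function(z) (z + 0.5)^2 * border_pdf(z, p, "left"),
              -1, 0, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' @rdname border_msd_1d
#' @param msd dimensionless saturation border MSD (0 < msd < 1/12-ish; the
#'   attainable range is capped by the uniform-border limit).
#' @export
eps_from_border_msd_1d <- function(msd) {
  vapply(msd, function(m) {
    stopifnot(m > 0)
    upper <- 1 / 12  # variance of the uniform density on a unit interval
    if (m >= upper * 0.999)
      stop("border MSD ", m, " is at or above the uniform-border limit 1/12",
           call. = FALSE)
    uniroot(function(e) border_msd_1d(e) - m, c(1e-4, 20),
            tol = 1e-10)$root
  }, numeric(1))
}
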