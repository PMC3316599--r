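#' Read relocation data from CSV
#'
#' Plain planar telemetry: columns `animal_id`, `x`, `y`, `t` in consistent
#' length/time units. Rows with non-finite coordinates are dropped (with a
#' message); timestamps out of order within an animal are sorted with a
#' warning.
#'
#' @param path CSV file path.
#' @return a `relocation` tibble.
#' @export
read_relocations <- function(path) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("empty relocation file: ", path, call. = FALSE)
  need <- c("animal_id", "x", "y", "t")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- is.finite(df$x) & is.finite(df$y) & is.finite(df$t)
  if (any(!ok)) message("dropped ", sum(!ok), " row(s) with non-finite coordinates")
  df <- df[ok, need]
  df <- dplyr::group_by(tibble::as_tibble(df), .data$animal_id)
  unsorted <- dplyr::summarise(df, u = is.unsorted(.data$t))$u
  if (any(unsorted)) warning("timestamps out of order for ", sum(unsorted),
                             " animal(s); sorted", call. = FALSE)
  dplyr::ungroup(dplyr::arrange(df, .data$t, .by_group = TRUE))
}

#' Estimate central places and CP spacing from relocations
#'
#' CP per animal is the coordinate-wise median of its fixes (a robust mode
#' proxy); `L` is the median nearest-neighbour distance among the estimated
#' CPs (median rather than mean so one non-adjacent animal cannot inflate
#' the spacing). Both can be overridden.
#'
#' @param data relocation tibble (`animal_id`, `x`, `y`, `t`).
#' @param cp optional named list / data frame of CPs overriding the estimate.
#' @param L optional known CP spacing (required if only one animal).
#' @return list with `cp` (tibble animal_id, x, y) and `L`.
#' @export
estimate_cp_and_L <- function(data, cp = NULL, L = NULL) {
  if (is.null(cp)) {
    cp <- dplyr::summarise(dplyr::group_by(data, .data$animal_id),
                           x = median(.data$x), y = median(.data$y),
                           .groups = "drop")
  } else if (is.numeric(cp) && length(cp) == 2) {
    cp <- tibble::tibble(animal_id = unique(data$animal_id),
                         x = cp[1], y = cp[2])
  } else cp <- tibble::as_tibble(cp)
  if (is.null(L)) {
    if (nrow(cp) < 2)
      stop("a single animal needs a user-supplied CP spacing `L`", call. = FALSE)
    d <- as.matrix(dist(cp[, c("x", "y")]))
    diag(d) <- Inf
    L <- median(apply(d, 1, min))
  }
  stopifnot(L > 0)
  list(cp = cp, L = L)
}

#' Animal MSD saturation check
#'
#' The inference programme requires the animal (not border) MSD to
#' saturate; otherwise the steady-state marginal cannot be fitted and the
#' pipeline stops with guidance. For a single track the robust diagnostic
#' is the time-averaged MSD over lags,
#' `msd(tau) = mean_t |x(t + tau) - x(t)|^2`, which grows linearly for an
#' unconfined walker and flattens at twice the positional variance for an
#' animal with a stable home range; the border saturation slope test is
#' applied to that curve.
#'
#' @param data relocation tibble.
#' @param cp optional CP override (kept for interface symmetry; the lag
#'   MSD itself does not need the CP).
#' @param n_lags number of sample lags evaluated (>= 20).
#' @param min_fixes minimum fixes per animal.
#' @inheritParams detect_saturation
#' @return list with `saturated` (the decision, taken on the lag-MSD curve
#'   pooled across animals), a `per_animal` diagnostic tibble and the
#'   pooled `curve`.
#' @export
check_msd_saturation <- function(data, cp = NULL, n_lags = 30, min_fixes = 30,
                                 window_fraction = 0.5, slope_tol = 0.12) {
  cnt <- dplyr::count(data, .data$animal_id)
  if (any(cnt$n < min_fixes))
    stop("animal(s) with fewer than ", min_fixes, " fixes: ",
         paste(cnt$animal_id[cnt$n < min_fixes], collapse = ", "), call. = FALSE)
  if (n_lags < 20) stop("need at least 20 lags", call. = FALSE)
  lag_curve <- function(d) {
    d <- d[order(d$t), ]
    n <- nrow(d)
    lags <- unique(round(seq(1, max(n_lags, floor(n / 3)), length.out = n_lags)))
    lags <- lags[lags < n]
    dt <- median(diff(d$t))
    tibble::tibble(lag_index = seq_along(lags), time = lags * dt,
                   msd = vapply(lags, function(k) {
                     i <- seq_len(n - k)
                     mean((d$x[i + k] - d$x[i])^2 + (d$y[i + k] - d$y[i])^2)
                   }, numeric(1)))
  }
  curves <- lapply(split(data, data$animal_id), lag_curve)
  per <- dplyr::bind_rows(lapply(names(curves), function(id) {
    cu <- curves[[id]]
    if (all(cu$msd == 0))
      return(tibble::tibble(animal_id = id, saturated = TRUE,
                            msd_level = 0, rel_slope = 0))
    s <- detect_saturation(cu, window_fraction, slope_tol)
    tibble::tibble(animal_id = id, saturated = s$saturated,
                   msd_level = s$value, rel_slope = s$rel_slope)
  }))
  pooled <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(curves), .data$lag_index),
    time = mean(.data$time), msd = mean(.data$msd), .groups = "drop")
  overall <- if (all(pooled$msd == 0))
    list(saturated = TRUE, value = 0, rel_slope = 0)
  else detect_saturation(pooled, window_fraction, slope_tol)
  out <- list(saturated = overall$saturated, per_animal = per,
              curve = pooled, msd_level = overall$value)
  if (!out$saturated)
    out$guidance <- paste("animal MSD has not saturated: the steady-state",
                          "marginal cannot be fitted; methods for",
                          "non-saturating (continually growing) home ranges",
                          "are needed instead")
  out
}

# negative log-likelihood of dimensionless radii under the 2D marginal;
# r may carry multiplicities w (binned data), which leaves the likelihood
# unchanged up to binning resolution but makes large fits cheap
marginal_nll <- function(par, r, w = NULL, n_nodes = 64) {
  beta <- par[1]; eps <- par[2]
  if (beta < 0 || eps <= 0) return(1e10)
  if (is.null(w)) w <- rep(1, length(r))
  q <- marginal_pdf_2d(r, analytic_params(beta, eps), n_nodes = n_nodes)
  if (any(!is.finite(q))) return(1e10)
  q <- pmax(q, 1e-300)        # keep the surface finite far outside support
  -sum(w * (log(2 * pi * r) + log(q)))
}

# collapse radii to unique values with multiplicities (lattice data repeat
# heavily); caps the support at `max_bins` quantile bins otherwise
bin_radii <- function(r, max_bins = 512) {
  u <- sort(unique(r))
  if (length(u) <= max_bins) {
    w <- as.numeric(table(match(r, u)))
    return(list(r = u, w = w))
  }
  br <- unique(quantile(u, seq(0, 1, length.out = max_bins + 1)))
  mid <- (br[-1] + br[-length(br)]) / 2
  idx <- findInterval(r, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(r = mid[sort(unique(idx))], w = as.numeric(table(idx)))
}

#' Fit the 2D marginal to relocation data
#'
#' Maximum likelihood of the dimensionless radial distances r/L (about
#' the CP) under the stationary 2D marginal, over the drift strength `beta`
#' and border-spread `eps`. Rotational symmetry makes the fit purely radial;
#' temporal autocorrelation is not modelled in the likelihood but an
#' effective-sample-size diagnostic is reported. Multi-start optimisation
#' with Hessian-based standard errors.
#'
#' @param data relocation tibble (one or more animals; radii are pooled per
#'   animal and the fit is per animal unless `pool = TRUE`).
#' @param cp CP tibble or vector; estimated if `NULL`.
#' @param L CP spacing; estimated if `NULL` (needs >= 2 animals).
#' @param pool fit all animals jointly (single territory shape) if TRUE.
#' @param starts matrix of optimisation starts (columns beta, eps).
#' @param n_nodes quadrature order of the marginal evaluation.
#' @return a `marginal_fit` object (see [tidy.marginal_fit()]); when several
#'   animals are fitted separately, a list of fits.
#' @export
fit_marginal <- function(data, cp = NULL, L = NULL, pool = TRUE,
                         starts = NULL, n_nodes = 64) {
  est <- estimate_cp_and_L(data, cp = cp, L = L)
  df <- dplyr::left_join(data, est$cp, by = "animal_id", suffix = c("", ".cp"))
  r <- sqrt((df$x - df$x.cp)^2 + (df$y - df$y.cp)^2) / est$L
  r <- pmax(r, 1e-9)
  if (!pool) {
    fits <- lapply(split(seq_len(nrow(df)), df$animal_id), function(ix)
      fit_marginal_radii(r[ix], est$L, starts, n_nodes))
    return(fits)
  }
  fit <- fit_marginal_radii(r, est$L, starts, n_nodes)
  fit$cp <- est$cp
  fit
}

fit_marginal_radii <- function(r, L, starts = NULL, n_nodes = 64) {
  if (is.null(starts)) {
    e0 <- min(max(sd(r), 0.02), 0.8)
    starts <- rbind(c(0.5, e0), c(2, e0), c(8, e0), c(2, 0.1))
  }
  bn <- bin_radii(r)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    op <- tryCatch(
      optim(starts[s, ], marginal_nll, r = bn$r, w = bn$w, n_nodes = n_nodes,
            method = "L-BFGS-B", lower = c(0, 5e-3), upper = c(60, 2),
            hessian = TRUE),
      error = function(e) NULL)
    if (!is.null(op) && op$value < 1e9 &&
        (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best))
    stop("marginal fit failed to converge from all starts", call. = FALSE)
  vc <- tryCatch(solve(best$hessian), error = function(e)
    matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  params <- analytic_params(best$par[1], best$par[2])
  ks <- ks_distance(sort(r), radial_cdf_2d(params))
  rho1 <- tryCatch(acf(r, lag.max = 1, plot = FALSE)$acf[2],
                   error = function(e) 0)
  ess <- length(r) * max((1 - rho1) / (1 + rho1), 1e-3)
  structure(list(beta_hat = best$par[1], eps_hat = best$par[2],
                 eps2_hat = best$par[2]^2,
                 se = c(beta = se[1], eps = se[2]), vcov = vc,
                 loglik = -best$value, n = length(r), ks = ks, ess = ess,
                 L = L, r = r, params = params, convergence = best$convergence),
            class = "marginal_fit")
}

#' Kolmogorov-Smirnov distance to a reference CDF
#'
#' @param x sample values.
#' @param cdf function giving the reference CDF.
#' @return the KS statistic `sup |F_n - F|`.
#' @export
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat("<marginal_fit> beta = ", signif(x$beta_hat, 4), " (se ",
      signif(x$se[1], 3), "), eps = ", signif(x$eps_hat, 4), " (se ",
      signif(x$se[2], 3), "), n = ", x$n, ", KS = ", signif(x$ks, 3),
      "\n", sep = "")
  invisible(x)
}

#' Tidy methods for fitted objects
#'
#' @param x a `marginal_fit` or `inference_result`.
#' @param ... unused.
#' @return a tibble of parameter estimates (`tidy`) or one-row fit summary
#'   (`glance`).
#' @export
#' @method tidy marginal_fit
tidy.marginal_fit <- function(x, ...) {
  tibble::tibble(term = c("beta", "eps", "eps2"),
                 estimate = c(x$beta_hat, x$eps_hat, x$eps2_hat),
                 std.error = c(x$se["beta"], x$se["eps"],
                               2 * x$eps_hat * x$se["eps"]))
}

#' @rdname tidy.marginal_fit
#' @export
#' @method glance marginal_fit
glance.marginal_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, ks = x$ks, ess = x$ess,
                 convergence = x$convergence)
}

#' Infer the active scent time from a fitted marginal
#'
#' The final steps of the inference programme: the fitted border-spread
#' `eps` gives the theoretically expected saturation MSD of the territory
#' radius; that value, equal to the simulation border MSD, is pushed through
#' the calibration surface at the fitted `beta` to recover
#' `Z = T_AS / K2`; the user-supplied diffusion constant `D` and population
#' density `rho` then give the active scent time
#' `T_AS = Z / (4 D rho)`. Uncertainty combines the fit and calibration
#' contributions by the delta method.
#'
#' @param fit a `marginal_fit`.
#' @param calibration a `calibration_map` (2D).
#' @param D animal diffusion constant (length^2 / time), from the data.
#' @param rho animal density (1 / length^2), from the data.
#' @param saturation result of [check_msd_saturation()]; if supplied and
#'   not saturated, inference is refused.
#' @param extrapolate slack factor on the calibrated Z range passed to
#'   [lookup_Z()].
#' @return an `inference_result` with `T_AS` (and interval), `Z_hat`,
#'   `msd_sat`, the fitted parameters and provenance.
#' @export
infer_active_scent_time <- function(fit, calibration, D, rho,
                                    saturation = NULL, extrapolate = 1.25) {
  if (missing(D) || missing(rho) || is.null(D) || is.null(rho))
    stop("both `D` and `rho` must be supplied by the user", call. = FALSE)
  stopifnot(D > 0, rho > 0)
  if (!is.null(saturation) && !isTRUE(saturation$saturated))
    stop("animal MSD not saturated; ", saturation$guidance, call. = FALSE)
  msd_sat <- radius_msd_from_params(eps = fit$eps_hat)
  zres <- lookup_Z(calibration, fit$beta_hat, msd_sat,
                   extrapolate = extrapolate)
  K2 <- 1 / (4 * D * rho)
  # delta method: propagate the fit uncertainty in (beta, eps) and the
  # calibration residual scatter to log Z
  h <- 1e-5
  dmsd <- (radius_msd_from_params(eps = fit$eps_hat + h) - msd_sat) / h
  se_logmsd <- abs(dmsd / msd_sat) * fit$se["eps"]
  if (!is.null(calibration$inverse)) {
    co <- calibration$inverse$coef
    se_logZ_fit <- sqrt((co[2] * fit$se["beta"])^2 + (co[3] * se_logmsd)^2)
    se_logZ_cal <- calibration$inverse$sigma
  } else {
    ln <- interp_line(calibration, fit$beta_hat)
    se_logZ_fit <- se_logmsd / abs(ln$slope)
    se_logZ_cal <- ifelse(is.finite(ln$sigma), ln$sigma, 0) / abs(ln$slope)
  }
  se_logZ <- unname(sqrt(se_logZ_fit^2 + se_logZ_cal^2))
  q <- qnorm(0.975)
  structure(list(beta_hat = fit$beta_hat, eps2_hat = fit$eps2_hat,
                 msd_sat = msd_sat, Z_hat = zres$Z,
                 Z_interval = c(exp(log(zres$Z) - q * se_logZ),
                                exp(log(zres$Z) + q * se_logZ)),
                 T_AS = zres$Z * K2,
                 T_AS_interval = zres$Z * K2 *
                   exp(c(-1, 1) * q * se_logZ),
                 K2 = K2, D = D, rho = rho, L = fit$L,
                 diagnostics = list(loglik = fit$loglik, ks = fit$ks,
                                    ess = fit$ess, n = fit$n),
                 calibration_meta = calibration$meta),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result>\n",
      "  beta_hat = ", signif(x$beta_hat, 4),
      ", eps2_hat = ", signif(x$eps2_hat, 4), "\n",
      "  saturation MSD (L^2 units) = ", signif(x$msd_sat, 4), "\n",
      "  Z_hat = ", signif(x$Z_hat, 4), "  [",
      signif(x$Z_interval[1], 4), ", ", signif(x$Z_interval[2], 4), "]\n",
      "  active scent time T_AS = ", signif(x$T_AS, 4), "  [",
      signif(x$T_AS_interval[1], 4), ", ", signif(x$T_AS_interval[2], 4),
      "]\n", sep = "")
  invisible(x)
}

#' @rdname tidy.marginal_fit
#' @export
#' @method tidy inference_result
tidy.inference_result <- function(x, ...) {
  tibble::tibble(term = c("beta", "eps2", "msd_sat", "Z", "T_AS"),
                 estimate = c(x$beta_hat, x$eps2_hat, x$msd_sat, x$Z_hat,
                              x$T_AS),
                 conf.low = c(NA, NA, NA, x$Z_interval[1], x$T_AS_interval[1]),
                 conf.high = c(NA, NA, NA, x$Z_interval[2], x$T_AS_interval[2]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
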