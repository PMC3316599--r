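#' Build the saturation-MSD calibration surface
#'
#' Runs ensembles of simulations over a grid of dimensionless parameters
#' `(beta, Z)` until the border MSD saturates, and stores the dimensionless
#' saturation MSD of the border observable (divided by L^2) with a fitted
#' per-`beta` trend line, straight in log(saturation MSD) versus log(Z).
#' This regenerated surface is what the inference programme inverts; nothing
#' is hard-coded from published figures.
#'
#' The saturation value is the stationary variance of the border observable
#' (deviation about its time mean over the post-burn-in window), the
#' quantity the analytic radius-variance relation produces; saturation
#' itself is additionally checked on the initial-referenced ensemble curve
#' and unsaturated grid points are flagged and excluded from the fit.
#'
#' @param betas,Zs grid values (beta >= 0, Z > 0).
#' @param replicates simulation replicates per grid point.
#' @param seed master seed; per-run seeds are split deterministically.
#' @param dimension 1 or 2 (the inference programme uses 2).
#' @param estimator `"ray"` stores the stationary variance of the border
#'   observable itself (the transparent saturation-MSD surface); `"fit"`
#'   stores the radius MSD implied (through the radius-variance relation)
#'   by fitting the analytic 2D marginal to the simulated positions at each
#'   grid point. The `"fit"` estimator measures the border spread with the
#'   same operator the inference programme applies to field data, which
#'   keeps the programme self-consistent when the simulated territories are
#'   hexagonal rather than circular; it is the default for inference use.
#' @param cp_spacing,n_animals,record_every,n_rays forwarded to
#'   [sim_config()].
#' @param t_max run length; defaults scale with the active scent time so
#'   every grid point passes several scent turnovers.
#' @param burn_fraction leading fraction of samples discarded as
#'   equilibration before the stationary variance is computed.
#' @param fit_animals number of animals pooled per `"fit"`-estimator fit
#'   (mirror the number of animals tracked in the data).
#' @return a `calibration_map`: list with `grid`, per-beta `lines`
#'   (intercept, slope, residual sd of the log-log fit) and `meta`.
#' @export
calibrate_saturation_map <- function(betas, Zs, replicates = 20, seed = 1,
                                     dimension = 2,
                                     estimator = c("fit", "ray"),
                                     cp_spacing = if (dimension == 1) 50 else 16,
                                     n_animals = if (dimension == 1) 2L else 30L,
                                     t_max = NULL,
                                     record_every = if (dimension == 1) 50 else 20,
                                     n_rays = 8L, burn_fraction = 0.5,
                                     fit_animals = 4L) {
  estimator <- match.arg(estimator)
  stopifnot(all(betas >= 0), all(Zs > 0), replicates >= 2)
  if (dimension == 1 && estimator == "fit")
    stop("the fitted estimator is for the 2D inference map", call. = FALSE)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max,
                                 length(betas) * length(Zs) * replicates),
                      nrow = replicates)
  grid <- expand.grid(beta = sort(betas), Z = sort(Zs))
  base <- sim_config(dimension = dimension, n_animals = n_animals,
                     cp_spacing = cp_spacing, record_every = record_every,
                     n_rays = n_rays, seed = 1L)
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    beta <- grid$beta[g]; Z <- grid$Z[g]
    tas <- tas_for_Z(Z, base)
    tmax_g <- if (is.null(t_max)) {
      if (dimension == 1) max(2e4, 5 * tas) else max(6000, 5 * tas)
    } else t_max
    cfg <- sim_config(dimension = dimension, n_animals = n_animals,
                      cp_spacing = cp_spacing, t_max = tmax_g,
                      record_every = record_every, n_rays = n_rays,
                      bias_p = bias_p_for_beta(beta, cp_spacing,
                                               base$lattice_spacing, dimension),
                      active_scent_time = tas, seed = 1L)
    vals <- numeric(replicates)
    beta_fits <- rep(NA_real_, replicates)
    ens <- NULL
    for (rpl in seq_len(replicates)) {
      cfg$seed <- run_seeds[rpl, g]
      rec <- run_simulation(cfg, record_positions = (estimator == "fit"))
      b <- rec$borders
      if (dimension == 1) {
        b <- b[b$defined, ]
        obs <- b$position; tm <- b$time; sid <- b$border
      } else {
        obs <- b$radius; tm <- b$time
        sid <- interaction(b$animal, b$ray, drop = TRUE)
      }
      if (estimator == "ray") {
        keep <- tm > burn_fraction * max(tm)
        df <- tibble::tibble(time = tm[keep], value = obs[keep],
                             series = sid[keep])
        m <- compute_msd(df, value, time = time, series = series,
                         reference = "mean", scale = cp_spacing)
        vals[rpl] <- mean(m$msd)
      } else {
        # fit a tracked subset of animals: the same measurement operator
        # the inference programme applies to field relocations
        ids <- 1L + ((rpl - 1L) * fit_animals + seq_len(fit_animals) - 1L) %%
          n_animals
        rr <- dimensionless_radii(rec, burn_fraction, animals = ids)
        fit <- tryCatch(
          fit_marginal_radii(rr, cfg$cp_spacing,
                             starts = rbind(c(beta, 0.1), c(beta, 0.3),
                                            c(beta / 2, 0.2))),
          error = function(e) NULL)
        vals[rpl] <- if (is.null(fit) || fit$eps_hat > 1.5) NA_real_ else
          radius_msd_from_params(eps = fit$eps_hat)
        beta_fits[rpl] <- if (is.null(fit)) NA_real_ else fit$beta_hat
      }
      ini <- compute_msd(tibble::tibble(time = tm, value = obs, series = sid),
                         value, time = time, series = series,
                         reference = "initial", scale = cp_spacing)
      ens <- if (is.null(ens)) ini$msd / replicates else {
        n0 <- min(length(ens), length(ini$msd))
        ens[seq_len(n0)] + ini$msd[seq_len(n0)] / replicates
      }
      if (rpl == replicates) ens_time <- ini$time[seq_along(ens)]
    }
    sat <- detect_saturation(tibble::tibble(time = ens_time, msd = ens))
    ok <- is.finite(vals)
    tibble::tibble(beta = beta, Z = Z,
                   msd_sat = if (any(ok)) mean(vals[ok]) else NA_real_,
                   stderr = if (sum(ok) > 1) sd(vals[ok]) / sqrt(sum(ok)) else NA_real_,
                   beta_fit = if (estimator == "fit") mean(beta_fits, na.rm = TRUE)
                              else beta,
                   saturated = sat$saturated && mean(ok) > 0.5,
                   n_rep = sum(ok))
  })
  grid_tb <- dplyr::bind_rows(rows)
  lines <- dplyr::group_modify(
    dplyr::group_by(grid_tb, .data$beta), function(d, key) {
      bf <- mean(d$beta_fit[d$saturated], na.rm = TRUE)
      d <- d[d$saturated & is.finite(d$msd_sat) & d$msd_sat > 0, ]
      if (nrow(d) < 2)
        return(tibble::tibble(beta_key = bf, intercept = NA_real_,
                              slope = NA_real_, sigma = NA_real_, n = nrow(d)))
      fit <- lm(log(msd_sat) ~ log(Z), data = d)
      tibble::tibble(beta_key = bf, intercept = coef(fit)[1],
                     slope = coef(fit)[2],
                     sigma = summary(fit)$sigma, n = nrow(d))
    })
  lines <- dplyr::ungroup(lines)
  inverse <- NULL
  if (estimator == "fit") {
    # joint inverse surface: the fitted beta and the fitted border MSD both
    # carry information about Z (the fitted beta drifts with Z under
    # hexagonal tiling), so Z is recovered from the pair rather than from a
    # per-beta line alone
    ok <- grid_tb$saturated & is.finite(grid_tb$msd_sat) & grid_tb$msd_sat > 0
    if (sum(ok) >= 4) {
      iv <- lm(log(Z) ~ beta_fit + log(msd_sat), data = grid_tb[ok, ])
      inverse <- list(coef = coef(iv), sigma = summary(iv)$sigma,
                      r2 = summary(iv)$r.squared)
    }
  }
  structure(list(grid = grid_tb, lines = lines, inverse = inverse,
                 meta = list(dimension = dimension, estimator = estimator,
                             cp_spacing = cp_spacing,
                             n_animals = n_animals, t_max = t_max,
                             record_every = record_every,
                             replicates = replicates, seed = seed,
                             burn_fraction = burn_fraction,
                             Z_range = range(grid_tb$Z),
                             beta_range = range(grid_tb$beta),
                             convention = "K1=1/(2*D*rho^2); K2=1/(4*D*rho); beta=v*L/D",
                             package_version = as.character(packageVersion("terriforage")))),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("<calibration_map> ", x$meta$dimension, "D, ",
      length(unique(x$grid$beta)), " beta x ", length(unique(x$grid$Z)),
      " Z grid, ", x$meta$replicates, " replicates\n", sep = "")
  print(x$grid, n = 6)
  invisible(x)
}

# interpolate per-beta trend-line coefficients at an arbitrary beta.
# Lines are keyed by `beta_key`: the microscopic beta for "ray" maps, the
# mean fitted beta for "fit" maps, so that a beta estimated from field data
# is compared on the same scale it was measured on.
interp_line <- function(map, beta) {
  ln <- map$lines[!is.na(map$lines$slope) & is.finite(map$lines$beta_key), ]
  if (nrow(ln) == 0) stop("calibration map has no fitted trend lines", call. = FALSE)
  ln <- ln[order(ln$beta_key), ]
  lo <- min(ln$beta_key); hi <- max(ln$beta_key)
  if (beta < lo - 1e-9 || beta > hi + 1e-9)
    stop("beta = ", signif(beta, 4), " outside the calibrated range [",
         signif(lo, 4), ", ", signif(hi, 4), "]", call. = FALSE)
  beta <- min(max(beta, lo), hi)
  if (nrow(ln) == 1) return(ln)
  tibble::tibble(beta_key = beta,
                 intercept = approx(ln$beta_key, ln$intercept, beta)$y,
                 slope = approx(ln$beta_key, ln$slope, beta)$y,
                 sigma = approx(ln$beta_key, ln$sigma, beta)$y,
                 n = NA_integer_)
}

#' Invert the calibration surface for Z
#'
#' Given a drift strength `beta` and a dimensionless saturation border MSD,
#' inverse-interpolates the per-beta log-log trend line (interpolating the
#' line coefficients between adjacent calibrated betas) and returns the
#' corresponding `Z = T_AS / diffusive time` with a calibration-uncertainty
#' interval.
#'
#' @param map a `calibration_map`.
#' @param beta drift strength within the calibrated range.
#' @param msd_sat dimensionless saturation MSD (> 0).
#' @param level confidence level of the interval.
#' @param extrapolate multiplicative slack allowed beyond the calibrated Z
#'   range before an out-of-range error is raised.
#' @return tibble with `Z`, `Z_lo`, `Z_hi`, `beta`, `msd_sat`.
#' @export
lookup_Z <- function(map, beta, msd_sat, level = 0.95, extrapolate = 1.25) {
  stopifnot(inherits(map, "calibration_map"), msd_sat > 0)
  q <- qnorm(1 - (1 - level) / 2)
  if (!is.null(map$inverse) && length(map$inverse$coef) == 3) {
    co <- map$inverse$coef
    logZ <- unname(co[1] + co[2] * beta + co[3] * log(msd_sat))
    zr <- map$meta$Z_range
    if (logZ < log(zr[1] / extrapolate) || logZ > log(zr[2] * extrapolate))
      stop("implied Z = ", signif(exp(logZ), 4),
           " lies outside the calibrated range [", zr[1], ", ", zr[2],
           "]; recalibrate over a wider grid", call. = FALSE)
    se <- map$inverse$sigma
    return(tibble::tibble(Z = exp(logZ), Z_lo = exp(logZ - q * se),
                          Z_hi = exp(logZ + q * se), beta = beta,
                          msd_sat = msd_sat))
  }
  ln <- interp_line(map, beta)
  if (abs(ln$slope) < 1e-12)
    stop("trend line at beta = ", beta, " is flat; Z is unidentifiable",
         call. = FALSE)
  logZ <- (log(msd_sat) - ln$intercept) / ln$slope
  zr <- map$meta$Z_range
  if (logZ < log(zr[1] / extrapolate) || logZ > log(zr[2] * extrapolate)) {
    attainable <- sort(exp(ln$intercept + ln$slope * log(zr)))
    stop("saturation MSD ", signif(msd_sat, 4),
         " is outside the attainable range [", signif(attainable[1], 4), ", ",
         signif(attainable[2], 4), "] for beta = ", signif(beta, 4),
         call. = FALSE)
  }
  se <- ifelse(is.finite(ln$sigma), ln$sigma, 0) / abs(ln$slope)
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(Z = exp(logZ), Z_lo = exp(logZ - q * se),
                 Z_hi = exp(logZ + q * se), beta = beta, msd_sat = msd_sat)
}

#' Write / read a calibration map
#'
#' The grid is written as CSV next to a JSON file holding the trend lines
#' and provenance, so a calibration can be reused across sessions.
#'
#' @param map a `calibration_map`.
#' @param path base path (without extension).
#' @return `write_calibration_map` invisibly returns the paths;
#'   `read_calibration_map` returns the `calibration_map`.
#' @export
write_calibration_map <- function(map, path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  write.csv(map$grid, csv, row.names = FALSE)
  jsonlite::write_json(list(lines = map$lines, inverse = map$inverse,
                            meta = map$meta), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(grid = csv, meta = js))
}

#' @rdname write_calibration_map
#' @export
read_calibration_map <- function(path) {
  grid <- tibble::as_tibble(read.csv(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$meta$Z_range <- as.numeric(meta$meta$Z_range)
  meta$meta$beta_range <- as.numeric(meta$meta$beta_range)
  inverse <- meta$inverse
  if (!is.null(inverse) && length(inverse)) inverse$coef <- unlist(inverse$coef)
  else inverse <- NULL
  structure(list(grid = grid, lines = tibble::as_tibble(meta$lines),
                 inverse = inverse, meta = meta$meta),
            class = "calibration_map")
}
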