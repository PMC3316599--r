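#' Mean square displacement of an observable
#'
#' Ensemble-averaged squared displacement of a recorded observable from a
#' per-series reference, as a function of time. Series (e.g. borders, rays,
#' animals) and replicates are averaged together at each sample time; the
#' result can be non-dimensionalised by a length scale.
#'
#' @param data long tibble/data frame with one row per (time, series,
#'   replicate) observation.
#' @param value name of the observable column (unquoted).
#' @param time,series,replicate column names (unquoted); `series` and
#'   `replicate` may be omitted if absent.
#' @param reference `"initial"` (first finite value of each series; the
#'   default, matching saturation-MSD usage) or `"mean"` (per-series time
#'   mean, i.e. the stationary variance).
#' @param scale length scale used to non-dimensionalise (MSD is divided by
#'   `scale^2`).
#' @return a tibble of class `msd_curve` with `time`, `msd`, `n` (number of
#'   contributing observations).
#' @export
compute_msd <- function(data, value, time = time, series = NULL,
                        replicate = NULL, reference = c("initial", "mean"),
                        scale = 1) {
  reference <- match.arg(reference)
  stopifnot(scale > 0)
  v <- rlang::enquo(value); tm <- rlang::enquo(time)
  se <- rlang::enquo(series); re <- rlang::enquo(replicate)
  df <- dplyr::transmute(data, .time = !!tm, .value = !!v,
                         .series = if (rlang::quo_is_null(se)) 1L else !!se,
                         .replicate = if (rlang::quo_is_null(re)) 1L else !!re)
  df <- df[is.finite(df$.value), ]
  if (nrow(df) == 0) stop("no finite observations", call. = FALSE)
  df <- dplyr::group_by(df, .data$.series, .data$.replicate)
  df <- dplyr::arrange(df, .data$.time, .by_group = TRUE)
  df <- dplyr::mutate(df, .ref = if (reference == "initial")
    dplyr::first(.data$.value) else mean(.data$.value))
  df <- dplyr::ungroup(df)
  out <- dplyr::summarise(dplyr::group_by(df, time = .data$.time),
                          msd = mean((.data$.value - .data$.ref)^2) / scale^2,
                          n = dplyr::n(), .groups = "drop")
  class(out) <- c("msd_curve", class(out))
  out
}

#' Saturation test for an MSD curve
#'
#' A curve is flagged unsaturated when the least-squares slope of MSD
#' against time over the trailing window is large relative to the window's
#' mean level (`|slope| * window_span / mean(msd) >= slope_tol`) AND
#' significantly positive (slope t-value above 2); noisy plateaus pass
#' either guard. The saturation value is the trailing-window mean.
#'
#' @param curve an `msd_curve` (or any tibble with `time` and `msd`).
#' @param window_fraction trailing fraction of samples used (default 0.5:
#'   long enough that square-root growth is distinguishable from plateau
#'   noise in modest ensembles).
#' @param slope_tol relative slope tolerance (default 0.12; a diffusive or
#'   square-root-growth curve scores well above this, a plateau well below).
#' @return list with `value` (trailing mean), `saturated` (flag),
#'   `rel_slope`, and the window bounds.
#' @export
detect_saturation <- function(curve, window_fraction = 0.5, slope_tol = 0.12) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  curve <- curve[is.finite(curve$msd), ]
  if (nrow(curve) < 20)
    stop("need at least 20 MSD points for the saturation test", call. = FALSE)
  n <- nrow(curve)
  win <- curve[curve$time >= quantile(curve$time, 1 - window_fraction), ]
  if (nrow(win) < 5) win <- curve[seq(max(1, n - 4), n), ]
  level <- mean(win$msd)
  if (level <= 0) return(list(value = level, saturated = TRUE, rel_slope = 0,
                              window = range(win$time)))
  fit <- lm(msd ~ time, data = win)
  slope <- coef(fit)[2]
  tval <- suppressWarnings(unname(coef(summary(fit))[2, "t value"]))
  if (!is.finite(tval)) tval <- sign(slope) * Inf
  rel <- abs(slope) * diff(range(win$time)) / level
  # unsaturated only when the trailing-window slope is both practically
  # large and significantly positive; a noisy plateau passes either guard
  list(value = level,
       saturated = unname(!(rel >= slope_tol && slope > 0 && tval > 2)),
       rel_slope = unname(rel), window = range(win$time))
}

#' Log-log growth exponent of an MSD curve
#'
#' Least-squares slope of log(msd) against log(time) over the trailing
#' decade (or a supplied time window); the subdiffusion diagnostic for
#' territory borders (single-file exponent 1/2).
#'
#' @param curve an `msd_curve`.
#' @param window time window; default the last decade `(t_max/10, t_max]`.
#' @return the fitted exponent.
#' @export
msd_exponent <- function(curve, window = NULL) {
  curve <- curve[is.finite(curve$msd) & curve$msd > 0 & curve$time > 0, ]
  if (is.null(window)) window <- c(max(curve$time) / 10, max(curve$time))
  w <- curve[curve$time > window[1] & curve$time <= window[2], ]
  if (nrow(w) < 5) stop("too few points in the fitting window", call. = FALSE)
  unname(coef(lm(log(msd) ~ log(time), data = w))[2])
}

#' Dimensionless parameters of a simulation configuration
#'
#' Collapses the microscopic parameters to the dimensionless pair governing
#' territorial dynamics: `Z`, the active scent time over the diffusive time
#' (`Z = T_AS / K1` with `K1 = 1/(2 D rho^2)` in 1D; `Z = T_AS / K2` with
#' `K2 = 1/(4 D rho)` in 2D), and `beta = v L / D`, the normalised drift
#' velocity. Here `D` is the walker's diffusion constant (`F a^2 / 2` in
#' 1D; `F a^2 / 4` in 2D, where jumps are shared between the axes), `rho`
#' is the animal density (per length in 1D, per area in 2D), and the drift
#' speed from the bias is `v = F a (2p - 1)` in 1D and
#' `v = F a (2p - 1) / 2` in 2D, so `beta = 2 (2p - 1) L / a` in both.
#'
#' @param config a [sim_config()].
#' @return one-row tibble with `Z`, `beta`, `D`, `v`, `rho`,
#'   `diffusive_time` and the convention string recorded in run manifests.
#' @export
dimensionless_parameters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  a <- config$lattice_spacing; f <- config$jump_rate
  L <- config$cp_spacing; p <- config$bias_p
  if (config$dimension == 1) {
    D <- f * a^2 / 2
    v <- f * a * (2 * p - 1)
    rho <- config$n_animals / (config$n_sites * a)
    tdiff <- 1 / (2 * D * rho^2)
  } else {
    D <- f * a^2 / 4
    v <- f * a * (2 * p - 1) / 2
    rho <- config$n_animals / (config$nx * config$ny * a^2)
    tdiff <- 1 / (4 * D * rho)
  }
  if (L <= 0 || D <= 0) stop("non-positive L or D", call. = FALSE)
  tibble::tibble(dimension = config$dimension,
                 Z = config$active_scent_time / tdiff,
                 beta = v * L / D, D = D, v = v, rho = rho,
                 diffusive_time = tdiff,
                 convention = "K1=1/(2*D*rho^2); K2=1/(4*D*rho); beta=v*L/D; D=F*a^2/2 (1D), F*a^2/4 (2D)")
}

#' Bias probability realising a target drift strength
#'
#' Inverts the `beta = v L / D` convention for the lattice kernel:
#' `p = 1/2 + beta a / (4 L)` in both dimensions.
#'
#' @param beta target dimensionless drift (>= 0).
#' @param L,a CP spacing and lattice spacing.
#' @param dimension 1 or 2 (the inversion coincides).
#' @return bias probability `p`.
#' @export
bias_p_for_beta <- function(beta, L, a = 1, dimension = 2) {
  stopifnot(beta >= 0)
  p <- 0.5 + beta * a / (4 * L)
  if (p > 1) stop("beta = ", beta, " is not realisable on this lattice ",
                  "(bias_p would exceed 1)", call. = FALSE)
  p
}

#' Active scent time realising a target Z
#'
#' @param Z target dimensionless active scent time (>= 0).
#' @param config a [sim_config()] providing `D` and `rho`.
#' @return the dimensional `T_AS`.
#' @export
tas_for_Z <- function(Z, config) {
  stopifnot(Z >= 0)
  Z * dimensionless_parameters(config)$diffusive_time
}
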