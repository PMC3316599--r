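#' Run a territorial central-place forager simulation
#'
#' Monte-Carlo simulation of lattice random walkers that deposit scent on
#' every site they stand on and cannot enter sites holding active foreign
#' scent (age below the active scent time). Movement is biased towards each
#' animal's central place. Positions and border observables are recorded
#' every `record_every` time units; runs are bit-reproducible given
#' `config$seed`.
#'
#' The border observable is the 1D inter-territory border position (midpoint
#' of the interstitial gap between the facing ends of two adjacent animals'
#' active-scent blocks, unwrapped continuously across the periodic boundary)
#' or, in 2D, the territory radius along `n_rays` equally spaced bearings
#' from each CP.
#'
#' @param config a [sim_config()].
#' @param record_positions keep per-animal positions (default TRUE; turn off
#'   to save memory in large calibration ensembles).
#' @return a `trajectory_record`: list with `positions` (tibble: time,
#'   animal, x, y), `borders` (1D: tibble time, border, position, defined;
#'   2D: tibble time, animal, ray, bearing, radius), `state` (final scent
#'   ownership), `config`, and `params` (the dimensionless parameters).
#' @examples
#' cfg <- sim_config(dimension = 1, cp_spacing = 10, active_scent_time = 50,
#'                   t_max = 200, record_every = 10, seed = 42)
#' rec <- run_simulation(cfg)
#' head(rec$borders)
#' @export
run_simulation <- function(config, record_positions = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sweeps <- max(1L, as.integer(round(config$t_max * config$jump_rate)))
  rec_every <- max(1L, as.integer(round(config$record_every * config$jump_rate)))

  if (config$dimension == 1) {
    raw <- cpp_run_sim_1d(config$n_sites, config$cp_sites, config$bias_p,
                          config$active_scent_time, config$jump_rate,
                          n_sweeps, rec_every, record_positions)
    borders <- tibble::tibble(
      time = rep(raw$times, 2L),
      border = rep(1:2, each = length(raw$times)),
      position = c(unwrap_ring(raw$borders[, 1], config$n_sites),
                   unwrap_ring(raw$borders[, 2], config$n_sites)) *
        config$lattice_spacing,
      defined = rep(raw$border_defined, 2L))
    positions <- NULL
    if (record_positions) {
      xu <- apply(raw$positions, 2, unwrap_ring, n_sites = config$n_sites)
      positions <- tibble::tibble(
        time = rep(raw$times, config$n_animals),
        animal = rep(seq_len(config$n_animals), each = length(raw$times)),
        x = as.vector(raw$positions) * config$lattice_spacing,
        y = 0,
        x_unwrapped = as.vector(xu) * config$lattice_spacing)
    }
    state <- list(scent_owner = ifelse(raw$scent_owner < 0, NA_integer_,
                                       raw$scent_owner + 1L),
                  scent_age = raw$scent_age,
                  final_positions = raw$final_positions + 0L,
                  time = raw$t_final)
  } else {
    ray_max <- config$cp_spacing / config$lattice_spacing * 1.5
    raw <- cpp_run_sim_2d(config$nx, config$ny, config$cp_x, config$cp_y,
                          config$bias_p, config$active_scent_time,
                          config$jump_rate, n_sweeps, rec_every,
                          config$n_rays, record_positions, ray_max)
    nt <- length(raw$times)
    # radii matrix columns are (animal, ray) pairs with ray varying fastest
    idx <- expand.grid(ray = seq_len(config$n_rays),
                       animal = seq_len(config$n_animals))
    borders <- tibble::tibble(
      time = rep(raw$times, times = nrow(idx)),
      animal = rep(idx$animal, each = nt),
      ray = rep(idx$ray, each = nt),
      bearing = 2 * pi * (rep(idx$ray, each = nt) - 1L) / config$n_rays,
      radius = as.vector(raw$radii) * config$lattice_spacing)
    positions <- NULL
    if (record_positions) {
      xu <- apply(raw$pos_x, 2, unwrap_ring, n_sites = config$nx)
      yu <- apply(raw$pos_y, 2, unwrap_ring, n_sites = config$ny)
      positions <- tibble::tibble(
        time = rep(raw$times, config$n_animals),
        animal = rep(seq_len(config$n_animals), each = nt),
        x = as.vector(raw$pos_x) * config$lattice_spacing,
        y = as.vector(raw$pos_y) * config$lattice_spacing,
        x_unwrapped = as.vector(xu) * config$lattice_spacing,
        y_unwrapped = as.vector(yu) * config$lattice_spacing)
    }
    state <- list(scent_owner = matrix(ifelse(raw$scent_owner < 0, NA_integer_,
                                              raw$scent_owner + 1L),
                                       nrow = config$nx, ncol = config$ny),
                  final_x = raw$final_x, final_y = raw$final_y,
                  time = raw$t_final)
  }
  structure(list(positions = positions, borders = borders, state = state,
                 config = config, params = dimensionless_parameters(config)),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("<trajectory_record> ", x$config$dimension, "D, ",
      x$config$n_animals, " animals, ",
      length(unique(x$borders$time)), " samples to t = ",
      max(x$borders$time), "\n", sep = "")
  cat("  dimensionless: Z = ", signif(x$params$Z, 4), ", beta = ",
      signif(x$params$beta, 4), "\n", sep = "")
  invisible(x)
}

#' Dimensionless radial distances of simulated animals about their CPs
#'
#' Minimal-image distance of every recorded fix from the owning animal's
#' central place, divided by the CP spacing; the quantity the analytic 2D
#' marginal describes. Used to compare simulations with the theory and to
#' build the fitted calibration surface.
#'
#' @param record a 2D `trajectory_record` with positions.
#' @param burn_fraction leading fraction of the record discarded.
#' @param animals optional subset of animal ids to keep.
#' @return numeric vector of dimensionless radii (pooled over the kept
#'   animals).
#' @export
dimensionless_radii <- function(record, burn_fraction = 0.5, animals = NULL) {
  cfg <- record$config
  if (cfg$dimension != 2) stop("needs a 2D record", call. = FALSE)
  p <- record$positions
  if (is.null(p)) stop("record was run with record_positions = FALSE", call. = FALSE)
  keep <- p$time > burn_fraction * max(p$time)
  if (!is.null(animals)) keep <- keep & p$animal %in% animals
  p <- p[keep, ]
  a <- cfg$lattice_spacing
  nx <- cfg$nx * a; ny <- cfg$ny * a
  cpx <- cfg$cp_x[p$animal] * a; cpy <- cfg$cp_y[p$animal] * a
  dx <- (p$x - cpx + nx / 2) %% nx - nx / 2
  dy <- (p$y - cpy + ny / 2) %% ny - ny / 2
  pmax(sqrt(dx^2 + dy^2) / cfg$cp_spacing, 1e-9)
}

#' Dimensionless CP-centred positions of simulated 1D animals
#'
#' Folds every recorded 1D fix into the coordinate frame of the owning
#' animal's territory: own CP at 0, conspecific CPs at -1 and 1 (lengths in
#' units of the CP spacing). This is the frame of the 1D marginal density.
#'
#' @param record a 1D `trajectory_record` with positions.
#' @param burn_fraction leading fraction of the record discarded.
#' @return numeric vector of dimensionless positions in (-1, 1).
#' @export
dimensionless_positions_1d <- function(record, burn_fraction = 0.5) {
  cfg <- record$config
  if (cfg$dimension != 1) stop("needs a 1D record", call. = FALSE)
  p <- record$positions
  if (is.null(p)) stop("record was run with record_positions = FALSE", call. = FALSE)
  p <- p[p$time > burn_fraction * max(p$time), ]
  a <- cfg$lattice_spacing
  ring <- cfg$n_sites * a
  cp <- cfg$cp_sites[p$animal] * a
  ((p$x - cp + ring / 2) %% ring - ring / 2) / cfg$cp_spacing
}

#' Cumulative distribution of a 1D or radial density curve
#'
#' Turns a density evaluated on a grid into an interpolated CDF function,
#' for goodness-of-fit testing against samples.
#'
#' @param grid abscissa grid (increasing).
#' @param dens density values on the grid (1D measure).
#' @return a function q -> F(q).
#' @export
cdf_from_density <- function(grid, dens) {
  stopifnot(length(grid) == length(dens), !is.unsorted(grid))
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- pmin(cdf / max(cdf), 1)
  f <- approxfun(grid, cdf, rule = 2)
  function(q) f(pmin(pmax(q, grid[1]), grid[length(grid)]))
}

# continuity unwrapping across the periodic boundary: successive samples are
# joined by the minimal ring displacement so the MSD never sees a wrap jump
unwrap_ring <- function(x, n_sites) {
  if (all(is.na(x))) return(x)
  d <- diff(x)
  d <- ifelse(is.na(d), 0, d)
  d[d > n_sites / 2] <- d[d > n_sites / 2] - n_sites
  d[d < -n_sites / 2] <- d[d < -n_sites / 2] + n_sites
  first <- which(!is.na(x))[1]
  out <- x[first] + c(rep(0, first - 1), 0, cumsum(d[first:length(d)]))[seq_along(x)]
  out[is.na(x)] <- NA_real_
  out
}

#' Border positions between 1D scent territories
#'
#' For each adjacent territory pair, the border is the midpoint of the
#' interstitial gap between the facing extremes of the two animals' active
#' contiguous scent blocks (the gap may be empty). Positions are returned in
#' ring coordinates (units of the lattice spacing).
#'
#' @param owner integer vector over ring sites: active-scent owner id of
#'   each site, `NA` where no active scent.
#' @return tibble with one row per interface: `from`, `to` (owner ids going
#'   clockwise) and `position`; zero rows with a `defined = FALSE` attribute
#'   if some animal holds no active scent.
#' @examples
#' own <- rep(NA_integer_, 20); own[4:8] <- 1L; own[11:16] <- 2L
#' extract_borders_1d(own)   # borders at 8.5 and 19 (0-based ring coords)
#' @export
extract_borders_1d <- function(owner) {
  n <- length(owner)
  ids <- sort(unique(owner[!is.na(owner)]))
  if (length(ids) < 2) {
    out <- tibble::tibble(from = integer(), to = integer(), position = numeric())
    attr(out, "defined") <- FALSE
    return(out)
  }
  o <- ifelse(is.na(owner), -1L, owner)
  # maximal runs on the circle
  brk <- which(o != c(o[n], o[-n]))   # run starts
  if (length(brk) == 0) stop("single-owner ring has no border")
  runs <- tibble::tibble(start = brk,
                         end = c(brk[-1] - 1L, brk[1] - 1L + n),
                         owner = o[brk])
  occ <- runs[runs$owner > 0, ]
  occ <- occ[order(occ$start), ]
  m <- nrow(occ)
  from <- to <- integer(m); posn <- numeric(m)
  for (k in seq_len(m)) {
    nxt <- if (k == m) 1L else k + 1L
    gap_start <- occ$end[k]                       # last site of this block
    gap_next <- if (k == m) occ$start[nxt] + n else occ$start[nxt]
    g <- gap_next - gap_start
    from[k] <- occ$owner[k]; to[k] <- occ$owner[nxt]
    posn[k] <- (gap_start - 1 + g / 2) %% n       # 0-based ring coordinate
  }
  out <- tibble::tibble(from = from, to = to, position = posn)
  attr(out, "defined") <- TRUE
  out
}

#' Radial territory border profile in 2D
#'
#' Along `n_rays` equally spaced bearings from an animal's central place,
#' the territory border radius: the midpoint of the interstitial gap
#' between the animal's farthest active scent claim on the bearing and the
#' nearest foreign claim beyond it (the same midpoint-of-gap definition as
#' the 1D border, applied radially). If a bearing meets no foreign scent
#' within range, the farthest own claim is returned; an animal with no
#' active scent at all gives a flagged all-`NA` profile. Small unmarked
#' holes inside the territory are ignored (they do not end the claim).
#'
#' @param owner integer matrix (nx by ny, torus): active-scent owner id per
#'   site, `NA` where empty.
#' @param cp length-2 integer CP site (0-based lattice coordinates).
#' @param animal_id owner id whose territory is profiled.
#' @param n_rays number of bearings.
#' @param ray_max maximum search distance (lattice units).
#' @return tibble with `ray`, `bearing`, `radius` (lattice units).
#' @export
extract_radius_profile_2d <- function(owner, cp, animal_id, n_rays = 8,
                                      ray_max = max(dim(owner)) / 2) {
  nx <- nrow(owner); ny <- ncol(owner)
  if (!any(!is.na(owner) & owner == animal_id))
    return(structure(tibble::tibble(ray = seq_len(n_rays),
                                    bearing = 2 * pi * (seq_len(n_rays) - 1) / n_rays,
                                    radius = NA_real_),
                     flagged = TRUE))
  bearing <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  radius <- vapply(bearing, function(th) {
    r_own <- 0; r_foreign <- NA_real_
    for (r in seq(0, ray_max, by = 0.5)) {
      sx <- (round(cp[1] + r * cos(th)) %% nx) + 1
      sy <- (round(cp[2] + r * sin(th)) %% ny) + 1
      ow <- owner[sx, sy]
      if (!is.na(ow)) {
        if (ow == animal_id) r_own <- r
        else { r_foreign <- r; break }
      }
    }
    if (is.na(r_foreign)) r_own else (r_own + r_foreign) / 2
  }, numeric(1))
  tibble::tibble(ray = seq_len(n_rays), bearing = bearing, radius = radius)
}
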