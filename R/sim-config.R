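#' Simulation configuration for territorial central-place foragers
#'
#' Collects every microscopic parameter of a run and validates the lattice /
#' central-place (CP) commensurability. In 1D the terrain is a ring of
#' `n_animals * cp_spacing / lattice_spacing` sites with uniformly spaced
#' CPs; in 2D it is a rectangular torus tiling a triangular (hexagonal
#' centroid) CP arrangement exactly.
#'
#' @param dimension 1 or 2.
#' @param n_animals number of walkers. Defaults: 2 in 1D, 30 in 2D.
#' @param cp_spacing distance `L` between central places of adjacent
#'   territories (same length unit as `lattice_spacing`).
#' @param lattice_spacing lattice constant `a`.
#' @param jump_rate rate `F` of jumping to a nearest-neighbour site (1/time).
#' @param bias_p probability of stepping towards the CP on the next jump;
#'   `1/2` is the neutral (unbiased) value, so `bias_p` must lie in
#'   `[0.5, 1]`.
#' @param active_scent_time time `T_AS` for which a deposited scent mark
#'   excludes conspecifics. `T_AS = 0` disables the interaction.
#' @param t_max run length (time units; `t_max * jump_rate` sweeps).
#' @param record_every sampling interval for trajectory and border records
#'   (time units).
#' @param n_rays number of equally spaced bearings used for the 2D radial
#'   border observable.
#' @param seed integer RNG seed; runs are bit-reproducible given the seed.
#'
#' @return an object of class `sim_config` (a validated named list, with
#'   derived lattice dimensions and CP sites attached).
#' @examples
#' cfg <- sim_config(dimension = 1, cp_spacing = 20, active_scent_time = 200,
#'                   t_max = 500, seed = 1)
#' cfg$n_sites
#' @export
sim_config <- function(dimension = 1,
                       n_animals = if (dimension == 1) 2L else 30L,
                       cp_spacing = if (dimension == 1) 50 else 16,
                       lattice_spacing = 1,
                       jump_rate = 1,
                       bias_p = 0.5,
                       active_scent_time = 0,
                       t_max = 1000,
                       record_every = 10,
                       n_rays = 8L,
                       seed = 1L) {
  if (!dimension %in% c(1, 2)) stop("`dimension` must be 1 or 2", call. = FALSE)
  stopifnot(lattice_spacing > 0, cp_spacing > 0, jump_rate > 0, t_max > 0,
            record_every > 0, n_rays >= 1, n_animals >= 1)
  if (active_scent_time < 0) stop("`active_scent_time` must be >= 0", call. = FALSE)
  if (bias_p < 0.5 || bias_p > 1)
    stop("`bias_p` must be in [0.5, 1] (drift towards the CP)", call. = FALSE)

  L_sites <- cp_spacing / lattice_spacing
  cfg <- list(dimension = as.integer(dimension), n_animals = as.integer(n_animals),
              cp_spacing = cp_spacing, lattice_spacing = lattice_spacing,
              jump_rate = jump_rate, bias_p = bias_p,
              active_scent_time = active_scent_time, t_max = t_max,
              record_every = record_every, n_rays = as.integer(n_rays),
              seed = as.integer(seed))

  if (dimension == 1) {
    if (abs(L_sites - round(L_sites)) > 1e-9)
      stop("incommensurable 1D lattice: cp_spacing / lattice_spacing = ",
           L_sites, " is not an integer", call. = FALSE)
    L_sites <- as.integer(round(L_sites))
    cfg$n_sites <- n_animals * L_sites
    cfg$cp_sites <- as.integer((seq_len(n_animals) - 1L) * L_sites)
  } else {
    if (abs(L_sites - round(L_sites)) > 1e-9 || round(L_sites) %% 2 != 0)
      stop("incommensurable 2D lattice: cp_spacing / lattice_spacing = ",
           L_sites, " must be an even integer (staggered hexagonal rows)",
           call. = FALSE)
    L_sites <- as.integer(round(L_sites))
    grid <- hex_grid_dims(n_animals)
    if (is.null(grid))
      stop("incommensurable 2D CP layout: n_animals = ", n_animals,
           " cannot be arranged as a staggered hexagonal grid ",
           "(needs ncol * nrow = n_animals with nrow even)", call. = FALSE)
    h <- as.integer(round(sqrt(3) / 2 * L_sites))
    cfg$nx <- grid[1] * L_sites
    cfg$ny <- grid[2] * h
    ij <- expand.grid(i = seq_len(grid[1]) - 1L, j = seq_len(grid[2]) - 1L)
    cfg$cp_x <- as.integer((ij$i * L_sites + (ij$j %% 2L) * (L_sites %/% 2L)) %% cfg$nx)
    cfg$cp_y <- as.integer(ij$j * h)
  }
  structure(cfg, class = "sim_config")
}

# staggered hexagonal layout: ncol columns x nrow rows, nrow even so the
# half-lattice row offsets wrap consistently on the torus
hex_grid_dims <- function(n) {
  for (ncol in rev(seq_len(floor(sqrt(n))))) {
    if (n %% ncol == 0 && (n / ncol) %% 2 == 0) return(c(ncol, n / ncol))
    if (n %% ncol == 0 && ncol %% 2 == 0) return(c(n / ncol, ncol))
  }
  NULL
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$dimension, "D, ", x$n_animals, " animals, L = ",
      x$cp_spacing, ", T_AS = ", x$active_scent_time,
      ", bias_p = ", x$bias_p, ", t_max = ", x$t_max, "\n", sep = "")
  invisible(x)
}

#' Initial lattice state
#'
#' Animals start at their central places with an empty scent field (the
#' paper does not state initial conditions; this is the package's choice).
#'
#' @param config a [sim_config()].
#' @return a `lattice_state`: time, per-animal positions, CP positions and a
#'   scent table (empty at time 0).
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dimension == 1) {
    pos <- tibble::tibble(animal = seq_len(config$n_animals),
                          x = config$cp_sites, y = 0L)
    cps <- pos
  } else {
    pos <- tibble::tibble(animal = seq_len(config$n_animals),
                          x = config$cp_x, y = config$cp_y)
    cps <- pos
  }
  structure(list(time = 0, positions = pos, cp_positions = cps,
                 scent = tibble::tibble(x = integer(), y = integer(),
                                        owner = integer(), age = numeric()),
                 config = config),
            class = "lattice_state")
}

#' Single-step movement kernel of the 2D central-place walker
#'
#' Probabilities of the four nearest-neighbour moves given the animal and CP
#' positions. The drift points along the unit vector towards the CP with a
#' magnitude set by `bias_p` alone, so it is independent of the distance to
#' the CP (the continuum limit is the 2D Holgate-Okubo localising tendency
#' with constant drift speed `v = F a (2 bias_p - 1) / 2`). At the CP the
#' kernel is symmetric.
#'
#' @param pos,cp numeric length-2 vectors (lattice units).
#' @param bias_p bias probability in `[0.5, 1]`.
#' @return named numeric vector of probabilities for moves
#'   `(+x, -x, +y, -y)`, summing to 1.
#' @examples
#' move_probabilities_2d(c(0, 0), c(0, 0), 0.8)   # uniform at the CP
#' move_probabilities_2d(c(3, 0), c(0, 0), 0.8)
#' @export
move_probabilities_2d <- function(pos, cp, bias_p) {
  stopifnot(length(pos) == 2, length(cp) == 2, bias_p >= 0.5, bias_p <= 1)
  pr <- cpp_move_probs_2d(cp[1] - pos[1], cp[2] - pos[2], bias_p)
  setNames(as.numeric(pr), c("+x", "-x", "+y", "-y"))
}
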