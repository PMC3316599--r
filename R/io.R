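#' Run manifest
#'
#' Provenance record written next to every artefact a run produces: the
#' configuration snapshot, seeds, package version and the dimensionless
#' convention in force.
#'
#' @param config a [sim_config()] or plain list of parameters.
#' @param seed master seed of the run.
#' @param extra optional named list merged into the manifest.
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(config, seed, extra = list()) {
  m <- c(list(config = unclass(config), seed = seed,
              package = "terriforage",
              version = as.character(packageVersion("terriforage")),
              convention = "K1=1/(2*D*rho^2); K2=1/(4*D*rho); beta=v*L/D; D=F*a^2/2; eps^2=K_b/lambda",
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds [sim_config()] fields by name; unknown fields raise an
#' error naming them.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, lst)
}

#' Write a trajectory record to CSV with a manifest
#'
#' Long-format CSV (time, animal_id, x, y) for positions and a second CSV
#' for the border observables, plus a JSON run manifest.
#'
#' @param record a `trajectory_record`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return invisibly, the written paths.
#' @export
write_trajectory <- function(record, dir, stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(record$positions)) {
    p <- file.path(dir, paste0(stem, "_positions.csv"))
    pos <- record$positions
    names(pos)[names(pos) == "animal"] <- "animal_id"
    write.csv(pos, p, row.names = FALSE)
    paths <- c(paths, positions = p)
  }
  b <- file.path(dir, paste0(stem, "_borders.csv"))
  write.csv(record$borders, b, row.names = FALSE)
  m <- file.path(dir, paste0(stem, "_manifest.json"))
  write_manifest(run_manifest(record$config, record$config$seed,
                              list(params = as.list(record$params))), m)
  invisible(c(paths, borders = b, manifest = m))
}

#' Generate a synthetic relocation fixture
#'
#' Writes a seeded synthetic relocation CSV (plus manifest): either i.i.d.
#' draws from the analytic 2D marginal (`kind = "analytic"`) or the
#' sub-sampled track of one animal from a full 2D simulation
#' (`kind = "sim"`). The test-suite uses these; no external data are ever
#' needed.
#'
#' @param kind `"analytic"` or `"sim"`.
#' @param params for `"analytic"`: an [analytic_params()]; for `"sim"`: a
#'   [sim_config()].
#' @param n number of fixes (analytic) / `thin` sampling stride in recorded
#'   samples (sim).
#' @param seed integer seed.
#' @param out output CSV path.
#' @param L CP spacing used to scale analytic draws.
#' @param animal which animal's track to keep (sim).
#' @param burn_fraction leading fraction of a simulated track discarded.
#' @return invisibly, the CSV path.
#' @export
generate_fixture <- function(kind = c("analytic", "sim"), params, seed, out,
                             n = 1000, L = 1, animal = 1,
                             burn_fraction = 0.5) {
  kind <- match.arg(kind)
  if (kind == "analytic") {
    df <- sample_relocations(params, n, seed = seed, L = L)
    manifest <- run_manifest(list(beta = params$beta, eps = params$eps,
                                  L = L, n = n, kind = kind), seed)
  } else {
    cfg <- params; cfg$seed <- as.integer(seed)
    rec <- run_simulation(cfg)
    pos <- rec$positions[rec$positions$animal == animal, ]
    pos <- pos[pos$time > burn_fraction * max(pos$time), ]
    if (n < nrow(pos)) pos <- pos[seq(1, nrow(pos), length.out = n), ]
    # continuity-unwrapped coordinates: telemetry has no periodic wrap
    df <- tibble::tibble(animal_id = animal,
                         x = if ("x_unwrapped" %in% names(pos))
                           pos$x_unwrapped else pos$x,
                         y = if ("y_unwrapped" %in% names(pos))
                           pos$y_unwrapped else pos$y,
                         t = pos$time)
    manifest <- run_manifest(cfg, seed, list(kind = kind, animal = animal))
  }
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  write.csv(df, out, row.names = FALSE)
  write_manifest(manifest, sub("\\.csv$", "_manifest.json", out))
  invisible(out)
}

#' Export a density curve on a user grid
#'
#' Evaluates one of the analytic densities on a grid and returns (and
#' optionally writes) a tidy curve.
#'
#' @param which one of `"marginal_1d"`, `"marginal_2d"`, `"border_left"`,
#'   `"border_right"`, `"radius"`, `"reduced_half"`, `"reduced_limit"`.
#' @param params an [analytic_params()].
#' @param n grid size.
#' @param out optional CSV path.
#' @return a `density_curve` tibble with `z` and `density`.
#' @export
density_curve <- function(which = c("marginal_1d", "marginal_2d",
                                    "border_left", "border_right", "radius",
                                    "reduced_half", "reduced_limit"),
                          params, n = 512, out = NULL) {
  which <- match.arg(which)
  grid <- switch(which,
    marginal_1d = seq(-1, 1, length.out = n),
    border_left = seq(-1, 0, length.out = n),
    border_right = seq(0, 1, length.out = n),
    reduced_half = ,
    reduced_limit = seq(1e-4, 1 - 1e-4, length.out = n),
    seq(0, radius_cutoff(params$eps), length.out = n))
  dens <- switch(which,
    marginal_1d = marginal_pdf_1d(grid, params),
    marginal_2d = marginal_pdf_2d(grid, params),
    border_left = border_pdf(grid, params, "left"),
    border_right = border_pdf(grid, params, "right"),
    radius = radius_pdf(grid, params),
    reduced_half = reduced_marginal_half(grid, params$beta, params$eps),
    reduced_limit = reduced_marginal_limit(grid, params$eps))
  curve <- tibble::tibble(z = grid, density = dens)
  attr(curve, "which") <- which
  attr(curve, "params") <- params
  class(curve) <- c("density_curve", class(curve))
  if (!is.null(out)) write.csv(curve, out, row.names = FALSE)
  curve
}
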