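#' Read a run configuration (YAML or JSON)
#'
#' Accepted top-level fields: `g`, `rho`, `rho_g`, `lambda`,
#' `lambda_out`, `k_b`, `edge_eps` (scalars or lists for sweeps),
#' `pattern` (`shape`, `outer_radius`, `inner_radius`), `seed`,
#' `n_seeds`, and `solver` (`dt`, `tol`, `max_steps`, `dt_max`).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("invalid configuration: unsupported config format '", ext, "'"))
}

config_pattern <- function(cfg) {
  pt <- cfg$pattern
  if (is.null(pt)) return(confinement_spec())
  confinement_spec(shape = if (is.null(pt$shape)) "circle" else pt$shape,
                   outer_radius = if (is.null(pt$outer_radius)) 172
                                  else pt$outer_radius,
                   inner_radius = pt$inner_radius)
}

config_params <- function(cfg) {
  take <- function(nm, def) if (is.null(cfg[[nm]])) def else cfg[[nm]]
  mechanics_params(K = take("K", 1),
                   rho = take("rho", 1)[1L],
                   g = take("g", 1)[1L],
                   rho_g = take("rho_g", 1)[1L],
                   lambda = take("lambda", 15),
                   lambda_out = take("lambda_out", 20),
                   k_b = take("k_b", 0.1),
                   edge_eps = take("edge_eps", 0.5))
}

config_solver <- function(cfg) {
  sv <- cfg$solver
  out <- list(dt = 0.01, tol = 0.05, max_steps = 20000, dt_max = 1)
  for (nm in names(out)) if (!is.null(sv[[nm]])) out[[nm]] <- sv[[nm]]
  out
}

#' Write a simulation state snapshot as JSON
#'
#' Serializes centers (with classes and mobility), the tessellation
#' (vertices, cell loops, junctions), the parameters and the run record
#' (energy, steps, convergence).
#'
#' @param state a `simulation_state`.
#' @param path output file.
#' @export
write_state_json <- function(state, path) {
  tess <- build_tessellation(state$centers)
  bounded_ids <- which(tess$bounded)
  loops <- lapply(bounded_ids, function(i)
    as.vector(attr(cell_polygon(tess, i), "vertex_id")))
  names(loops) <- as.character(bounded_ids)
  p <- state$params
  obj <- list(
    centers = data.frame(id = state$centers$id, x = state$centers$x,
                         y = state$centers$y,
                         class = state$centers$class,
                         mobile = state$centers$mobile),
    vertices = data.frame(id = seq_len(nrow(tess$vertices)),
                          x = tess$vertices[, 1L],
                          y = tess$vertices[, 2L]),
    cells = loops,
    junctions = tess$junctions,
    params = p[c("K", "rho", "g", "rho_g", "lambda", "lambda_out",
                 "k_b", "edge_eps")],
    pattern = state$pattern[c("shape", "outer_radius", "inner_radius",
                              "center")],
    run = list(seed = state$seed, phase = state$phase,
               energy = state$energy, step_count = state$step_count,
               converged = state$converged,
               stop_reason = state$stop_reason,
               max_force = state$max_force))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run's energy trace as CSV
#'
#' @param state a relaxed `simulation_state`.
#' @param path output file.
#' @export
write_energy_trace <- function(state, path) {
  utils::write.csv(
    data.frame(step = seq_along(state$energy_trace) - 1L,
               energy = state$energy_trace),
    path, row.names = FALSE)
  invisible(path)
}
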