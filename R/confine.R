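#' Initialize a confined micropattern
#'
#' Implements the two-phase confinement protocol: seed `n_per_side^2`
#' jittered-lattice cell centers in the square domain, demarcate the
#' pattern by thresholding each center's distance to the pattern center,
#' and round the border by relaxing the whole monolayer under the
#' initialization energy (area elasticity about the seeded intrinsic
#' areas `A0_a`, junction tension `lambda`, the rim tension `lambda_out`
#' on pattern-edge junctions, and the global area penalty `k_b`).  The
#' confinement is then frozen: exterior centers and the outermost
#' demarcated ring (the boundary cells, those sharing a junction with an
#' exterior cell) are fixed, and the remaining demarcated cells stay
#' movable.  The intrinsic areas `A0_a` are the seeded-tessellation
#' areas, kept unchanged through both phases; as every term dropped
#' between the phases depends only on centers that are fixed afterwards,
#' the rounded state is an exact main-phase equilibrium at
#' `g = rho = rho_g = 1`.
#'
#' @param spec a [confinement_spec()].
#' @param seed integer seed for the jittered lattice.
#' @param params a [mechanics_params()]; `K`, `lambda`, `lambda_out` and
#'   `k_b` are used in this phase.
#' @param n_per_side,domain_side,jitter passed to [generate_seed_points()].
#'   The defaults (25 cells per side, 693.1 um domain, jitter 0.08) give a
#'   27.7 um lattice spacing calibrated so the default 172 um circle
#'   demarcates about 121 cells, matching the in-vitro size ratio between
#'   cell and micropattern.
#' @param dt,tol,max_steps,dt_max,... solver settings for the
#'   border-rounding relaxation (see [relax()]).
#' @return a `simulation_state`: list with `centers`, `params` (now
#'   carrying the per-cell intrinsic areas), `pattern`, `energy`,
#'   `energy_trace`, `step_count`, `converged`, `seed`.
#' @export
initialize_pattern <- function(spec, seed = 1L,
                               params = mechanics_params(),
                               n_per_side = 25, domain_side = 693.1,
                               jitter = 0.08,
                               dt = 0.01, tol = 0.01, max_steps = 20000,
                               dt_max = 1, ...) {
  stopifnot(inherits(spec, "confinement_spec"))
  centers <- generate_seed_points(n_per_side, domain_side, jitter, seed)
  if (is.null(spec$center)) spec$center <- c(domain_side / 2, domain_side / 2)
  d <- sqrt((centers$x - spec$center[1])^2 + (centers$y - spec$center[2])^2)
  demarc <- if (spec$shape == "circle") d <= spec$outer_radius
            else d >= spec$inner_radius & d <= spec$outer_radius
  if (sum(demarc) < 20)
    stop("invalid configuration: demarcated pattern holds fewer than ",
         "20 cells")
  centers$class <- ifelse(demarc, "interior", "exterior")

  ## the seeded tessellation supplies the intrinsic areas A0_a of every
  ## cell in the square monolayer; they are kept through both phases
  tess0 <- build_tessellation(centers)
  if (any(demarc & !tess0$bounded))
    stop("degenerate geometry: demarcated cell is unbounded")
  params$A0_init <- tess0$areas
  params$A0_total_init <- sum(tess0$areas[demarc])

  ## during border rounding the whole monolayer relaxes; only the two
  ## outermost lattice rows (whose near-collinear trios make degenerate
  ## hull geometry) stay fixed as the frame
  h <- domain_side / n_per_side
  edge <- pmin(centers$x, centers$y,
               domain_side - centers$x, domain_side - centers$y)
  mobile <- edge > 2 * h & tess0$bounded
  centers$mobile <- mobile

  state <- structure(
    list(centers = centers, params = params, pattern = spec,
         domain_side = domain_side,
         cell_scale = domain_side / n_per_side, seed = seed,
         energy = NA_real_, energy_trace = numeric(0),
         step_count = 0L, converged = NA, phase = "seeded",
         n_demarcated = sum(demarc)),
    class = "simulation_state")
  state <- relax(state, "initialization", dt = dt, tol = tol,
                 max_steps = max_steps, dt_max = dt_max, ...)

  ## freeze the confinement; the intrinsic areas carry over unchanged, so
  ## the rounded state is an exact main-phase equilibrium at g = rho = 1
  tess1 <- build_tessellation(state$centers)
  state$params$A0 <- state$params$A0_init
  state$params$A0_total <- sum(tess1$areas[demarc])
  j <- tess1$junctions
  ext <- state$centers$class == "exterior"
  btouch <- c(j$cell1[ext[j$cell2]], j$cell2[ext[j$cell1]])
  boundary <- intersect(unique(btouch), which(demarc))
  state$centers$class[boundary] <- "boundary"
  state$centers$mobile <- state$centers$class == "interior"
  state$phase <- "initialized"
  state
}

#' Relax a confined monolayer to its main-phase equilibrium
#'
#' Applies the main-phase parameters (prestretch `g`, stiffness
#' differential `rho`, contractility differential `rho_g`, junction
#' tension `lambda`) to an initialized pattern and relaxes the interior
#' cell centers to mechanical equilibrium.  Boundary and exterior centers
#' stay fixed; boundary cells still deform and transmit forces through
#' their junctions and areas.
#'
#' @inheritParams initialize_pattern
#' @param g prestretch in `(0, 1]`.
#' @param rho stiffness differential in `(0, 1]`.
#' @param rho_g contractility differential in `(0, 1]`.
#' @param lambda junction tension for the main phase.
#' @param init optionally a precomputed state from [initialize_pattern()]
#'   (with matching `spec` and `seed`); when supplied the initialization
#'   is not rerun, which makes parameter sweeps over `g`, `rho`, `rho_g`
#'   cheap.
#' @param dt,tol,max_steps,dt_max,... solver settings for the main
#'   relaxation (see [relax()]).
#' @return the equilibrated `simulation_state` (phase `"main"`), carrying
#'   the main-phase parameters, energy trace and convergence flag.
#' @export
run_equilibrium <- function(spec = confinement_spec(), g = 1, rho = 1,
                            rho_g = 1, seed = 1L, lambda = 15,
                            params = mechanics_params(lambda = lambda),
                            init = NULL,
                            n_per_side = 25, domain_side = 693.1,
                            jitter = 0.08,
                            dt = 0.01, tol = 0.01, max_steps = 20000,
                            dt_max = 1, ...) {
  if (is.null(init))
    init <- initialize_pattern(spec, seed, params = params,
                               n_per_side = n_per_side,
                               domain_side = domain_side, jitter = jitter,
                               dt = dt, tol = tol, max_steps = max_steps,
                               dt_max = dt_max, ...)
  state <- init
  state$params$g <- g
  state$params$rho <- rho
  state$params$rho_g <- rho_g
  state$params$lambda <- params$lambda
  relax(state, "main", dt = dt, tol = tol, max_steps = max_steps,
        dt_max = dt_max, ...)
}

#' @export
print.simulation_state <- function(x, ...) {
  cls <- table(x$centers$class)
  cat("simulation_state (phase ", x$phase, "): ",
      nrow(x$centers), " centers [", paste(names(cls), cls,
      sep = "=", collapse = ", "), "]\n", sep = "")
  cat("  energy ", format(x$energy), ", steps ", x$step_count,
      ", converged ", x$converged, "\n", sep = "")
  if (!is.null(x$params$g))
    cat("  g=", x$params$g, " rho=", x$params$rho,
        " rho_g=", x$params$rho_g, " lambda=", x$params$lambda,
        "\n", sep = "")
  invisible(x)
}
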