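#' Global structure-parameter estimate for an image
#'
#' Convenience wrapper: orientation field, angle-deviation map, then the
#' energy-weighted k_H over pixels above the weight threshold, optionally
#' restricted to a radial band.
#'
#' @param image numeric matrix.
#' @param center pattern center `c(x, y)` in pixels.
#' @param window_sigma structure-tensor window (pixels).
#' @param weight_quantile weight threshold quantile (see [kH_profile()]).
#' @param r_limits optional radial band `c(min, max)` in pixels.
#' @return estimated k_H.
#' @export
estimate_kH <- function(image, center, window_sigma = 1.5,
                        weight_quantile = 0.5, r_limits = NULL) {
  field <- local_orientation(image, window_sigma)
  alpha <- angle_deviation_map(field, center)
  w <- field$weight
  pos <- w > 0 & !is.na(alpha)
  if (!any(pos)) stop("undefined statistic: no weighted pixels")
  thr <- stats::quantile(w[pos], weight_quantile)
  use <- pos & w >= thr
  if (!is.null(r_limits)) {
    nr <- nrow(image); nc <- ncol(image)
    px <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[1L]
    py <- matrix(seq_len(nr), nr, nc) - center[2L]
    r <- sqrt(px^2 + py^2)
    use <- use & r >= r_limits[1L] & r <= r_limits[2L]
  }
  structure_parameter(alpha[use], w[use])
}

#' Traction force on a micropost tip
#'
#' Cantilever-beam relation `F = (3 E I / L^3) x` for a solid circular
#' post, with area moment of inertia `I = pi d^4 / 64`.
#'
#' @param E elastic modulus of the post material (Pa).
#' @param diameter post diameter (m).
#' @param height post height `L` (m).
#' @param deflection tip deflection `x` (m).
#' @param I area moment of inertia; computed from `diameter` by default.
#' @return force in newtons (vectorized over `deflection`).
#' @examples
#' micropost_force(2.5e6, 2e-6, 8.4e-6, 1e-6)   # ~9.9 nN
#' @export
micropost_force <- function(E, diameter, height, deflection,
                            I = pi * diameter^4 / 64) {
  if (any(c(E, diameter, height) <= 0) || I <= 0)
    stop("invalid configuration: post geometry and modulus must be ",
         "positive")
  (3 * E * I / height^3) * deflection
}

#' Sweep the prestretch / stiffness-differential parameter grid
#'
#' Runs [run_equilibrium()] for every combination of `g`, `rho`, `rho_g`
#' and seed, reusing one initialization per seed, and reports per-cell
#' morphometrics plus per-condition descriptive group statistics
#' (mean +/- s.e.m. over the per-seed group means, interior vs boundary).
#' The default grid brackets the strongly separated corner (rho = 0.4,
#' g = 0.5) and the null corner (rho = g = 1).
#'
#' @param g,rho,rho_g parameter values, each in `(0, 1]`; the grid is
#'   their Cartesian product.
#' @param spec a [confinement_spec()].
#' @param n_seeds number of replicate patterns per condition.
#' @param seed_base seeds are `seed_base + 0:(n_seeds-1)`.
#' @param out_dir optional output directory; per-run cell tables are
#'   written there as CSV and already-present runs are skipped (the sweep
#'   is resumable), alongside `summary.csv` and a JSON run manifest.
#' @param params baseline [mechanics_params()].
#' @param verbose print one line per run.
#' @param ... solver settings forwarded to [run_equilibrium()].
#' @return list with `cells` (all per-cell rows), `summary` (one row per
#'   condition x class) and `manifest` (run bookkeeping).
#' @export
run_sweep <- function(g = c(0.5, 0.75, 1), rho = c(0.4, 0.7, 1),
                      rho_g = 1, spec = confinement_spec(), n_seeds = 5,
                      seed_base = 1L, out_dir = NULL,
                      params = mechanics_params(), verbose = FALSE, ...) {
  if (n_seeds < 1) stop("invalid configuration: 'n_seeds' must be >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- expand.grid(g = g, rho = rho, rho_g = rho_g,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- seed_base + seq_len(n_seeds) - 1L
  cells <- list()
  manifest <- list()
  for (sd in seeds) {
    init <- NULL
    for (k in seq_len(nrow(grid))) {
      tag <- sprintf("g%s_rho%s_rhog%s_seed%d", grid$g[k], grid$rho[k],
                     grid$rho_g[k], sd)
      csv <- if (is.null(out_dir)) NULL
             else file.path(out_dir, paste0("cells_", tag, ".csv"))
      if (!is.null(csv) && file.exists(csv)) {
        sm <- utils::read.csv(csv)
        conv <- TRUE; steps <- NA_integer_
      } else {
        if (is.null(init))
          init <- initialize_pattern(spec, seed = sd, params = params,
                                     ...)
        eq <- run_equilibrium(g = grid$g[k], rho = grid$rho[k],
                              rho_g = grid$rho_g[k], seed = sd,
                              params = params, init = init, ...)
        sm <- summarize_state(eq)
        conv <- isTRUE(eq$converged); steps <- eq$step_count
        if (!is.null(csv)) utils::write.csv(sm, csv, row.names = FALSE)
      }
      sm$g <- grid$g[k]; sm$rho <- grid$rho[k]; sm$rho_g <- grid$rho_g[k]
      sm$seed <- sd; sm$converged <- conv
      cells[[tag]] <- sm
      manifest[[tag]] <- list(g = grid$g[k], rho = grid$rho[k],
                              rho_g = grid$rho_g[k], seed = sd,
                              converged = conv, steps = steps)
      if (verbose)
        message(tag, ": ", if (conv) "converged" else "NOT converged")
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  summary <- sweep_summary(cells)
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cells = cells, summary = summary, manifest = manifest)
}

## Condition x class summary: mean +/- s.e.m. over per-seed group means.
sweep_summary <- function(cells) {
  key <- interaction(cells$g, cells$rho, cells$rho_g, drop = TRUE)
  do.call(rbind, lapply(split(cells, key), function(d) {
    do.call(rbind, lapply(split(d, d$class), function(dc) {
      per_seed <- split(dc, dc$seed)
      ms <- function(f) vapply(per_seed, function(s) {
        v <- f(s); mean(v[!is.na(v)])
      }, 1)
      sem <- function(v) stats::sd(v) / sqrt(length(v))
      a <- ms(function(s) s$area)
      e <- ms(function(s) s$elongation)
      ang <- ms(function(s) s$angle_deviation_deg)
      data.frame(g = dc$g[1L], rho = dc$rho[1L], rho_g = dc$rho_g[1L],
                 class = dc$class[1L], n_seeds = length(per_seed),
                 n_cells = nrow(dc),
                 mean_area = mean(a), sem_area = sem(a),
                 mean_elongation = mean(e), sem_elongation = sem(e),
                 mean_angle_deviation = mean(ang),
                 sem_angle_deviation = sem(ang),
                 all_converged = all(dc$converged),
                 row.names = NULL)
    }))
  }))
}
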