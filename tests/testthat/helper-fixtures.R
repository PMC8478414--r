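## Shared fixtures.  Equilibrium states are expensive (seconds), so they
## are memoised for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

cached_init <- function(seed) {
  memo(paste0("init", seed),
       suppressWarnings(initialize_pattern(confinement_spec(),
                                           seed = seed)))
}

cached_run <- function(g, rho, rho_g, seed) {
  memo(sprintf("run_%s_%s_%s_%s", g, rho, rho_g, seed),
       suppressWarnings(run_equilibrium(g = g, rho = rho, rho_g = rho_g,
                                        seed = seed,
                                        init = cached_init(seed))))
}

## Small confined configuration at unit length scale (mean cell area ~1),
## with classes, intrinsic areas and parameters set but NOT relaxed;
## positions of the demarcated cells are randomly jiggled.  Used for
## force/energy consistency checks where machine-precision finite
## differences need an O(100) energy scale.
make_confined_state <- function(seed, n_per_side = 9, domain_side = 9,
                                outer_radius = 2.8, jiggle = 0.05,
                                params = mechanics_params(edge_eps = 5e-4)) {
  centers <- generate_seed_points(n_per_side, domain_side, 0.2, seed)
  ctr <- c(domain_side / 2, domain_side / 2)
  spec <- confinement_spec(outer_radius = outer_radius)
  spec$center <- ctr
  d <- sqrt((centers$x - ctr[1])^2 + (centers$y - ctr[2])^2)
  demarc <- d <= outer_radius
  centers$class <- ifelse(demarc, "interior", "exterior")
  tess0 <- build_tessellation(centers)
  params$A0_init <- tess0$areas
  params$A0_total_init <- sum(tess0$areas[demarc])
  params$A0 <- params$A0_init
  params$A0_total <- params$A0_total_init
  j <- tess0$junctions
  ext <- centers$class == "exterior"
  btouch <- c(j$cell1[ext[j$cell2]], j$cell2[ext[j$cell1]])
  boundary <- intersect(unique(btouch), which(demarc))
  centers$class[boundary] <- "boundary"
  centers$mobile <- centers$class == "interior"
  mi <- which(centers$mobile)
  centers$x[mi] <- centers$x[mi] + stats::runif(length(mi), -jiggle, jiggle)
  centers$y[mi] <- centers$y[mi] + stats::runif(length(mi), -jiggle, jiggle)
  structure(list(centers = centers, params = params, pattern = spec,
                 domain_side = domain_side,
                 cell_scale = domain_side / n_per_side, seed = seed),
            class = "simulation_state")
}

## Central finite differences of the total energy for selected centers.
fd_forces <- function(state, phase, ids, h = 1e-6) {
  out <- matrix(NA_real_, length(ids), 2L)
  for (k in seq_along(ids)) {
    i <- ids[k]
    for (comp in 1:2) {
      sp <- state; sm <- state
      col <- if (comp == 1) "x" else "y"
      sp$centers[[col]][i] <- sp$centers[[col]][i] + h
      sm$centers[[col]][i] <- sm$centers[[col]][i] - h
      out[k, comp] <- -(total_energy(sp, phase) -
                        total_energy(sm, phase)) / (2 * h)
    }
  }
  out
}

## Regular n-gon (counter-clockwise) with given circumradius and center.
regular_polygon <- function(n, circumradius = 1, center = c(0, 0),
                            phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + circumradius * cos(th),
        center[2] + circumradius * sin(th))
}
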