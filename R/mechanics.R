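## Mechanics core: monolayer energy, analytic forces on cell centers via
## the chain rule through the Voronoi vertices, and gradient-flow
## relaxation.
##
## The total energy is a sum of per-cell terms
##   E_a = 1/2 K_a (g_a A0_a) (A_a/(g_a A0_a) - 1)^2 + sum_{b in Gamma_a} lambda l_b
## so a junction shared by two energy-bearing cells contributes twice to
## the total.  During initialization the prestretch is 1, pattern-rim
## junctions carry lambda + lambda_out in place of the bulk 2*lambda, and
## a global penalty 1/2 k_b A0 (A/A0 - 1)^2 keeps the micropattern area
## near its seeded value.

## Per-cell effective parameter vectors for one phase, aligned to the
## full center table.
##
## Initialization phase: the monolayer fills the whole square, so every
## bounded cell carries an elastic term (K, g = 1) and every junction the
## tension lambda; junctions crossing the pattern rim additionally carry
## lambda_out, and the demarcated patch area enters the global k_b
## penalty.  Main phase: only non-exterior cells remain tissue; boundary
## cells take the stiffness differential rho and contractility
## differential rho_g.
mech_fields <- function(state, phase = c("main", "initialization")) {
  phase <- match.arg(phase)
  p <- state$params
  cls <- state$centers$class
  n <- nrow(state$centers)
  in_patch <- !is.na(cls) & cls != "exterior"
  eps <- if (is.null(p$edge_eps)) 0 else p$edge_eps
  if (phase == "initialization") {
    if (is.null(p$A0_init))
      stop("invalid state: initialization-phase intrinsic areas not set")
    ## the init monolayer covers the whole square; the outermost lattice
    ## rows next to the convex hull are excluded so that hull slivers
    ## (whose circumcenters shoot far out) never carry tension
    in_energy <- rep(TRUE, n)
    if (!is.null(state$domain_side)) {
      sc <- if (is.null(state$cell_scale)) 1 else state$cell_scale
      edge <- pmin(state$centers$x, state$centers$y,
                   state$domain_side - state$centers$x,
                   state$domain_side - state$centers$y)
      in_energy <- edge > 0.8 * sc
    }
    list(phase = phase, in_energy = in_energy, in_patch = in_patch,
         Kc = rep(p$K, n), gA0 = p$A0_init,
         lam = p$lambda, lamout = p$lambda_out, kb = p$k_b,
         A0_total = p$A0_total_init, eps = eps)
  } else {
    if (is.null(p$A0))
      stop("invalid state: intrinsic areas A0 not set (run ",
           "initialize_pattern first)")
    bnd <- !is.na(cls) & cls == "boundary"
    Kc <- ifelse(in_patch, p$K * ifelse(bnd, p$rho, 1), 0)
    geff <- p$g * ifelse(bnd, p$rho_g, 1)
    gA0 <- ifelse(in_patch, geff * p$A0, NA_real_)
    list(phase = phase, in_energy = in_patch, in_patch = in_patch,
         Kc = Kc, gA0 = gA0,
         lam = p$lambda, lamout = 0, kb = 0, A0_total = NA_real_,
         eps = eps)
  }
}

## Energy, analytic forces and areas for a coordinate set.  All vectors in
## `fld` must be aligned to (x, y).  `mobile` marks centers allowed to
## move; forces on fixed centers are reported as zero.
mech_eval <- function(x, y, fld, mobile, want_forces = TRUE) {
  g <- geom_core(x, y)
  if (any(mobile & g$hull))
    stop("degenerate geometry: a movable cell center reached the ",
         "convex hull")
  ## unbounded (hull) cells and cells without a recorded intrinsic area
  ## drop out of the energy; they are fixed frame cells whose terms are
  ## constants
  fld$in_energy <- fld$in_energy & !g$hull & is.finite(fld$gA0)
  fld$in_patch <- fld$in_patch & fld$in_energy
  n <- length(x)
  c1x <- g$omega[g$jt1, 1L]; c1y <- g$omega[g$jt1, 2L]
  c2x <- g$omega[g$jt2, 1L]; c2y <- g$omega[g$jt2, 2L]
  rax <- x[g$jc1]; ray <- y[g$jc1]
  rbx <- x[g$jc2]; rby <- y[g$jc2]
  ## CCW orientation sign for cell jc1
  s <- sign((c2x - c1x) * (ray - rby) + (c2y - c1y) * (rbx - rax))
  s[s == 0] <- 1
  crossA <- (c1x - rax) * (c2y - ray) - (c1y - ray) * (c2x - rax)
  crossB <- (c1x - rbx) * (c2y - rby) - (c1y - rby) * (c2x - rbx)
  contrib <- c(0.5 * s * crossA, -0.5 * s * crossB)
  grp <- c(g$jc1, g$jc2)
  areas <- numeric(n)
  sums <- rowsum(contrib, grp)
  areas[as.integer(rownames(sums))] <- sums[, 1L]
  areas[g$hull] <- NA_real_

  inE <- fld$in_energy
  Arel <- areas[inE] / fld$gA0[inE] - 1
  E_el <- sum(0.5 * fld$Kc[inE] * fld$gA0[inE] * Arel^2)

  lx <- c2x - c1x; ly <- c2y - c1y
  l <- sqrt(lx^2 + ly^2)
  sl <- sqrt(l^2 + fld$eps^2)           # smoothed junction length
  aE <- inE[g$jc1]; bE <- inE[g$jc2]
  coef <- 2 * fld$lam * (aE & bE)       # once per adjacent tissue cell
  if (fld$phase == "initialization") {
    ## pattern-rim junctions carry lambda + lambda_out, both attributed
    ## to the demarcated cell (the exterior partner is slated for removal
    ## at confinement and contributes no tension across the rim)
    rim <- xor(fld$in_patch[g$jc1] & aE, fld$in_patch[g$jc2] & bE)
    coef <- coef - fld$lam * rim + fld$lamout * rim
  }
  E_ten <- sum(coef * (sl - fld$eps))

  E_area <- 0
  dEdAtot <- 0
  if (fld$phase == "initialization" && fld$kb > 0) {
    Atot <- sum(areas[fld$in_patch])
    E_area <- 0.5 * fld$kb * fld$A0_total * (Atot / fld$A0_total - 1)^2
    dEdAtot <- fld$kb * (Atot / fld$A0_total - 1)
  }
  E <- E_el + E_ten + E_area
  if (!want_forces)
    return(list(E = E, areas = areas, geom = g, forces = NULL,
                max_force = NA_real_))

  ## dE/dA per cell
  eA <- numeric(n)
  eA[inE] <- fld$Kc[inE] * Arel
  eA[fld$in_patch] <- eA[fld$in_patch] + dEdAtot

  ## accumulate dE/domega over junctions
  m <- nrow(g$omega)
  w1 <- eA[g$jc1] * 0.5 * s       # weight of crossA
  w2 <- -eA[g$jc2] * 0.5 * s      # weight of crossB
  ## d crossA/d c1 = (c2y - ray, -(c2x - rax)); d/d c2 = (-(c1y - ray), c1x - rax)
  g1x <- w1 * (c2y - ray) + w2 * (c2y - rby)
  g1y <- -w1 * (c2x - rax) - w2 * (c2x - rbx)
  g2x <- -w1 * (c1y - ray) - w2 * (c1y - rby)
  g2y <- w1 * (c1x - rax) + w2 * (c1x - rbx)
  ## tension: d(coef*sl)/dc1 = coef*(c1-c2)/sl
  tl <- if (fld$eps > 0) coef / sl else {
    tmp <- numeric(length(l)); pos <- l > 1e-12
    tmp[pos] <- coef[pos] / l[pos]; tmp
  }
  g1x <- g1x - tl * lx; g1y <- g1y - tl * ly
  g2x <- g2x + tl * lx; g2y <- g2y + tl * ly
  gox <- numeric(m); goy <- numeric(m)
  sx <- rowsum(c(g1x, g2x), c(g$jt1, g$jt2))
  sy <- rowsum(c(g1y, g2y), c(g$jt1, g$jt2))
  gox[as.integer(rownames(sx))] <- sx[, 1L]
  goy[as.integer(rownames(sy))] <- sy[, 1L]

  ## chain rule through the circumcenter: omega solves M omega = q with
  ## M = 2 [(p2-p1)'; (p3-p1)'].
  t1 <- g$tri[, 1L]; t2 <- g$tri[, 2L]; t3 <- g$tri[, 3L]
  p1x <- x[t1]; p1y <- y[t1]; p2x <- x[t2]; p2y <- y[t2]
  p3x <- x[t3]; p3y <- y[t3]
  ox <- g$omega[, 1L]; oy <- g$omega[, 2L]
  m11 <- 2 * (p2x - p1x); m12 <- 2 * (p2y - p1y)
  m21 <- 2 * (p3x - p1x); m22 <- 2 * (p3y - p1y)
  det <- m11 * m22 - m12 * m21
  i11 <- m22 / det; i12 <- -m12 / det
  i21 <- -m21 / det; i22 <- m11 / det
  ## gradient contributions: node2 gets (go . Minv[,1]) * 2*(p2 - omega), etc.
  a2 <- gox * i11 + goy * i21
  a3 <- gox * i12 + goy * i22
  a1 <- a2 + a3
  gc_x <- rowsum(c(a1 * 2 * (ox - p1x), a2 * 2 * (p2x - ox),
                   a3 * 2 * (p3x - ox)), c(t1, t2, t3))
  gc_y <- rowsum(c(a1 * 2 * (oy - p1y), a2 * 2 * (p2y - oy),
                   a3 * 2 * (p3y - oy)), c(t1, t2, t3))
  Fx <- numeric(n); Fy <- numeric(n)
  Fx[as.integer(rownames(gc_x))] <- -gc_x[, 1L]
  Fy[as.integer(rownames(gc_y))] <- -gc_y[, 1L]
  Fx[!mobile] <- 0; Fy[!mobile] <- 0
  maxF <- if (any(mobile)) max(abs(c(Fx[mobile], Fy[mobile]))) else 0
  list(E = E, areas = areas, geom = g,
       forces = cbind(Fx, Fy), max_force = maxF)
}

#' Total monolayer energy
#'
#' Sums the per-cell energies of all non-exterior cells (a junction shared
#' by two tissue cells therefore contributes twice its tension term); in
#' the initialization phase the global area penalty
#' `1/2 k_b A0 (A/A0 - 1)^2` is added, with `A` the total area of the
#' demarcated cells.
#'
#' @param state a `simulation_state` from [initialize_pattern()] or
#'   [run_equilibrium()].
#' @param phase `"main"` or `"initialization"`.
#' @return scalar energy.
#' @export
total_energy <- function(state, phase = c("main", "initialization")) {
  fld <- mech_fields(state, match.arg(phase))
  mech_eval(state$centers$x, state$centers$y, fld,
            mobile = state$centers$mobile, want_forces = FALSE)$E
}

#' Per-cell energies
#'
#' Each cell's elastic term plus its own junction-tension sum (per-cell
#' convention: the shared junction appears once in each adjacent cell's
#' energy).
#'
#' @inheritParams total_energy
#' @return numeric vector, `NA` for cells outside the energy sum.
#' @export
cell_energies <- function(state, phase = c("main", "initialization")) {
  phase <- match.arg(phase)
  fld <- mech_fields(state, phase)
  x <- state$centers$x; y <- state$centers$y
  ev <- mech_eval(x, y, fld, mobile = state$centers$mobile,
                  want_forces = FALSE)
  g <- ev$geom
  n <- length(x)
  out <- rep(NA_real_, n)
  inE <- fld$in_energy & !g$hull & is.finite(fld$gA0)
  out[inE] <- 0.5 * fld$Kc[inE] * fld$gA0[inE] *
    (ev$areas[inE] / fld$gA0[inE] - 1)^2
  l <- sqrt((g$omega[g$jt1, 1L] - g$omega[g$jt2, 1L])^2 +
            (g$omega[g$jt1, 2L] - g$omega[g$jt2, 2L])^2)
  l <- sqrt(l^2 + fld$eps^2) - fld$eps   # same regularization as the total
  aE <- inE[g$jc1]; bE <- inE[g$jc2]
  both <- aE & bE
  add <- function(cells, val) {
    if (!length(cells)) return()
    sm <- rowsum(val, cells)
    ids <- as.integer(rownames(sm))
    out[ids] <<- out[ids] + sm[, 1L]
  }
  inP <- fld$in_patch & inE
  rim <- if (phase == "initialization") xor(inP[g$jc1], inP[g$jc2])
         else rep(FALSE, length(l))
  nr_ <- both & !rim
  add(c(g$jc1[nr_], g$jc2[nr_]), rep(fld$lam * l[nr_], 2L))
  if (any(rim)) {
    rimcell <- ifelse(inP[g$jc1], g$jc1, g$jc2)[rim]
    add(rimcell, (fld$lam + fld$lamout) * l[rim])
  }
  out
}

#' Forces on cell centers
#'
#' Analytic gradient `-dE/dr` of the total energy with respect to every
#' movable cell center, chained through the dependence of each Voronoi
#' vertex on its three generating centers.  Fixed centers receive zero.
#'
#' @inheritParams total_energy
#' @return n x 2 matrix of force components.
#' @export
forces <- function(state, phase = c("main", "initialization")) {
  fld <- mech_fields(state, match.arg(phase))
  ev <- mech_eval(state$centers$x, state$centers$y, fld,
                  mobile = state$centers$mobile)
  unname(ev$forces)
}

#' Relax a state to mechanical equilibrium by gradient flow
#'
#' Explicit-Euler descent `r <- r + dt * F` on the movable cell centers,
#' with the tessellation rebuilt after every move.  A step that increases
#' the energy (or degenerates the geometry) is rejected and retried with
#' `dt` halved; after accepted steps `dt` recovers geometrically up to
#' `dt_max`, so accepted energies are non-increasing while the flow still
#' takes near-maximal stable steps.
#'
#' @inheritParams total_energy
#' @param dt initial time step.
#' @param tol convergence tolerance on the largest movable-center force
#'   component.
#' @param max_steps maximum number of accepted steps.
#' @param dt_max upper bound for the adaptive step.
#' @param plateau_tol,plateau_window secondary stopping rule: stop when
#'   the mean energy decrease per accepted step over the last
#'   `plateau_window` steps falls below `plateau_tol * (1 + |E|)`.  With
#'   strong junction tension the minimizer can sit in a narrow
#'   rosette-stabilized valley where the descent creeps while the
#'   configuration no longer changes measurably; the plateau rule
#'   recognises that state as converged (`$stop_reason` records which
#'   rule fired).
#' @param trace_every record the energy every this many accepted steps
#'   (the first and last step are always recorded).
#' @return the updated `simulation_state`; `$energy_trace` holds the
#'   accepted-step energies, `$converged` the convergence flag (a
#'   non-converged run carries a warning, not an error), `$step_count`
#'   the accepted steps taken.
#' @export
relax <- function(state, phase = c("main", "initialization"),
                  dt = 0.01, tol = 0.01, max_steps = 20000,
                  dt_max = 1, plateau_tol = 1e-10,
                  plateau_window = 200L, trace_every = 1L) {
  phase <- match.arg(phase)
  fld_full <- mech_fields(state, phase)
  n <- nrow(state$centers)
  ## restrict the working tessellation to centers near the pattern: every
  ## energy-bearing cell and its 2-ring force stencil lies well inside.
  ## the whole square stays in play during initialization (the outermost
  ## lattice rows are the geometric frame for everything else); only the
  ## main phase, where just the pattern interior moves, can be cut down
  act <- rep(TRUE, n)
  if (phase == "main" && !is.null(state$pattern)) {
    sc <- if (is.null(state$cell_scale)) 1 else state$cell_scale
    ctr <- state$pattern$center
    d <- sqrt((state$centers$x - ctr[1])^2 + (state$centers$y - ctr[2])^2)
    ## two rows of frame beyond the energy-bearing cells: the local
    ## tessellation around every energy term matches the full domain, and
    ## slivers at the artificial subset rim never carry tension
    act <- d <= state$pattern$outer_radius + 5 * sc
    act <- act | fld_full$in_energy | state$centers$mobile
  }
  idx <- which(act)
  x <- state$centers$x[idx]; y <- state$centers$y[idx]
  mobile <- state$centers$mobile[idx]
  fld <- fld_full
  for (nm in c("in_energy", "in_patch", "Kc", "gA0"))
    fld[[nm]] <- fld_full[[nm]][idx]

  ev <- mech_eval(x, y, fld, mobile)
  trace <- ev$E
  ehist <- numeric(max_steps + 1L); ehist[1L] <- ev$E
  steps <- 0L
  converged <- ev$max_force < tol
  stop_reason <- if (converged) "force_tol" else "max_steps"
  mi <- which(mobile)
  while (!converged && steps < max_steps) {
    accepted <- FALSE
    while (!accepted) {
      xn <- x; yn <- y
      xn[mi] <- x[mi] + dt * ev$forces[mi, 1L]
      yn[mi] <- y[mi] + dt * ev$forces[mi, 2L]
      evn <- tryCatch(mech_eval(xn, yn, fld, mobile),
                      error = function(e) NULL)
      if (!is.null(evn) && is.finite(evn$E) && evn$E <= ev$E) {
        accepted <- TRUE
        x <- xn; y <- yn; ev <- evn
        dt <- min(dt * 1.1, dt_max)
      } else {
        dt <- dt / 2
        if (dt < 1e-14) {
          warning("relaxation stalled: step size underflow")
          accepted <- TRUE   # keep current state, bail out below
          steps <- max_steps
        }
      }
    }
    steps <- steps + 1L
    ehist[steps + 1L] <- ev$E
    if (steps %% trace_every == 0L) trace <- c(trace, ev$E)
    if (ev$max_force < tol) {
      converged <- TRUE
      stop_reason <- "force_tol"
    } else if (steps > plateau_window &&
               ehist[steps + 1L - plateau_window] - ev$E <
                 plateau_tol * plateau_window * (1 + abs(ev$E))) {
      ## energy decrease per step has fallen below resolution: the state
      ## sits in a (possibly rosette-pinned) minimum
      converged <- TRUE
      stop_reason <- "energy_plateau"
    }
  }
  if (!converged)
    warning("relaxation did not converge in ", max_steps,
            " steps (max force ", format(ev$max_force), ")")
  if (trace[length(trace)] != ev$E) trace <- c(trace, ev$E)
  state$centers$x[idx] <- x
  state$centers$y[idx] <- y
  ## report energies on the full-domain scale: cells outside the working
  ## subset contribute a constant offset
  if (length(idx) < n) {
    Efull <- mech_eval(state$centers$x, state$centers$y, fld_full,
                       state$centers$mobile, want_forces = FALSE)$E
    trace <- trace + (Efull - ev$E)
    ev$E <- Efull
  }
  state$energy <- ev$E
  state$energy_trace <- trace
  state$step_count <- steps
  state$converged <- converged
  state$stop_reason <- stop_reason
  state$max_force <- ev$max_force
  state$phase <- phase
  state
}
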