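#' Shape tensor of a cell polygon
#'
#' `S = (1/Z) sum_i z_i (x) z_i`, the mean outer product of the vectors
#' `z_i` from the polygon's area centroid to its `Z` vertices.  Its two
#' eigenvalues (units length^2) describe the squared extent of the cell
#' along its principal axes.
#'
#' @param loop matrix of polygon vertices in order (columns x, y).
#' @return symmetric positive semidefinite 2 x 2 matrix.
#' @export
shape_tensor <- function(loop) {
  loop <- as.matrix(loop)
  if (nrow(loop) < 3L)
    stop("invalid polygon: fewer than 3 vertices")
  ctr <- polygon_centroid(loop)
  z <- sweep(loop, 2L, ctr)
  crossprod(z) / nrow(loop)
}

#' Cell elongation from a shape tensor
#'
#' Ratio of the larger to the smaller shape-tensor eigenvalue
#' (`max(lambda_a, lambda_b) / min(lambda_a, lambda_b)`); 1 for an
#' isotropic cell.  Note this is an eigenvalue (squared-axis) ratio.
#'
#' @param S 2 x 2 symmetric positive definite shape tensor.
#' @return elongation >= 1.
#' @export
elongation <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-12 * sum(ev))
    stop("degenerate shape: near-zero minor eigenvalue")
  ev[1L] / ev[2L]
}

#' Angle deviation of a cell's major axis from the radial direction
#'
#' The acute angle (degrees, in `[0, 90]`) between the eigenvector of the
#' larger shape-tensor eigenvalue and the outward radial direction from
#' the pattern center through the cell centroid.  0 means radial
#' alignment, 90 circumferential, 45 the isotropic expectation.  For a
#' near-isotropic cell (elongation below `1 + tol`) the orientation is
#' undefined and `NA` is returned.
#'
#' @param S shape tensor.
#' @param centroid cell centroid (length-2).
#' @param pattern_center pattern center (length-2).
#' @param tol elongation margin below which the axis is treated as
#'   undefined.
#' @return angle in degrees, or `NA` for a degenerate (isotropic) cell.
#' @export
angle_deviation <- function(S, centroid, pattern_center, tol = 1e-6) {
  rad <- centroid - pattern_center
  nr <- sqrt(sum(rad^2))
  if (nr == 0)
    stop("undefined radial direction: centroid at the pattern center")
  ee <- eigen(S, symmetric = TRUE)
  if (ee$values[1L] / ee$values[2L] < 1 + tol) return(NA_real_)
  v <- ee$vectors[, 1L]
  ca <- abs(sum(v * rad)) / nr
  acos(min(max(ca, 0), 1)) * 180 / pi
}

#' Principal cell strains from the shape tensor
#'
#' The shape-tensor eigenvalues are rescaled so that the ellipse they
#' represent has the cell's area `A`; its semi-axes divided by the radius
#' `sqrt(g A0 / pi)` of the stress-free circular configuration (area
#' `g A0`) give the two principal stretches.  An isotropic cell at its
#' rest area yields `(1, 1)`, and the product of the stretches always
#' equals `A / (g A0)`.
#'
#' @param S shape tensor.
#' @param area cell area `A`.
#' @param gA0 stress-free (prestretched) reference area `g A0`.
#' @return numeric `c(eps_a, eps_b)` with `eps_a >= eps_b > 0`.
#' @export
cell_strains <- function(S, area, gA0) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-12 * sum(ev))
    stop("degenerate shape: near-zero minor eigenvalue")
  ## semi-axes proportional to sqrt(eigenvalue), scaled to enclose area A
  scale2 <- area / (pi * sqrt(ev[1L] * ev[2L]))
  semi <- sqrt(ev * scale2)
  unname(semi / sqrt(gA0 / pi))
}

#' Per-cell average stress tensor
#'
#' `sigma = (1/A) sum_b (Lambda_b / 2) t_b (x) t_b l_b
#'  + K_eff (A / (g_eff A0) - 1) I`,
#' where the sum runs over the cell's junctions with unit direction
#' `t_b`, length `l_b` and tension `Lambda_b`, and the second term is the
#' isotropic elastic pressure.  Positive diagonal values are tensile.
#'
#' @param loop cell polygon vertices in order; consecutive vertices bound
#'   the cell's junctions.
#' @param lambda per-edge junction tension, recycled as needed (use 0 for
#'   edges without tension, e.g. pattern-rim junctions).
#' @param area cell area.
#' @param K_eff effective stiffness of the cell.
#' @param gA0 effective stress-free area `g_eff A0`.
#' @return symmetric 2 x 2 stress tensor.
#' @export
cell_stress <- function(loop, lambda, area, K_eff, gA0) {
  loop <- as.matrix(loop)
  nv <- nrow(loop)
  if (nv < 3L) stop("invalid polygon: fewer than 3 vertices")
  lambda <- rep_len(lambda, nv)
  nxt <- c(seq_len(nv)[-1L], 1L)
  ex <- loop[nxt, 1L] - loop[, 1L]
  ey <- loop[nxt, 2L] - loop[, 2L]
  l <- sqrt(ex^2 + ey^2)
  keep <- l > 0
  ex <- ex[keep] / l[keep]; ey <- ey[keep] / l[keep]
  lk <- l[keep]; lam <- lambda[keep]
  sxx <- sum(lam / 2 * ex * ex * lk)
  sxy <- sum(lam / 2 * ex * ey * lk)
  syy <- sum(lam / 2 * ey * ey * lk)
  press <- K_eff * (area / gA0 - 1)
  matrix(c(sxx / area + press, sxy / area,
           sxy / area, syy / area + press), 2L, 2L)
}

#' Morphometric summary of an equilibrated state
#'
#' One row per non-exterior cell with the geometric readouts (area,
#' elongation, angle deviation from the radial direction, normalized
#' radius) and the mechanical readouts (principal strains, radial and
#' circumferential stress).  Near-isotropic cells carry `NA` angle
#' deviation.
#'
#' @param state a `simulation_state` (typically from [run_equilibrium()]).
#' @return data frame with columns `cell_id`, `class`, `x`, `y`,
#'   `normalized_radius`, `area`, `elongation`, `angle_deviation_deg`,
#'   `lambda_a`, `lambda_b`, `eps_a`, `eps_b`, `sigma_rr`, `sigma_tt`.
#' @export
summarize_state <- function(state) {
  tess <- build_tessellation(state$centers)
  cls <- state$centers$class
  ids <- which(!is.na(cls) & cls != "exterior")
  p <- state$params
  ctr <- state$pattern$center
  ext <- !is.na(cls) & cls == "exterior"
  ## junction tension map: lambda on junctions between two tissue cells
  jkey <- paste(pmin(tess$junctions$vertex1, tess$junctions$vertex2),
                pmax(tess$junctions$vertex1, tess$junctions$vertex2))
  jlam <- ifelse(ext[tess$junctions$cell1] | ext[tess$junctions$cell2],
                 0, p$lambda)
  names(jlam) <- jkey
  out <- do.call(rbind, lapply(ids, function(i) {
    loop <- cell_polygon(tess, i)
    vid <- attr(loop, "vertex_id")
    S <- shape_tensor(loop)
    ctd <- polygon_centroid(loop)
    A <- tess$areas[i]
    bnd <- cls[i] == "boundary"
    K_eff <- p$K * if (bnd) p$rho else 1
    gA0 <- p$g * (if (bnd) p$rho_g else 1) * p$A0[i]
    nv <- length(vid)
    ekey <- paste(pmin(vid, c(vid[-1L], vid[1L])),
                  pmax(vid, c(vid[-1L], vid[1L])))
    lam <- unname(jlam[ekey]); lam[is.na(lam)] <- 0
    sig <- cell_stress(loop, lam, A, K_eff, gA0)
    rad <- ctd - ctr; nr <- sqrt(sum(rad^2))
    rhat <- rad / nr; that <- c(-rhat[2L], rhat[1L])
    eps <- cell_strains(S, A, gA0)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    data.frame(cell_id = i, class = cls[i], x = ctd[1L], y = ctd[2L],
               normalized_radius = nr / state$pattern$outer_radius,
               area = A,
               elongation = ev[1L] / ev[2L],
               angle_deviation_deg = angle_deviation(S, ctd, ctr),
               lambda_a = ev[1L], lambda_b = ev[2L],
               eps_a = eps[1L], eps_b = eps[2L],
               sigma_rr = drop(rhat %*% sig %*% rhat),
               sigma_tt = drop(that %*% sig %*% that))
  }))
  rownames(out) <- NULL
  out
}

#' Group summary (mean +/- s.e.m.) of a morphometric table
#'
#' Descriptive statistics of area, elongation and angle deviation for
#' interior vs boundary cells.  Cells with undefined (near-isotropic)
#' angle deviation are excluded from the angle mean; their count is
#' reported.
#'
#' @param summary a data frame from [summarize_state()].
#' @return data frame with one row per cell class.
#' @export
summarize_groups <- function(summary) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  do.call(rbind, lapply(split(summary, summary$class), function(d) {
    ang <- d$angle_deviation_deg[!is.na(d$angle_deviation_deg)]
    data.frame(class = d$class[1L], n_cells = nrow(d),
               mean_area = mean(d$area), sem_area = sem(d$area),
               mean_elongation = mean(d$elongation),
               sem_elongation = sem(d$elongation),
               mean_angle_deviation = mean(ang),
               sem_angle_deviation = sem(ang),
               n_angle_undefined = sum(is.na(d$angle_deviation_deg)),
               row.names = NULL)
  }))
}
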