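#' Voronoi vertex of a trio of adjacent cell centers
#'
#' The Voronoi tessellation is dual to the Delaunay triangulation: each
#' Delaunay triangle of cell centers contributes one Voronoi vertex, the
#' circumcenter of the trio, expressed in barycentric form
#' `omega = a r_i + b r_j + c r_k`.
#'
#' @param r_i,r_j,r_k numeric length-2 vectors, the three cell centers.
#' @return list with `omega` (the vertex), and barycentric weights
#'   `a`, `b`, `c` (summing to 1).
#' @examples
#' compute_vertex(c(0, 0), c(2, 0), c(0, 2))$omega  # c(1, 1)
#' @export
compute_vertex <- function(r_i, r_j, r_k) {
  u <- r_i - r_j; v <- r_j - r_k; w <- r_i - r_k
  cr <- u[1] * v[2] - u[2] * v[1]
  D <- 2 * cr * cr
  L2 <- max(sum(u^2), sum(v^2), sum(w^2))
  if (D <= 1e-12 * L2 * L2)
    stop("degenerate geometry: collinear trio of cell centers")
  a <- sum(v^2) * sum(u * w) / D
  b <- sum(w^2) * sum(-u * v) / D
  c_ <- sum(u^2) * sum((r_k - r_i) * (r_k - r_j)) / D
  list(omega = a * r_i + b * r_j + c_ * r_k, a = a, b = b, c = c_)
}

## Vectorised circumcenters for triangles given as index matrix `tri`
## into coordinates (x, y).  Returns an n_tri x 2 matrix.
circumcenters <- function(tri, x, y) {
  p1x <- x[tri[, 1L]]; p1y <- y[tri[, 1L]]
  p2x <- x[tri[, 2L]]; p2y <- y[tri[, 2L]]
  p3x <- x[tri[, 3L]]; p3y <- y[tri[, 3L]]
  ux <- p1x - p2x; uy <- p1y - p2y
  vx <- p2x - p3x; vy <- p2y - p3y
  wx <- p1x - p3x; wy <- p1y - p3y
  cr <- ux * vy - uy * vx
  D <- 2 * cr * cr
  L2 <- pmax(ux^2 + uy^2, vx^2 + vy^2, wx^2 + wy^2)
  if (any(D <= 1e-12 * L2 * L2))
    stop("degenerate geometry: collinear triangle in triangulation")
  a <- (vx^2 + vy^2) * (ux * wx + uy * wy) / D
  b <- (wx^2 + wy^2) * (-ux * vx - uy * vy) / D
  cc <- (ux^2 + uy^2) * ((p3x - p1x) * (p3x - p2x) +
                         (p3y - p1y) * (p3y - p2y)) / D
  cbind(a * p1x + b * p2x + cc * p3x,
        a * p1y + b * p2y + cc * p3y)
}

## Core geometry used by both build_tessellation() and the mechanics
## evaluator: triangles, Voronoi vertices, junction table, hull flags.
geom_core <- function(x, y) {
  tm <- interp::tri.mesh(x, y)
  tr <- interp::triangles(tm)
  tri <- tr[, 1:3, drop = FALSE]
  nb <- tr[, 4:6, drop = FALSE]
  omega <- circumcenters(tri, x, y)
  m <- nrow(tri)
  idx <- seq_len(m)
  ## junction for each internal Delaunay edge: neighbour triangle nb[, i]
  ## lies opposite node i, so the shared edge is the other two nodes
  jc1 <- integer(0); jc2 <- integer(0); jt1 <- integer(0); jt2 <- integer(0)
  other <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  for (i in 1:3) {
    keep <- nb[, i] > idx        # each internal edge once
    if (!any(keep)) next
    jc1 <- c(jc1, tri[keep, other[[i]][1L]])
    jc2 <- c(jc2, tri[keep, other[[i]][2L]])
    jt1 <- c(jt1, idx[keep])
    jt2 <- c(jt2, nb[keep, i])
  }
  hull <- logical(length(x))
  for (i in 1:3) {
    bd <- nb[, i] == 0L
    if (any(bd)) {
      hull[tri[bd, other[[i]][1L]]] <- TRUE
      hull[tri[bd, other[[i]][2L]]] <- TRUE
    }
  }
  list(tri = tri, omega = omega, jc1 = jc1, jc2 = jc2,
       jt1 = jt1, jt2 = jt2, hull = hull)
}

## Signed star-decomposition areas of bounded Voronoi cells.
## For the junction between cells a and b the counter-clockwise traversal
## direction around a is (r_b - r_a) rotated by +90 degrees; summing the
## signed triangle (r_a, c1, c2) contributions over a closed loop is the
## shoelace area.
voronoi_areas <- function(g, x, y) {
  c1 <- g$omega[g$jt1, , drop = FALSE]
  c2 <- g$omega[g$jt2, , drop = FALSE]
  dx <- x[g$jc2] - x[g$jc1]
  dy <- y[g$jc2] - y[g$jc1]
  ## s = +1 if (c2 - c1) agrees with the CCW direction for cell jc1
  s <- sign((c2[, 1L] - c1[, 1L]) * (-dy) + (c2[, 2L] - c1[, 2L]) * dx)
  s[s == 0] <- 1
  crossA <- (c1[, 1L] - x[g$jc1]) * (c2[, 2L] - y[g$jc1]) -
            (c1[, 2L] - y[g$jc1]) * (c2[, 1L] - x[g$jc1])
  crossB <- (c1[, 1L] - x[g$jc2]) * (c2[, 2L] - y[g$jc2]) -
            (c1[, 2L] - y[g$jc2]) * (c2[, 1L] - x[g$jc2])
  contrib <- c(0.5 * s * crossA, -0.5 * s * crossB)
  grp <- c(g$jc1, g$jc2)
  areas <- numeric(length(x))
  sums <- rowsum(contrib, grp)
  areas[as.integer(rownames(sums))] <- sums[, 1L]
  areas[g$hull] <- NA_real_
  areas
}

#' Build the Voronoi tessellation of a set of cell centers
#'
#' Computes the Delaunay triangulation of the centers, places one Voronoi
#' vertex (circumcenter) per triangle, and assembles the junction table
#' (one record per adjacent cell pair) and per-cell polygon areas.  Cells
#' whose generators lie on the convex hull are unbounded and flagged; they
#' carry `NA` area.
#'
#' @param centers a `cell_centers` data frame (or any data frame with
#'   `x`, `y` columns).
#' @return A `tessellation` object: list with `centers`, `vertices`
#'   (n_tri x 2 matrix of Voronoi vertex coordinates), `triangles`
#'   (generator trios), `junctions` (data frame `cell1`, `cell2`,
#'   `vertex1`, `vertex2`, `length`), `areas`, `n_vertices` (per-cell
#'   vertex count, `NA` for unbounded cells) and `bounded`.
#' @export
build_tessellation <- function(centers) {
  x <- centers$x; y <- centers$y
  if (length(x) < 4L)
    stop("invalid configuration: need at least 4 cell centers")
  g <- geom_core(x, y)
  areas <- voronoi_areas(g, x, y)
  len <- sqrt((g$omega[g$jt1, 1L] - g$omega[g$jt2, 1L])^2 +
              (g$omega[g$jt1, 2L] - g$omega[g$jt2, 2L])^2)
  junctions <- data.frame(cell1 = g$jc1, cell2 = g$jc2,
                          vertex1 = g$jt1, vertex2 = g$jt2,
                          length = len)
  zv <- integer(length(x))
  tab <- table(c(g$jc1, g$jc2))
  zv[as.integer(names(tab))] <- as.integer(tab)
  zv[g$hull] <- NA_integer_
  out <- list(centers = centers, vertices = g$omega,
              triangles = g$tri, junctions = junctions,
              areas = areas, n_vertices = zv, bounded = !g$hull)
  class(out) <- "tessellation"
  out
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Voronoi tessellation:", nrow(x$centers), "cells (",
      sum(x$bounded), "bounded ),", nrow(x$vertices), "vertices,",
      nrow(x$junctions), "junctions\n")
  invisible(x)
}

#' Ordered polygon of one bounded Voronoi cell
#'
#' @param tess a `tessellation`.
#' @param id cell id (generator index).
#' @param dedup_tol relative tolerance below which consecutive duplicate
#'   vertices (from near-cocircular centers) are merged.
#' @return matrix of vertex coordinates in counter-clockwise order, with
#'   the originating Voronoi-vertex indices in `attr(, "vertex_id")`.
#' @export
cell_polygon <- function(tess, id, dedup_tol = 1e-9) {
  if (!tess$bounded[id])
    stop("invalid polygon: cell ", id, " is unbounded")
  inc <- which(tess$triangles[, 1L] == id | tess$triangles[, 2L] == id |
               tess$triangles[, 3L] == id)
  vx <- tess$vertices[inc, 1L]; vy <- tess$vertices[inc, 2L]
  cx <- tess$centers$x[id]; cy <- tess$centers$y[id]
  ord <- order(atan2(vy - cy, vx - cx))
  inc <- inc[ord]; vx <- vx[ord]; vy <- vy[ord]
  ## drop consecutive (near-)duplicates from cocircular configurations
  scale <- max(abs(c(vx - cx, vy - cy)), 1e-300)
  nxt <- c(seq_along(vx)[-1L], 1L)
  dup <- sqrt((vx - vx[nxt])^2 + (vy - vy[nxt])^2) < dedup_tol * scale
  if (any(dup) && !all(dup)) {
    keep <- !dup
    inc <- inc[keep]; vx <- vx[keep]; vy <- vy[keep]
  }
  out <- cbind(x = vx, y = vy)
  attr(out, "vertex_id") <- inc
  out
}

#' Shoelace area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param loop matrix of polygon vertices (one row per vertex, columns x, y).
#' @return signed area (positive when counter-clockwise).
#' @export
polygon_area <- function(loop) {
  loop <- as.matrix(loop)
  if (nrow(loop) < 3L)
    stop("invalid polygon: fewer than 3 vertices")
  x <- loop[, 1L]; y <- loop[, 2L]
  nxt <- c(seq_len(nrow(loop))[-1L], 1L)
  0.5 * sum(x * y[nxt] - x[nxt] * y)
}

## Area centroid of a simple polygon (CCW), shoelace-based.
polygon_centroid <- function(loop) {
  x <- loop[, 1L]; y <- loop[, 2L]
  nxt <- c(seq_len(nrow(loop))[-1L], 1L)
  cr <- x * y[nxt] - x[nxt] * y
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-300) return(colMeans(loop))
  c(sum((x + x[nxt]) * cr), sum((y + y[nxt]) * cr)) / (6 * a)
}

#' Serialize a tessellation to JSON
#'
#' Writes centers, Voronoi vertex coordinates, per-cell vertex-index loops
#' and the junction table.
#'
#' @param tess a `tessellation`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @export
tessellation_json <- function(tess, path = NULL) {
  bounded_ids <- which(tess$bounded)
  loops <- lapply(bounded_ids, function(i)
    as.vector(attr(cell_polygon(tess, i), "vertex_id")))
  names(loops) <- as.character(bounded_ids)
  obj <- list(
    centers = data.frame(id = tess$centers$id, x = tess$centers$x,
                         y = tess$centers$y,
                         class = tess$centers$class,
                         mobile = tess$centers$mobile),
    vertices = data.frame(id = seq_len(nrow(tess$vertices)),
                          x = tess$vertices[, 1L], y = tess$vertices[, 2L]),
    cells = loops,
    junctions = tess$junctions)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-cell table of a tessellation
#'
#' @param x a `tessellation`.
#' @param ... unused.
#' @return data frame with one row per cell: id, class, area, vertex count,
#'   boundedness.
#' @export
as.data.frame.tessellation <- function(x, ...) {
  data.frame(id = x$centers$id, class = x$centers$class,
             x = x$centers$x, y = x$centers$y,
             area = x$areas, n_vertices = x$n_vertices,
             bounded = x$bounded)
}
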