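## Synthetic fiber images with known orientation statistics, used to
## validate the orientation pipeline end to end.

#' Exact structure parameter of a named orientation density
#'
#' Evaluates `k_H = (1/pi) integral rho(alpha) sin^2(alpha) d alpha` by
#' quadrature for the supported axial densities of the fiber-angle
#' deviation `alpha` (relative to the local radial direction):
#' `"uniform"` on `(-pi/2, pi/2]`, `"delta"` at `alpha0`, and
#' `"vonmises"` (axial von Mises, density proportional to
#' `exp(kappa * cos(2 * (alpha - alpha0)))`).
#'
#' @param density list with `family` and, as needed, `alpha0` (radians,
#'   default 0) and `kappa` (concentration, von Mises only).
#' @return the exact k_H.
#' @export
orientation_density_kH <- function(density) {
  family <- density$family
  alpha0 <- if (is.null(density$alpha0)) 0 else density$alpha0
  switch(family,
    uniform = 0.5,
    delta = sin(alpha0)^2,
    vonmises = {
      kappa <- density$kappa
      if (is.null(kappa) || kappa < 0)
        stop("invalid configuration: von Mises density needs kappa >= 0")
      f <- function(a) exp(kappa * (cos(2 * (a - alpha0)) - 1))
      z <- stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-10)$value
      num <- stats::integrate(function(a) f(a) * sin(a)^2,
                              -pi / 2, pi / 2, rel.tol = 1e-10)$value
      num / z
    },
    stop("invalid configuration: unknown orientation density family '",
         family, "'"))
}

sample_alpha <- function(density, n) {
  family <- density$family
  alpha0 <- if (is.null(density$alpha0)) 0 else density$alpha0
  switch(family,
    uniform = stats::runif(n, -pi / 2, pi / 2),
    delta = rep(alpha0, n),
    vonmises = {
      kappa <- density$kappa
      out <- numeric(0)
      while (length(out) < n) {
        m <- 2L * (n - length(out)) + 10L
        cand <- stats::runif(m, -pi / 2, pi / 2)
        acc <- stats::runif(m) < exp(kappa * (cos(2 * (cand - alpha0)) - 1))
        out <- c(out, cand[acc])
      }
      out[seq_len(n)]
    },
    stop("invalid configuration: unknown orientation density family '",
         family, "'"))
}

#' Render a synthetic fiber image with known orientation statistics
#'
#' Draws `n_fibers` straight anti-aliased line segments in an annular
#' region around the pattern center.  Each fiber's angle relative to the
#' local radial direction at its midpoint is sampled from the requested
#' orientation density, so the image realizes a known ground-truth
#' structure parameter (returned alongside, computed by quadrature).
#' Additive Gaussian noise emulates camera noise.
#'
#' @inheritParams orientation_density_kH
#' @param n_fibers number of fibers (>= 1).
#' @param fiber_length fiber length in pixels.
#' @param noise_sigma standard deviation of additive Gaussian noise, in
#'   units of the (unit) fiber peak intensity.
#' @param seed integer seed; the image is deterministic given the seed.
#' @param size image side in pixels.
#' @param center pattern center `c(x, y)`; defaults to the image center.
#' @param r_range radial band (fractions of `size`) holding the fiber
#'   midpoints; the inner cutoff avoids the region where the radial
#'   direction turns over within a fiber length.
#' @param profile_sigma width (pixels) of the Gaussian cross-section used
#'   for anti-aliased rendering.
#' @return list with `image` (matrix in `[0, 1]`), `k_H` (exact
#'   ground-truth), `alphas` (the sampled angle deviations), `density`,
#'   `center`.
#' @export
synth_fiber_image <- function(density = list(family = "uniform"),
                              n_fibers = 500, fiber_length = 12,
                              noise_sigma = 0.02, seed = 1L,
                              size = 256L, center = NULL,
                              r_range = c(0.15, 0.45),
                              profile_sigma = 0.6) {
  if (n_fibers < 1) stop("invalid configuration: 'n_fibers' must be >= 1")
  kH <- orientation_density_kH(density)   # validates the family too
  set.seed(seed)
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  img <- matrix(0, size, size)
  r0 <- r_range[1L] * size; r1 <- r_range[2L] * size
  rr <- sqrt(stats::runif(n_fibers, r0^2, r1^2))
  phi <- stats::runif(n_fibers, -pi, pi)
  alphas <- sample_alpha(density, n_fibers)
  mx <- center[1L] + rr * cos(phi)
  my <- center[2L] + rr * sin(phi)
  th <- phi + alphas                       # fiber axis direction
  hx <- fiber_length / 2 * cos(th); hy <- fiber_length / 2 * sin(th)
  cut <- 3 * profile_sigma
  for (i in seq_len(n_fibers)) {
    x1 <- mx[i] - hx[i]; x2 <- mx[i] + hx[i]
    y1 <- my[i] - hy[i]; y2 <- my[i] + hy[i]
    cmin <- max(1L, floor(min(x1, x2) - cut))
    cmax <- min(size, ceiling(max(x1, x2) + cut))
    rmin <- max(1L, floor(min(y1, y2) - cut))
    rmax <- min(size, ceiling(max(y1, y2) + cut))
    if (cmin > cmax || rmin > rmax) next
    cols <- cmin:cmax; rows <- rmin:rmax
    px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    py <- matrix(rows, length(rows), length(cols))
    ## distance from pixel centers to the segment
    ex <- x2 - x1; ey <- y2 - y1
    ll <- ex^2 + ey^2
    t <- ((px - x1) * ex + (py - y1) * ey) / ll
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2
    img[rows, cols] <- img[rows, cols] + exp(-d2 / (2 * profile_sigma^2))
  }
  img <- pmin(img, 1)
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, noise_sigma),
                        size, size)
  img <- pmax(img, 0)
  mx2 <- max(img)
  if (mx2 > 0) img <- img / mx2
  list(image = img, k_H = kH, alphas = alphas, density = density,
       center = center)
}

#' Write a synthetic fiber image with its ground-truth sidecar
#'
#' Saves the rendered image as TIFF (or PNG) plus a JSON sidecar with
#' the generator parameters and the exact structure parameter.
#'
#' @param fibers result of [synth_fiber_image()].
#' @param path image path (`.tif`/`.png`); the sidecar is written next to
#'   it with extension `.json`.
#' @export
write_synth_fibers <- function(fibers, path) {
  write_gray_image(fibers$image, path)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(density = fibers$density, k_H = fibers$k_H,
         center = fibers$center, n_fibers = length(fibers$alphas)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
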