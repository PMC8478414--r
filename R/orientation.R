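## Fiber-orientation quantification for 2D grayscale images.
##
## Conventions: images are numeric matrices indexed [row, col]; pixel
## coordinates are (x, y) = (col, row) with pixel centers at integers.
## Fiber angles are axial (headless), folded to (-pi/2, pi/2], measured
## from the +x (column) axis.

gaussian_kernel2 <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

fold_axial <- function(theta) {
  out <- ((theta + pi / 2) %% pi) - pi / 2
  out[out <= -pi / 2] <- pi / 2
  out
}

#' Local fiber orientation by the gradient structure tensor
#'
#' Estimates a per-pixel fiber axis: image gradients are computed by
#' central differences, their outer products are averaged under a
#' Gaussian window of width `window_sigma`, and the fiber axis is taken
#' perpendicular to the dominant gradient direction (the eigenvector of
#' the smaller structure-tensor eigenvalue).  The per-pixel weight is the
#' tensor energy (trace); for a locally constant image it is 0 and the
#' angle undefined (`NA`).
#'
#' @param image numeric matrix (grayscale, `[row, col]`), at least 16 x 16.
#' @param window_sigma Gaussian window width in pixels.
#' @return an `orientation_field`: list with `angle` (radians in
#'   `(-pi/2, pi/2]`, `NA` where undefined), `weight` (>= 0), `dim`.
#' @export
local_orientation <- function(image, window_sigma = 1.5) {
  image <- as.matrix(image)
  if (nrow(image) < 16L || ncol(image) < 16L)
    stop("invalid input: image must be at least 16 x 16 pixels")
  if (window_sigma <= 0)
    stop("invalid configuration: 'window_sigma' must be positive")
  nr <- nrow(image); nc <- ncol(image)
  ## central differences, one-sided at the borders
  gx <- image[, c(2:nc, nc)] - image[, c(1L, 1:(nc - 1L))]
  gx <- gx / 2; gx[, 1L] <- gx[, 1L] * 2; gx[, nc] <- gx[, nc] * 2
  gy <- image[c(2:nr, nr), ] - image[c(1L, 1:(nr - 1L)), ]
  gy <- gy / 2; gy[1L, ] <- gy[1L, ] * 2; gy[nr, ] <- gy[nr, ] * 2
  k <- gaussian_kernel2(window_sigma)
  Jxx <- EBImage::filter2(gx * gx, k, boundary = "replicate")
  Jxy <- EBImage::filter2(gx * gy, k, boundary = "replicate")
  Jyy <- EBImage::filter2(gy * gy, k, boundary = "replicate")
  energy <- Jxx + Jyy
  energy[energy < 0] <- 0
  ## dominant (gradient) orientation; fiber axis is perpendicular
  theta_g <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)
  angle <- fold_axial(theta_g + pi / 2)
  angle[energy <= 0] <- NA_real_
  structure(list(angle = angle, weight = energy, dim = c(nr, nc)),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("orientation_field:", x$dim[1L], "x", x$dim[2L], "pixels,",
      sum(x$weight > 0), "with positive weight\n")
  invisible(x)
}

#' Per-pixel fiber angle deviation from the radial direction
#'
#' The acute angle `alpha` between the local fiber axis and the outward
#' radial direction from `center`, folded to `[0, pi/2]` (the axial
#' mirror symmetry `rho(alpha) = rho(-alpha)` is built into the folding).
#'
#' @param field an [local_orientation()] result.
#' @param center pattern center as `c(x, y)` pixel coordinates.
#' @return matrix of angles in `[0, pi/2]`; `NA` where the orientation is
#'   undefined and at the exact center pixel.
#' @export
angle_deviation_map <- function(field, center) {
  stopifnot(inherits(field, "orientation_field"))
  nr <- field$dim[1L]; nc <- field$dim[2L]
  if (center[1L] < 1 || center[1L] > nc || center[2L] < 1 ||
      center[2L] > nr)
    stop("invalid input: center outside the image")
  px <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[1L]
  py <- matrix(seq_len(nr), nr, nc) - center[2L]
  phi <- atan2(py, px)
  alpha <- abs(fold_axial(field$angle - phi))
  alpha[px == 0 & py == 0] <- NA_real_
  alpha
}

#' Structure parameter k_H of a fiber-angle sample
#'
#' For the normalized axial orientation density `rho(alpha)` on
#' `(-pi/2, pi/2]`, the 2D structure tensor reduces to the scalar
#' `k_H = (1/pi) integral rho(alpha) sin^2(alpha) d alpha`, estimated
#' here as the weighted mean of `sin^2(alpha)`.  0 means purely radial
#' fibers, 1 purely circumferential, 0.5 an isotropic distribution.
#'
#' @param alphas angle deviations (radians); sign is irrelevant.
#' @param weights optional non-negative weights (e.g. orientation
#'   energies); equal weights by default.
#' @return k_H in `[0, 1]`.
#' @export
structure_parameter <- function(alphas, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(alphas))
  keep <- !is.na(alphas) & !is.na(weights)
  alphas <- alphas[keep]; weights <- weights[keep]
  if (length(alphas) == 0L || sum(weights) <= 0)
    stop("undefined statistic: no positively weighted angles")
  sum(weights * sin(alphas)^2) / sum(weights)
}

#' Radial profile of the structure parameter
#'
#' Computes k_H within concentric annuli around the pattern center.  To
#' suppress background pixels, only pixels whose weight reaches the
#' `weight_quantile` quantile of the positive weights are used.
#'
#' @param field an `orientation_field`.
#' @param center pattern center `c(x, y)` in pixels.
#' @param bin_width annulus width in pixels.
#' @param weight_quantile quantile of positive weights below which pixels
#'   are ignored (0 keeps all weighted pixels).
#' @param max_radius outermost analyzed radius; defaults to the largest
#'   radius with any analyzable pixel.
#' @return a `radial_profile` data frame: `zone_index`, `r_norm` (bin
#'   center / outermost radius), `value` (k_H, `NA` for empty bins),
#'   `n_pixels`.
#' @export
kH_profile <- function(field, center, bin_width = 5,
                       weight_quantile = 0.5, max_radius = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  if (bin_width <= 0)
    stop("invalid configuration: 'bin_width' must be positive")
  alpha <- angle_deviation_map(field, center)
  nr <- field$dim[1L]; nc <- field$dim[2L]
  px <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[1L]
  py <- matrix(seq_len(nr), nr, nc) - center[2L]
  r <- sqrt(px^2 + py^2)
  w <- field$weight
  pos <- w > 0 & !is.na(alpha)
  if (!any(pos)) stop("undefined statistic: no weighted pixels")
  thr <- stats::quantile(w[pos], weight_quantile)
  use <- pos & w >= thr
  if (is.null(max_radius)) max_radius <- max(r[use])
  use <- use & r <= max_radius
  zone <- floor(r[use] / bin_width) + 1L
  nz <- max(zone)
  kh <- rep(NA_real_, nz); np <- integer(nz)
  ssum <- rowsum(w[use] * sin(alpha[use])^2, zone)
  wsum <- rowsum(w[use], zone)
  cnt <- table(factor(zone, levels = seq_len(nz)))
  ids <- as.integer(rownames(ssum))
  kh[ids] <- ssum[, 1L] / wsum[, 1L]
  np <- as.integer(cnt)
  out <- data.frame(zone_index = seq_len(nz),
                    r_norm = ((seq_len(nz) - 0.5) * bin_width) /
                      (nz * bin_width),
                    value = kh, n_pixels = np)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Stack images about their pattern centers
#'
#' Each image is shifted by an integer pixel offset so its pattern center
#' lands on the center of the output frame, the shifted images are
#' summed, and the sum is normalized to peak 1.
#'
#' @param images list of numeric matrices.
#' @param centers list (or 2-column matrix) of `c(x, y)` pattern centers,
#'   one per image.
#' @return normalized stacked matrix with the frame size of the largest
#'   input image.
#' @export
stack_images <- function(images, centers) {
  if (length(images) == 0L) stop("invalid input: empty image list")
  if (is.matrix(centers)) centers <- asplit(centers, 1L)
  if (length(centers) != length(images))
    stop("invalid input: one center per image required")
  nr <- max(vapply(images, nrow, 1L))
  nc <- max(vapply(images, ncol, 1L))
  oc <- c(round((nc + 1) / 2), round((nr + 1) / 2))   # (x, y)
  out <- matrix(0, nr, nc)
  for (i in seq_along(images)) {
    img <- as.matrix(images[[i]])
    ctr <- centers[[i]]
    if (ctr[1L] < 1 || ctr[1L] > ncol(img) || ctr[2L] < 1 ||
        ctr[2L] > nrow(img))
      stop("invalid input: center ", i, " outside its image")
    dx <- oc[1L] - round(ctr[1L]); dy <- oc[2L] - round(ctr[2L])
    src_r <- seq_len(nrow(img)); src_c <- seq_len(ncol(img))
    dst_r <- src_r + dy; dst_c <- src_c + dx
    keep_r <- dst_r >= 1L & dst_r <= nr
    keep_c <- dst_c >= 1L & dst_c <= nc
    out[dst_r[keep_r], dst_c[keep_c]] <-
      out[dst_r[keep_r], dst_c[keep_c]] + img[src_r[keep_r], src_c[keep_c]]
  }
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Radial intensity profile over concentric zones
#'
#' Mean pixel intensity per concentric zone of width `zone_width` around
#' `center`, against the distance normalized by the outermost configured
#' zone radius.  Zones (or parts of zones) outside the image simply
#' contribute fewer pixels.
#'
#' @param map numeric matrix (e.g. a stacked intensity map).
#' @param center `c(x, y)` in pixels.
#' @param n_zones number of concentric zones.
#' @param zone_width zone width in pixels (default 1: single-pixel-width
#'   zones).
#' @return a `radial_profile` data frame with `n_zones` rows.
#' @export
radial_intensity_profile <- function(map, center, n_zones,
                                     zone_width = 1) {
  if (n_zones < 1) stop("invalid configuration: 'n_zones' must be >= 1")
  map <- as.matrix(map)
  nr <- nrow(map); nc <- ncol(map)
  px <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[1L]
  py <- matrix(seq_len(nr), nr, nc) - center[2L]
  r <- sqrt(px^2 + py^2)
  zone <- floor(r / zone_width) + 1L
  use <- zone <= n_zones
  zs <- factor(zone[use], levels = seq_len(n_zones))
  vals <- tapply(map[use], zs, mean)
  cnts <- as.integer(table(zs))
  out <- data.frame(zone_index = seq_len(n_zones),
                    r_norm = ((seq_len(n_zones) - 0.5) * zone_width) /
                      (n_zones * zone_width),
                    value = as.numeric(vals), n_pixels = cnts)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Write a radial profile as CSV
#'
#' @param profile a `radial_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path image file; format chosen by extension.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("invalid input: unsupported image format '", ext, "'"))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

#' Write a grayscale image (TIFF or PNG)
#'
#' @param image numeric matrix; values are clipped to `[0, 1]`.
#' @param path output file; format chosen by extension.
#' @export
write_gray_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path),
    png = png::writePNG(image, path),
    stop("invalid input: unsupported image format '", ext, "'"))
  invisible(path)
}
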