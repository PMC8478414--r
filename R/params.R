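#' Mechanical parameters of the monolayer model
#'
#' The per-cell energy is
#' `E_a = 1/2 K_a (g A0_a) (A_a / (g A0_a) - 1)^2 + sum_b lambda l_b`,
#' where `g` is the isotropic prestretch (condensation tendency; `g < 1`
#' shrinks the intrinsic cell area), `rho` the boundary-to-interior
#' stiffness ratio, and `rho_g` the boundary-to-interior prestretch ratio
#' (contractility differential).  `lambda_out` is the extra rim tension and
#' `k_b` the global area-penalty stiffness, both used only while rounding
#' the pattern border during initialization.
#'
#' @param K interior cell area stiffness (energy/area).
#' @param rho stiffness differential, boundary/interior, in `(0, 1]`.
#' @param g prestretch in `(0, 1]`.
#' @param rho_g contractility differential in `(0, 1]`.
#' @param lambda junction tension (energy/length).
#' @param lambda_out rim tension used during initialization.
#' @param k_b global area-penalty stiffness used during initialization.
#' @param edge_eps junction-length regularization (micrometres, ~2% of
#'   the cell spacing):
#'   the tension term uses `sqrt(l^2 + edge_eps^2) - edge_eps`, which
#'   equals `l` up to `edge_eps` but is differentiable at `l = 0`, where
#'   the bare length is kinked.  Zero-length junctions (four-fold
#'   vertices), which strong tension actively stabilizes, would otherwise
#'   pin the gradient flow on non-smooth energy valleys.
#' @return a `mechanics_params` list; intrinsic areas (`A0`, `A0_total`)
#'   are attached by [initialize_pattern()].
#' @export
mechanics_params <- function(K = 1, rho = 1, g = 1, rho_g = 1,
                             lambda = 15, lambda_out = 20, k_b = 0.1,
                             edge_eps = 0.5) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0 || v > 1)
      stop("invalid configuration: '", nm, "' must lie in (0, 1]")
  }
  chk01(rho, "rho"); chk01(g, "g"); chk01(rho_g, "rho_g")
  for (nm in c("K", "lambda", "lambda_out", "k_b", "edge_eps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("invalid configuration: '", nm, "' must be >= 0")
  }
  out <- list(K = K, rho = rho, g = g, rho_g = rho_g, lambda = lambda,
              lambda_out = lambda_out, k_b = k_b, edge_eps = edge_eps,
              A0 = NULL, A0_total = NULL)
  class(out) <- "mechanics_params"
  out
}

#' Confinement (micropattern) geometry
#'
#' @param shape `"circle"` or `"annulus"`.
#' @param outer_radius outer pattern radius in micrometres.  The default
#'   (172, the circular micropattern radius) captures about 121 cells at
#'   the default seeding calibration (25 x 25 cells, 27.7 um spacing).
#' @param inner_radius inner radius (annulus only), `0 < inner < outer`.
#' @param center pattern center; defaults to the domain center when the
#'   spec is used by [initialize_pattern()].
#' @return a `confinement_spec` list.
#' @export
confinement_spec <- function(shape = c("circle", "annulus"),
                             outer_radius = 172, inner_radius = NULL,
                             center = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(outer_radius) || outer_radius <= 0)
    stop("invalid configuration: 'outer_radius' must be positive")
  if (shape == "annulus") {
    if (is.null(inner_radius) || inner_radius <= 0 ||
        inner_radius >= outer_radius)
      stop("invalid configuration: annulus needs 0 < inner_radius < ",
           "outer_radius")
  } else inner_radius <- NULL
  out <- list(shape = shape, outer_radius = outer_radius,
              inner_radius = inner_radius, center = center)
  class(out) <- "confinement_spec"
  out
}
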