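#' Generate seed points on a jittered square lattice
#'
#' Places `n_per_side^2` cell centers on a square lattice spanning
#' `[0, domain_side]^2` and perturbs each coordinate by a uniform jitter.
#' This is the initial cell-tissue configuration from which the circular
#' (or annular) micropattern is demarcated; with the default domain side
#' equal to `n_per_side` the mean cell area is 1, so lengths are measured
#' in units of the typical cell diameter.
#'
#' @param n_per_side integer >= 3, number of lattice rows/columns.
#' @param domain_side side length of the square domain (dimensionless).
#' @param jitter fraction of the lattice spacing, in `[0, 0.5)`, by which
#'   each coordinate is perturbed (uniformly on `+/- jitter * spacing`).
#' @param seed integer seed; a fixed seed gives an identical point set.
#' @return A `cell_centers` data frame with columns `id`, `x`, `y`,
#'   `mobile` (logical) and `class` (`"interior"`, `"boundary"`,
#'   `"exterior"` or `NA` when not yet assigned), with the domain side
#'   stored in `attr(, "domain_side")`.
#' @examples
#' pts <- generate_seed_points(25, 25, jitter = 0.3, seed = 1)
#' nrow(pts)  # 625
#' @export
generate_seed_points <- function(n_per_side, domain_side, jitter = 0,
                                 seed = NULL) {
  if (!is.numeric(n_per_side) || length(n_per_side) != 1L ||
      n_per_side < 3 || n_per_side != round(n_per_side))
    stop("invalid configuration: 'n_per_side' must be an integer >= 3")
  if (!is.numeric(domain_side) || length(domain_side) != 1L ||
      !is.finite(domain_side) || domain_side <= 0)
    stop("invalid configuration: 'domain_side' must be positive")
  if (!is.numeric(jitter) || jitter < 0 || jitter >= 0.5)
    stop("invalid configuration: 'jitter' must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_per_side)
  h <- domain_side / n
  centers <- (seq_len(n) - 0.5) * h
  g <- expand.grid(x = centers, y = centers)
  m <- n * n
  if (jitter > 0) {
    g$x <- g$x + stats::runif(m, -jitter * h, jitter * h)
    g$y <- g$y + stats::runif(m, -jitter * h, jitter * h)
  }
  new_cell_centers(g$x, g$y, domain_side = domain_side)
}

#' Construct a validated set of cell centers
#'
#' @param x,y coordinates.
#' @param mobile logical vector, whether each center may move.
#' @param class per-cell label: `"interior"`, `"boundary"`, `"exterior"`
#'   or `NA` before confinement is applied.
#' @param domain_side side of the bounding square domain.
#' @param min_sep minimum pairwise separation; defaults to
#'   `1e-6 * domain_side`.
#' @return a `cell_centers` data frame.
#' @export
new_cell_centers <- function(x, y, mobile = TRUE, class = NA_character_,
                             domain_side = max(x, y), min_sep = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("invalid configuration: non-finite center positions")
  n <- length(x)
  if (is.null(min_sep)) min_sep <- 1e-6 * domain_side
  if (n > 1L && n <= 5000L) {
    ## O(n^2) check is fine at the scales this model runs at
    dmin <- min(stats::dist(cbind(x, y)))
    if (dmin < min_sep)
      stop("invalid configuration: two centers closer than the minimum ",
           "separation (", format(dmin), " < ", format(min_sep), ")")
  }
  out <- data.frame(id = seq_len(n), x = x, y = y,
                    mobile = rep_len(mobile, n),
                    class = rep_len(class, n),
                    stringsAsFactors = FALSE)
  attr(out, "domain_side") <- domain_side
  class(out) <- c("cell_centers", "data.frame")
  out
}
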