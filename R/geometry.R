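#' One-dimensional cortical domain
#'
#' Discretizes the cortex path along which LGN intensity is measured, either
#' as a periodic circle (the projected path around a flat mitotic cell) or as
#' a finite line (cells plated on thin micropatterned lines). Coordinates are
#' continuous microns; the periodic domain is the half-open interval `[0, L)`.
#'
#' The requested grid spacing is adjusted so that an integer number of cells
#' fits exactly: `n = round(L/dx)` nodes for a periodic domain, `n + 1` for a
#' line.
#'
#' @param L Domain length in um.
#' @param dx Target grid spacing in um (default 0.2, resolving the ~1 um
#'   diffusive boundary layer `sqrt(D/koff)` of the default kinetics).
#' @param periodic Logical; `TRUE` for a circle, `FALSE` for a finite line
#'   with no-flux ends.
#' @return An object of class `"domain_1d"` with fields `L`, `dx`, `periodic`,
#'   `x` (node coordinates) and `n` (node count).
#' @examples
#' dom <- domain_1d(80)
#' range(dom$x)
#' @export
domain_1d <- function(L, dx = 0.2, periodic = TRUE) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0, is.numeric(dx), dx > 0)
  if (periodic) {
    n <- max(4L, as.integer(round(L / dx)))
    dx <- L / n
    x <- seq(0, by = dx, length.out = n)
  } else {
    n <- max(4L, as.integer(round(L / dx))) + 1L
    dx <- L / (n - 1L)
    x <- seq(0, L, length.out = n)
  }
  structure(list(L = L, dx = dx, periodic = periodic, x = x, n = n),
            class = "domain_1d")
}

#' @export
print.domain_1d <- function(x, ...) {
  cat(sprintf("<domain_1d> %s, L = %g um, dx = %g um, %d nodes\n",
              if (x$periodic) "periodic" else "line", x$L, x$dx, x$n))
  invisible(x)
}

check_in_domain <- function(x, domain, what = "coordinate") {
  lo <- 0
  hi <- if (domain$periodic) domain$L else domain$L
  bad <- x < lo | (if (domain$periodic) x >= hi else x > hi)
  if (any(bad)) {
    stop(sprintf("%s %g outside the domain [0, %g%s", what, x[bad][1],
                 domain$L, if (domain$periodic) ")" else "]"))
  }
  invisible(TRUE)
}

#' Distance between two cortical positions
#'
#' Minimum-image distance on a periodic domain, `min_k |x - y + kL|`; plain
#' absolute difference on a line domain. This is the metric underlying the
#' chromatin-proximity dependence of LGN unbinding.
#'
#' @param x,y Positions in um, inside the domain. Vectorized (recycled).
#' @param domain A [domain_1d()].
#' @return Distances in um.
#' @export
periodic_distance <- function(x, y, domain) {
  check_in_domain(x, domain, "position x =")
  check_in_domain(y, domain, "position y =")
  d <- abs(x - y)
  if (domain$periodic) pmin(d, domain$L - d) else d
}

#' Chromatin (DNA) region on the cortex path
#'
#' The mitotic DNA mass is modelled as an interval of finite half-extent
#' centred at `center`; the Ran-GTP-dependent inhibition of cortical LGN acts
#' within `d_inh` of its edge (~4 um in metaphase cells).
#'
#' @param center DNA centre position in um.
#' @param half_extent Half-width of the DNA mass in um (default 4, roughly
#'   half a metaphase DNA plate).
#' @param d_inh Inhibition range in um measured from the DNA edge (default 4).
#' @return An object of class `"dna_region"`.
#' @export
dna_region <- function(center, half_extent = 4, d_inh = 4) {
  stopifnot(half_extent >= 0, d_inh >= 0)
  structure(list(center = center, half_extent = half_extent, d_inh = d_inh),
            class = "dna_region")
}

#' Distance from a cortical position to the DNA region
#'
#' Zero inside the DNA interval, otherwise the (minimum-image) distance to its
#' nearest edge.
#'
#' @param x Positions in um (vectorized).
#' @param dna A [dna_region()].
#' @param domain A [domain_1d()].
#' @return Distances in um.
#' @export
distance_to_dna <- function(x, dna, domain) {
  ctr <- dna$center
  if (domain$periodic) ctr <- ctr %% domain$L
  pmax(0, periodic_distance(x, ctr, domain) - dna$half_extent)
}

#' Elliptical cell geometry
#'
#' Mitotic cell outlines are fitted by ellipses; `a` and `b` are the half-axes
#' (long and short). The ellipse axes are aligned with the lab axes; the
#' orientation simulations work in this body frame and rotate reported angles.
#'
#' @param a,b Long/short half-axes in um, `a >= b > 0`.
#' @return An object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(a, b) {
  if (!(a >= b && b > 0)) stop("degenerate axes: need a >= b > 0")
  structure(list(a = a, b = b), class = "cell_geometry")
}

# Arclength table of the ellipse x = a cos t, y = b sin t on a fine parameter
# grid; used both for perimeter quadrature and arclength inversion.
ellipse_arclength_table <- function(a, b, n_fine) {
  t <- seq(0, 2 * pi, length.out = n_fine + 1L)
  px <- a * cos(t)
  py <- b * sin(t)
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  list(t = t, s = c(0, cumsum(seg)))
}

#' Ellipse perimeter
#'
#' Computed by dense polyline quadrature (accurate to well below 0.1%).
#'
#' @param geometry A [cell_geometry()].
#' @return Perimeter in um.
#' @export
ellipse_perimeter <- function(geometry) {
  tab <- ellipse_arclength_table(geometry$a, geometry$b, 8192L)
  tab$s[length(tab$s)]
}

#' Discretize a cell contour at uniform arclength
#'
#' Places `n_nodes` nodes on the ellipse, uniformly spaced in arclength, and
#' records for each node its position, arclength coordinate, polar angle and
#' outward normal angle. The contour is closed: node `n + 1` is node 1.
#'
#' @param geometry A [cell_geometry()].
#' @param n_nodes Number of nodes (>= 16).
#' @return An object of class `"contour"` with fields `s` (arclength), `pos`
#'   (n x 2 positions), `theta` (polar angles in `[0, 2*pi)`), `normal`
#'   (outward normal angles), `ds` (per-node segment lengths, all equal),
#'   `perimeter`, and `geometry`.
#' @export
build_contour <- function(geometry, n_nodes = 256L) {
  stopifnot(n_nodes >= 16L)
  a <- geometry$a; b <- geometry$b
  tab <- ellipse_arclength_table(a, b, max(4096L, 16L * n_nodes))
  P <- tab$s[length(tab$s)]
  s_nodes <- seq(0, P, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
  t_nodes <- stats::approx(tab$s, tab$t, xout = s_nodes, ties = "ordered")$y
  pos <- cbind(a * cos(t_nodes), b * sin(t_nodes))
  theta <- atan2(pos[, 2], pos[, 1]) %% (2 * pi)
  normal <- atan2(a * sin(t_nodes), b * cos(t_nodes))
  structure(list(s = s_nodes, pos = pos, theta = theta, normal = normal,
                 ds = rep(P / n_nodes, n_nodes), perimeter = P,
                 geometry = geometry, n = n_nodes),
            class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> ellipse a = %g, b = %g um, %d nodes, perimeter %.3f um\n",
              x$geometry$a, x$geometry$b, x$n, x$perimeter))
  invisible(x)
}
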