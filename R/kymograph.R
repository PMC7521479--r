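#' Space-time intensity kymograph
#'
#' The interchange format between experiment, simulation, synthetic data and
#' quantification: an intensity matrix over cortical position and frame time,
#' optionally carrying the DNA track (position and half-extent per frame) and
#' a record of the normalization applied.
#'
#' @param x Spatial node coordinates in um (rows of `I`).
#' @param t Frame times in min, strictly increasing (columns of `I`).
#' @param I Intensity matrix, `length(x)` x `length(t)`.
#' @param dna Optional data frame with columns `t`, `xn` (DNA centre, um; may
#'   be unwrapped/cumulative on a periodic domain) and optionally `w`
#'   (half-extent, um).
#' @param L Domain length in um.
#' @param periodic Logical: circle or line topology.
#' @param normalization One of `"raw"`, `"global"`, `"per-frame"`.
#' @return An object of class `"kymograph"`.
#' @export
kymograph <- function(x, t, I, dna = NULL, L = max(x) + (x[2] - x[1]),
                      periodic = TRUE, normalization = "raw") {
  I <- as.matrix(I)
  stopifnot(nrow(I) == length(x), ncol(I) == length(t))
  if (any(diff(t) <= 0)) stop("frame times must be strictly increasing")
  if (!is.null(dna)) {
    stopifnot(is.data.frame(dna), all(c("t", "xn") %in% names(dna)),
              nrow(dna) == length(t))
  }
  normalization <- match.arg(normalization, c("raw", "global", "per-frame"))
  structure(list(x = x, t = t, I = I, dna = dna, L = L, periodic = periodic,
                 normalization = normalization),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d nodes x %d frames, L = %g um (%s), %s intensities\n",
              nrow(x$I), ncol(x$I), x$L,
              if (x$periodic) "periodic" else "line", x$normalization))
  invisible(x)
}

# Reconstruct the domain a kymograph was sampled on.
kymo_domain <- function(kymo) {
  domain_1d(kymo$L, kymo$x[2] - kymo$x[1], periodic = kymo$periodic)
}

#' Time-stamped position track
#'
#' @param t Frame times in min, strictly increasing.
#' @param x Positions in um (1D) or a two-column matrix (2D).
#' @return A data frame of class `"trajectory"` with columns `t`, `x`
#'   (and `y` in 2D).
#' @export
trajectory <- function(t, x) {
  if (any(diff(t) <= 0)) stop("frame times must be strictly increasing")
  if (is.matrix(x)) {
    stopifnot(nrow(x) == length(t), ncol(x) == 2)
    out <- data.frame(t = t, x = x[, 1], y = x[, 2])
  } else {
    stopifnot(length(x) == length(t))
    out <- data.frame(t = t, x = x)
  }
  class(out) <- c("trajectory", "data.frame")
  out
}
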