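#' Astral microtubule length distribution (parametric)
#'
#' Astral microtubules radiate from the centrosome; their plus ends sample
#' cortical LGN and transmit dynein pulling forces. The length density
#' `rho(l)` feeds both the 1D signed end density `pMT` and the 2D reach
#' probability `P(l >= d)`. The default is an exponential with mean 6 um
#' truncated at 20 um, a reasonable parametric stand-in for measured astral
#' length histograms in flat mitotic cells; an empirical histogram can be
#' supplied with [mt_empirical()].
#'
#' @param mean Mean parameter of the (untruncated) exponential, um.
#' @param max_length Truncation length, um.
#' @return An object of class `"mt_model"`.
#' @export
mt_exponential <- function(mean = 6, max_length = 20) {
  stopifnot(mean > 0, max_length > mean / 10)
  structure(list(type = "exponential", mean = mean, max_length = max_length,
                 norm = 1 - exp(-max_length / mean)),
            class = "mt_model")
}

#' Astral microtubule length distribution (empirical histogram)
#'
#' Accepts a two-column table (length in um, weight) such as a digitized
#' length histogram; the density is linearly interpolated between the given
#' lengths and normalized to integrate to 1.
#'
#' @param lengths Microtubule lengths (um), increasing.
#' @param weights Non-negative weights (counts or densities).
#' @return An object of class `"mt_model"`.
#' @export
mt_empirical <- function(lengths, weights) {
  stopifnot(length(lengths) == length(weights), length(lengths) >= 2,
            all(diff(lengths) > 0), all(weights >= 0), any(weights > 0))
  area <- sum(diff(lengths) * (utils::head(weights, -1) + utils::tail(weights, -1)) / 2)
  dens <- weights / area
  grid <- seq(min(lengths), max(lengths), length.out = 2048L)
  dgrid <- stats::approx(lengths, dens, xout = grid, ties = "ordered")$y
  surv <- rev(cumsum(rev(dgrid)) - rev(dgrid) / 2) * (grid[2] - grid[1])
  structure(list(type = "empirical", lengths = lengths, density_pts = dens,
                 grid = grid, dgrid = dgrid, surv = surv,
                 max_length = max(lengths)),
            class = "mt_model")
}

#' Microtubule length density rho(l)
#'
#' @param mt An `mt_model`.
#' @param l Lengths in um (vectorized).
#' @return Density values (1/um), zero outside the support.
#' @export
mt_density <- function(mt, l) {
  if (mt$type == "exponential") {
    out <- exp(-l / mt$mean) / (mt$mean * mt$norm)
    out[l < 0 | l > mt$max_length] <- 0
    out
  } else {
    out <- stats::approx(mt$grid, mt$dgrid, xout = l, yleft = 0, yright = 0,
                         ties = "ordered")$y
    out[is.na(out)] <- 0
    out
  }
}

#' Microtubule reach probability P(l >= d)
#'
#' Probability that an astral microtubule is long enough to reach a cortex
#' point at distance `d` from the pole; weights cortical pulling forces in
#' the 2D torque model.
#'
#' @param mt An `mt_model`.
#' @param d Distances in um (vectorized).
#' @return Probabilities in `[0, 1]`.
#' @export
mt_survival <- function(mt, d) {
  if (mt$type == "exponential") {
    out <- (exp(-pmax(d, 0) / mt$mean) - exp(-mt$max_length / mt$mean)) / mt$norm
    out[d >= mt$max_length] <- 0
    pmin(pmax(out, 0), 1)
  } else {
    out <- stats::approx(mt$grid, mt$surv, xout = d, yleft = 1, yright = 0,
                         ties = "ordered")$y
    out[is.na(out)] <- 0
    pmin(pmax(out, 0), 1)
  }
}

#' Signed astral microtubule end density pMT(u)
#'
#' `pMT(u) = sign(u) rho(|u|) / 2`: the odd density of microtubule plus ends
#' at signed offset `u` from the centrosome of a radially symmetric aster
#' projected on the 1D cortex path.
#'
#' @param mt An `mt_model`.
#' @param u Signed offsets in um.
#' @return Signed density values.
#' @export
pmt <- function(mt, u) {
  sign(u) * mt_density(mt, abs(u)) / 2
}
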