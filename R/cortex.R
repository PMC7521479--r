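#' Cortical LGN exchange kinetics
#'
#' Parameters of the reaction-diffusion dynamics of cortex-bound LGN:
#' \deqn{\partial_t c = D \partial_x^2 c + b - k_{off}(x)\, c,}
#' where binding from the (unlimited) cytoplasmic reservoir supplies a
#' constant source `b` and unbinding is faster near the chromatin
#' (`koff_near`, timescale ~10 min) than far from it (`koff_far`, ~90 min).
#' By default `b = koff_far` so the far-field steady-state concentration is 1;
#' concentrations are therefore dimensionless multiples of the unperturbed
#' cortical level.
#'
#' @param D Diffusion constant, um^2/min (default 0.01; cortical LGN
#'   accumulations are nearly immobile).
#' @param b Binding source, concentration/min (default `koff_far`).
#' @param koff_near Unbinding rate within the inhibition range, 1/min
#'   (default 1/10).
#' @param koff_far Unbinding rate far from the DNA, 1/min (default 1/90).
#' @param sigma Width in um of the smooth near/far switch (default 0.5;
#'   0 gives a hard step).
#' @return An object of class `"lgn_kinetics"`.
#' @export
lgn_kinetics <- function(D = 0.01, koff_near = 1 / 10, koff_far = 1 / 90,
                         b = koff_far, sigma = 0.5) {
  stopifnot(D >= 0, b >= 0, koff_near >= 0, koff_far >= 0, sigma >= 0)
  if (koff_near < koff_far) stop("koff_near must be >= koff_far")
  structure(list(D = D, b = b, koff_near = koff_near, koff_far = koff_far,
                 sigma = sigma),
            class = "lgn_kinetics")
}

#' Cortical LGN concentration field
#'
#' @param domain A [domain_1d()].
#' @param c Concentration at each node (default uniform 1, the far-field
#'   steady state of the default kinetics).
#' @param time Time stamp in min.
#' @return An object of class `"cortex_field"`.
#' @export
cortex_field <- function(domain, c = rep(1, domain$n), time = 0) {
  stopifnot(length(c) == domain$n)
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("cortex field must be finite and non-negative")
  }
  structure(list(domain = domain, c = as.numeric(c), time = time),
            class = "cortex_field")
}

# Smooth step from 1 (inside) to 0 (outside), centred at d_inh with width
# sigma; sigma = 0 gives a hard step (1 for d <= d_inh).
smooth_step <- function(d, d_inh, sigma) {
  if (sigma <= 0) return(as.numeric(d <= d_inh))
  1 / (1 + exp((d - d_inh) / sigma))
}

#' Position-dependent unbinding-rate profile
#'
#' `koff(x) = koff_far + (koff_near - koff_far) g(dist(x))`, with `g` a smooth
#' step in the distance to the DNA edge, centred at the inhibition range
#' `d_inh` of the DNA region. At distance 0 the rate is (essentially)
#' `koff_near`; far away it is `koff_far`; at distance exactly `d_inh` (with
#' `sigma > 0`) it is the midpoint.
#'
#' @param domain A [domain_1d()].
#' @param dna A [dna_region()].
#' @param kinetics An [lgn_kinetics()].
#' @return Numeric vector of rates (1/min), one per node.
#' @export
koff_profile <- function(domain, dna, kinetics) {
  d <- distance_to_dna(domain$x, dna, domain)
  kinetics$koff_far + (kinetics$koff_near - kinetics$koff_far) *
    smooth_step(d, dna$d_inh, kinetics$sigma)
}

# Unchecked koff profile for the integrator hot loops (xw already wrapped).
koff_fast <- function(x, L, periodic, xw, w, d_inh, kinetics) {
  d <- abs(x - xw)
  if (periodic) d <- pmin(d, L - d)
  d <- d - w
  d[d < 0] <- 0
  kinetics$koff_far + (kinetics$koff_near - kinetics$koff_far) *
    smooth_step(d, d_inh, kinetics$sigma)
}

# Second-difference Laplacian (n x n, dense) for a periodic circle or a
# no-flux line. Row sums are zero and the matrix is symmetric, so backward
# Euler diffusion conserves mass exactly and preserves positivity.
laplacian_matrix <- function(n, dx, periodic) {
  L <- matrix(0, n, n)
  idx <- seq_len(n)
  L[cbind(idx, idx)] <- -2
  L[cbind(idx[-n], idx[-1])] <- 1
  L[cbind(idx[-1], idx[-n])] <- 1
  if (periodic) {
    L[1, n] <- L[1, n] + 1
    L[n, 1] <- L[n, 1] + 1
  } else {
    L[1, 1] <- -1
    L[n, n] <- -1
  }
  L / dx^2
}

# Backward-Euler diffusion propagator (I - dt D Lap)^{-1}. The inverse of
# this M-matrix is entrywise non-negative, so the diffusion half-step cannot
# create negative concentrations at any dt. On a periodic grid the matrix is
# circulant and is applied spectrally (FFT multipliers 1/(1 + dt D lambda_k)
# with the discrete Laplacian eigenvalues lambda_k); on a line the cached
# dense inverse is used.
.op_cache <- new.env(parent = emptyenv())

diffusion_operator <- function(n, dx, D, dt, periodic) {
  if (D <= 0 || dt <= 0) return(NULL)
  if (periodic) {
    k <- seq_len(n) - 1L
    lambda <- (2 - 2 * cos(2 * pi * k / n)) / dx^2
    mult <- 1 / (1 + dt * D * lambda)
    # The propagator is a circulant convolution with a rapidly decaying
    # symmetric kernel. When it is narrow, apply it as an explicit paired
    # convolution: elementwise commutative additions keep a mirror-symmetric
    # field mirror-symmetric to the last bit, so an exactly symmetric
    # configuration (e.g. an unperturbed bipolar spindle) is a true fixed
    # point of the discretization.
    kern <- Re(stats::fft(mult, inverse = TRUE)) / n
    m <- which(kern[seq_len(n %/% 2)] >= 1e-17)
    m <- if (length(m)) max(m) - 1L else 0L
    if (m >= 1L && m <= 48L) {
      kj <- kern[2:(m + 1L)]
      k0 <- 1 - 2 * sum(kj)  # exact unit mass: uniform fields stay uniform
      return(list(kernel = c(k0, kj)))
    }
    return(list(fft_mult = mult))
  }
  key <- paste(n, signif(dx, 12), signif(D, 12), signif(dt, 12), sep = "|")
  op <- .op_cache[[key]]
  if (is.null(op)) {
    if (length(ls(.op_cache)) > 16L) rm(list = ls(.op_cache), envir = .op_cache)
    A <- diag(n) - dt * D * laplacian_matrix(n, dx, periodic)
    op <- solve(A)
    assign(key, op, envir = .op_cache)
  }
  op
}

apply_diffusion <- function(op, v) {
  if (is.list(op)) {
    if (!is.null(op$kernel)) {
      k <- op$kernel
      n <- length(v)
      out <- k[1] * v
      for (j in seq_len(length(k) - 1L)) {
        idx_m <- c((n - j + 1L):n, seq_len(n - j))   # shift by -j
        idx_p <- c((j + 1L):n, seq_len(j))           # shift by +j
        out <- out + k[j + 1L] * (v[idx_m] + v[idx_p])
      }
      out
    } else {
      Re(stats::fft(stats::fft(v) * op$fft_mult, inverse = TRUE)) / length(v)
    }
  } else {
    as.numeric(op %*% v)
  }
}

# One reaction-diffusion step on a raw concentration vector, Strang-split:
# half a reaction step, a full backward-Euler diffusion step, half a
# reaction step. The reaction half-steps use the pointwise exact exponential
# update (exact for pure exchange, positive for any dt), so the splitting
# error is O(dt^2) and the scheme's stationary profile agrees with the
# boundary-value steady state to second order. b may be a vector (localized
# sources).
cortex_step_raw <- function(c, koff, D, b, dx, dt, periodic, op = NULL) {
  if (D <= 0) {
    cn <- react_exact(c, koff, b, dt)
  } else {
    if (is.null(op)) op <- diffusion_operator(length(c), dx, D, dt, periodic)
    cn <- react_exact(c, koff, b, dt / 2)
    cn <- apply_diffusion(op, cn)
    cn[cn < 0] <- 0  # clip roundoff-level negatives
    cn <- react_exact(cn, koff, b, dt / 2)
  }
  if (any(!is.finite(cn))) {
    stop(sprintf(paste0("non-finite cortex field after step at dt = %g, ",
                        "dx = %g: unstable parameter combination"), dt, dx))
  }
  cn
}

react_exact <- function(c, koff, b, dt) {
  f <- exp(-koff * dt)
  if (all(koff > 0)) {
    c * f + b * (1 - f) / koff
  } else {
    pos <- koff > 0
    cn <- c * f
    cn[pos] <- cn[pos] + (b * (1 - f) / koff)[pos]
    cn[!pos] <- cn[!pos] + (if (length(b) > 1) b[!pos] else b) * dt
    cn
  }
}

#' Advance the cortical LGN field by one time step
#'
#' Semi-implicit scheme: the local exchange `b - koff(x) c` is advanced with
#' its exact exponential solution at each node, then diffusion is advanced
#' with one backward-Euler step. Both halves preserve non-negativity for any
#' `dt`; a uniform field at the fixed point `b/koff` (uniform `koff`) is
#' unchanged to machine precision.
#'
#' @param field A [cortex_field()].
#' @param koff Unbinding-rate vector, one per node (see [koff_profile()]).
#' @param kinetics An [lgn_kinetics()].
#' @param dt Time step in min.
#' @param b Optional source override (scalar or per-node vector); defaults to
#'   `kinetics$b`.
#' @return The advanced [cortex_field()].
#' @export
step_cortex <- function(field, koff, kinetics, dt, b = kinetics$b) {
  stopifnot(dt > 0, length(koff) == field$domain$n)
  dom <- field$domain
  cn <- cortex_step_raw(field$c, koff, kinetics$D, b, dom$dx, dt,
                        dom$periodic)
  cortex_field(dom, cn, field$time + dt)
}

#' Steady-state LGN profile around stationary DNA
#'
#' Solves the linear boundary-value problem `D c'' + b - koff(x) c = 0`
#' directly (dense linear solve on the grid). With a stationary spindle the
#' cortical LGN pattern is stable; this profile is the model's counterpart.
#'
#' @param dna A [dna_region()].
#' @param kinetics An [lgn_kinetics()].
#' @param domain A [domain_1d()].
#' @return A [cortex_field()] containing the steady profile.
#' @export
steady_state_profile <- function(dna, kinetics, domain) {
  koff <- koff_profile(domain, dna, kinetics)
  A <- kinetics$D * laplacian_matrix(domain$n, domain$dx, domain$periodic) -
    diag(koff)
  c <- tryCatch(solve(A, rep(-kinetics$b, domain$n)),
                error = function(e) stop("singular steady-state system: ",
                                         conditionMessage(e)))
  cortex_field(domain, pmax(c, 0))
}

# Integral of a nodal field over the domain (finite-volume weights: uniform
# dx on a circle, trapezoid on a line).
field_integral <- function(values, domain) {
  if (domain$periodic) {
    sum(values) * domain$dx
  } else {
    w <- rep(domain$dx, domain$n)
    w[c(1L, domain$n)] <- domain$dx / 2
    sum(values * w)
  }
}
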