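#' Monopolar spindle state (1D)
#'
#' The DNA centre `xn` and centrosome `xc = xn + delta` move as a rigid unit;
#' `v0` is the characteristic velocity absorbing motor force per unit LGN,
#' microtubule number, and friction (population mean 6.7 um/min across cells,
#' fitted per cell in practice).
#'
#' @param xn DNA centre position, um.
#' @param delta Rigid centrosome-DNA offset `xc - xn`, um.
#' @param v0 Characteristic velocity, um/min (>= 0).
#' @return An object of class `"monopolar_spindle"`.
#' @export
monopolar_spindle <- function(xn, delta = 0, v0 = 6.7) {
  stopifnot(v0 >= 0)
  structure(list(xn = xn, delta = delta, v0 = v0),
            class = "monopolar_spindle")
}

#' Bipolar spindle state (1D)
#'
#' Two asters at `center +/- half_sep` flanking the metaphase DNA plate at
#' `center`.
#'
#' @param center Metaphase DNA (spindle centre) position, um.
#' @param half_sep Pole half-separation, um (> 0).
#' @param v0 Characteristic velocity, um/min.
#' @return An object of class `"bipolar_spindle"`.
#' @export
bipolar_spindle <- function(center, half_sep = 5, v0 = 6.7) {
  stopifnot(half_sep > 0, v0 >= 0)
  structure(list(center = center, half_sep = half_sep, v0 = v0),
            class = "bipolar_spindle")
}

# Linear interpolation of a nodal field at arbitrary positions; periodic
# wrap on a circle, zero outside a line domain (no cortex beyond the ends).
interp_field <- function(values, domain, q) {
  n <- domain$n
  if (domain$periodic) {
    pos <- (q %% domain$L) / domain$dx
    i0 <- floor(pos + 1e-9)  # snap on-node queries to the node exactly
    frac <- pmax(pos - i0, 0)
    i0 <- (as.integer(i0) %% n) + 1L
    i1 <- i0 %% n + 1L
    values[i0] * (1 - frac) + values[i1] * frac
  } else {
    out <- numeric(length(q))
    inside <- q >= 0 & q <= domain$L
    pos <- q[inside] / domain$dx
    i0 <- pmin(floor(pos + 1e-9), n - 2)
    frac <- pmax(pos - i0, 0)
    i0 <- as.integer(i0) + 1L
    out[inside] <- values[i0] * (1 - frac) + values[i0 + 1L] * frac
    out
  }
}

# Unit-v0 aster force integral: (1/2) Int rho(u) [cbar(xc+u) - cbar(xc-u)] du.
# This is Int cbar(x) pMT(x - xc) dx with the sign discontinuity of pMT
# handled analytically, so a mirror-symmetric field gives exactly zero.
force_integral <- function(cbar, domain, xc, mt, du = domain$dx) {
  u <- seq(du, mt$max_length, by = du)
  w <- rep(du, length(u))
  w[length(u)] <- du / 2  # trapezoid end weight (the u = 0 term vanishes)
  rho <- mt_density(mt, u)
  cp <- interp_field(cbar, domain, xc + u)
  cm <- interp_field(cbar, domain, xc - u)
  0.5 * sum(w * rho * (cp - cm))
}

#' DNA velocity from LGN-weighted cortical forces
#'
#' The equation of motion of the DNA-spindle-centrosome structure:
#' `v = v0 * Int cbar(x) pMT(x - xc) dx`, where `cbar` is the LGN field
#' normalized to its spatial mean and `pMT` the signed microtubule end
#' density about the centrosome. Antisymmetric under mirror reflection of the
#' whole configuration; zero for a uniform field.
#'
#' @param field A [cortex_field()].
#' @param spindle A [monopolar_spindle()].
#' @param mt An `mt_model`.
#' @return Velocity in um/min.
#' @export
dna_velocity <- function(field, spindle, mt) {
  m <- mean(field$c)
  if (!is.finite(m) || m <= 0) stop("degenerate normalization: mean of c <= 0")
  xc <- spindle$xn + spindle$delta
  if (field$domain$periodic) xc <- xc %% field$domain$L
  spindle$v0 * force_integral(field$c / m, field$domain, xc, mt)
}

# Count direction reversals of a 1D track, ignoring sub-min_disp jitter.
count_reversals <- function(x, min_disp = 1) {
  n <- 0L
  dir <- 0
  ref <- x[1]
  for (xi in x[-1]) {
    if (dir == 0) {
      if (abs(xi - ref) >= min_disp) {
        dir <- sign(xi - ref)
        ref <- xi
      }
    } else if ((xi - ref) * dir >= 0) {
      ref <- xi
    } else if ((ref - xi) * dir >= min_disp) {
      n <- n + 1L
      dir <- -dir
      ref <- xi
    }
  }
  n
}

classify_regime <- function(xn_frames, speed, cv, min_disp = 1) {
  if (count_reversals(xn_frames, min_disp) >= 2L) return("oscillatory")
  if (is.finite(cv) && cv < 0.05 && speed > 0.05) return("traveling")
  "stationary"
}

# Shared integrator for the coupled 1D cortex-spindle dynamics. `poles` is a
# function(xn) returning centrosome position(s); the velocity is the sum of
# aster force integrals at each pole times v0.
simulate_coupled_1d <- function(kinetics, xn0, v0, poles_of, mt, domain,
                                T, dt, seed, perturb_amp, w_dna, d_inh,
                                save_dt, c0) {
  nst <- as.integer(round(T / dt))
  stopifnot(nst >= 10)
  set.seed(seed)
  sgn <- sample(c(-1, 1), 1)
  x <- domain$x
  L <- domain$L
  if (is.null(c0)) {
    base <- kinetics$b / max(kinetics$koff_far, 1e-12)
    c0 <- base * (1 + sgn * perturb_amp * sin(2 * pi * (x - xn0) / L))
  }
  stopifnot(length(c0) == domain$n)
  cvals <- pmax(as.numeric(c0), 0)
  op <- diffusion_operator(domain$n, domain$dx, kinetics$D, dt,
                           domain$periodic)
  save_every <- max(1L, as.integer(round(save_dt / dt)))
  frames <- seq(0L, nst, by = save_every)
  kymo <- matrix(NA_real_, domain$n, length(frames))
  xn_fr <- numeric(length(frames))
  v_fr <- numeric(length(frames))
  vstep <- numeric(nst)
  xn <- xn0

  velocity_at <- function(xn_cur, cb) {
    ps <- poles_of(xn_cur)
    if (domain$periodic) ps <- ps %% L
    v0 * sum(vapply(ps, function(p) force_integral(cb, domain, p, mt),
                    numeric(1)))
  }

  fi <- 1L
  kymo[, 1L] <- cvals
  xn_fr[1L] <- xn
  cb <- cvals / mean(cvals)
  v_fr[1L] <- velocity_at(xn, cb)

  for (k in seq_len(nst)) {
    xw <- if (domain$periodic) xn %% L else xn
    koff <- koff_fast(x, L, domain$periodic, xw, w_dna, d_inh, kinetics)
    cvals <- cortex_step_raw(cvals, koff, kinetics$D, kinetics$b, domain$dx,
                             dt, domain$periodic, op)
    cb <- cvals / mean(cvals)
    v <- velocity_at(xn, cb)
    vstep[k] <- v
    # advect; sub-step so the spindle never crosses more than dx/2 per update
    remaining <- dt
    iter <- 0L
    while (remaining > 0 && iter < 16L) {
      vcur <- if (iter == 0L) v else velocity_at(xn, cb)
      dts <- if (abs(vcur) > 0) min(remaining, domain$dx / 2 / abs(vcur)) else remaining
      xn <- xn + vcur * dts
      if (!domain$periodic) xn <- min(max(xn, 0), L)
      remaining <- remaining - dts
      iter <- iter + 1L
    }
    if (k %% save_every == 0L) {
      fi <- fi + 1L
      kymo[, fi] <- cvals
      xn_fr[fi] <- xn
      v_fr[fi] <- v
    }
  }

  tail_idx <- seq.int(max(1L, as.integer(0.8 * nst)), nst)
  speeds <- abs(vstep[tail_idx])
  asym <- mean(speeds)
  cv <- if (asym > 0) stats::sd(speeds) / asym else Inf
  times <- frames * dt
  poles_fr <- t(vapply(xn_fr, poles_of, numeric(length(poles_of(xn0)))))
  dna_track <- data.frame(t = times, xn = xn_fr, w = w_dna)
  ky <- kymograph(x, times, kymo, dna = dna_track, L = L,
                  periodic = domain$periodic, normalization = "raw")
  structure(list(
    times = times, xn = xn_fr, xc = poles_fr, v = v_fr,
    kymograph = ky, asymptotic_speed = asym, speed_cv = cv,
    regime = classify_regime(xn_fr, asym, cv),
    n_reversals = count_reversals(xn_fr),
    seed = seed, perturb_sign = sgn, dt = dt, T = T,
    kinetics = kinetics, mt = mt, domain = domain,
    w_dna = w_dna, d_inh = d_inh, v0 = v0
  ), class = "sim_result_1d")
}

#' @export
print.sim_result_1d <- function(x, ...) {
  cat(sprintf(paste0("<sim_result_1d> T = %g min, regime %s, asymptotic ",
                     "speed %.3f um/min (CV %.1f%%), %d reversals\n"),
              x$T, x$regime, x$asymptotic_speed, 100 * x$speed_cv,
              x$n_reversals))
  invisible(x)
}

#' Coupled monopolar spindle-cortex simulation (1D)
#'
#' Alternates cortical reaction-diffusion steps with spindle advection under
#' the LGN-weighted aster force. From a near-uniform LGN field with a small
#' seeded antisymmetric perturbation, the default parameters break symmetry
#' spontaneously and settle into a traveling wave: constant DNA velocity with
#' a co-moving LGN depletion trough.
#'
#' @param kinetics An [lgn_kinetics()].
#' @param spindle A [monopolar_spindle()].
#' @param mt An `mt_model`.
#' @param domain A [domain_1d()] (periodic for a circular cortex path).
#' @param T Total time, min (several far-field unbinding times recommended,
#'   `T >= 5/koff_far`).
#' @param dt Time step, min.
#' @param seed Integer seed fixing the perturbation sign.
#' @param perturb_amp Amplitude of the seeded antisymmetric perturbation of
#'   the initial LGN field (fraction of the uniform level).
#' @param w_dna DNA half-extent, um.
#' @param d_inh Inhibition range, um.
#' @param save_dt Kymograph/trajectory frame interval, min.
#' @param c0 Optional explicit initial LGN field (overrides the perturbed
#'   uniform default).
#' @return A `"sim_result_1d"` with frame times, unwrapped DNA/centrosome
#'   trajectory, frame velocities, raw-concentration [kymograph()], the
#'   asymptotic speed (mean |v| over the final 20% of `T`), its coefficient
#'   of variation, and a regime label (`stationary`, `traveling`,
#'   `oscillatory`).
#' @export
simulate_monopolar <- function(kinetics = lgn_kinetics(),
                               spindle = monopolar_spindle(domain$L / 2),
                               mt = mt_exponential(),
                               domain = domain_1d(80),
                               T = 450, dt = 0.05, seed = 1L,
                               perturb_amp = 1e-3, w_dna = 4, d_inh = 4,
                               save_dt = 1, c0 = NULL) {
  simulate_coupled_1d(kinetics, spindle$xn, spindle$v0,
                      function(xn) xn + spindle$delta,
                      mt, domain, T, dt, seed, perturb_amp, w_dna, d_inh,
                      save_dt, c0)
}

#' Monopolar simulation on a finite line
#'
#' Same coupled dynamics as [simulate_monopolar()] with no-flux LGN ends and
#' the aster force integral truncated at the line ends: as the spindle
#' approaches an end, forward-pointing microtubules lose their cortical
#' targets and the rear pull turns the spindle around, reproducing the
#' back-and-forth oscillations of cells on thin micropatterned lines.
#'
#' @inheritParams simulate_monopolar
#' @export
simulate_on_line <- function(kinetics = lgn_kinetics(),
                             spindle = monopolar_spindle(domain$L / 2),
                             mt = mt_exponential(),
                             domain = domain_1d(60, periodic = FALSE),
                             T = 450, dt = 0.05, seed = 1L,
                             perturb_amp = 1e-3, w_dna = 4, d_inh = 4,
                             save_dt = 1, c0 = NULL) {
  if (domain$periodic) stop("simulate_on_line requires a line domain")
  if (domain$L <= 2 * mt$mean) {
    stop("line length should exceed twice the mean microtubule length")
  }
  simulate_coupled_1d(kinetics, spindle$xn, spindle$v0,
                      function(xn) xn + spindle$delta,
                      mt, domain, T, dt, seed, perturb_amp, w_dna, d_inh,
                      save_dt, c0)
}

#' Coupled bipolar spindle-cortex simulation (1D)
#'
#' The force is the sum of the two asters' integrals; the DNA (metaphase
#' plate), which carries the unbinding inhibition, sits at the spindle
#' centre. The symmetric configuration is a fixed point of the discretization
#' (an unperturbed symmetric state stays put); depending on parameters a
#' perturbation can grow into a moving state (see [bipolar_moving_params()]).
#'
#' @inheritParams simulate_monopolar
#' @param spindle A [bipolar_spindle()].
#' @export
simulate_bipolar_1d <- function(kinetics = lgn_kinetics(),
                                spindle = bipolar_spindle(domain$L / 2),
                                mt = mt_exponential(),
                                domain = domain_1d(80),
                                T = 450, dt = 0.05, seed = 1L,
                                perturb_amp = 0, w_dna = 4, d_inh = 4,
                                save_dt = 1, c0 = NULL) {
  simulate_coupled_1d(kinetics, spindle$center, spindle$v0,
                      function(xn) c(xn - spindle$half_sep,
                                     xn + spindle$half_sep),
                      mt, domain, T, dt, seed, perturb_amp, w_dna, d_inh,
                      save_dt, c0)
}

#' Parameter set with a moving bipolar regime
#'
#' A shipped configuration for which the 1D bipolar spindle, when perturbed,
#' leaves the symmetric rest state and travels: a compact spindle (small pole
#' separation) with a stronger characteristic velocity, so each aster samples
#' the asymmetric LGN landscape beyond the plate.
#'
#' @return A list with elements `kinetics`, `spindle` (a [bipolar_spindle()]
#'   with the domain-centre position to be set by the caller), `mt`,
#'   `w_dna`, `d_inh`.
#' @export
bipolar_moving_params <- function() {
  list(kinetics = lgn_kinetics(),
       half_sep = 2,
       v0 = 25,
       mt = mt_exponential(mean = 8, max_length = 24),
       w_dna = 4, d_inh = 4)
}

#' Cortex-only simulation with an imposed DNA track
#'
#' Reproduces the kymograph-matching procedure: the DNA position is imposed
#' (e.g. an experimentally measured track), only the cortical LGN field
#' evolves, and the simulated kymograph is sampled at the track's frame times
#' and normalized to its spatiotemporal mean.
#'
#' @param kinetics An [lgn_kinetics()].
#' @param dna_track Data frame with columns `t` (min, strictly increasing)
#'   and `xn` (um; may be unwrapped on a periodic domain), optionally `w`
#'   (DNA half-extent per frame).
#' @param domain A [domain_1d()].
#' @param dt Solver time step, min.
#' @param w_dna DNA half-extent used when the track has no `w` column, um.
#' @param d_inh Inhibition range, um.
#' @param c0 Initial LGN field; defaults to the steady-state profile for the
#'   first track position.
#' @param normalize Normalize the output to the spatiotemporal mean
#'   (default TRUE).
#' @return A [kymograph()] sampled at the track frame times, with the track
#'   attached.
#' @export
simulate_imposed_dna <- function(kinetics, dna_track, domain, dt = 0.05,
                                 w_dna = 4, d_inh = 4, c0 = NULL,
                                 normalize = TRUE) {
  stopifnot(is.data.frame(dna_track), all(c("t", "xn") %in% names(dna_track)))
  tt <- dna_track$t
  if (any(diff(tt) <= 0)) stop("track times must be strictly increasing")
  if (!domain$periodic &&
      (any(dna_track$xn < 0) || any(dna_track$xn > domain$L))) {
    stop("DNA track leaves the line domain")
  }
  w <- if ("w" %in% names(dna_track)) dna_track$w else rep(w_dna, length(tt))
  if (is.null(c0)) {
    xw0 <- if (domain$periodic) dna_track$xn[1] %% domain$L else dna_track$xn[1]
    c0 <- steady_state_profile(dna_region(xw0, w[1], d_inh), kinetics,
                               domain)$c
  }
  cvals <- as.numeric(c0)
  op <- diffusion_operator(domain$n, domain$dx, kinetics$D, dt,
                           domain$periodic)
  nst <- as.integer(round((tt[length(tt)] - tt[1]) / dt))
  step_t <- tt[1] + seq_len(nst) * dt
  xn_step <- stats::approx(tt, dna_track$xn, xout = step_t, rule = 2)$y
  w_step <- stats::approx(tt, w, xout = step_t, rule = 2)$y
  out <- matrix(NA_real_, domain$n, length(tt))
  out[, 1] <- cvals
  fi <- 1L
  frame_step <- round((tt - tt[1]) / dt)
  xg <- domain$x
  for (k in seq_len(nst)) {
    xw <- if (domain$periodic) xn_step[k] %% domain$L else xn_step[k]
    koff <- koff_fast(xg, domain$L, domain$periodic, xw, w_step[k], d_inh,
                      kinetics)
    cvals <- cortex_step_raw(cvals, koff, kinetics$D, kinetics$b, domain$dx,
                             dt, domain$periodic, op)
    while (fi < length(tt) && frame_step[fi + 1L] == k) {
      fi <- fi + 1L
      out[, fi] <- cvals
    }
  }
  if (normalize) {
    out <- out / mean(out)
    norm <- "global"
  } else {
    norm <- "raw"
  }
  kymograph(domain$x, tt, out,
            dna = data.frame(t = tt, xn = dna_track$xn, w = w),
            L = domain$L, periodic = domain$periodic, normalization = norm)
}
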