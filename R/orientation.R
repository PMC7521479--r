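#' Mitotic rounding schedule
#'
#' Cell shape during mitotic entry: both elliptical half-axes relax
#' exponentially from their interphase values toward the common rounded
#' radius, `a(t) = R + (a0 - R) exp(-max(t, 0)/tau)`, with time measured from
#' nuclear envelope breakdown (NEB). Bipolar spindle assembly completes
#' `t_bipolar` minutes after NEB (~9 min), splitting mitosis into a rounding/
#' patterning phase (I) and a spindle-rotation phase (II).
#'
#' @param a0,b0 Interphase half-axes, um (`a0 >= b0 > 0`).
#' @param R Final rounded radius, um.
#' @param tau Rounding relaxation time, min.
#' @param t_bipolar Spindle-formation time after NEB, min (default 9).
#' @return An object of class `"rounding_schedule"`.
#' @export
rounding_schedule <- function(a0 = 20, b0 = 7, R = 10, tau = 4,
                              t_bipolar = 9) {
  stopifnot(a0 >= b0, b0 > 0, R > 0, tau > 0, t_bipolar > 0)
  structure(list(a0 = a0, b0 = b0, R = R, tau = tau, t_bipolar = t_bipolar),
            class = "rounding_schedule")
}

#' Cell shape at a given time of the rounding schedule
#'
#' @param schedule A [rounding_schedule()].
#' @param t Time after NEB, min (pre-NEB times give the interphase shape).
#' @return A [cell_geometry()].
#' @export
evolve_shape <- function(schedule, t) {
  f <- exp(-max(t, 0) / schedule$tau)
  cell_geometry(schedule$R + (schedule$a0 - schedule$R) * f,
                schedule$R + (schedule$b0 - schedule$R) * f)
}

#' Remap a cortical field between two contours, conserving bound LGN
#'
#' Cortex-bound material does not detach when the cell changes shape: per
#' material segment, concentration scales inversely with segment length,
#' `c_new = c_old * ds_old/ds_new`, so the contour integral of `c` is
#' conserved to machine precision. Uniform shrinkage of the perimeter
#' therefore concentrates LGN -- the "accumulation by rounding" that seeds
#' the phase-I pattern.
#'
#' @param c_old Concentration per node on the old contour.
#' @param contour_old,contour_new [build_contour()] objects with the same
#'   node count and material parameterization.
#' @return Concentration per node on the new contour.
#' @export
remap_contour_field <- function(c_old, contour_old, contour_new) {
  stopifnot(contour_old$n == contour_new$n, length(c_old) == contour_old$n)
  if (any(contour_new$ds <= 0)) stop("zero-length contour segment")
  c_old * contour_old$ds / contour_new$ds
}

#' Bipolar spindle state (2D)
#'
#' @param phi Spindle angle in radians relative to the interphase long cell
#'   axis (nematic: `phi` and `phi + pi` are the same orientation).
#' @param half_sep Pole half-separation, um.
#' @param w_plate Metaphase-plate half-length, um (phase-II DNA footprint).
#' @param r_dna Phase-I DNA disc radius, um.
#' @param mu_r Rotational mobility, rad/(min x torque unit). The default is
#'   calibrated once so that a defaults run completes reorientation from
#'   `phi0 = pi/4` within ~20 min of phase II, then frozen.
#' @return An object of class `"spindle_2d"`.
#' @export
spindle_2d <- function(phi = pi / 4, half_sep = 5, w_plate = 6, r_dna = 5,
                       mu_r = 0.5) {
  stopifnot(half_sep >= 0, w_plate >= 0, r_dna >= 0, mu_r >= 0)
  structure(list(phi = phi, half_sep = half_sep, w_plate = w_plate,
                 r_dna = r_dna, mu_r = mu_r),
            class = "spindle_2d")
}

# Distance from points (n x 2) to a segment [A, B].
point_segment_distance <- function(p, A, B) {
  ab <- B - A
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((p[, 1] - A[1])^2 + (p[, 2] - A[2])^2))
  }
  tt <- ((p[, 1] - A[1]) * ab[1] + (p[, 2] - A[2]) * ab[2]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  qx <- A[1] + tt * ab[1]
  qy <- A[2] + tt * ab[2]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
}

#' Unbinding-rate profile along the cell contour
#'
#' Phase I: distance from each contour node to the DNA disc (radius `r_dna`
#' at the cell centre). Phase II: distance to the metaphase plate, the
#' segment through the centre perpendicular to the spindle axis with
#' half-length `w_plate`. The same smooth step as in 1D converts distance to
#' a rate. During rounding this inhibits LGN along the short cell axis (the
#' cortex there is within `d_inh` of the disc) while the long-axis poles
#' remain far, which is what patterns the crescents.
#'
#' @param contour A [build_contour()] object.
#' @param spindle A [spindle_2d()] (its `phi` orients the phase-II plate).
#' @param phase `"I"` or `"II"`.
#' @param kinetics An [lgn_kinetics()].
#' @param d_inh Inhibition range from the DNA footprint, um.
#' @return Rate per contour node, 1/min.
#' @export
contour_koff <- function(contour, spindle, phase = c("I", "II"), kinetics,
                         d_inh = 4) {
  phase <- match.arg(phase)
  p <- contour$pos
  if (phase == "I") {
    d <- pmax(0, sqrt(p[, 1]^2 + p[, 2]^2) - spindle$r_dna)
  } else {
    u <- c(-sin(spindle$phi), cos(spindle$phi)) * spindle$w_plate
    d <- point_segment_distance(p, -u, u)
  }
  kinetics$koff_far + (kinetics$koff_near - kinetics$koff_far) *
    smooth_step(d, d_inh, kinetics$sigma)
}

# Interpolate a contour field at arbitrary polar angles (contour is
# star-shaped about the centre, theta is monotone along the nodes).
interp_contour <- function(values, contour, theta_q) {
  th <- contour$theta
  n <- contour$n
  tq <- theta_q %% (2 * pi)
  i0 <- findInterval(tq, th)
  i0[i0 == 0L] <- n  # below first node: wrap to last
  i1 <- i0 %% n + 1L
  th0 <- th[i0]
  dth <- (th[i1] - th0) %% (2 * pi)
  dth[dth == 0] <- 2 * pi
  frac <- ((tq - th0) %% (2 * pi)) / dth
  values[i0] * (1 - frac) + values[i1] * frac
}

#' Torque on the bipolar spindle from LGN-weighted cortical pulling
#'
#' For each pole, microtubule directions are quadratured over the full
#' circle; a direction contributes the probability `P(l >= d)` that an
#' astral microtubule reaches the cortex at distance `d`, times the LGN
#' concentration at the contact point, times the lever arm of a unit pull
#' along the microtubule direction about the cell centre:
#' `Gamma = sum_poles Int dtheta P(l >= d) c(contact) [r x f]_z`.
#'
#' @param cvals LGN concentration per contour node (absolute scale: torque is
#'   proportional to the amount of cortical force generators, so reduced LGN
#'   slows rotation).
#' @param contour A [build_contour()] object.
#' @param spindle A [spindle_2d()].
#' @param mt An `mt_model`.
#' @param n_dir Number of microtubule directions per pole (>= 360).
#' @return Torque in model units (positive rotates `phi` counterclockwise).
#' @export
spindle_torque <- function(cvals, contour, spindle, mt, n_dir = 720L) {
  stopifnot(n_dir >= 360L)
  a <- contour$geometry$a
  b <- contour$geometry$b
  ls <- spindle$half_sep
  poles <- rbind(c(ls * cos(spindle$phi), ls * sin(spindle$phi)),
                 c(-ls * cos(spindle$phi), -ls * sin(spindle$phi)))
  dth <- 2 * pi / n_dir
  th <- (seq_len(n_dir) - 0.5) * dth
  ct <- cos(th)
  st <- sin(th)
  total <- 0
  for (i in 1:2) {
    px <- poles[i, 1]
    py <- poles[i, 2]
    if ((px / a)^2 + (py / b)^2 >= 1) stop("spindle pole outside the contour")
    A <- (ct / a)^2 + (st / b)^2
    B <- 2 * (px * ct / a^2 + py * st / b^2)
    C <- (px / a)^2 + (py / b)^2 - 1
    d <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
    qx <- px + d * ct
    qy <- py + d * st
    cq <- interp_contour(cvals, contour, atan2(qy, qx))
    w <- mt_survival(mt, d)
    total <- total + sum(w * cq * (qx * st - qy * ct)) * dth
  }
  total
}

#' Nematic order of the contour LGN distribution
#'
#' The 2-fold orientational moment of intensity along the contour:
#' `Q = Int c(s) (cos 2theta, sin 2theta) ds / Int c(s) ds` with `theta(s)`
#' the contour polar angle. `S_LGN = |Q|` measures how strongly LGN is
#' concentrated along one axis; the nematic angle `= atan2(Qy, Qx)/2` is that
#' axis, reported in `(-pi/2, pi/2]`.
#'
#' @param cvals Intensity per contour node (>= 0, not all zero).
#' @param contour A [build_contour()] object.
#' @return A list with `S` in `[0, 1]`, `angle` in radians, and `degenerate`
#'   (TRUE when `S` is numerically zero and the angle is reported as 0).
#' @export
nematic_order <- function(cvals, contour) {
  w <- cvals * contour$ds
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) stop("zero total contour intensity")
  qx <- sum(w * cos(2 * contour$theta)) / tot
  qy <- sum(w * sin(2 * contour$theta)) / tot
  S <- sqrt(qx^2 + qy^2)
  if (S < 1e-12) {
    list(S = S, angle = 0, degenerate = TRUE)
  } else {
    list(S = S, angle = wrap_nematic(atan2(qy, qx) / 2), degenerate = FALSE)
  }
}

#' Spindle alignment parameter
#'
#' `a = cos 2 phi` for `phi` the spindle angle relative to the interphase
#' long cell axis: 1 when aligned, -1 when perpendicular.
#'
#' @param phi Angle(s) in radians.
#' @return Values in `[-1, 1]`.
#' @export
alignment <- function(phi) cos(2 * phi)

# Wrap an angle into the nematic fundamental interval (-pi/2, pi/2].
wrap_nematic <- function(phi) {
  out <- (phi + pi / 2) %% pi - pi / 2
  ifelse(out == -pi / 2, pi / 2, out)
}

#' Two-phase 2D simulation of mitotic rounding and spindle orientation
#'
#' Phase I (`t < t_bipolar`): the cell rounds along the schedule, cortical
#' material is remapped conservatively onto each new contour, and LGN
#' exchange with DNA-disc inhibition patterns the cortex; the spindle angle
#' is frozen. Phase II: the DNA footprint becomes the metaphase plate
#' (perpendicular to the spindle axis) and the spindle rotates with
#' `dphi/dt = mu_r * Gamma` under the LGN-weighted cortical torque.
#'
#' The simulation runs in the body frame of the interphase ellipse;
#' `axis_angle` rotates all reported angles, so rotating the initial
#' condition rotates the output exactly.
#'
#' @param schedule A [rounding_schedule()].
#' @param spindle A [spindle_2d()] carrying the initial angle `phi` (relative
#'   to the long axis).
#' @param kinetics An [lgn_kinetics()].
#' @param mt An `mt_model`.
#' @param lgn_scale Multiplies the binding source `b`; values well below 1
#'   emulate LGN RNAi (less protein reaching the cortex).
#' @param cue Optional external cue, a list with `angle` (contour polar
#'   angle, body frame), `strength` (source units) and optionally `width`
#'   (rad, default 0.3): a localized additive binding source.
#' @param T Total time after NEB, min.
#' @param dt Time step, min.
#' @param n_nodes Contour nodes.
#' @param d_inh Inhibition range from the DNA footprint, um.
#' @param axis_angle Lab-frame angle of the interphase long axis, rad.
#' @param save_dt Recording interval, min.
#' @return An object of class `"orientation_result"`: time stamps, `phi`
#'   (lab frame, unwrapped), `alignment` `a(t) = cos 2(phi - axis_angle)`,
#'   nematic magnitude `S_lgn(t)` and lab-frame nematic angle, torque trace,
#'   the contour kymograph (nodes x frames), shape series, and the final
#'   regime (`aligned`, `misaligned`, or `cue-captured`).
#' @export
run_orientation <- function(schedule = rounding_schedule(),
                            spindle = spindle_2d(),
                            kinetics = lgn_kinetics(),
                            mt = mt_exponential(),
                            lgn_scale = 1, cue = NULL,
                            T = 40, dt = 0.05, n_nodes = 256L,
                            d_inh = 4, axis_angle = 0, save_dt = 0.5) {
  nst <- as.integer(round(T / dt))
  phi <- spindle$phi  # body frame
  b0 <- kinetics$b * lgn_scale
  contour <- build_contour(evolve_shape(schedule, 0), n_nodes)
  cvals <- rep(b0 / kinetics$koff_far, n_nodes)
  cue_src <- function(contour) {
    if (is.null(cue)) return(0)
    width <- if (is.null(cue$width)) 0.3 else cue$width
    dthw <- abs(((contour$theta - cue$angle + pi) %% (2 * pi)) - pi)
    cue$strength * exp(-0.5 * (dthw / width)^2)
  }
  save_every <- max(1L, as.integer(round(save_dt / dt)))
  frames <- seq(0L, nst, by = save_every)
  nf <- length(frames)
  out_t <- frames * dt
  out_phi <- numeric(nf)
  out_S <- numeric(nf)
  out_nem <- numeric(nf)
  out_torque <- numeric(nf)
  kymo <- matrix(NA_real_, n_nodes, nf)
  shape <- matrix(NA_real_, nf, 2)

  op <- NULL
  op_ds <- -1
  record <- function(fi, torque) {
    nem <- nematic_order(cvals, contour)
    out_phi[fi] <<- phi
    out_S[fi] <<- nem$S
    out_nem[fi] <<- nem$angle
    out_torque[fi] <<- torque
    kymo[, fi] <<- cvals
    shape[fi, ] <<- c(contour$geometry$a, contour$geometry$b)
  }
  record(1L, 0)

  for (k in seq_len(nst)) {
    t_now <- k * dt
    new_contour <- build_contour(evolve_shape(schedule, t_now), n_nodes)
    cvals <- remap_contour_field(cvals, contour, new_contour)
    contour <- new_contour
    phase <- if (t_now < schedule$t_bipolar) "I" else "II"
    sp <- spindle
    sp$phi <- phi
    koff <- contour_koff(contour, sp, phase, kinetics, d_inh = d_inh)
    ds <- contour$ds[1]
    if (is.null(op) || abs(ds - op_ds) / op_ds > 0.01) {
      op <- diffusion_operator(n_nodes, ds, kinetics$D, dt, periodic = TRUE)
      op_ds <- ds
    }
    bvec <- b0 + cue_src(contour)
    cvals <- cortex_step_raw(cvals, koff, kinetics$D, bvec, ds, dt,
                             periodic = TRUE, op = op)
    torque <- 0
    if (phase == "II" && spindle$mu_r > 0) {
      torque <- spindle_torque(cvals, contour, sp, mt)
      phi <- phi + dt * spindle$mu_r * torque
    }
    if (k %% save_every == 0L) record(k %/% save_every + 1L, torque)
  }

  a_final <- alignment(phi)
  regime <- if (!is.null(cue) &&
                abs(wrap_nematic(phi - cue$angle)) < pi / 12) {
    "cue-captured"
  } else if (a_final > 0.9) "aligned" else "misaligned"

  structure(list(
    times = out_t,
    phi = out_phi + axis_angle,
    alignment = alignment(out_phi),
    S_lgn = out_S,
    nematic_angle = wrap_nematic(out_nem + axis_angle),
    torque = out_torque,
    kymograph = kymo,
    contour = contour,
    shape = data.frame(t = out_t, a_long = shape[, 1], b_short = shape[, 2]),
    regime = regime,
    schedule = schedule, spindle = spindle, kinetics = kinetics,
    lgn_scale = lgn_scale, cue = cue, axis_angle = axis_angle,
    dt = dt, T = T
  ), class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(paste0("<orientation_result> T = %g min, phi: %.1f deg -> ",
                     "%.1f deg, final alignment %.3f (%s)\n"),
              x$T, 180 / pi * x$phi[1], 180 / pi * x$phi[n],
              x$alignment[n], x$regime))
  invisible(x)
}
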