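test_that("the rounding schedule interpolates from interphase shape to the rounded circle", {
  sch <- rounding_schedule(a0 = 20, b0 = 7, R = 10, tau = 4)
  g0 <- evolve_shape(sch, 0)
  expect_equal(c(g0$a, g0$b), c(20, 7))
  gT <- evolve_shape(sch, 10 * sch$tau)
  expect_lt(abs(gT$a - 10), 1e-4 * 10)
  expect_lt(abs(gT$b - 10), 1e-4 * 3)
  gap <- sapply(seq(0, 20, 0.5), function(t) {
    g <- evolve_shape(sch, t); g$a - g$b
  })
  expect_true(all(diff(gap) < 0))
  # pre-NEB times give the interphase shape
  gpre <- evolve_shape(sch, -3)
  expect_equal(c(gpre$a, gpre$b), c(20, 7))
})

test_that("contour remapping conserves bound LGN exactly", {
  c1 <- build_contour(cell_geometry(12, 8), 128)
  same <- remap_contour_field(rep(1.5, 128), c1, c1)
  expect_equal(same, rep(1.5, 128))

  # circle radius halved: concentration doubles
  big <- build_contour(cell_geometry(10, 10), 128)
  small <- build_contour(cell_geometry(5, 5), 128)
  expect_equal(remap_contour_field(rep(1, 128), big, small), rep(2, 128),
               tolerance = 1e-9)

  # arbitrary ellipse-to-circle remap conserves the contour integral
  set.seed(8)
  cv <- runif(128, 0.2, 3)
  c2 <- build_contour(cell_geometry(9, 9), 128)
  cv2 <- remap_contour_field(cv, c1, c2)
  expect_rel_equal(sum(cv2 * c2$ds), sum(cv * c1$ds), 1e-10)
})

test_that("contour koff inhibits the short-axis cortex in phase I and the plate flanks in phase II", {
  kin <- lgn_kinetics()
  ct <- build_contour(cell_geometry(20, 7), 256)
  sp <- spindle_2d(phi = 0, r_dna = 5, w_plate = 6)
  koffI <- contour_koff(ct, sp, "I", kin, d_inh = 4)
  i_short <- which.min(abs(ct$theta - pi / 2))  # short-axis cortex, 2 um from disc
  i_long <- which.min(ct$theta)                 # long-axis pole, 15 um away
  expect_gt(koffI[i_short], 0.9 * kin$koff_near)
  expect_equal(koffI[i_long], kin$koff_far, tolerance = 1e-6)

  # pointlike DNA far from every node: uniform far rate
  sp0 <- spindle_2d(phi = 0, r_dna = 0, w_plate = 0)
  ct_big <- build_contour(cell_geometry(30, 25), 256)
  expect_equal(contour_koff(ct_big, sp0, "I", kin, d_inh = 4),
               rep(kin$koff_far, 256), tolerance = 1e-6)

  # phase II at phi = pi/4: distances match a brute-force point-to-segment scan
  ct_r <- build_contour(cell_geometry(10, 10), 256)
  sp45 <- spindle_2d(phi = pi / 4, w_plate = 6)
  koffII <- contour_koff(ct_r, sp45, "II", kin, d_inh = 4)
  seg <- seq(-1, 1, length.out = 4001)
  u <- c(-sin(pi / 4), cos(pi / 4)) * 6
  brute_d <- sapply(seq_len(256), function(i) {
    min(sqrt((ct_r$pos[i, 1] - seg * u[1])^2 + (ct_r$pos[i, 2] - seg * u[2])^2))
  })
  koff_brute <- kin$koff_far + (kin$koff_near - kin$koff_far) *
    spindlecortex:::smooth_step(brute_d, 4, kin$sigma)
  expect_equal(koffII, koff_brute, tolerance = 1e-4)
  # inhibited arcs centred perpendicular to the spindle axis (phi +/- pi/2)
  hot <- ct_r$theta[koffII > 0.9 * max(koffII)]
  expect_true(all(abs(sin(hot - 3 * pi / 4)) < 0.5))
})

test_that("cortical torque vanishes by symmetry and matches a dense brute-force quadrature", {
  ct <- build_contour(cell_geometry(10, 10), 256)
  mt <- mt_exponential()
  cres <- 1 + cos(2 * ct$theta)

  expect_lt(abs(spindle_torque(cres, ct, spindle_2d(phi = 0), mt)), 1e-10)
  expect_lt(abs(spindle_torque(cres, ct, spindle_2d(phi = pi / 2), mt)), 1e-10)
  expect_lt(abs(spindle_torque(rep(1, 256), ct, spindle_2d(phi = pi / 4), mt)),
            1e-10)

  # independent brute-force quadrature with 1e4 directions (circle geometry)
  sp <- spindle_2d(phi = pi / 4, half_sep = 5)
  G <- spindle_torque(cres, ct, sp, mt)
  expect_lt(G, 0)  # rotates phi = pi/4 toward the long axis at 0
  brute <- 0
  ndir <- 1e4
  for (pole_sign in c(1, -1)) {
    p <- pole_sign * 5 * c(cos(pi / 4), sin(pi / 4))
    th <- (seq_len(ndir) - 0.5) * 2 * pi / ndir
    # ray-circle intersection from p
    bq <- 2 * (p[1] * cos(th) + p[2] * sin(th))
    cq <- sum(p^2) - 100
    dd <- (-bq + sqrt(bq^2 - 4 * cq)) / 2
    qx <- p[1] + dd * cos(th)
    qy <- p[2] + dd * sin(th)
    cq_at <- 1 + cos(2 * atan2(qy, qx))
    brute <- brute + sum(mt_survival(mt, dd) * cq_at *
                           (qx * sin(th) - qy * cos(th))) * 2 * pi / ndir
  }
  expect_rel_equal(G, brute, 0.01)

  expect_error(spindle_torque(cres, ct, spindle_2d(phi = 0, half_sep = 11), mt),
               "outside")
})

test_that("nematic order obeys its closed forms", {
  ct <- build_contour(cell_geometry(10, 10), 360)
  u <- nematic_order(rep(2, 360), ct)
  expect_lt(u$S, 1e-10)
  expect_true(u$degenerate)
  expect_equal(u$angle, 0)

  for (beta in c(0.2, 0.6, 1)) {
    for (th0 in c(0, 0.4, -1.2)) {
      nm <- nematic_order(1 + beta * cos(2 * (ct$theta - th0)), ct)
      expect_rel_equal(nm$S, beta / 2, 1e-6)
      expect_equal(nm$angle, th0, tolerance = 1e-6)
    }
  }

  # two narrow antipodal crescents: S -> 1 at the crescent axis
  th0 <- 0.7
  for (w in c(0.2, 0.05)) {
    cv <- exp(-0.5 * (sin(ct$theta - th0) / w)^2)
    nm <- nematic_order(cv, ct)
    expect_equal(nm$angle, th0, tolerance = 1e-6)
  }
  s_wide <- nematic_order(exp(-0.5 * (sin(ct$theta - th0) / 0.2)^2), ct)$S
  s_narrow <- nematic_order(exp(-0.5 * (sin(ct$theta - th0) / 0.05)^2), ct)$S
  expect_gt(s_narrow, s_wide)
  expect_gt(s_narrow, 0.95)

  expect_error(nematic_order(rep(0, 360), ct), "zero total")
})

test_that("the alignment parameter is cos 2 phi", {
  expect_equal(alignment(0), 1)
  expect_equal(alignment(pi / 2), -1)
  expect_equal(alignment(pi / 4), 0, tolerance = 1e-15)
})

test_that("an aligned spindle stays aligned and the output rotates exactly with the frame", {
  res0 <- run_orientation(spindle = spindle_2d(phi = 0), T = 20)
  expect_lt(max(abs(res0$phi)), 1e-6)

  psi <- 0.8
  resA <- run_orientation(spindle = spindle_2d(phi = pi / 4), T = 20)
  resB <- run_orientation(spindle = spindle_2d(phi = pi / 4), T = 20,
                          axis_angle = psi)
  expect_equal(resB$phi, resA$phi + psi)
  expect_equal(resB$S_lgn, resA$S_lgn)
  expect_equal(resB$alignment, resA$alignment)
})

test_that("LGN order rises during rounding, is bounded, and the nematic axis matches the long axis", {
  res <- cached_sim("orient45",
                    run_orientation(spindle = spindle_2d(phi = pi / 4), T = 40))
  expect_true(all(res$S_lgn >= 0 & res$S_lgn <= 1))
  i9 <- which(res$times == 9)
  # by spindle formation the LGN pattern carries more nematic order than a
  # uniform field on the same (nearly round) contour: shape-independent
  # ordering built up during rounding
  ct9 <- build_contour(evolve_shape(res$schedule, 9), 256)
  s_shape <- nematic_order(rep(1, 256), ct9)$S
  expect_gt(res$S_lgn[i9], s_shape + 0.05)
  expect_lt(abs(res$nematic_angle[i9]), 5 * pi / 180)      # along the long axis
  # stabilizes after the rise
  late <- res$S_lgn[res$times >= 25]
  expect_lt(max(late) - min(late), 0.08)
  # defaults reorient from pi/4: strong final alignment
  expect_gt(res$alignment[length(res$alignment)], 0.9)
  expect_equal(res$regime, "aligned")
})

test_that("a strong perpendicular cue captures the spindle", {
  res <- run_orientation(spindle = spindle_2d(phi = pi / 4),
                         cue = list(angle = pi / 2, strength = 0.3), T = 40)
  expect_lt(abs(res$phi[length(res$phi)] - pi / 2), pi / 36)
  expect_equal(res$regime, "cue-captured")
})
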