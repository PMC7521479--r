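test_that("DNA velocity vanishes for uniform LGN, reads step contrasts, and is mirror-antisymmetric", {
  dom <- domain_1d(80)
  mt <- mt_exponential()
  sp <- monopolar_spindle(40, v0 = 6.7)

  expect_equal(dna_velocity(cortex_field(dom, rep(2, dom$n)), sp, mt), 0)

  # step contrast +/- eps around the centrosome -> v = v0 * eps (to
  # quadrature accuracy: the integrand is discontinuous at the step)
  eps <- 0.05
  cvals <- 1 + eps * sign(sin(pi * (dom$x - 40) / dom$L))  # +eps ahead, -eps behind
  v <- dna_velocity(cortex_field(dom, cvals), sp, mt)
  expect_rel_equal(v, 6.7 * eps, 0.02)

  # mirror reflection of field and spindle negates the velocity
  set.seed(1)
  cr <- 1 + 0.3 * sin(2 * pi * dom$x / dom$L) + 0.1 * cos(6 * pi * dom$x / dom$L)
  v1 <- dna_velocity(cortex_field(dom, cr), monopolar_spindle(30, v0 = 5), mt)
  cm <- rev(cr)  # mirror about the midpoint between nodes
  xm <- (dom$L - dom$dx) - 30
  v2 <- dna_velocity(cortex_field(dom, cm), monopolar_spindle(xm, v0 = 5), mt)
  expect_equal(v1, -v2, tolerance = 1e-10)

  expect_error(dna_velocity(cortex_field(dom, rep(0, dom$n)), sp, mt),
               "degenerate")
})

test_that("equal near/far rates give a stationary spindle", {
  kin0 <- lgn_kinetics(koff_near = 1 / 90, koff_far = 1 / 90)
  sim <- simulate_monopolar(kin0, domain = domain_1d(80), T = 300, seed = 4)
  expect_equal(sim$regime, "stationary")
  expect_lt(sim$asymptotic_speed, 1e-3)
})

test_that("defaults break symmetry into a traveling wave whose direction follows the seeded perturbation", {
  sim <- mono_default()
  expect_equal(sim$regime, "traveling")
  expect_gt(sim$asymptotic_speed, 0.05)
  expect_lt(sim$speed_cv, 0.05)
  nfr <- length(sim$v)
  expect_equal(sign(mean(sim$v[(nfr - 20):nfr])), sim$perturb_sign)

  # opposite-sign perturbation seed travels the other way
  sim2 <- cached_sim("mono450b",
                     simulate_monopolar(domain = domain_1d(80), T = 450,
                                        seed = 4))
  expect_true(sim2$perturb_sign != sim$perturb_sign)
  expect_equal(sign(sim2$v[length(sim2$v)]), sim2$perturb_sign)
})

test_that("in the traveling regime the LGN profile translates rigidly with the spindle", {
  sim <- mono_default()
  ky <- sim$kymograph
  dom <- sim$domain
  i1 <- which(ky$t == 400)
  i2 <- which(ky$t == 430)
  shift <- sim$xn[i2] - sim$xn[i1]
  c1 <- ky$I[, i1]
  c2 <- ky$I[, i2]
  # translate frame 1 by the spindle displacement (periodic interpolation)
  c1s <- spindlecortex:::interp_field(c1, dom, (dom$x - shift) %% dom$L)
  expect_lt(sqrt(mean((c2 - c1s)^2)) / mean(c2), 0.02)
})

test_that("the coupled dynamics are translation-equivariant and parity-odd", {
  dom <- domain_1d(40)
  kin <- lgn_kinetics()
  base_c0 <- 1 + 1e-2 * sin(2 * pi * (dom$x - 20) / dom$L)
  run <- function(xn, c0) {
    simulate_monopolar(kin, monopolar_spindle(xn), domain = dom, T = 30,
                       perturb_amp = 0, c0 = c0, save_dt = 2)
  }
  a <- run(20, base_c0)
  # shift everything by an integer number of grid cells
  delta <- 25 * dom$dx
  shift_idx <- c(16:dom$n, 1:15)  # c0 shifted by +25 nodes... compute directly
  c0_shift <- 1 + 1e-2 * sin(2 * pi * (dom$x - delta - 20) / dom$L)
  b <- run(20 + delta, c0_shift)
  expect_equal(b$xn - delta, a$xn, tolerance = 1e-8)

  # parity: mirrored initial data negates velocities frame by frame
  c0_mirror <- rev(base_c0)
  xm <- (dom$L - dom$dx) - 20
  m <- run(xm, c0_mirror)
  expect_equal(m$v, -a$v, tolerance = 1e-8)
})

test_that("a separated centrosome-DNA pair has no rest state: force is immediate and growing", {
  dom <- domain_1d(80)
  kin <- lgn_kinetics()
  ss <- steady_state_profile(dna_region(40, 4, 4), kin, dom)
  sim <- simulate_monopolar(spindle = monopolar_spindle(40, delta = 4),
                            domain = dom, T = 20, perturb_amp = 0,
                            c0 = ss$c, save_dt = 1)
  v <- abs(sim$v)
  expect_gt(v[1], 0.1)            # immediate net force from the asymmetry
  expect_true(all(diff(v[1:4]) > 0))  # early growth away from rest
})

test_that("on a 60 um line the spindle oscillates end to end with center-maximal speed", {
  sim <- line_default()
  expect_equal(sim$regime, "oscillatory")
  expect_gte(sim$n_reversals, 2)
  # turning points within 15 um of the line ends
  expect_lt(min(sim$xn), 15)
  expect_gt(max(sim$xn), sim$domain$L - 15)

  pp <- phase_portrait(trajectory(sim$times, sim$xn), W = 5)
  third <- sim$domain$L / 3
  mid <- pp$position > third & pp$position < 2 * third
  expect_gt(max(abs(pp$velocity[mid])), 0.95 * max(abs(pp$velocity)))
  # near-zero velocity at the positional extremes
  i_ext <- c(which.min(pp$position), which.max(pp$position))
  expect_lt(max(abs(pp$velocity[i_ext])), 0.25 * max(abs(pp$velocity)))
})

test_that("bipolar symmetric configurations are exact rest states; feedback-free perturbations die out", {
  dom <- domain_1d(80)
  sym <- simulate_bipolar_1d(domain = dom, T = 100, perturb_amp = 0)
  expect_lt(sym$asymptotic_speed, 1e-10)
  expect_lt(max(abs(sym$xn - 40)), 1e-10)

  kin0 <- lgn_kinetics(koff_near = 1 / 90, koff_far = 1 / 90)
  dec <- simulate_bipolar_1d(kin0, domain = dom, T = 300, perturb_amp = 1e-2,
                             seed = 5)
  expect_equal(dec$regime, "stationary")
  expect_lt(dec$asymptotic_speed, 0.01)
})

test_that("the shipped bipolar parameter set yields a moving state under perturbation", {
  dom <- domain_1d(80)
  mp <- bipolar_moving_params()
  sim <- simulate_bipolar_1d(mp$kinetics,
                             bipolar_spindle(40, mp$half_sep, mp$v0),
                             mp$mt, dom, T = 450, perturb_amp = 1e-3,
                             seed = 1, w_dna = mp$w_dna, d_inh = mp$d_inh)
  expect_equal(sim$regime, "traveling")
  expect_gt(sim$asymptotic_speed, 0.05)
})

test_that("imposed-DNA kymographs are consistent with the steady state and the coupled run", {
  dom <- domain_1d(80)
  kin <- lgn_kinetics()
  # stationary track: final frame equals the steady-state profile
  tr0 <- data.frame(t = seq(0, 60, 3), xn = 40)
  ky0 <- simulate_imposed_dna(kin, tr0, dom, normalize = FALSE)
  ss <- steady_state_profile(dna_region(40, 4, 4), kin, dom)
  expect_lt(max(abs(ky0$I[, ncol(ky0$I)] - ss$c) / ss$c), 1e-3)

  # faster DNA outruns unbinding: shallower depletion trail at 3v
  depth <- function(v) {
    tr <- data.frame(t = seq(0, 120, 3), xn = 40 + v * seq(0, 120, 3))
    ky <- simulate_imposed_dna(kin, tr, dom)
    last <- ky$I[, ncol(ky$I)]
    1 - min(last / mean(last))
  }
  expect_lt(depth(3), depth(1))

  # the coupled run's own track reproduces its kymograph
  simc <- mono_movie()
  ky <- simulate_imposed_dna(kin, simc$kymograph$dna, dom,
                             c0 = simc$kymograph$I[, 1], normalize = FALSE)
  rel_rms <- sqrt(mean((ky$I - simc$kymograph$I)^2)) / mean(simc$kymograph$I)
  expect_lt(rel_rms, 0.01)

  expect_error(simulate_imposed_dna(kin, data.frame(t = c(0, 3), xn = c(10, 70)),
                                    domain_1d(60, periodic = FALSE)), "leaves")
})

test_that("the asymptotic wave speed is grid-converged (dx and dt halved)", {
  coarse <- cached_sim("mono300",
                       simulate_monopolar(domain = domain_1d(80), T = 300,
                                          seed = 1))
  fine <- simulate_monopolar(domain = domain_1d(80, dx = 0.1), T = 300,
                             dt = 0.025, seed = 1)
  expect_rel_equal(fine$asymptotic_speed, coarse$asymptotic_speed, 0.02)
})
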