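#' Fluorescence noise model
#'
#' Multiplicative Gaussian noise (a fraction of the signal) plus an additive
#' Gaussian background, with clamping at zero: the simplest model consistent
#' with normalized fluorescence kymographs.
#'
#' @param mult_sd Multiplicative SD as a fraction of signal (default 0.1).
#' @param bg_mean,bg_sd Additive background mean and SD, intensity units
#'   (defaults 0.05 and 0.02 of the signal scale).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(mult_sd = 0.1, bg_mean = 0.05, bg_sd = 0.02) {
  stopifnot(mult_sd >= 0, bg_sd >= 0)
  structure(list(mult_sd = mult_sd, bg_mean = bg_mean, bg_sd = bg_sd),
            class = "noise_model")
}

# Apply the noise model to an intensity matrix (RNG state of the caller).
apply_noise <- function(I, noise) {
  eps_m <- matrix(stats::rnorm(length(I), 0, noise$mult_sd), nrow(I))
  eps_a <- matrix(stats::rnorm(length(I), noise$bg_mean, noise$bg_sd), nrow(I))
  pmax(I * (1 + eps_m) + eps_a, 0)
}

#' Synthetic monopolar-spindle experiment
#'
#' Runs the coupled monopolar simulation, samples the kymograph at the frame
#' interval, applies imaging noise, and returns the noisy data together with
#' a ground-truth manifest. Identical seeds give identical datasets. The
#' quantification functions never need the manifest, enabling honest
#' parameter-recovery tests.
#'
#' @param kinetics,spindle,mt,domain Model components (see
#'   [simulate_monopolar()]).
#' @param noise A [noise_model()] (`noise_model(0, 0, 0)` for noiseless
#'   output).
#' @param frame_interval Frame interval, min (2, 3 or 5 in the emulated
#'   experiments).
#' @param T Movie duration, min.
#' @param seed Integer seed (simulation perturbation and noise).
#' @param dir Optional directory: data files are written under `dir/data`,
#'   the ground-truth manifest under `dir/truth`.
#' @param ... Further arguments passed to [simulate_monopolar()].
#' @return A list with `kymograph` (noisy, raw normalization), `trajectory`
#'   (the DNA track, unwrapped), `truth` (manifest list including the clean
#'   simulation result summary).
#' @export
make_monopolar_dataset <- function(kinetics = lgn_kinetics(),
                                   spindle = monopolar_spindle(domain$L / 2),
                                   mt = mt_exponential(),
                                   domain = domain_1d(80),
                                   noise = noise_model(),
                                   frame_interval = 3, T = 450,
                                   seed = 1L, dir = NULL, ...) {
  sim <- simulate_monopolar(kinetics, spindle, mt, domain, T = T,
                            seed = seed, save_dt = frame_interval, ...)
  finish_dataset(sim, noise, seed, dir,
                 extra = list(v0 = spindle$v0, delta = spindle$delta,
                              frame_interval = frame_interval))
}

#' Synthetic line-pattern experiment
#'
#' As [make_monopolar_dataset()] on a finite line (default 60 um), where the
#' coupled dynamics oscillate; the manifest records the number of direction
#' reversals.
#'
#' @inheritParams make_monopolar_dataset
#' @export
make_line_dataset <- function(kinetics = lgn_kinetics(),
                              spindle = monopolar_spindle(domain$L / 2),
                              mt = mt_exponential(),
                              domain = domain_1d(60, periodic = FALSE),
                              noise = noise_model(),
                              frame_interval = 3, T = 450,
                              seed = 1L, dir = NULL, ...) {
  sim <- simulate_on_line(kinetics, spindle, mt, domain, T = T,
                          seed = seed, save_dt = frame_interval, ...)
  finish_dataset(sim, noise, seed, dir,
                 extra = list(v0 = spindle$v0, delta = spindle$delta,
                              frame_interval = frame_interval))
}

finish_dataset <- function(sim, noise, seed, dir, extra = list()) {
  set.seed(seed + 104729L)  # decouple noise draws from the simulation seed
  ky <- sim$kymograph
  ky$I <- apply_noise(ky$I, noise)
  track <- trajectory(sim$times, sim$xn)
  truth <- c(list(
    seed = seed,
    D = sim$kinetics$D, b = sim$kinetics$b,
    koff_near = sim$kinetics$koff_near, koff_far = sim$kinetics$koff_far,
    sigma = sim$kinetics$sigma,
    w_dna = sim$w_dna, d_inh = sim$d_inh,
    L = sim$domain$L, dx = sim$domain$dx, periodic = sim$domain$periodic,
    T = sim$T, dt = sim$dt,
    mt_type = sim$mt$type,
    mt_mean = if (sim$mt$type == "exponential") sim$mt$mean else NA,
    mt_max = sim$mt$max_length,
    noise_mult_sd = noise$mult_sd, noise_bg_mean = noise$bg_mean,
    noise_bg_sd = noise$bg_sd,
    asymptotic_speed = sim$asymptotic_speed, regime = sim$regime,
    n_reversals = sim$n_reversals
  ), extra)
  out <- list(kymograph = ky, trajectory = track, truth = truth)
  if (!is.null(dir)) {
    data_dir <- file.path(dir, "data")
    truth_dir <- file.path(dir, "truth")
    dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
    write_kymograph(ky, file.path(data_dir, "kymograph.tsv"))
    write_track(track, file.path(data_dir, "track.tsv"))
    write_manifest(truth, file.path(truth_dir, "manifest.yml"))
  }
  out
}

#' Synthetic rounding-and-orientation experiments
#'
#' One [run_orientation()] per requested initial angle; returns per-cell
#' contour kymographs, shape series mimicking measured rounding axes, angle
#' tracks, and ground-truth manifests. Noise is applied to contour
#' intensities only.
#'
#' @param schedule A [rounding_schedule()].
#' @param spindle,kinetics,mt Model components (see [run_orientation()]).
#' @param noise A [noise_model()].
#' @param phi0 Vector of initial spindle angles, rad.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [run_orientation()].
#' @return A list of per-cell lists with `kymograph` (nodes x frames),
#'   `shape`, `angles` (data frame `t`, `phi`), `truth`.
#' @export
make_rounding_dataset <- function(schedule = rounding_schedule(),
                                  spindle = spindle_2d(),
                                  kinetics = lgn_kinetics(),
                                  mt = mt_exponential(),
                                  noise = noise_model(),
                                  phi0 = c(0, pi / 6, pi / 4, pi / 3),
                                  seed = 1L, ...) {
  lapply(seq_along(phi0), function(i) {
    sp <- spindle
    sp$phi <- phi0[i]
    res <- run_orientation(schedule, sp, kinetics, mt, ...)
    set.seed(seed + i)
    ky <- apply_noise(res$kymograph, noise)
    list(kymograph = ky,
         shape = res$shape,
         angles = data.frame(t = res$times, phi = res$phi),
         truth = list(seed = seed, phi0 = phi0[i], mu_r = spindle$mu_r,
                      final_phi = res$phi[length(res$phi)],
                      regime = res$regime))
  })
}

#' Cohort specification for synthetic populations
#'
#' @param n Number of cells.
#' @param v0_mean,v0_sd Population mean and SD of the per-cell characteristic
#'   velocity (defaults 6.7 and 6.7 um/min; draws are truncated at 0 since
#'   the printed SD equals the mean).
#' @param L_range Range of cortical path lengths, um.
#' @param frame_intervals Allowed frame intervals, min.
#' @param seed Master seed; every per-cell draw and seed derives from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 12L, v0_mean = 6.7, v0_sd = 6.7,
                        L_range = c(60, 100), frame_intervals = c(2, 3, 5),
                        seed = 1L) {
  stopifnot(n >= 1, v0_sd >= 0, all(frame_intervals %in% c(2, 3, 5)))
  structure(list(n = as.integer(n), v0_mean = v0_mean, v0_sd = v0_sd,
                 L_range = L_range, frame_intervals = frame_intervals,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-cell parameter draws for a cohort
#'
#' Draws each cell's `v0` from a normal truncated at 0, a domain length, a
#' frame interval from the allowed set, and a derived per-cell seed, all
#' deterministically from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per cell: `cell`, `v0`, `L`,
#'   `frame_interval`, `seed`.
#' @export
cohort_draws <- function(spec) {
  set.seed(spec$seed)
  v0 <- numeric(spec$n)
  for (i in seq_len(spec$n)) {
    repeat {
      z <- stats::rnorm(1, spec$v0_mean, spec$v0_sd)
      if (z >= 0) break
    }
    v0[i] <- z
  }
  data.frame(
    cell = seq_len(spec$n),
    v0 = v0,
    L = stats::runif(spec$n, spec$L_range[1], spec$L_range[2]),
    frame_interval = sample(rep(spec$frame_intervals, length.out = spec$n),
                            spec$n),
    seed = sample.int(.Machine$integer.max - 1L, spec$n)
  )
}

#' Synthetic cohort of monopolar-spindle movies
#'
#' One [make_monopolar_dataset()] per cell with parameters from
#' [cohort_draws()]; the cohort manifest records every draw.
#'
#' @param spec A [cohort_spec()].
#' @param T Movie duration per cell, min.
#' @param noise A [noise_model()].
#' @param dir Optional output directory (one subdirectory per cell plus an
#'   `index.tsv` and cohort manifest).
#' @param ... Further arguments passed to [make_monopolar_dataset()].
#' @return A list with `draws` (the parameter table) and `cells` (the list
#'   of datasets).
#' @export
make_cohort <- function(spec = cohort_spec(), T = 240, noise = noise_model(),
                        dir = NULL, ...) {
  draws <- cohort_draws(spec)
  cells <- lapply(seq_len(spec$n), function(i) {
    dom <- domain_1d(draws$L[i])
    make_monopolar_dataset(
      spindle = monopolar_spindle(dom$L / 2, v0 = draws$v0[i]),
      domain = dom,
      noise = noise,
      frame_interval = draws$frame_interval[i],
      T = T, seed = draws$seed[i],
      dir = if (is.null(dir)) NULL else file.path(dir, sprintf("cell%02d", i)),
      ...)
  })
  if (!is.null(dir)) {
    utils::write.table(draws, file.path(dir, "index.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_manifest(c(unclass(spec), list(T = T)),
                   file.path(dir, "cohort_manifest.yml"))
  }
  list(draws = draws, cells = cells)
}
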