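#' Normalize a fluorescence kymograph
#'
#' Background is subtracted (negatives clamped to zero before averaging) and
#' the intensity is divided either by the spatiotemporal mean (`global`, the
#' analysis normalization) or by each frame's own spatial mean (`per-frame`,
#' the display normalization). Global normalization is invariant under a
#' uniform detector gain.
#'
#' @param kymo A [kymograph()] with raw intensities.
#' @param background Background intensity outside the cell.
#' @param mode `"global"` or `"per-frame"`.
#' @return The normalized [kymograph()].
#' @export
normalize_kymograph <- function(kymo, background = 0,
                                mode = c("global", "per-frame")) {
  mode <- match.arg(mode)
  I <- pmax(kymo$I - background, 0)
  if (mode == "global") {
    m <- mean(I)
    if (m <= 0) stop("non-positive mean intensity after background subtraction")
    I <- I / m
    kymo$normalization <- "global"
  } else {
    m <- colMeans(I)
    if (any(m <= 0)) stop("non-positive frame mean after background subtraction")
    I <- sweep(I, 2, m, "/")
    kymo$normalization <- "per-frame"
  }
  kymo$I <- I
  kymo
}

# Cumulative trapezoid integral of y over t, starting at 0.
cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Per-cell characteristic-velocity fit
#'
#' Fits the single free coefficient `v0` of the DNA equation of motion to an
#' observed displacement track. Per frame, the unit-`v0` velocity
#' `u(t_j) = Int cbar(x, t_j) pMT(x - xc_j) dx` is computed from the
#' kymograph; its cumulative trapezoid `g(t)` is the predicted displacement
#' per unit `v0`, and the least-squares solution through the origin is the
#' closed form `v0 = sum(g * dx_obs) / sum(g^2)`. The fit is exactly
#' invariant to intensity scale (each frame is normalized to its spatial
#' mean) and exactly linear in the observed displacement.
#'
#' @param kymo A [kymograph()] (any normalization; frames are re-normalized
#'   internally).
#' @param dna_track Data frame with `t`, `xn` (unwrapped, um); defaults to
#'   the track attached to the kymograph. Provides the observed
#'   displacement.
#' @param mt An `mt_model`.
#' @param delta Centrosome-DNA offset `xc - xn`, um, or a per-frame vector.
#' @param xc_track Optional separately measured centrosome track (data frame
#'   with `xn`) used for the force positions; defaults to `dna_track`.
#' @return A list with `v0` (um/min, clipped at 0 with `clipped` flag),
#'   `predicted` (displacement at the frame times), `unit_response` (`g`),
#'   and `t`.
#' @export
fit_v0 <- function(kymo, dna_track = kymo$dna, mt = mt_exponential(),
                   delta = 0, xc_track = dna_track) {
  stopifnot(!is.null(dna_track), nrow(dna_track) == length(kymo$t))
  dom <- kymo_domain(kymo)
  nfr <- length(kymo$t)
  delta <- rep_len(delta, nfr)
  u <- numeric(nfr)
  for (j in seq_len(nfr)) {
    cc <- kymo$I[, j]
    m <- mean(cc)
    if (m <= 0) stop("degenerate frame: non-positive mean intensity")
    xc <- xc_track$xn[j] + delta[j]
    if (dom$periodic) xc <- xc %% dom$L
    u[j] <- force_integral(cc / m, dom, xc, mt)
  }
  g <- cumtrapz(kymo$t, u)
  if (all(g == 0)) stop("no force signal: unit response identically zero")
  dx_obs <- dna_track$xn - dna_track$xn[1]
  v0 <- sum(g * dx_obs) / sum(g^2)
  clipped <- v0 < 0
  if (clipped) v0 <- 0
  list(v0 = v0, predicted = v0 * g, unit_response = g, t = kymo$t,
       clipped = clipped)
}

#' Kinetic-parameter fit to an observed kymograph
#'
#' Formalizes the kymograph-matching procedure as least squares: the forward
#' model is [simulate_imposed_dna()] with the observed DNA track, and a
#' derivative-free simplex search over `log(D, koff_near, koff_far, d_inh)`
#' minimizes the RMS difference between the simulated and observed
#' (globally normalized) kymographs.
#'
#' @param kymo Observed [kymograph()] (normalized internally if raw).
#' @param dna_track DNA track (defaults to the one attached to `kymo`).
#' @param domain Optional [domain_1d()] (defaults to the kymograph's grid).
#' @param init Initial guess: list or named vector with `D`, `koff_near`,
#'   `koff_far`, `d_inh`.
#' @param dt Forward-model time step, min.
#' @param maxit Simplex iteration budget per stage.
#' @param restarts Simplex restarts from the current best point.
#' @return A list with the fitted `D`, `koff_near`, `koff_far`, `d_inh`,
#'   the RMS `residual`, `converged` flag, and the evaluation count.
#' @export
fit_kinetics <- function(kymo, dna_track = kymo$dna, domain = NULL,
                         init = list(D = 0.02, koff_near = 0.2,
                                     koff_far = 0.02, d_inh = 6),
                         dt = 0.05, maxit = 400L, restarts = 1L) {
  if (is.null(domain)) domain <- kymo_domain(kymo)
  if (kymo$normalization != "global") kymo <- normalize_kymograph(kymo)
  obs <- kymo$I
  w0 <- if ("w" %in% names(dna_track)) dna_track$w[1] else 4
  objective <- function(logp) {
    p <- exp(logp)
    if (p[2] < p[3]) return(1e6)  # koff_near < koff_far: outside the model
    kin <- lgn_kinetics(D = p[1], koff_near = p[2], koff_far = p[3],
                        b = p[3], sigma = 0.5)
    sim <- tryCatch(
      simulate_imposed_dna(kin, dna_track, domain, dt = dt, w_dna = w0,
                           d_inh = p[4]),
      error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    sqrt(mean((sim$I - obs)^2))
  }
  p0 <- log(unlist(init)[c("D", "koff_near", "koff_far", "d_inh")])
  best <- list(par = p0, value = objective(p0), counts = 0L)
  for (s in seq_len(1L + restarts)) {
    fit <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       abstol = 1e-9))
    if (fit$value <= best$value) {
      best <- list(par = fit$par, value = fit$value,
                   counts = best$counts + fit$counts[1])
    }
    if (best$value < 1e-8) break  # exact fit reached (noiseless data)
  }
  p <- exp(best$par)
  list(D = p[[1]], koff_near = p[[2]], koff_far = p[[3]], d_inh = p[[4]],
       residual = best$value, converged = best$value < 1e-3,
       evaluations = best$counts)
}

#' DNA-to-high-LGN inhibition range
#'
#' The minimum distance between the DNA and cortex sites whose intensity
#' reaches the top `1 - q` quantile (default threshold at the 0.975
#' quantile): threshold the frame, then take the minimum DNA distance over
#' supra-threshold sites (ties at the threshold included).
#'
#' @param intensity Intensity per site (>= 40 sites so the top quantile is
#'   non-empty).
#' @param distance Distance of each site to the DNA region, um.
#' @param q Quantile defining "high-level" intensity (default 0.975;
#'   linear-interpolation sample quantile).
#' @return Minimum distance in um.
#' @export
inhibition_range <- function(intensity, distance, q = 0.975) {
  stopifnot(length(intensity) == length(distance), length(intensity) >= 40)
  thr <- stats::quantile(intensity, q, names = FALSE, type = 7)
  min(distance[intensity >= thr])
}

#' Inhibition range from a stationary LGN profile
#'
#' Recovers the model's DNA-to-cortex inhibition range from the steady-state
#' LGN profile around a stationary DNA region: the local off-rate is
#' reconstructed from the stationary balance `koff(x) = (D c'' + b) / c`
#' using the solver's own discrete Laplacian, and the returned estimate is
#' the distance from the DNA edge at which the reconstructed rate crosses
#' the midpoint between its near and far plateau values (linear
#' interpolation between nodes, averaged over the crossings on both sides).
#'
#' @param dna A [dna_region()] (its `d_inh` is the quantity being recovered;
#'   only its position/extent are used by the reconstruction).
#' @param kinetics An [lgn_kinetics()].
#' @param domain A [domain_1d()].
#' @return Estimated inhibition range in um.
#' @export
estimate_inhibition_midpoint <- function(dna, kinetics, domain) {
  ss <- steady_state_profile(dna, kinetics, domain)
  Lap <- laplacian_matrix(domain$n, domain$dx, domain$periodic)
  koff_rec <- (kinetics$D * as.numeric(Lap %*% ss$c) + kinetics$b) / ss$c
  mid <- (max(koff_rec) + min(koff_rec)) / 2
  d <- distance_to_dna(domain$x, dna, domain)
  s <- koff_rec - mid
  cross <- which(s[-domain$n] * s[-1] < 0)
  if (!length(cross)) stop("no off-rate transition found in the profile")
  est <- vapply(cross, function(j) {
    d[j] + (0 - s[j]) * (d[j + 1] - d[j]) / (s[j + 1] - s[j])
  }, numeric(1))
  mean(est)
}

#' Per-interval speeds and maximum excursion of a track
#'
#' Frame-to-frame speeds `|dx|/dt` and the maximum distance of the track
#' from its time-averaged position; trajectories exceeding 10 um excursion
#' (freely wandering spindles) are flagged.
#'
#' @param track A [trajectory()] (1D or 2D), positions unwrapped.
#' @return A list with `speeds` (um/min), `mean_speed`, `max_excursion`
#'   (um), and `exceeds_10um`.
#' @export
speeds_and_excursion <- function(track) {
  stopifnot(nrow(track) >= 2)
  if (any(diff(track$t) == 0)) stop("duplicate timestamps in track")
  P <- as.matrix(track[, setdiff(names(track), "t"), drop = FALSE])
  step <- sqrt(rowSums(diff(P)^2))
  speeds <- step / diff(track$t)
  ctr <- colMeans(P)
  exc <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  list(speeds = speeds, mean_speed = mean(speeds),
       max_excursion = max(exc), exceeds_10um = max(exc) > 10)
}

#' Phase portrait of a 1D track
#'
#' Moving-average smoothing (window `W` frames, odd; windows shrink
#' symmetrically near the ends, which leaves linear trends exactly
#' unchanged) followed by central-difference velocities
#' (one-sided at the endpoints), giving the (position, velocity) portrait in
#' which line-pattern oscillations appear as closed loops with pauses at the
#' positional extremes.
#'
#' @param track A 1D [trajectory()].
#' @param W Smoothing window in frames (odd, `< nrow(track)`).
#' @return A data frame with `t`, `position`, `velocity`.
#' @export
phase_portrait <- function(track, W = 5L) {
  n <- nrow(track)
  if (W %% 2L == 0L) stop("smoothing window W must be odd")
  if (W >= n) stop("smoothing window W must be smaller than the track length")
  h <- (W - 1L) %/% 2L
  x <- track$x
  xs <- vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)  # symmetric window: unbiased on linear trends
    mean(x[(i - r):(i + r)])
  }, numeric(1))
  tt <- track$t
  v <- numeric(n)
  v[1] <- (xs[2] - xs[1]) / (tt[2] - tt[1])
  v[n] <- (xs[n] - xs[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- (xs[i + 1] - xs[i - 1]) / (tt[i + 1] - tt[i - 1])
  }
  data.frame(t = tt, position = xs, velocity = v)
}

#' Cohort alignment summary
#'
#' Interpolates each cell's spindle-angle track to a common time grid,
#' converts to the alignment parameter `a = cos 2 phi`, and reports the
#' pointwise mean and standard deviation.
#'
#' @param angle_tracks List of data frames with columns `t` and `phi` (rad).
#' @param grid Common time grid (defaults to the first track's times).
#' @return A data frame with `t`, `mean_a`, `sd_a`, `n`.
#' @export
alignment_summary <- function(angle_tracks, grid = NULL) {
  if (length(angle_tracks) == 0) stop("empty set of angle tracks")
  if (is.null(grid)) grid <- angle_tracks[[1]]$t
  A <- vapply(angle_tracks, function(tr) {
    phi <- stats::approx(tr$t, tr$phi, xout = grid, rule = 2)$y
    cos(2 * phi)
  }, numeric(length(grid)))
  A <- matrix(A, nrow = length(grid))
  data.frame(t = grid,
             mean_a = rowMeans(A),
             sd_a = apply(A, 1, stats::sd),
             n = length(angle_tracks))
}
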