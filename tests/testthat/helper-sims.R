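# Cached reference simulations shared across test files (computed once per
# test session).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, expr) {
  if (is.null(.sim_cache[[name]])) assign(name, expr, envir = .sim_cache)
  .sim_cache[[name]]
}

# Default coupled monopolar run, long enough to settle into the traveling
# wave (T covers 5 far-field unbinding times).
mono_default <- function() {
  cached_sim("mono450",
             simulate_monopolar(domain = domain_1d(80), T = 450, seed = 1))
}

# Default run on a 60 um line (oscillatory regime).
line_default <- function() {
  cached_sim("line450", simulate_on_line(T = 450, seed = 2))
}

# Defaults sampled like a movie: frames every 3 min for 120 min.
mono_movie <- function() {
  cached_sim("mono120",
             simulate_monopolar(domain = domain_1d(80), T = 120, seed = 1,
                                save_dt = 3))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
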