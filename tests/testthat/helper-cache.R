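# Expensive network simulations are shared across test files through a
# per-session memo cache, so the default PING run, the white-noise run, etc.
# are computed once however many tests consult them.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# default PING run under constant drive (resonance reference)
default_ping <- function() {
  cached("default_ping", simulate_ping(duration = 5, seed = 1))
}

# matched PING+M run: identical drive and seed
default_ping_m <- function() {
  cached("default_ping_m",
         simulate_ping(duration = 5, seed = 1, variant = "ping_m"))
}

default_lif <- function() {
  cached("default_lif", simulate_lif(duration = 5, seed = 1))
}

# white-noise transmission run: default network plus titrated noise
whitenoise_run <- function() {
  cached("whitenoise_run", {
    dur <- 40
    wn <- generate_white_noise(mean = 0.75, fs = 1017.1, duration = dur,
                               seed = 101)
    sim <- simulate_ping(ping_params(), stimulus = wn, seed = 5)
    list(wn = wn, sim = sim, dur = dur)
  })
}

# mild bivariate AR(2) fixture with x -> y coupling (GC ground truth)
gc_fixture_spec <- function() {
  var_spec(A = list(matrix(c(0.5, 0.1, 0, 0.5), 2, 2),
                    matrix(c(-0.36, 0, 0, -0.36), 2, 2)),
           Sigma = diag(2), fs = 200)
}
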