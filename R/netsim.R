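#' Hodgkin-Huxley point-neuron parameter sets
#'
#' `rtm_neuron()` returns the reduced Traub-Miles pyramidal-cell parameters
#' and `wb_neuron()` the Wang-Buzsaki basket-cell parameters (capacitance in
#' uF/cm^2, reversal potentials in mV, maximal conductances in mS/cm^2).
#' `g_M` is the M-current conductance, 0 except for the adapting excitatory
#' cells of the PING+M variant (0.4 mS/cm^2).
#'
#' @param g_M M-current maximal conductance (mS/cm^2).
#' @return Named list of neuron parameters.
#' @export
rtm_neuron <- function(g_M = 0) {
  stopifnot(g_M >= 0)
  list(C = 1, v_Na = 50, v_K = -100, v_L = -67,
       g_Na = 100, g_K = 80, g_L = 0.1, g_M = g_M)
}

#' @rdname rtm_neuron
#' @export
wb_neuron <- function() {
  list(C = 1, v_Na = 55, v_K = -90, v_L = -65,
       g_Na = 35, g_K = 9, g_L = 0.1, g_M = 0)
}

#' Synaptic kinetics
#'
#' Two-variable rise/decay gating: excitatory synapses rise with
#' tau_r = tau_peak = 0.5 ms and decay with tau_d = 3 ms toward a 0 mV
#' reversal; inhibitory synapses decay with 9 ms toward -75 mV. The decay
#' constant of the auxiliary drive variable is solved numerically so the
#' gate peaks exactly `tau_peak` after a spike.
#'
#' @param tau_r,tau_peak,tau_d rise, peak, decay time constants (ms).
#' @param v_rev synaptic reversal potential (mV).
#' @return Named list, including the solved `tau_dq`.
#' @export
synapse_params <- function(tau_r = 0.5, tau_peak = 0.5, tau_d = 3,
                           v_rev = 0) {
  stopifnot(tau_r > 0, tau_peak > 0, tau_d > 0)
  list(tau_r = tau_r, tau_peak = tau_peak, tau_d = tau_d, v_rev = v_rev,
       tau_dq = solve_tau_dq(tau_r, tau_peak, tau_d))
}

# decay constant of the auxiliary synaptic variable such that the gate s
# peaks tau_peak ms after a presynaptic spike (q(0) = 1, s(0) = 0)
solve_tau_dq <- function(tau_r, tau_peak, tau_d) {
  peak_time <- function(tau_dq) {
    dt <- 0.002
    q <- 1; s <- 0; t <- 0; s_prev <- -1
    while (t < 20) {
      dq <- -q / tau_dq
      ds <- q * (1 - s) / tau_r - s / tau_d
      q <- q + dt * dq
      s <- s + dt * ds
      t <- t + dt
      if (s < s_prev) return(t - dt)
      s_prev <- s
    }
    t
  }
  stats::uniroot(function(x) peak_time(x) - tau_peak,
                 interval = c(0.01, 10), tol = 1e-4)$root
}

#' PING network parameters
#'
#' Defaults are the printed parameter table of the conductance-based
#' pyramidal-interneuron gamma network: 200 RTM excitatory cells, 50 WB
#' basket cells, mean excitatory drive 1.5 uA/cm^2 with a frozen Gaussian
#' across-neuron spread of 0.05 uA/cm^2, no recurrent excitation, and
#' synaptic conductance scales g_EI = g_II = 0.25 mS/cm^2 on 50% random
#' connectivity. Subscripts are presynaptic-first (g_EI couples E onto I).
#'
#' NOTE: g_IE (I onto E) is not part of the printed table; it defaults to
#' 0.25 mS/cm^2, matching g_EI and g_II. Override it explicitly if you want
#' a different feedback-inhibition strength.
#'
#' The conductance of an individual existing synapse is
#' `g_XY / (p_XY * N_X)`, so the expected aggregate conductance onto a cell
#' equals the table value independently of pool size.
#'
#' @param N_E,N_I pool sizes.
#' @param I_E,I_I mean external drives (uA/cm^2).
#' @param sigma_E across-neuron drive spread (uA/cm^2), frozen per neuron.
#' @param g_EE,g_EI,g_IE,g_II synaptic conductance scales (mS/cm^2).
#' @param p_EI,p_IE,p_II connection probabilities.
#' @param drive_gain stimulus-to-current scale (uA/cm^2 per drive unit).
#' @param dt integration step (ms).
#' @param fs_out output sampling rate for rates and field proxy (Hz).
#' @return A `ping_params` list.
#' @export
ping_params <- function(N_E = 200, N_I = 50, I_E = 1.5, sigma_E = 0.05,
                        I_I = 0, g_EE = 0, g_EI = 0.25, g_IE = 0.25,
                        g_II = 0.25, p_EI = 0.5, p_IE = 0.5, p_II = 0.5,
                        drive_gain = 1, dt = 0.02, fs_out = 1000) {
  stopifnot(N_E > 0, N_I > 0, dt > 0,
            all(c(p_EI, p_IE, p_II) >= 0), all(c(p_EI, p_IE, p_II) <= 1),
            all(c(g_EE, g_EI, g_IE, g_II) >= 0))
  structure(list(N_E = N_E, N_I = N_I, I_E = I_E, sigma_E = sigma_E,
                 I_I = I_I, g_EE = g_EE, g_EI = g_EI, g_IE = g_IE,
                 g_II = g_II, p_EI = p_EI, p_IE = p_IE, p_II = p_II,
                 drive_gain = drive_gain, dt = dt, fs_out = fs_out),
            class = "ping_params")
}

#' LIF network parameters
#'
#' Printed defaults of the leaky integrate-and-fire network: 200 excitatory
#' and 50 inhibitory units, tau = R C = 24 ms exactly, Euler step 0.5 ms,
#' instantaneous synapses with per-pair magnitudes drawn once uniformly in
#' `[0, PSP]`. PSP subscripts are postsynaptic-first (the only reading under
#' which the printed signs are consistent): `PSP_EI = -0.8` is the jump onto
#' an E cell when an I cell fires. Excitatory cells are never mutually
#' connected, whatever `PSP_EE` says; the remaining connectivity is
#' all-to-all.
#'
#' @param N_E,N_I pool sizes.
#' @param I_E mean excitatory drive (nA); `sigma_E` its frozen spread.
#' @param I_I inhibitory drive (nA).
#' @param PSP_EE,PSP_IE,PSP_EI,PSP_II postsynaptic-potential magnitudes (mV).
#' @param dt Euler step (ms).
#' @param C capacitance (nF); R input resistance (MOhm).
#' @param V_spike,V_thresh,V_reset,V_leak voltages (mV).
#' @param drive_gain stimulus-to-current scale (nA per drive unit).
#' @return A `lif_params` list with derived `tau = R * C`.
#' @export
lif_params <- function(N_E = 200, N_I = 50, I_E = 1.5, sigma_E = 0.05,
                       I_I = 0, PSP_EE = 1.1, PSP_IE = 0.6, PSP_EI = -0.8,
                       PSP_II = -0.8, dt = 0.5, C = 0.6, R = 40,
                       V_spike = 30, V_thresh = -40, V_reset = -75,
                       V_leak = -60, drive_gain = 1) {
  stopifnot(dt > 0, V_thresh > V_reset, C > 0, R > 0)
  structure(list(N_E = N_E, N_I = N_I, I_E = I_E, sigma_E = sigma_E,
                 I_I = I_I, PSP_EE = PSP_EE, PSP_IE = PSP_IE,
                 PSP_EI = PSP_EI, PSP_II = PSP_II, dt = dt, C = C, R = R,
                 V_spike = V_spike, V_thresh = V_thresh, V_reset = V_reset,
                 V_leak = V_leak, tau = R * C, drive_gain = drive_gain),
            class = "lif_params")
}

new_sim_result <- function(raster, field, fs_out, duration, params, seed,
                           model, pools, connectivity = NULL) {
  structure(list(raster = raster, field = field, fs_out = fs_out,
                 duration = duration, params = params, seed = seed,
                 model = model, pools = pools, connectivity = connectivity),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> model=%s, %.1f s, %d spikes from %d units\n",
              x$model, x$duration, nrow(x$raster),
              length(unique(x$raster$unit))))
  invisible(x)
}

#' Simulate the conductance-based PING network
#'
#' Integrates the recurrent E-I network of reduced Traub-Miles pyramidal
#' cells and Wang-Buzsaki basket cells with a classical fixed-step 4th-order
#' scheme (default step 0.02 ms). The external current to excitatory cell i
#' is `I_E + eta_i + drive_gain * stimulus(t)` with `eta_i` a frozen
#' per-neuron Gaussian offset of spread `sigma_E` (deterministic
#' heterogeneity, not temporal noise). Variants: `"ping_m"` adds the
#' M-current (g_M = 0.4 mS/cm^2) to the excitatory cells, producing
#' spike-frequency adaptation; `"no_II"` removes I-to-I connectivity.
#' Results are bit-for-bit reproducible under a fixed seed.
#'
#' @param params a [ping_params()].
#' @param stimulus optional `stim_trace` added to the excitatory drive
#'   (zero-order held onto the integration grid).
#' @param seed integer seed (connectivity, heterogeneity, initial voltages).
#' @param variant `"ping"`, `"ping_m"`, or `"no_II"`.
#' @param duration duration (s); defaults to the stimulus duration.
#' @param neuron_e,neuron_i neuron parameter lists ([rtm_neuron()],
#'   [wb_neuron()]).
#' @param g_M M-current conductance used by `variant = "ping_m"`.
#' @return A `sim_result`: `raster` (tibble `unit`, `pool`, `time_s`),
#'   `field` (tibble `time_s`, `field`; negated total synaptic current onto
#'   the E pool at `fs_out`), plus parameter/seed provenance.
#' @export
simulate_ping <- function(params = ping_params(), stimulus = NULL, seed = 1L,
                          variant = c("ping", "ping_m", "no_II"),
                          duration = NULL,
                          neuron_e = rtm_neuron(), neuron_i = wb_neuron(),
                          g_M = 0.4) {
  variant <- match.arg(variant)
  p <- params
  if (is.null(duration)) {
    if (is.null(stimulus)) abort("give a stimulus or an explicit duration")
    duration <- nrow(stimulus) / stim_fs(stimulus)
  }
  if (variant == "ping_m") neuron_e$g_M <- g_M
  if (variant == "ping_m" && neuron_e$g_M <= 0)
    abort("ping_m variant requires g_M > 0 on excitatory cells")
  g_II <- if (variant == "no_II") 0 else p$g_II

  n <- p$N_E + p$N_I
  type <- c(rep(0L, p$N_E), rep(1L, p$N_I))
  syn_e <- synapse_params(0.5, 0.5, 3, 0)
  syn_i <- synapse_params(0.5, 0.5, 9, -75)

  wiring <- withr_seed(seed, {
    Wt <- matrix(0, n, n)                       # post x pre
    iE <- seq_len(p$N_E); iI <- p$N_E + seq_len(p$N_I)
    add_block <- function(Wt, pre, post, g, prob) {
      if (g > 0 && prob > 0) {
        conn <- matrix(runif(length(post) * length(pre)) < prob,
                       length(post), length(pre))
        Wt[post, pre] <- Wt[post, pre] + conn * g / (prob * length(pre))
      }
      Wt
    }
    Wt <- add_block(Wt, iE, iI, p$g_EI, p$p_EI)
    Wt <- add_block(Wt, iI, iE, p$g_IE, p$p_IE)
    Wt <- add_block(Wt, iI, iI, g_II, p$p_II)
    if (p$g_EE > 0) Wt <- add_block(Wt, iE, iE, p$g_EE, 1)
    eta <- rnorm(p$N_E, 0, p$sigma_E)
    v0 <- runif(n, -75, -55)
    list(Wt = Wt, eta = eta, v0 = v0)
  })

  dt <- p$dt
  n_steps <- round(duration * 1000 / dt)
  dec <- max(1L, round(1000 / (p$fs_out * dt)))
  stim_vec <- if (is.null(stimulus)) numeric(0)
              else stim_at(stimulus, (seq_len(n_steps) - 1) * dt / 1000)
  res <- sim_hh_cpp(type = type,
                    g_M = c(rep(neuron_e$g_M, p$N_E), rep(0, p$N_I)),
                    I0 = c(p$I_E + wiring$eta, rep(p$I_I, p$N_I)),
                    gain1 = c(rep(p$drive_gain, p$N_E), rep(0, p$N_I)),
                    gain2 = rep(0, n), stim1 = stim_vec, stim2 = numeric(0),
                    Wt = wiring$Wt,
                    tau_r = rep(c(syn_e$tau_r, syn_i$tau_r), c(p$N_E, p$N_I)),
                    tau_d = rep(c(syn_e$tau_d, syn_i$tau_d), c(p$N_E, p$N_I)),
                    tau_dq = rep(c(syn_e$tau_dq, syn_i$tau_dq),
                                 c(p$N_E, p$N_I)),
                    v_rev = rep(c(syn_e$v_rev, syn_i$v_rev),
                                c(p$N_E, p$N_I)),
                    field_pool = type == 0L, v_init = wiring$v0,
                    par_e = unlist(neuron_e[c("C", "v_Na", "v_K", "v_L",
                                              "g_Na", "g_K", "g_L")]),
                    par_i = unlist(neuron_i[c("C", "v_Na", "v_K", "v_L",
                                              "g_Na", "g_K", "g_L")]),
                    dt = dt, n_steps = n_steps, dec = dec)
  pools <- c(rep("E", p$N_E), rep("I", p$N_I))
  raster <- tibble(unit = res$spike_cell,
                   pool = pools[res$spike_cell],
                   time_s = res$spike_time)
  fs_out <- 1000 / (dt * dec)
  field <- tibble(time_s = (seq_along(res$field) - 1) / fs_out,
                  field = res$field)
  new_sim_result(raster, field, fs_out, duration,
                 c(p, list(variant = variant, g_M_E = neuron_e$g_M)),
                 seed, paste0("ping", if (variant != "ping")
                   paste0("_", sub("ping_", "", variant))), pools,
                 connectivity = wiring$Wt)
}

#' Simulate the LIF network
#'
#' Forward-Euler integration of the printed update rule
#' `V = V + dt * (-(V - E) + I R) / tau` at dt = 0.5 ms. Spiking units reset
#' to `V_reset` and deliver instantaneous PSP jumps to their targets (one
#' step later). Connectivity is all-to-all except between excitatory cells;
#' each ordered pair's magnitude is a frozen uniform draw in `[0, PSP]`.
#'
#' @param params a [lif_params()].
#' @param stimulus optional `stim_trace` added to the excitatory drive (nA).
#' @param seed integer seed.
#' @param duration duration (s); defaults to the stimulus duration.
#' @return A `sim_result` (the LIF model has no synaptic-current field
#'   proxy; `field` holds the population spike count per output bin).
#' @export
simulate_lif <- function(params = lif_params(), stimulus = NULL, seed = 1L,
                         duration = NULL) {
  p <- params
  if (is.null(duration)) {
    if (is.null(stimulus)) abort("give a stimulus or an explicit duration")
    duration <- nrow(stimulus) / stim_fs(stimulus)
  }
  n <- p$N_E + p$N_I
  iE <- seq_len(p$N_E); iI <- p$N_E + seq_len(p$N_I)
  wiring <- withr_seed(seed, {
    Wt <- matrix(0, n, n)                       # post x pre
    draw <- function(nr, nc, psp) matrix(runif(nr * nc) * psp, nr, nc)
    Wt[iI, iE] <- draw(p$N_I, p$N_E, p$PSP_IE)  # onto I from E
    Wt[iE, iI] <- draw(p$N_E, p$N_I, p$PSP_EI)  # onto E from I
    Wt[iI, iI] <- draw(p$N_I, p$N_I, p$PSP_II)
    diag(Wt) <- 0                               # no self-synapses
    eta <- rnorm(p$N_E, 0, p$sigma_E)
    v0 <- runif(n, p$V_reset, p$V_thresh)
    list(Wt = Wt, eta = eta, v0 = v0)
  })
  n_steps <- round(duration * 1000 / p$dt)
  stim_vec <- if (is.null(stimulus)) numeric(0)
              else stim_at(stimulus, (seq_len(n_steps) - 1) * p$dt / 1000)
  res <- sim_lif_cpp(I0 = c(p$I_E + wiring$eta, rep(p$I_I, p$N_I)),
                     gain = c(rep(p$drive_gain, p$N_E), rep(0, p$N_I)),
                     stim = stim_vec, Wt = wiring$Wt, v_init = wiring$v0,
                     dt = p$dt, n_steps = n_steps, R = p$R, tau = p$tau,
                     E = p$V_leak, v_thresh = p$V_thresh,
                     v_reset = p$V_reset)
  pools <- c(rep("E", p$N_E), rep("I", p$N_I))
  raster <- tibble(unit = res$spike_cell, pool = pools[res$spike_cell],
                   time_s = res$spike_time)
  fs_out <- 1000
  cnt <- bin_spikes(raster$time_s, fs_out, duration)
  field <- tibble(time_s = (seq_along(cnt) - 1) / fs_out, field = cnt)
  new_sim_result(raster, field, fs_out, duration, unclass(p), seed, "lif",
                 pools, connectivity = wiring$Wt)
}

#' Simulate the gated two-excitatory-population network
#'
#' One inhibitory pool is recurrently coupled with a first excitatory pool
#' (E1) exactly as in the PING network and driven by `stimulus_1`. The
#' resulting rhythmic inhibition is also fed into a second excitatory pool
#' (E2), which is driven by the independent `stimulus_2` and projects to no
#' one (out-degree zero): the E1-I circuit gates transmission through E2
#' without receiving anything back from it.
#'
#' @param params a [ping_params()] (E1/I structure and conductances).
#' @param e2_size number of E2 cells.
#' @param stimulus_1,stimulus_2 independent white-noise `stim_trace`s for E1
#'   and E2 (a shared noise seed triggers a warning).
#' @param seed integer seed.
#' @param g_IE2 I-onto-E2 conductance scale (mS/cm^2); 0 disconnects the
#'   gate.
#' @param I_E2 tonic drive to E2 (uA/cm^2). The default keeps E2 below
#'   rheobase so that its spikes are fluctuation-driven and any rhythmicity
#'   in them comes from the gating inhibition, not from intrinsic pacemaking.
#' @return A `sim_result` with pools `E1`, `E2`, `I`.
#' @export
simulate_gated <- function(params = ping_params(), e2_size = 200,
                           stimulus_1, stimulus_2, seed = 1L,
                           g_IE2 = params$g_IE, I_E2 = 0) {
  p <- params
  s1 <- attr(stimulus_1, "params")$seed
  s2 <- attr(stimulus_2, "params")$seed
  if (!is.null(s1) && !is.null(s2) && identical(s1, s2))
    warn("stimulus_1 and stimulus_2 share a seed: the two noise streams are identical")
  duration <- nrow(stimulus_1) / stim_fs(stimulus_1)
  n <- p$N_E + p$N_I + e2_size
  iE1 <- seq_len(p$N_E)
  iI <- p$N_E + seq_len(p$N_I)
  iE2 <- p$N_E + p$N_I + seq_len(e2_size)
  type <- integer(n); type[iI] <- 1L
  syn_e <- synapse_params(0.5, 0.5, 3, 0)
  syn_i <- synapse_params(0.5, 0.5, 9, -75)
  wiring <- withr_seed(seed, {
    Wt <- matrix(0, n, n)
    blk <- function(pre, post, g, prob) {
      conn <- matrix(runif(length(post) * length(pre)) < prob,
                     length(post), length(pre))
      conn * g / (prob * length(pre))
    }
    if (p$g_EI > 0) Wt[iI, iE1] <- blk(iE1, iI, p$g_EI, p$p_EI)
    if (p$g_IE > 0) Wt[iE1, iI] <- blk(iI, iE1, p$g_IE, p$p_IE)
    if (p$g_II > 0) Wt[iI, iI] <- blk(iI, iI, p$g_II, p$p_II)
    if (g_IE2 > 0) Wt[iE2, iI] <- blk(iI, iE2, g_IE2, p$p_IE)
    eta1 <- rnorm(p$N_E, 0, p$sigma_E)
    eta2 <- rnorm(e2_size, 0, p$sigma_E)
    v0 <- runif(n, -75, -55)
    list(Wt = Wt, eta1 = eta1, eta2 = eta2, v0 = v0)
  })
  dt <- p$dt
  n_steps <- round(duration * 1000 / dt)
  dec <- max(1L, round(1000 / (p$fs_out * dt)))
  tt <- (seq_len(n_steps) - 1) * dt / 1000
  ne <- rtm_neuron(); ni <- wb_neuron()
  res <- sim_hh_cpp(type = type, g_M = rep(0, n),
                    I0 = c(p$I_E + wiring$eta1, rep(p$I_I, p$N_I),
                           I_E2 + wiring$eta2),
                    gain1 = ifelse(seq_len(n) %in% iE1, p$drive_gain, 0),
                    gain2 = ifelse(seq_len(n) %in% iE2, p$drive_gain, 0),
                    stim1 = stim_at(stimulus_1, tt),
                    stim2 = stim_at(stimulus_2, tt),
                    Wt = wiring$Wt,
                    tau_r = ifelse(type == 0L, syn_e$tau_r, syn_i$tau_r),
                    tau_d = ifelse(type == 0L, syn_e$tau_d, syn_i$tau_d),
                    tau_dq = ifelse(type == 0L, syn_e$tau_dq, syn_i$tau_dq),
                    v_rev = ifelse(type == 0L, syn_e$v_rev, syn_i$v_rev),
                    field_pool = type == 0L, v_init = wiring$v0,
                    par_e = unlist(ne[c("C", "v_Na", "v_K", "v_L",
                                        "g_Na", "g_K", "g_L")]),
                    par_i = unlist(ni[c("C", "v_Na", "v_K", "v_L",
                                        "g_Na", "g_K", "g_L")]),
                    dt = dt, n_steps = n_steps, dec = dec)
  pools <- character(n); pools[iE1] <- "E1"; pools[iI] <- "I"
  pools[iE2] <- "E2"
  raster <- tibble(unit = res$spike_cell, pool = pools[res$spike_cell],
                   time_s = res$spike_time)
  fs_out <- 1000 / (dt * dec)
  field <- tibble(time_s = (seq_along(res$field) - 1) / fs_out,
                  field = res$field)
  new_sim_result(raster, field, fs_out, duration,
                 c(p, list(e2_size = e2_size, g_IE2 = g_IE2)), seed,
                 "gated", pools, connectivity = wiring$Wt)
}

#' Field-potential proxy of a simulation
#'
#' The continuous field analog retained by the conductance-based simulators:
#' the negated sum of all synaptic currents onto the excitatory pool,
#' averaged onto the output grid. Constant for a silent network.
#'
#' @param sim a `sim_result`.
#' @return Tibble `time_s`, `field`.
#' @export
field_proxy <- function(sim) {
  if (is.null(sim$field)) abort("simulation did not retain synaptic states")
  sim$field
}

#' Binned population firing rate
#'
#' @param sim a `sim_result`.
#' @param pool pool label(s) to include (default: all).
#' @param fs_out bin rate (Hz), default the simulation output rate.
#' @return Tibble `time_s`, `rate` (total spikes/s of the pool).
#' @export
pop_rate <- function(sim, pool = NULL, fs_out = NULL) {
  fs_out <- fs_out %||% sim$fs_out
  st <- sim$raster
  if (!is.null(pool)) st <- st[st$pool %in% pool, ]
  cnt <- bin_spikes(st$time_s, fs_out, sim$duration)
  tibble(time_s = (seq_along(cnt) - 1) / fs_out, rate = cnt * fs_out)
}

#' Multi-unit activity analog: pooled spikes of a unit subsample
#'
#' @param sim a `sim_result`.
#' @param n_units subsample size (default 20).
#' @param pool pool(s) to draw from (default excitatory pools).
#' @param seed seed for the subsample.
#' @return Sorted spike times (s) of the pooled subsample.
#' @export
mua_spikes <- function(sim, n_units = 20, pool = NULL, seed = 1L) {
  pools <- unique(sim$pools)
  if (is.null(pool)) pool <- grep("^E", pools, value = TRUE)
  units <- which(sim$pools %in% pool)
  pick <- withr_seed(seed, sample(units, min(n_units, length(units))))
  sort(sim$raster$time_s[sim$raster$unit %in% pick])
}

#' Single-neuron frequency-current (f-I) curve
#'
#' Firing rate of one isolated cell as a function of constant drive; the
#' oracle for rheobase location and integration accuracy.
#'
#' @param drive_grid drive levels (uA/cm^2 for HH models, nA for LIF).
#' @param model `"rtm"`, `"wb"`, or `"lif"`.
#' @param dt integration step (ms).
#' @param duration total simulated time per level (s).
#' @param transient discarded initial time (s).
#' @param g_M M-current conductance for `"rtm"` (default 0).
#' @return Tibble `drive`, `rate` (spikes/s).
#' @export
single_neuron_fI <- function(drive_grid, model = c("rtm", "wb", "lif"),
                             dt = NULL, duration = 1.3, transient = 0.3,
                             g_M = 0) {
  model <- match.arg(model)
  rate <- vapply(drive_grid, function(I) {
    if (model == "lif") {
      p <- lif_params(N_E = 1, N_I = 0, I_E = I, sigma_E = 0)
      if (!is.null(dt)) p$dt <- dt
      n_steps <- round(duration * 1000 / p$dt)
      res <- sim_lif_cpp(I0 = I, gain = 0, stim = numeric(0),
                         Wt = matrix(0, 1, 1), v_init = p$V_leak,
                         dt = p$dt, n_steps = n_steps, R = p$R, tau = p$tau,
                         E = p$V_leak, v_thresh = p$V_thresh,
                         v_reset = p$V_reset)
    } else {
      ne <- if (model == "rtm") rtm_neuron(g_M) else wb_neuron()
      ty <- if (model == "rtm") 0L else 1L
      dt_use <- dt %||% 0.02
      n_steps <- round(duration * 1000 / dt_use)
      syn <- synapse_params()
      res <- sim_hh_cpp(type = ty, g_M = ne$g_M, I0 = I, gain1 = 0,
                        gain2 = 0, stim1 = numeric(0), stim2 = numeric(0),
                        Wt = matrix(0, 1, 1), tau_r = syn$tau_r,
                        tau_d = syn$tau_d, tau_dq = syn$tau_dq,
                        v_rev = syn$v_rev, field_pool = TRUE, v_init = -67,
                        par_e = unlist(rtm_neuron()[c("C", "v_Na", "v_K",
                          "v_L", "g_Na", "g_K", "g_L")]),
                        par_i = unlist(wb_neuron()[c("C", "v_Na", "v_K",
                          "v_L", "g_Na", "g_K", "g_L")]),
                        dt = dt_use, n_steps = n_steps, dec = 1000L)
    }
    sum(res$spike_time > transient) / (duration - transient)
  }, numeric(1))
  tibble(drive = drive_grid, rate = rate)
}

#' Welch power spectral density
#'
#' Hann-tapered averaged periodogram over 50%-overlapping segments, used for
#' locating spectral peaks of population signals.
#'
#' @param signal numeric vector or tibble with a signal column.
#' @param fs sampling rate (Hz) for bare vectors.
#' @param seg_s segment length (s).
#' @param demean remove the signal mean first (default TRUE).
#' @return Tibble `freq`, `power`.
#' @export
welch_psd <- function(signal, fs = NULL, seg_s = 1, demean = TRUE) {
  xs <- extract_signal(signal, fs)
  x <- xs$x; fs <- xs$fs
  if (demean) x <- x - mean(x)
  n_seg <- min(length(x), round(seg_s * fs))
  taper <- hann_window(n_seg)
  step <- max(1L, floor(n_seg / 2))
  starts <- seq.int(1L, length(x) - n_seg + 1L, by = step)
  nf <- floor(n_seg / 2) + 1L
  P <- numeric(nf)
  for (s0 in starts) {
    X <- fft((x[s0 + seq_len(n_seg) - 1L] - 0) * taper)[seq_len(nf)]
    P <- P + Mod(X)^2
  }
  P <- P / (length(starts) * sum(taper^2) * fs)
  tibble(freq = (seq_len(nf) - 1) * fs / n_seg, power = P)
}

#' Spectral peak frequency with parabolic interpolation
#'
#' @param signal numeric vector or tibble.
#' @param fs sampling rate (Hz) for bare vectors.
#' @param band `c(lo, hi)` Hz searched.
#' @param seg_s Welch segment length (s).
#' @param transient initial time discarded (s).
#' @return List `freq` (Hz), `power`, and the `psd` tibble.
#' @export
spectral_peak <- function(signal, fs = NULL, band = c(10, 200), seg_s = 1,
                          transient = 0) {
  xs <- extract_signal(signal, fs)
  x <- xs$x
  if (transient > 0) x <- x[-seq_len(round(transient * xs$fs))]
  psd <- welch_psd(x, xs$fs, seg_s = seg_s)
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  i <- sel[which.max(psd$power[sel])]
  f <- psd$freq[i]
  if (i > 1 && i < nrow(psd)) {      # parabolic refinement on log power
    y <- log(pmax(psd$power[(i - 1):(i + 1)], .Machine$double.xmin))
    den <- y[1] - 2 * y[2] + y[3]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (y[1] - y[3]) / den
      f <- f + delta * (psd$freq[2] - psd$freq[1])
    }
  }
  list(freq = f, power = psd$power[i], psd = psd)
}

#' Gamma-band power of a signal
#'
#' Integrated Welch power inside the gamma band.
#'
#' @inheritParams spectral_peak
#' @param band gamma band, default 30-90 Hz.
#' @return Band power (signal units^2).
#' @export
band_power <- function(signal, fs = NULL, band = c(30, 90), seg_s = 1,
                       transient = 0) {
  xs <- extract_signal(signal, fs)
  x <- xs$x
  if (transient > 0) x <- x[-seq_len(round(transient * xs$fs))]
  psd <- welch_psd(x, xs$fs, seg_s = seg_s)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$power[sel]) * (psd$freq[2] - psd$freq[1])
}

#' Tidy a simulation result into its spike raster
#' @param x a `sim_result`.
#' @param ... unused.
#' @return Tibble `unit`, `pool`, `time_s`.
#' @export
tidy.sim_result <- function(x, ...) x$raster

#' One-row summary of a simulation
#' @param x a `sim_result`.
#' @param ... unused.
#' @return Tibble with spike counts, mean per-neuron rates, and the
#'   population-rate gamma peak.
#' @export
glance.sim_result <- function(x, ...) {
  re <- pop_rate(x, grep("^E", unique(x$pools), value = TRUE))
  n_e <- sum(grepl("^E", x$pools))
  pk <- spectral_peak(re$rate, x$fs_out, band = c(10, 200),
                      transient = min(0.5, x$duration / 4))
  tibble(model = x$model, duration = x$duration,
         n_spikes = nrow(x$raster),
         rate_e = sum(grepl("^E", x$raster$pool)) / n_e / x$duration,
         rate_i = sum(x$raster$pool == "I") / sum(x$pools == "I") /
           x$duration,
         peak_freq = pk$freq)
}
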