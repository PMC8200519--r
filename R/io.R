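#' Run configuration for a simulate-and-analyze protocol
#'
#' A run configuration names a model, a stimulus protocol, the analyses to
#' apply, and the seeds, with every unspecified model parameter resolving to
#' the printed table defaults. Configurations round-trip losslessly through
#' YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param model `"ping"`, `"ping_m"`, `"no_II"`, `"lif"`, or `"gated"`.
#' @param stimulus list with `kind` and protocol parameters (as in
#'   [generate_stimulus()]), plus `duration` and optionally `fs`.
#' @param params named list of model parameter overrides (fields of
#'   [ping_params()] / [lif_params()]).
#' @param analyses character vector from `"spectrum"`, `"tfr"`,
#'   `"hysteresis"`, `"sta"`, `"gc"`.
#' @param seed integer seed.
#' @param duration duration (s) when no stimulus is given.
#' @return A `run_config` list.
#' @export
run_config <- function(model = "ping", stimulus = NULL, params = list(),
                       analyses = "spectrum", seed = 1L, duration = NULL) {
  models <- c("ping", "ping_m", "no_II", "lif", "gated")
  if (!model %in% models)
    abort(paste0("unknown model; must be one of: ",
                 paste(models, collapse = ", ")))
  known <- if (model == "lif") names(formals(lif_params))
           else c(names(formals(ping_params)), "e2_size", "g_IE2", "I_E2")
  bad <- setdiff(names(params), known)
  if (length(bad))
    abort(paste0("unknown parameter field(s): ", paste(bad, collapse = ", ")))
  an_known <- c("spectrum", "tfr", "hysteresis", "sta", "gc")
  bad_an <- setdiff(analyses, an_known)
  if (length(bad_an))
    abort(paste0("unknown analysis selection(s): ",
                 paste(bad_an, collapse = ", ")))
  structure(list(model = model, stimulus = stimulus, params = params,
                 analyses = analyses, seed = as.integer(seed),
                 duration = duration),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate and analyze one protocol, persisting a result bundle
#'
#' Builds the stimulus, runs the configured model, applies the selected
#' analyses, and writes everything to `out_dir` as plain-text files: the
#' raster as `raster.csv` (`trial`, `unit`, `time_s`), continuous signals
#' and spectra as CSV, and a provenance manifest (`manifest.json`) holding
#' the resolved parameters, seeds and package version. A rerun from the same
#' config reproduces the raster bit-for-bit.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   persistence and just returns the bundle.
#' @return Invisibly, a list with `sim` and one entry per analysis.
#' @export
run_protocol <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stim <- NULL
  if (!is.null(config$stimulus)) {
    sa <- config$stimulus
    stim <- do.call(generate_stimulus,
                    c(list(kind = sa$kind,
                           duration = sa$duration %||% config$duration,
                           fs = sa$fs %||% 1017.1,
                           seed = sa$seed %||% config$seed),
                      sa[setdiff(names(sa),
                                 c("kind", "duration", "fs", "seed"))]))
  }
  p_over <- config$params
  sim <- switch(config$model,
    lif = simulate_lif(do.call(lif_params, p_over), stim,
                       seed = config$seed, duration = config$duration),
    gated = {
      extra <- p_over[intersect(names(p_over),
                                c("e2_size", "g_IE2", "I_E2"))]
      pp <- do.call(ping_params,
                    p_over[setdiff(names(p_over), names(extra))])
      s2 <- generate_white_noise(
        mean = attr(stim, "params")$mean %||% 1, fs = stim_fs(stim),
        duration = nrow(stim) / stim_fs(stim), seed = config$seed + 7919L)
      do.call(simulate_gated,
              c(list(params = pp, stimulus_1 = stim, stimulus_2 = s2,
                     seed = config$seed), extra))
    },
    simulate_ping(do.call(ping_params, p_over), stim, seed = config$seed,
                  variant = if (config$model == "ping") "ping"
                            else config$model,
                  duration = config$duration)
  )
  bundle <- list(sim = sim)
  e_pools <- grep("^E", unique(sim$pools), value = TRUE)
  rate_e <- pop_rate(sim, e_pools)
  if ("spectrum" %in% config$analyses) {
    bundle$spectrum <- welch_psd(rate_e$rate, sim$fs_out)
    pk <- spectral_peak(rate_e$rate, sim$fs_out, band = c(10, 200),
                        transient = min(0.5, sim$duration / 4))
    bundle$peak <- tibble(peak_freq = pk$freq, peak_power = pk$power)
  }
  sig <- if (sim$model == "lif") rate_e$rate else field_proxy(sim)$field
  if (any(c("tfr", "hysteresis") %in% config$analyses)) {
    bundle$tfr <- tf_power(sig, sim$fs_out, freqs = seq(12, 100, 1))
  }
  if ("hysteresis" %in% config$analyses) {
    bundle$hysteresis <- hysteresis_curves(bundle$tfr, stim,
                                           band = c(12, 100))
  }
  if ("sta" %in% config$analyses) {
    mua <- mua_spikes(sim, 20, seed = config$seed + 1L)
    bundle$sta <- spike_triggered_average(
      tibble(time_s = stim$time_s, value = stim$intensity), mua, 0.1)
  }
  if ("gc" %in% config$analyses) {
    mua <- mua_spikes(sim, 20, seed = config$seed + 1L)
    fs <- stim_fs(stim)
    len <- floor(2 * fs)
    n_tr <- floor(nrow(stim) / len)
    y <- bin_spikes(mua, fs, sim$duration)
    tx <- lapply(seq_len(n_tr), function(i)
      stim$intensity[(i - 1) * len + seq_len(len)])
    ty <- lapply(seq_len(n_tr), function(i) y[(i - 1) * len + seq_len(len)])
    bundle$gc <- suppressWarnings(
      granger_from_csd(estimate_csd(tx, ty, fs = fs), fmin = 1, fmax = 150))
  }
  if (!is.null(out_dir)) persist_bundle(bundle, config, stim, out_dir)
  invisible(bundle)
}

persist_bundle <- function(bundle, config, stim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(as.data.frame(d),
                                          file.path(out_dir, f),
                                          row.names = FALSE)
  sim <- bundle$sim
  wcsv(cbind(trial = 1L, sim$raster[, c("unit", "time_s")]), "raster.csv")
  wcsv(sim$field, "field.csv")
  if (!is.null(stim)) write_stim_csv(stim, file.path(out_dir, "stimulus.csv"))
  if (!is.null(bundle$spectrum)) wcsv(bundle$spectrum, "spectrum.csv")
  if (!is.null(bundle$hysteresis)) wcsv(bundle$hysteresis, "hysteresis.csv")
  if (!is.null(bundle$sta)) wcsv(bundle$sta, "sta.csv")
  if (!is.null(bundle$gc)) wcsv(bundle$gc, "gc.csv")
  if (!is.null(bundle$tfr)) wcsv(tidy(bundle$tfr), "tfr.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gammaflow")),
    config = unclass(config),
    resolved_params = sim$params,
    seed = sim$seed,
    model = sim$model,
    n_spikes = nrow(sim$raster))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Regenerate a canned modeling scenario
#'
#' Each scenario is a pre-configured simulate-and-analyze run matching one
#' of the package's headline model analyses:
#' \describe{
#'   \item{resonance}{default PING under constant drive; population-rate and
#'     field spectra with the gamma peak.}
#'   \item{drive_sweep}{constant-drive levels from 1x to 2x the default
#'     excitatory drive; peak frequency and gamma power per level.}
#'   \item{hysteresis}{10-s slow sine for PING and PING+M; rising/falling
#'     power and frequency curves and loop areas.}
#'   \item{entrainment}{sinusoidal drive at 5-80 Hz; cross-correlation
#'     modulation depth per frequency and the phase-slope latency fit.}
#'   \item{whitenoise_gc}{white-noise drive of PING; spike-triggered input
#'     average and the directed transfer spectra both ways.}
#'   \item{gated}{two-excitatory-population model; E2 spike-triggered
#'     averages of its own noise and of the inhibitory population, with and
#'     without the inhibitory gate.}
#' }
#' Scenario sizes are reduced relative to the full acceptance analyses so a
#' scenario completes in minutes; pass `duration`/`seeds` overrides for
#' larger runs.
#'
#' @param figure_id one of the scenario names above.
#' @param out_dir optional directory for the persisted bundle and plots.
#' @param seed integer seed.
#' @param duration base simulation length (s) where applicable.
#' @return A list of tibbles/objects specific to the scenario.
#' @export
reproduce <- function(figure_id = c("resonance", "drive_sweep", "hysteresis",
                                    "entrainment", "whitenoise_gc", "gated"),
                      out_dir = NULL, seed = 1L, duration = NULL) {
  figure_id <- match.arg(figure_id)
  out <- switch(figure_id,
    resonance = {
      dur <- duration %||% 5
      sim <- simulate_ping(duration = dur, seed = seed)
      re <- pop_rate(sim, "E")
      fp <- field_proxy(sim)
      list(sim = glance(sim),
           rate_peak = spectral_peak(re$rate, sim$fs_out, band = c(10, 200),
                                     transient = 0.5),
           field_peak = spectral_peak(fp$field, sim$fs_out,
                                      band = c(10, 200), transient = 0.5),
           spectrum = welch_psd(re$rate, sim$fs_out))
    },
    drive_sweep = {
      dur <- duration %||% 3
      levels <- seq(1.5, 3, length.out = 5)
      sweep <- purrr::map_dfr(levels, function(I) {
        ps <- simulate_ping(ping_params(I_E = I), duration = dur,
                            seed = seed)
        ls <- simulate_lif(lif_params(I_E = I), duration = dur, seed = seed)
        purrr::map_dfr(list(ps, ls), function(s) {
          re <- pop_rate(s, "E")
          pk <- spectral_peak(re$rate, s$fs_out, band = c(25, 95),
                              transient = 0.5)
          tibble(model = s$model, drive = I, peak_freq = pk$freq,
                 gamma_power = band_power(re$rate, s$fs_out,
                                          band = c(30, 90),
                                          transient = 0.5))
        })
      })
      list(sweep = sweep)
    },
    hysteresis = {
      st <- generate_stimulus("slow_sine", duration = duration %||% 10,
                              peak = 2)
      purrr::map(list(ping = "ping", ping_m = "ping_m"), function(v) {
        sim <- simulate_ping(ping_params(I_E = 0), stimulus = st,
                             seed = seed, variant = v)
        tfr <- tf_power(field_proxy(sim)$field, sim$fs_out,
                        freqs = seq(12, 100, 1))
        hc <- hysteresis_curves(tfr, st, band = c(12, 100))
        list(curves = hc, freq_area = hysteresis_area(hc, "freq"),
             power_area = hysteresis_area(hc, "power"))
      })
    },
    entrainment = {
      freqs <- c(5, 10, 20, 40, 80)
      dur <- duration %||% 2
      rows <- purrr::map(freqs, function(f) {
        st <- generate_stimulus("sinusoid", duration = dur, freq = f,
                                max = 1)
        sim <- simulate_ping(ping_params(I_E = 1), stimulus = st,
                             seed = seed)
        dens <- spike_density(mua_spikes(sim, 20, seed = seed + 1L),
                              sigma_ms = 1.25, fs_out = stim_fs(st),
                              t_range = c(0, dur))
        xc <- xcorr_modulation(dens$density, st$intensity,
                               max_lag = min(0.05, 0.6 / f),
                               fs = stim_fs(st))
        list(stim = st, dens = dens, depth = xc$modulation_depth,
             lag = xc$peak_lag)
      })
      lat <- phase_slope_latency(purrr::map(rows, "stim"),
                                 purrr::map(rows, ~ .x$dens$density),
                                 freqs)
      list(modulation = tibble(freq = freqs,
                               depth = purrr::map_dbl(rows, "depth"),
                               peak_lag = purrr::map_dbl(rows, "lag")),
           latency = lat)
    },
    whitenoise_gc = {
      dur <- duration %||% 40
      cfg <- run_config("ping",
                        stimulus = list(kind = "white_noise", mean = 0.75,
                                        duration = dur),
                        analyses = c("spectrum", "sta", "gc"), seed = seed)
      b <- run_protocol(cfg, out_dir = out_dir)
      list(peak = b$peak, sta = b$sta, gc = b$gc)
    },
    gated = {
      dur <- duration %||% 30
      wn1 <- generate_white_noise(0.4, duration = dur, seed = seed + 11L)
      wn2 <- generate_white_noise(0.8, duration = dur, seed = seed + 12L)
      res <- purrr::map(c(gate_on = 0.25, gate_off = 0),
        function(g2) {
          sim <- simulate_gated(ping_params(), 200, wn1, wn2, seed = seed,
                                g_IE2 = g2, I_E2 = 0)
          e2 <- sort(sim$raster$time_s[sim$raster$pool == "E2"])
          sta_wn <- spike_triggered_average(
            tibble(time_s = wn2$time_s, value = wn2$intensity), e2, 0.08)
          ri <- pop_rate(sim, "I")
          sta_i <- spike_triggered_average(
            tibble(time_s = ri$time_s, value = ri$rate), e2, 0.08)
          f0 <- spectral_peak(pop_rate(sim, "E1")$rate, sim$fs_out,
                              band = c(20, 120), transient = 0.5)$freq
          list(sta_wn = sta_wn, sta_inhib = sta_i, gamma_freq = f0,
               e2_rate = length(e2) / sum(sim$pools == "E2") / dur)
        })
      res
    })
  if (!is.null(out_dir) && figure_id != "whitenoise_gc") {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS_free <- function(x, f) {
      if (is.data.frame(x))
        utils::write.csv(as.data.frame(x), file.path(out_dir, f),
                         row.names = FALSE)
    }
    purrr::iwalk(out, function(x, nm) saveRDS_free(x, paste0(nm, ".csv")))
  }
  out
}
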