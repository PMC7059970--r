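#' Integration settings
#'
#' Fixed-step classical Runge-Kutta (RK4) integration at `dt` = 0.01 ms.
#' The first `t_transient` ms (default 1000) are flagged for exclusion from
#' spectral analysis but are simulated and recorded like the rest. Traces are
#' decimated by `record_stride` steps on output (default 10, i.e. sampled at
#' 10 kHz); spikes are detected at full step resolution.
#'
#' @param dt Step (ms). @param t_total Total simulated time (ms).
#' @param t_transient Initial window excluded from analysis (ms).
#' @param record_stride Output decimation factor (steps per recorded sample).
#' @param seed Master RNG seed (initial conditions + noise streams).
#' @return An object of class `integration_settings`.
#' @export
integration_settings <- function(dt = 0.01, t_total = 2000, t_transient = 1000,
                                 record_stride = 10L, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (t_transient >= t_total) stop("t_transient must be < t_total", call. = FALSE)
  structure(list(dt = dt, t_total = t_total, t_transient = t_transient,
                 record_stride = as.integer(record_stride), seed = as.integer(seed)),
            class = c("integration_settings", "striatr_params"))
}

#' Background-drive (noise) specification
#'
#' Each FSI dendrite receives an independent excitatory Poisson event train
#' (rate 100/s). The paper-level description fixes the rate but not the event
#' waveform; here each event injects a current pulse of amplitude
#' `fsi_poisson_amplitude` with either a single-step rectangular kernel
#' (`"step"`, the default) or a one-sided exponential kernel with 1 ms decay
#' (`"exp"`). The default amplitude (1200 uA/cm^2 for one 0.01 ms step, i.e.
#' 12 uA*ms/cm^2 of charge per event) was calibrated once so that the single
#' low-dopamine FSI (tonic drive 7 uA/cm^2) shows theta-range (4-7 Hz)
#' interburst frequencies under 100/s input; see the methods vignette.
#'
#' Each SPN receives additive Gaussian current noise with mean zero, unit
#' standard deviation and amplitude `4 * dt` per step, implemented literally
#' (`spn_scaling = "dt"`); a `"sqrt_dt"` switch is provided since the printed
#' scaling is dimensionally suspect.
#'
#' @param fsi_poisson_rate Events per second per FSI.
#' @param fsi_poisson_amplitude Event amplitude (uA/cm^2).
#' @param fsi_poisson_kernel `"exp"` (1 ms decay) or `"step"` (single step).
#' @param fsi_poisson_tau Decay of the exponential kernel (ms).
#' @param spn_gauss_amplitude Gaussian noise amplitude before time-step
#'   scaling.
#' @param spn_scaling `"dt"` (literal), `"sqrt_dt"`, or `"none"`.
#' @param on Master switch; `FALSE` gives noise-free dynamics.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fsi_poisson_rate = 100, fsi_poisson_amplitude = 1200,
                       fsi_poisson_kernel = c("step", "exp"),
                       fsi_poisson_tau = 1,
                       spn_gauss_amplitude = 4,
                       spn_scaling = c("dt", "sqrt_dt", "none"),
                       on = TRUE) {
  fsi_poisson_kernel <- match.arg(fsi_poisson_kernel)
  spn_scaling <- match.arg(spn_scaling)
  if (fsi_poisson_rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (spn_gauss_amplitude < 0) stop("noise amplitude must be >= 0", call. = FALSE)
  structure(list(fsi_poisson_rate = fsi_poisson_rate,
                 fsi_poisson_amplitude = fsi_poisson_amplitude,
                 fsi_poisson_kernel = fsi_poisson_kernel,
                 fsi_poisson_tau = fsi_poisson_tau,
                 spn_gauss_amplitude = spn_gauss_amplitude,
                 spn_scaling = spn_scaling, on = on),
            class = c("noise_spec", "striatr_params"))
}

spn_noise_sd <- function(noise, dt) {
  if (!noise$on) return(0)
  noise$spn_gauss_amplitude * switch(noise$spn_scaling,
                                     dt = dt, sqrt_dt = sqrt(dt), none = 1)
}

#' Classical RK4 step
#'
#' One fourth-order Runge-Kutta update of a generic state, used for
#' single-cell work and as the reference for the compiled network integrator.
#'
#' @param state Named list or numeric vector.
#' @param rhs Function `rhs(state)` returning the derivative in the same
#'   shape.
#' @param dt Step (ms).
#' @return Updated state, same shape as `state`.
#' @examples
#' rk4_step(1, function(y) -y, 0.01)  # ~ exp(-0.01)
#' @export
rk4_step <- function(state, rhs, dt) {
  is_list <- is.list(state)
  as_vec <- function(s) if (is_list) unlist(s) else s
  from_vec <- function(v) if (is_list) utils::relist(v, state) else v
  y <- as_vec(state)
  k1 <- as_vec(rhs(from_vec(y)))
  k2 <- as_vec(rhs(from_vec(y + dt / 2 * k1)))
  k3 <- as_vec(rhs(from_vec(y + dt / 2 * k2)))
  k4 <- as_vec(rhs(from_vec(y + dt * k3)))
  if (any(!is.finite(k1))) stop("non-finite derivative at state", call. = FALSE)
  from_vec(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

#' Poisson event-train current drive
#'
#' Samples a homogeneous Poisson event train binned to the integration step
#' and convolves it with the event kernel, giving a per-step current trace.
#' The mean injected charge per second is `rate * amplitude * kernel
#' integral`.
#'
#' @param rate Events per second.
#' @param amplitude Event amplitude (uA/cm^2).
#' @param kernel `"exp"` or `"step"`; `tau` is the exponential decay (ms).
#' @param dt Step (ms). @param t_total Duration (ms).
#' @param tau Exponential kernel decay (ms).
#' @return A tibble with columns `time` (ms), `current` (uA/cm^2), and
#'   attribute `n_events`.
#' @export
poisson_drive <- function(rate, amplitude = 1, kernel = c("exp", "step"),
                          dt = 0.01, t_total = 1000, tau = 1) {
  kernel <- match.arg(kernel)
  stopifnot(rate >= 0)
  n <- floor(t_total / dt)
  events <- stats::runif(n) < rate / 1000 * dt
  cur <- if (kernel == "step") {
    ifelse(events, amplitude, 0)
  } else {
    stats::filter(amplitude * events, exp(-dt / tau), method = "recursive") |>
      as.numeric()
  }
  out <- tibble::tibble(time = (seq_len(n)) * dt, current = cur)
  attr(out, "n_events") <- sum(events)
  out
}

resolve_syn <- function(condition, spec, syn = NULL) {
  if (is.null(syn)) {
    syn <- synapse_params(g_fsi_fsi = condition$g_fsi_fsi,
                          n_spn = max(spec$n_d1, spec$n_d2),
                          g_gj = condition$g_gj)
  }
  syn
}

engine_config <- function(spec, conn, condition, fsi, spn, syn,
                          fsi_I_app_cell = NULL, spn_I_app_cell = NULL,
                          fsi_g_L_cell = NULL, fsi_g_D_cell = NULL,
                          include_spn = TRUE, include_fsi = TRUE) {
  nf <- spec$n_fsi; n1 <- spec$n_d1; n2 <- spec$n_d2
  if (!include_fsi) {
    # an absent population is encoded by zeroing its drives and outgoing
    # conductances; sizes stay fixed so state layout is stable
    fsi_I_app_cell <- rep(-5, nf)  # held well below rheobase, silent
  }
  if (is.null(fsi_I_app_cell)) fsi_I_app_cell <- rep(condition$I_app_fsi, nf)
  if (is.null(spn_I_app_cell)) {
    spn_I_app_cell <- c(rep(condition$I_app_d1, n1), rep(condition$I_app_d2, n2))
  }
  if (is.null(fsi_g_L_cell)) fsi_g_L_cell <- rep(fsi$g_L, nf)
  if (is.null(fsi_g_D_cell)) fsi_g_D_cell <- rep(fsi$g_D, nf)
  list(
    n_fsi = nf, n_d1 = n1, n_d2 = n2,
    fsi = c(unclass(fsi), list(g_L_cell = fsi_g_L_cell, g_D_cell = fsi_g_D_cell,
                               I_app_cell = fsi_I_app_cell)),
    spn = c(unclass(spn), list(Qs = qs_factor(spn$Q10, spn$T_body, spn$T_ref),
                               I_app_cell = spn_I_app_cell)),
    syn = list(g_fsi_fsi = if (include_fsi) syn$g_fsi_fsi else 0,
               g_fsi_spn = if (include_fsi && include_spn) syn$g_fsi_spn else 0,
               g_spn_spn = if (include_spn) syn$g_spn_spn else 0,
               tau_i = syn$tau_i, tau_r = syn$tau_r, E_i = syn$E_i,
               g_gj = if (include_fsi) syn$g_gj else 0),
    conn = conn[c("gj", "fsi_inh", "fsi_d1", "fsi_d2", "d1_d1", "d2_d2")]
  )
}

initial_state <- function(cfg, v_range = c(-90, -50)) {
  nf <- cfg$n_fsi; ns <- cfg$n_d1 + cfg$n_d2
  v_fsi <- stats::runif(nf, v_range[1], v_range[2])
  v_spn <- stats::runif(ns, v_range[1], v_range[2])
  kf <- fsi_gating_rates(v_fsi)
  y <- c(v_fsi, kf$h_inf, kf$n_inf, kf$a_inf, kf$b_inf,   # soma
         v_fsi, kf$h_inf, kf$n_inf, kf$a_inf, kf$b_inf)   # dendrite
  ks <- spn_gating_rates(v_spn, cfg$spn$Qs)
  ss <- function(a, b) a / (a + b)
  y <- c(y, v_spn, ss(ks$alpha_m, ks$beta_m), ss(ks$alpha_h, ks$beta_h),
         ss(ks$alpha_n, ks$beta_n), ss(ks$alpha_w, ks$beta_w))
  c(y, rep(0, nf), rep(0, ns))  # synaptic gates closed
}

#' Simulate a striatal microcircuit
#'
#' Integrates the coupled FSI/SPN network with RK4 at fixed step, injecting
#' independent Poisson drive into FSI dendrites and Gaussian current noise
#' into SPNs, and detecting spikes online (upward crossings of `threshold`
#' with a refractory window). Identical `(configuration, seed)` pairs give
#' bitwise-identical results.
#'
#' @param spec A [network_spec()]. @param condition A [dopamine_condition()].
#' @param settings An [integration_settings()]. @param noise A [noise_spec()].
#' @param fsi,spn,syn Cell/synapse parameter objects; `syn = NULL` derives
#'   conductances from the condition and spec.
#' @param conn Optional pre-built [build_connectivity()] result (for exact
#'   re-runs from exported edge lists).
#' @param populations Which populations are active: `"combined"`,
#'   `"fsi_only"`, or `"spn_only"`. Inactive populations are silenced
#'   (no drive, zero outgoing conductances) rather than removed, so state
#'   shapes are stable.
#' @param fsi_I_app_cell,spn_I_app_cell,fsi_g_L_cell,fsi_g_D_cell Optional
#'   per-cell parameter vectors (heterogeneity, assembly protocols).
#' @param pulses Optional pulse protocol, see [pulse_protocol()].
#' @param threshold,refractory Spike detector settings (mV, ms).
#' @param record_gates Also record the full state (gates included) at every
#'   output sample; memory-heavy, meant for small networks.
#' @return An object of class `striatal_sim`: recorded time grid (ms),
#'   voltage matrices (`v_fsi_soma`, `v_fsi_dend`, `v_spn`), per-cell GABA-A
#'   current traces (`i_gaba`), gap-junction current traces (`i_gj`), a spike
#'   tibble, and the resolved configuration for provenance.
#' @examples
#' \donttest{
#' fx <- make_fixture("tiny")
#' sim <- simulate_network(fx$spec, fx$condition, fx$settings, fx$noise)
#' glance(sim)
#' }
#' @export
simulate_network <- function(spec = network_spec(),
                             condition = dopamine_condition("baseline"),
                             settings = integration_settings(),
                             noise = noise_spec(),
                             fsi = fsi_params(), spn = spn_params(),
                             syn = NULL, conn = NULL,
                             populations = c("combined", "fsi_only", "spn_only"),
                             fsi_I_app_cell = NULL, spn_I_app_cell = NULL,
                             fsi_g_L_cell = NULL, fsi_g_D_cell = NULL,
                             pulses = NULL,
                             threshold = 0, refractory = 2,
                             record_gates = FALSE) {
  populations <- match.arg(populations)
  if (is.null(conn)) conn <- build_connectivity(spec)
  check_conn_sizes(conn, spec)
  syn <- resolve_syn(condition, spec, syn)
  include_fsi <- populations != "spn_only"
  include_spn <- populations != "fsi_only"
  if (!include_spn && is.null(spn_I_app_cell)) {
    spn_I_app_cell <- rep(-5, spec$n_d1 + spec$n_d2)
  }
  cfg <- engine_config(spec, conn, condition, fsi, spn, syn,
                       fsi_I_app_cell, spn_I_app_cell, fsi_g_L_cell,
                       fsi_g_D_cell, include_spn, include_fsi)
  n_steps <- round(settings$t_total / settings$dt)
  pm <- if (is.null(pulses)) matrix(0, 0, 4) else as_pulse_matrix(pulses, spec)

  set.seed(settings$seed)
  y0 <- initial_state(cfg)
  raw <- engine_simulate(
    cfg, y0,
    list(dt = settings$dt, n_steps = as.integer(n_steps),
         record_stride = settings$record_stride, record_gates = record_gates),
    list(on = noise$on,
         fsi_poisson_rate = noise$fsi_poisson_rate / 1000,  # events per ms
         fsi_poisson_amplitude = noise$fsi_poisson_amplitude,
         fsi_poisson_kernel = if (noise$fsi_poisson_kernel == "exp") 1L else 0L,
         fsi_poisson_tau = noise$fsi_poisson_tau,
         spn_noise_sd = spn_noise_sd(noise, settings$dt)),
    pm,
    list(threshold = threshold, refractory = refractory))

  nf <- spec$n_fsi
  pop <- c(rep("fsi", nf), rep("d1", spec$n_d1), rep("d2", spec$n_d2))
  spikes <- tibble::tibble(
    cell = raw$spike_id,
    population = pop[raw$spike_id],
    time = raw$spike_time
  )
  structure(list(
    time = raw$time,
    v_fsi_soma = raw$v_fsi_soma, v_fsi_dend = raw$v_fsi_dend,
    v_spn = raw$v_spn, i_gaba = raw$i_gaba, i_gj = raw$i_gj,
    spikes = spikes,
    gate_range = c(raw$gate_min, raw$gate_max),
    final_state = raw$final_state,
    states = raw$states,
    spec = spec, condition = condition, settings = settings, noise = noise,
    fsi = fsi, spn = spn, syn = syn, conn = conn, populations = populations
  ), class = "striatal_sim")
}

check_conn_sizes <- function(conn, spec) {
  ok <- nrow(conn$gj) == spec$n_fsi && ncol(conn$fsi_d1) == spec$n_d1 &&
        ncol(conn$fsi_d2) == spec$n_d2 && nrow(conn$d1_d1) == spec$n_d1 &&
        nrow(conn$d2_d2) == spec$n_d2
  if (!ok) stop("connectivity matrices inconsistent with population sizes",
                call. = FALSE)
  invisible(TRUE)
}

#' Pulse protocol for assembly experiments
#'
#' Timed rectangular current pulses delivered to index ranges of a
#' population (SPN pulses enter the soma, FSI pulses the dendrite).
#'
#' @param population `"d1"`, `"d2"`, or `"fsi"`.
#' @param cells Integer vector of within-population 1-based indices.
#' @param onset Pulse start (ms). @param duration Pulse length (ms).
#' @param amplitude Pulse current (uA/cm^2).
#' @return A `pulse_protocol` tibble; several can be row-bound.
#' @export
pulse_protocol <- function(population, cells, onset, duration = 20,
                           amplitude = 4) {
  out <- tibble::tibble(population = population, cell = as.integer(cells),
                        onset = onset, duration = duration,
                        amplitude = amplitude)
  class(out) <- c("pulse_protocol", class(out))
  out
}

as_pulse_matrix <- function(pulses, spec) {
  offset <- c(fsi = 0L, d1 = spec$n_fsi, d2 = spec$n_fsi + spec$n_d1)
  limit <- c(fsi = spec$n_fsi, d1 = spec$n_d1, d2 = spec$n_d2)
  if (any(pulses$cell < 1) || any(pulses$cell > limit[pulses$population])) {
    stop("pulse cell indices outside population", call. = FALSE)
  }
  cbind(offset[pulses$population] + pulses$cell,
        pulses$onset, pulses$duration, pulses$amplitude)
}

#' Simulate a single isolated FSI
#'
#' Convenience wrapper running one two-compartment FSI with constant drive
#' (noise optional), used for rheobase sweeps and burst analyses.
#'
#' @param I_ext Tonic dendritic drive (uA/cm^2).
#' @param fsi An [fsi_params()] object.
#' @param settings An [integration_settings()].
#' @param noise A [noise_spec()]; default off.
#' @return A `striatal_sim` restricted to one FSI.
#' @export
simulate_fsi <- function(I_ext = 8, fsi = fsi_params(),
                         settings = integration_settings(),
                         noise = noise_spec(on = FALSE)) {
  spec <- network_spec(n_fsi = 1, n_d1 = 1, n_d2 = 1, p_fsi_gj = 0,
                       p_fsi_inh = 0, p_fsi_spn = 0, p_spn_spn = 0,
                       seed = settings$seed)
  simulate_network(spec, dopamine_condition("baseline", I_app_fsi = I_ext),
                   settings, noise, fsi = fsi, populations = "fsi_only")
}

#' Simulate an isolated SPN population
#'
#' Runs one all-to-all inhibitory SPN subnetwork (the D1 slot) with the given
#' applied current, without FSIs.
#'
#' @param n Number of SPNs. @param I_app Applied current (uA/cm^2).
#' @param settings,noise,spn Standard parameter objects.
#' @return A `striatal_sim`.
#' @export
simulate_spn_population <- function(n = 100, I_app = 1.19,
                                    settings = integration_settings(),
                                    noise = noise_spec(),
                                    spn = spn_params()) {
  spec <- network_spec(n_fsi = 1, n_d1 = n, n_d2 = 1, p_fsi_gj = 0,
                       p_fsi_inh = 0, p_fsi_spn = 0, seed = settings$seed)
  simulate_network(spec, dopamine_condition("baseline", I_app_d1 = I_app),
                   settings, noise, spn = spn, populations = "spn_only",
                   # the single placeholder D2 cell is held silent
                   spn_I_app_cell = c(rep(I_app, n), -5),
                   syn = synapse_params(n_spn = n, g_gj = 0))
}

#' Parameter sweep
#'
#' Runs [simulate_network()] over a grid of values for one parameter
#' (addressed by a path such as `"condition.I_app_fsi"`, `"fsi.g_D"`,
#' `"syn.g_gj"`, or `"noise.fsi_poisson_rate"`), with `n_repeats` seeds per
#' value, and returns a tidy long-format summary (one row per value x
#' repeat) produced by `summarise` applied to each simulation.
#'
#' @param values Numeric vector of parameter values.
#' @param parameter Dotted path into the configuration.
#' @param n_repeats Seeds per value.
#' @param summarise Function `f(sim)` returning a one-row data frame.
#' @param seed Base seed; run r at value v uses seed `seed + 1000 v_index + r`.
#' @param ... Passed on to [simulate_network()].
#' @param spec,condition,settings,noise,fsi,spn Base configuration.
#' @return A tibble with columns `parameter`, `value`, `rep`, `seed`, and
#'   the summary columns.
#' @export
run_sweep <- function(values, parameter,
                      spec = network_spec(),
                      condition = dopamine_condition("baseline"),
                      settings = integration_settings(),
                      noise = noise_spec(),
                      fsi = fsi_params(), spn = spn_params(),
                      n_repeats = 1, summarise = sweep_summary, seed = 1, ...) {
  if (!length(values)) {
    return(tibble::tibble(parameter = character(), value = numeric(),
                          rep = integer(), seed = integer()))
  }
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(path) != 2) stop("parameter path must be '<object>.<field>'", call. = FALSE)
  grid <- tidyr::expand_grid(vi = seq_along(values), rep = seq_len(n_repeats))
  purrr::pmap_dfr(grid, function(vi, rep) {
    v <- values[vi]
    cfgs <- list(spec = spec, condition = condition, settings = settings,
                 noise = noise, fsi = fsi, spn = spn)
    if (!path[1] %in% names(cfgs)) stop("unknown configuration object: ", path[1],
                                        call. = FALSE)
    if (!path[2] %in% names(cfgs[[path[1]]])) {
      stop("unknown field ", path[2], " in ", path[1], call. = FALSE)
    }
    cfgs[[path[1]]][[path[2]]] <- v
    cfgs$settings$seed <- as.integer(seed + 1000 * vi + rep)
    cfgs$spec$seed <- cfgs$settings$seed
    sim <- simulate_network(cfgs$spec, cfgs$condition, cfgs$settings,
                            cfgs$noise, fsi = cfgs$fsi, spn = cfgs$spn, ...)
    dplyr::bind_cols(tibble::tibble(parameter = parameter, value = v,
                                    rep = rep, seed = cfgs$settings$seed),
                     summarise(sim))
  })
}

#' Default sweep summary: firing and burst statistics per population
#' @param sim A `striatal_sim`.
#' @return One-row tibble with per-population firing rates and FSI burst
#'   statistics.
#' @export
sweep_summary <- function(sim) {
  dur_s <- (sim$settings$t_total - sim$settings$t_transient) / 1000
  post <- sim$spikes[sim$spikes$time >= sim$settings$t_transient, ]
  rate <- function(p, n) sum(post$population == p) / n / dur_s
  fsi_spk <- post$time[post$population == "fsi" & post$cell == 1]
  bs <- burst_stats(fsi_spk)
  tibble::tibble(
    rate_fsi = rate("fsi", sim$spec$n_fsi),
    rate_d1 = rate("d1", sim$spec$n_d1),
    rate_d2 = rate("d2", sim$spec$n_d2),
    intraburst_rate = bs$intraburst_rate,
    interburst_freq = bs$interburst_freq,
    n_bursts = bs$n_bursts
  )
}

#' @export
print.striatal_sim <- function(x, ...) {
  cat("<striatal_sim>", x$spec$n_fsi, "FSI /", x$spec$n_d1, "D1 /",
      x$spec$n_d2, "D2;", x$settings$t_total, "ms at dt =", x$settings$dt,
      "ms\n")
  cat("  condition:", x$condition$label, " populations:", x$populations,
      " spikes:", nrow(x$spikes), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation result
#'
#' @param x A `striatal_sim`.
#' @param what `"spikes"` (default), `"voltage"` (long per-cell traces,
#'   decimated by `every`), or `"lfp"` (surrogate LFP per population).
#' @param every Keep every `every`-th recorded sample for `"voltage"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy striatal_sim
#' @export
tidy.striatal_sim <- function(x, what = c("spikes", "voltage", "lfp"),
                              every = 10L, ...) {
  what <- match.arg(what)
  if (what == "spikes") return(x$spikes)
  if (what == "lfp") {
    return(tibble::tibble(
      time = x$time,
      fsi = surrogate_lfp(x, "fsi", trim = FALSE),
      spn = surrogate_lfp(x, "spn", trim = FALSE),
      all = surrogate_lfp(x, "all", trim = FALSE)))
  }
  keep <- seq(1, length(x$time), by = every)
  nf <- x$spec$n_fsi
  vf <- tibble::as_tibble(x$v_fsi_soma[keep, , drop = FALSE], .name_repair = "minimal")
  names(vf) <- paste0("fsi_", seq_len(nf))
  vs <- tibble::as_tibble(x$v_spn[keep, , drop = FALSE], .name_repair = "minimal")
  names(vs) <- c(paste0("d1_", seq_len(x$spec$n_d1)),
                 paste0("d2_", seq_len(x$spec$n_d2)))
  dplyr::bind_cols(tibble::tibble(time = x$time[keep]), vf, vs) |>
    tidyr::pivot_longer(-time, names_to = "cell", values_to = "voltage") |>
    tidyr::separate_wider_delim("cell", "_", names = c("population", "index"))
}

#' One-row summary of a simulation
#' @param x A `striatal_sim`. @param ... Unused.
#' @return Tibble with durations, cell counts, spike counts and mean rates
#'   (post-transient).
#' @method glance striatal_sim
#' @export
glance.striatal_sim <- function(x, ...) {
  post <- x$spikes[x$spikes$time >= x$settings$t_transient, ]
  dur_s <- (x$settings$t_total - x$settings$t_transient) / 1000
  tibble::tibble(
    t_total = x$settings$t_total, dt = x$settings$dt,
    n_fsi = x$spec$n_fsi, n_d1 = x$spec$n_d1, n_d2 = x$spec$n_d2,
    condition = x$condition$label,
    n_spikes = nrow(x$spikes),
    rate_fsi = sum(post$population == "fsi") / x$spec$n_fsi / dur_s,
    rate_d1 = sum(post$population == "d1") / x$spec$n_d1 / dur_s,
    rate_d2 = sum(post$population == "d2") / x$spec$n_d2 / dur_s
  )
}
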