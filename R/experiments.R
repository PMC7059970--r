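#' Fixture configurations
#'
#' Pinned-seed configurations at three problem sizes: `tiny` (5 FSI, 10+10
#' SPN, 500 ms) for unit tests, `small` (20 FSI, 40+40 SPN, 2 s) for
#' integration tests, and `paper` (50 FSI, 100+100 SPN, 4 s) for full
#' experiments.
#'
#' @param scale `"tiny"`, `"small"`, or `"paper"`.
#' @param condition_label `"baseline"` or `"high"`.
#' @param seed Overrides the pinned seed.
#' @return A list with elements `spec`, `condition`, `settings`, `noise`,
#'   `fsi`, `spn`.
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper"),
                         condition_label = "baseline", seed = NULL) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    tiny = list(n_fsi = 5, n_spn = 10, t_total = 500, t_transient = 200, seed = 101L),
    small = list(n_fsi = 20, n_spn = 40, t_total = 2000, t_transient = 500, seed = 202L),
    paper = list(n_fsi = 50, n_spn = 100, t_total = 4000, t_transient = 1000, seed = 303L))
  if (!is.null(seed)) dims$seed <- as.integer(seed)
  list(
    spec = network_spec(n_fsi = dims$n_fsi, n_d1 = dims$n_spn,
                        n_d2 = dims$n_spn, seed = dims$seed),
    condition = dopamine_condition(condition_label),
    settings = integration_settings(t_total = dims$t_total,
                                    t_transient = dims$t_transient,
                                    seed = dims$seed),
    noise = noise_spec(),
    fsi = fsi_params(), spn = spn_params()
  )
}

#' Run a population/condition experiment
#'
#' Simulates one of the canonical configurations (FSI network alone, SPN
#' populations alone, or the combined microcircuit) under a dopamine
#' condition and returns the standard analysis bundle: per-observable band
#' peaks, the surrogate LFPs and mean voltages, spike raster, and glance
#' summary.
#'
#' @param populations `"fsi_only"`, `"spn_only"`, or `"combined"`.
#' @param condition A [dopamine_condition()] or label.
#' @param scale Fixture scale passed to [make_fixture()].
#' @param seed Simulation seed.
#' @param settings Optional [integration_settings()] override.
#' @return A list of class `condition_experiment`: `sim`, `band_summary`
#'   (tibble: observable x band peaks), `lfp`, `summary`.
#' @export
run_condition_experiment <- function(populations = c("combined", "fsi_only", "spn_only"),
                                     condition = "baseline",
                                     scale = "paper", seed = 1L,
                                     settings = NULL) {
  populations <- match.arg(populations)
  if (is.character(condition)) condition <- dopamine_condition(condition)
  fx <- make_fixture(scale, condition$label, seed = seed)
  if (!is.null(settings)) fx$settings <- settings
  fx$settings$seed <- as.integer(seed)
  fx$spec$seed <- as.integer(seed)
  sim <- simulate_network(fx$spec, condition, fx$settings, fx$noise,
                          populations = populations)
  observables <- list()
  if (populations != "spn_only") {
    observables$lfp_fsi <- surrogate_lfp(sim, "fsi")
    observables$meanv_fsi <- mean_voltage(sim, "fsi")
  }
  if (populations != "fsi_only") {
    observables$meanv_d1 <- mean_voltage(sim, "d1")
    observables$meanv_d2 <- mean_voltage(sim, "d2")
    observables$lfp_spn <- surrogate_lfp(sim, "spn")
  }
  observables$lfp_all <- surrogate_lfp(sim, "all")
  band_summary <- purrr::imap_dfr(observables, function(x, nm) {
    dplyr::mutate(multitaper_psd(x)$peaks, observable = nm, .before = 1)
  })
  structure(list(sim = sim, band_summary = band_summary,
                 lfp = observables$lfp_all, summary = glance(sim)),
            class = "condition_experiment")
}

#' @export
print.condition_experiment <- function(x, ...) {
  cat("<condition_experiment>", x$sim$populations, "/",
      x$sim$condition$label, "\n")
  print(x$band_summary[, c("observable", "band", "peak_frequency", "peak_power")],
        n = 30)
  invisible(x)
}

#' Heterogeneity sweep
#'
#' Per-cell FSI parameters are drawn uniformly from
#' `[default (1 - h), default (1 + h)]`; `h = 0` reproduces the homogeneous
#' network and `h = 1` spans zero to twice the default. Band summaries of
#' the FSI network mean voltage are recorded per heterogeneity level.
#'
#' @param parameter `"g_L"`, `"g_D"`, or `"I_app"`.
#' @param h_values Heterogeneity levels in \[0,1\].
#' @param condition A [dopamine_condition()] or label.
#' @param scale Fixture scale. @param n_repeats Seeds per level.
#' @param seed Base seed.
#' @return A tibble: one row per (h, repeat, band) with peak frequency and
#'   power of the FSI mean-voltage spectrum.
#' @export
heterogeneity_sweep <- function(parameter = c("g_L", "g_D", "I_app"),
                                h_values = c(0, 0.1, 0.2),
                                condition = "high", scale = "small",
                                n_repeats = 1, seed = 1L) {
  parameter <- match.arg(parameter)
  if (any(h_values < 0 | h_values > 1)) stop("h must lie in [0,1]", call. = FALSE)
  if (is.character(condition)) condition <- dopamine_condition(condition)
  grid <- tidyr::expand_grid(h = h_values, rep = seq_len(n_repeats))
  purrr::pmap_dfr(grid, function(h, rep) {
    fx <- make_fixture(scale, condition$label)
    run_seed <- as.integer(seed + 7919 * rep)
    fx$settings$seed <- run_seed
    fx$spec$seed <- run_seed
    nf <- fx$spec$n_fsi
    default <- switch(parameter, g_L = fx$fsi$g_L, g_D = fx$fsi$g_D,
                      I_app = condition$I_app_fsi)
    set.seed(run_seed + 1L)
    vals <- stats::runif(nf, default * (1 - h), default * (1 + h))
    args <- list(spec = fx$spec, condition = condition, settings = fx$settings,
                 noise = fx$noise, populations = "fsi_only")
    if (parameter == "g_L") args$fsi_g_L_cell <- vals
    if (parameter == "g_D") args$fsi_g_D_cell <- vals
    if (parameter == "I_app") args$fsi_I_app_cell <- vals
    sim <- do.call(simulate_network, args)
    pk <- multitaper_psd(mean_voltage(sim, "fsi"))$peaks
    dplyr::mutate(pk, parameter = parameter, h = h, rep = rep,
                  seed = run_seed, .before = 1)
  })
}

#' Assembly pulse experiment
#'
#' Reproduces the cell-assembly protocol: in the combined high-dopamine
#' network, a 20 ms excitatory pulse drives D1 cells 50-100 ("assembly 1")
#' at 1680 ms and a second pulse drives D1 cells 25-75 ("assembly 2") at
#' 2080 ms. With FSIs present, delta/theta-periodic gamma inhibition
#' terminates assembly 1 before the second pulse; without FSIs, assembly 1's
#' beta-rhythmic firing persists. Coherence is summarised by pairwise
#' spike-time synchrony within each assembly over post-pulse windows.
#'
#' @param with_fsi Include the FSI network.
#' @param pulse_amplitude Pulse current (uA/cm^2).
#' @param onsets Pulse onset times (ms) for assemblies 1 and 2.
#' @param assembly1,assembly2 D1 cell index ranges.
#' @param scale Fixture scale. @param seed Simulation seed.
#' @param coherence_window Post-pulse synchrony window (ms).
#' @return A list: `sim`, and `summary` tibble with per-assembly synchrony
#'   in the window after each pulse plus late-window persistence of
#'   assembly 1.
#' @export
assembly_pulse_experiment <- function(with_fsi = TRUE, pulse_amplitude = 4,
                                      onsets = c(1680, 2080),
                                      assembly1 = 50:100, assembly2 = 25:75,
                                      scale = "paper", seed = 1L,
                                      coherence_window = 200) {
  fx <- make_fixture(scale, "high", seed = seed)
  if (max(assembly1, assembly2) > fx$spec$n_d1) {
    assembly1 <- intersect(assembly1, seq_len(fx$spec$n_d1))
    assembly2 <- intersect(assembly2, seq_len(fx$spec$n_d1))
  }
  if (any(onsets > fx$settings$t_total)) {
    stop("pulse onsets outside the simulation window", call. = FALSE)
  }
  pulses <- dplyr::bind_rows(
    pulse_protocol("d1", assembly1, onsets[1], amplitude = pulse_amplitude),
    pulse_protocol("d1", assembly2, onsets[2], amplitude = pulse_amplitude))
  sim <- simulate_network(fx$spec, dopamine_condition("high"), fx$settings,
                          fx$noise,
                          populations = if (with_fsi) "combined" else "spn_only",
                          pulses = pulses)
  gid <- function(cells) fx$spec$n_fsi + cells  # D1 global ids
  win <- function(t0) c(t0, t0 + coherence_window)
  late <- c(onsets[2] + coherence_window,
            min(fx$settings$t_total, onsets[2] + 3 * coherence_window))
  spikes_in <- function(cells, rng) {
    sum(sim$spikes$cell %in% gid(cells) & sim$spikes$time >= rng[1] &
          sim$spikes$time < rng[2])
  }
  summary <- tibble::tibble(
    with_fsi = with_fsi,
    sync_assembly1_post1 = spike_synchrony(sim$spikes, gid(assembly1),
                                           win(onsets[1])),
    sync_assembly2_post2 = spike_synchrony(sim$spikes, gid(assembly2),
                                           win(onsets[2])),
    assembly1_late_spikes = spikes_in(assembly1, late),
    assembly1_post1_spikes = spikes_in(assembly1, win(onsets[1])),
    assembly1_persists = spikes_in(assembly1, late) >
      0.25 * spikes_in(assembly1, win(onsets[1])) *
        diff(late) / coherence_window
  )
  list(sim = sim, summary = summary)
}
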