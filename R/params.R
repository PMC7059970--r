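#' Fast-spiking interneuron (FSI) parameters
#'
#' Builds the parameter set for the two-compartment striatal FSI model:
#' a soma and a dendrite, each carrying a transient sodium current, a fast
#' (delayed-rectifier) potassium current, a leak current, and a fast-activating
#' slowly-inactivating D-type potassium current. Dendritic maximal conductances
#' are all scaled by `dendrite_scale` relative to the soma, and the two
#' compartments are coupled by an ohmic conductance `g_compartment`.
#'
#' The D-current is the source of the cell's burst (stutter) dynamics: its slow
#' inactivation (`tau_b`, 150 ms) silences the cell between gamma-frequency
#' spike bursts and imposes a minimum firing rate near 40 Hz at the default
#' conductance.
#'
#' @param c_m Specific membrane capacitance (mF/cm^2).
#' @param g_Na,g_K,g_L,g_D Maximal conductances (mS/cm^2) of the sodium, fast
#'   potassium, leak, and D-type potassium currents (somatic values).
#' @param E_Na,E_K,E_L Reversal potentials (mV). The D-current reverses at
#'   `E_K`.
#' @param tau_a,tau_b D-current activation and inactivation time constants
#'   (ms).
#' @param dendrite_scale Factor applied to all dendritic conductances relative
#'   to the soma (unitless, in (0, 1]).
#' @param g_compartment Soma-dendrite coupling conductance (mS/cm^2).
#' @return An object of class `fsi_params` (a named list).
#' @examples
#' p <- fsi_params()
#' p$g_D
#' @export
fsi_params <- function(c_m = 1, g_Na = 112.5, g_K = 225, g_L = 0.25, g_D = 6,
                       E_Na = 50, E_K = -90, E_L = -70,
                       tau_a = 2, tau_b = 150,
                       dendrite_scale = 0.1, g_compartment = 0.5) {
  p <- list(c_m = c_m, g_Na = g_Na, g_K = g_K, g_L = g_L, g_D = g_D,
            E_Na = E_Na, E_K = E_K, E_L = E_L,
            tau_a = tau_a, tau_b = tau_b,
            dendrite_scale = dendrite_scale, g_compartment = g_compartment)
  validate_fsi_params(p)
  structure(p, class = c("fsi_params", "striatr_params"))
}

validate_fsi_params <- function(p) {
  conds <- unlist(p[c("c_m", "g_Na", "g_K", "g_L", "g_D", "g_compartment")])
  if (any(!is.finite(conds)) || any(conds < 0)) {
    stop("FSI conductances and capacitance must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(p$tau_a) || !is.finite(p$tau_b) || p$tau_a <= 0 || p$tau_b <= 0) {
    stop("tau_a and tau_b must be > 0", call. = FALSE)
  }
  if (p$dendrite_scale <= 0 || p$dendrite_scale > 1) {
    stop("dendrite_scale must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Spiny projection neuron (SPN) parameters
#'
#' Parameter set for the single-compartment striatal SPN model with a
#' transient sodium current, a delayed-rectifier potassium current, a leak
#' current, and a slow non-inactivating M-type potassium current. M-current
#' kinetics, originally characterised at `T_ref` = 23 degrees C, are scaled to
#' body temperature by the factor [qs_factor()].
#'
#' @param c_m Specific membrane capacitance (mF/cm^2).
#' @param g_Na,g_K,g_L,g_M Maximal conductances (mS/cm^2).
#' @param E_Na,E_K,E_L Reversal potentials (mV); the M-current reverses at
#'   `E_K`.
#' @param Q10 Temperature sensitivity of the M-current rate functions.
#' @param T_body,T_ref Simulation and reference temperatures (degrees C).
#' @return An object of class `spn_params`.
#' @examples
#' spn_params()$g_M
#' @export
spn_params <- function(c_m = 1, g_Na = 100, g_K = 80, g_L = 0.1, g_M = 1.25,
                       E_Na = 50, E_K = -100, E_L = -67,
                       Q10 = 2.3, T_body = 37, T_ref = 23) {
  p <- list(c_m = c_m, g_Na = g_Na, g_K = g_K, g_L = g_L, g_M = g_M,
            E_Na = E_Na, E_K = E_K, E_L = E_L,
            Q10 = Q10, T_body = T_body, T_ref = T_ref)
  conds <- unlist(p[c("c_m", "g_Na", "g_K", "g_L", "g_M")])
  if (any(!is.finite(conds)) || any(conds < 0)) {
    stop("SPN conductances and capacitance must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(Q10) || Q10 <= 1) stop("Q10 must be > 1", call. = FALSE)
  structure(p, class = c("spn_params", "striatr_params"))
}

#' Temperature scaling factor for M-current kinetics
#'
#' Q_s = Q10 ^ ((T_body - T_ref) / 10). With the defaults (Q10 = 2.3,
#' 37 vs 23 degrees C) this is 2.3^1.4 = 3.209.
#'
#' @param Q10 Temperature sensitivity (> 0).
#' @param T_body,T_ref Temperatures (degrees C).
#' @return A scalar multiplier applied to the M-current opening and closing
#'   rates.
#' @examples
#' qs_factor()        # 3.209
#' qs_factor(4, 33, 23)  # exactly 4
#' @export
qs_factor <- function(Q10 = 2.3, T_body = 37, T_ref = 23) {
  stopifnot(is.finite(Q10), Q10 > 0)
  Q10^((T_body - T_ref) / 10)
}

#' GABA-A synapse and gap-junction parameters
#'
#' Synaptic kinetics are shared across connection classes (decay `tau_i` =
#' 13 ms, reversal `E_i` = -80 mV); FSI-sourced synapses additionally use the
#' fast rise constant `tau_r` = 0.25 ms in their open-rate function. Maximal
#' conductances onto SPN targets are normalised by the size of the target SPN
#' subpopulation (0.6 / n for FSI->SPN, 0.1 / n for SPN->SPN), preserving the
#' ~6:1 strength ratio of feedforward to recurrent inhibition at any network
#' size. The FSI-FSI inhibitory conductance and the gap-junction conductance
#' are not normalised and depend on the dopamine condition.
#'
#' @param g_fsi_fsi FSI->FSI GABA-A maximal conductance (mS/cm^2).
#' @param g_fsi_spn_total,g_spn_spn_total Total conductance budgets divided by
#'   `n_spn` to give per-connection maxima.
#' @param n_spn Size of each target SPN subpopulation used for normalisation.
#' @param tau_i Decay time constant (ms). @param tau_r Rise time constant (ms).
#' @param E_i GABA-A reversal potential (mV).
#' @param g_gj Gap-junction (electrical) conductance between FSI dendrites
#'   (mS/cm^2).
#' @return An object of class `synapse_params` with resolved per-connection
#'   conductances `g_fsi_spn` and `g_spn_spn`.
#' @export
synapse_params <- function(g_fsi_fsi = 0.1,
                           g_fsi_spn_total = 0.6, g_spn_spn_total = 0.1,
                           n_spn = 100,
                           tau_i = 13, tau_r = 0.25, E_i = -80,
                           g_gj = 0.15) {
  if (tau_i <= tau_r || tau_r <= 0) stop("need tau_i > tau_r > 0", call. = FALSE)
  g <- c(g_fsi_fsi, g_fsi_spn_total, g_spn_spn_total, g_gj)
  if (any(!is.finite(g)) || any(g < 0)) stop("conductances must be >= 0", call. = FALSE)
  structure(list(g_fsi_fsi = g_fsi_fsi,
                 g_fsi_spn = g_fsi_spn_total / n_spn,
                 g_spn_spn = g_spn_spn_total / n_spn,
                 g_fsi_spn_total = g_fsi_spn_total,
                 g_spn_spn_total = g_spn_spn_total,
                 n_spn = n_spn,
                 tau_i = tau_i, tau_r = tau_r, E_i = E_i, g_gj = g_gj),
            class = c("synapse_params", "striatr_params"))
}

#' Dopamine condition parameter bundle
#'
#' Dopaminergic tone is modelled as a bundle of five parameter changes:
#' tonic FSI drive, gap-junction conductance, FSI-FSI inhibitory conductance,
#' and the tonic drives to D1 and D2 SPNs (dopamine being excitatory at D1
#' receptors and inhibitory at D2 receptors).
#'
#' | field       | baseline | high  |
#' |-------------|----------|-------|
#' | I_app_fsi   | 7        | 14    |
#' | g_gj        | 0.15     | 0.3   |
#' | g_fsi_fsi   | 0.1      | 0.005 |
#' | I_app_d1    | 1.19     | 1.29  |
#' | I_app_d2    | 1.19     | 1.09  |
#'
#' @param label `"baseline"` or `"high"`.
#' @param ... Named per-field overrides (e.g. `I_app_fsi = 8`).
#' @return An object of class `da_condition`.
#' @examples
#' dopamine_condition("high")$I_app_fsi  # 14
#' @export
dopamine_condition <- function(label = c("baseline", "high"), ...) {
  label <- match.arg(label)
  bundle <- switch(label,
    baseline = list(label = "baseline", I_app_fsi = 7, g_gj = 0.15,
                    g_fsi_fsi = 0.1, I_app_d1 = 1.19, I_app_d2 = 1.19),
    high     = list(label = "high", I_app_fsi = 14, g_gj = 0.3,
                    g_fsi_fsi = 0.005, I_app_d1 = 1.29, I_app_d2 = 1.09)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), setdiff(names(bundle), "label"))
    if (length(bad)) stop("unknown dopamine fields: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    bundle[names(dots)] <- dots
  }
  structure(bundle, class = c("da_condition", "striatr_params"))
}

#' @export
print.striatr_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- unlist(x)
  for (nm in names(flat)) cat(" ", nm, "=", flat[[nm]], "\n")
  invisible(x)
}

#' Write / read a parameter configuration
#'
#' Serialises a full simulation configuration (network spec, condition,
#' cell/synapse parameters, integration settings, noise spec) to a plain-text
#' hierarchical YAML file and back, so runs can be reproduced exactly.
#'
#' @param config A named list of parameter objects, e.g. as returned by
#'   [make_fixture()].
#' @param path File path.
#' @return `read_config()` returns the configuration list with classes
#'   restored; `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(x, strip) else x
  out <- lapply(config, function(x) {
    if (inherits(x, "striatr_params") || inherits(x, "network_spec") ||
        inherits(x, "integration_settings") || inherits(x, "noise_spec")) {
      c(list(.class = class(x)[1]), strip(unclass(x)))
    } else strip(x)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(x) {
    if (is.list(x) && !is.null(x$.class)) {
      cls <- x$.class
      x$.class <- NULL
      ctor <- switch(cls,
        fsi_params = fsi_params, spn_params = spn_params,
        synapse_params = NULL, da_condition = NULL,
        network_spec = NULL, integration_settings = NULL, noise_spec = NULL,
        NULL)
      if (cls == "da_condition") {
        lab <- x$label
        do.call(dopamine_condition, c(list(label = lab), x[setdiff(names(x), "label")]))
      } else if (cls == "network_spec") {
        do.call(network_spec, x)
      } else if (cls == "integration_settings") {
        do.call(integration_settings, x)
      } else if (cls == "noise_spec") {
        do.call(noise_spec, x)
      } else if (cls == "synapse_params") {
        do.call(synapse_params, x[c("g_fsi_fsi", "g_fsi_spn_total", "g_spn_spn_total",
                                    "n_spn", "tau_i", "tau_r", "E_i", "g_gj")])
      } else if (!is.null(ctor)) {
        do.call(ctor, x)
      } else x
    } else x
  }
  lapply(raw, rebuild)
}
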