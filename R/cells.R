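#' FSI gating steady states and time constants
#'
#' Voltage-dependent kinetics of the two-compartment FSI model. Sodium
#' activation is treated as instantaneous (`m = m_inf(V)`), following the
#' source single-cell model; sodium inactivation `h`, potassium activation
#' `n`, and the D-current activation `a` and inactivation `b` relax towards
#' their steady states with the returned time constants (`tau_a`, `tau_b` are
#' voltage-independent and live in [fsi_params()]).
#'
#' @param V Membrane voltage (mV); vectorised.
#' @return A tibble with columns `V`, `m_inf`, `h_inf`, `tau_h`, `n_inf`,
#'   `tau_n`, `a_inf`, `b_inf` (time constants in ms).
#' @examples
#' fsi_gating_rates(-24)$m_inf  # 0.5 by construction
#' @export
fsi_gating_rates <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  tibble::tibble(
    V = V,
    m_inf = 1 / (1 + exp(-(V + 24) / 11.5)),
    h_inf = 1 / (1 + exp((V + 58.3) / 6.7)),
    tau_h = 0.5 + 14 / (1 + exp((V + 60) / 12)),
    n_inf = 1 / (1 + exp(-(V + 12.4) / 6.8)),
    tau_n = (0.087 + 11.4 / (1 + exp((V + 14.6) / 8.6))) *
            (0.087 + 11.4 / (1 + exp(-(V - 1.3) / 18.7))),
    a_inf = 1 / (1 + exp(-(V + 50) / 20)),
    b_inf = 1 / (1 + exp((V + 70) / 6))
  )
}

# x / (1 - exp(-x / s)) with the removable singularity at x = 0 evaluated by
# its limit s; expm1 keeps the expression accurate near the singularity.
rate_linexp <- function(x, s) {
  out <- ifelse(abs(x) < 1e-6, s, x / -expm1(-x / s))
  out
}

#' SPN gating rate functions
#'
#' Opening (alpha) and closing (beta) rates for the SPN sodium activation
#' `m` and inactivation `h`, potassium activation `n`, and M-current
#' activation `w` gates. M-current rates are multiplied by the temperature
#' factor `Qs` (see [qs_factor()]). Removable singularities of the
#' linear-over-exponential forms (at V = -54, -52, -27 and -30 mV) are
#' evaluated by their analytic limits.
#'
#' @param V Membrane voltage (mV); vectorised.
#' @param Qs M-current temperature scaling factor (> 0).
#' @return A tibble with columns `V`, `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`, `alpha_w`, `beta_w` (rates in 1/ms).
#' @examples
#' spn_gating_rates(-54)$alpha_m  # 1.28, the analytic limit
#' @export
spn_gating_rates <- function(V, Qs = qs_factor()) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  stopifnot(Qs > 0)
  tibble::tibble(
    V = V,
    alpha_m = 0.32 * rate_linexp(V + 54, 4),
    beta_m  = 0.28 * rate_linexp(-(V + 27), 5),
    alpha_h = 0.128 * exp(-(V + 50) / 18),
    beta_h  = 4 / (1 + exp(-(V + 27) / 5)),
    alpha_n = 0.032 * rate_linexp(V + 52, 5),
    beta_n  = 0.5 * exp(-(V + 57) / 40),
    alpha_w = Qs * 1e-4 * rate_linexp(V + 30, 9),
    beta_w  = Qs * 1e-4 * rate_linexp(-(V + 30), 9)
  )
}

#' FSI single-cell right-hand side
#'
#' Derivative of the two-compartment FSI state. Somatic and dendritic
#' compartments each carry sodium, potassium, leak and D-currents (dendritic
#' maximal conductances scaled by `dendrite_scale`); they exchange the ohmic
#' coupling currents `I_ds = g_c (V_d - V_s)` into the soma and
#' `I_sd = g_c (V_s - V_d)` into the dendrite, which are equal and opposite.
#' Synaptic (GABA-A) inhibition enters the soma; external drive (tonic +
#' noise) and gap-junction current enter the dendrite.
#'
#' @param state Named list: `V_soma`, `V_dend`, and per-compartment gates
#'   `h_s`, `n_s`, `a_s`, `b_s`, `h_d`, `n_d`, `a_d`, `b_d` (all in \[0,1\]).
#' @param params An [fsi_params()] object.
#' @param I_syn_soma GABA-A current onto the soma (uA/cm^2, outward positive).
#' @param I_syn_dend Gap-junction current into the dendrite (uA/cm^2, inward
#'   positive).
#' @param I_ext External drive into the dendrite (uA/cm^2).
#' @return Named list of derivatives (same names as `state`).
#' @export
fsi_rhs <- function(state, params = fsi_params(),
                    I_syn_soma = 0, I_syn_dend = 0, I_ext = 0) {
  p <- params
  gates <- unlist(state[c("h_s", "n_s", "a_s", "b_s", "h_d", "n_d", "a_d", "b_d")])
  if (any(gates < 0) || any(gates > 1)) stop("gating variables outside [0,1]", call. = FALSE)

  comp <- function(V, h, n, a, b, scale, I_extra) {
    k <- fsi_gating_rates(V)
    I_Na <- scale * p$g_Na * k$m_inf^3 * h * (V - p$E_Na)
    I_K  <- scale * p$g_K * n^2 * (V - p$E_K)
    I_L  <- scale * p$g_L * (V - p$E_L)
    I_D  <- scale * p$g_D * a^3 * b * (V - p$E_K)
    list(dV = (-I_Na - I_K - I_L - I_D + I_extra) / p$c_m,
         dh = (k$h_inf - h) / k$tau_h,
         dn = (k$n_inf - n) / k$tau_n,
         da = (k$a_inf - a) / p$tau_a,
         db = (k$b_inf - b) / p$tau_b)
  }

  gc <- p$g_compartment
  I_ds <- gc * (state$V_dend - state$V_soma)  # into soma
  I_sd <- gc * (state$V_soma - state$V_dend)  # into dendrite
  s <- comp(state$V_soma, state$h_s, state$n_s, state$a_s, state$b_s,
            1, -I_syn_soma + I_ds)
  d <- comp(state$V_dend, state$h_d, state$n_d, state$a_d, state$b_d,
            p$dendrite_scale, I_ext + I_syn_dend + I_sd)
  list(V_soma = s$dV, V_dend = d$dV,
       h_s = s$dh, n_s = s$dn, a_s = s$da, b_s = s$db,
       h_d = d$dh, n_d = d$dn, a_d = d$da, b_d = d$db)
}

#' FSI state at gating steady state for a given voltage
#'
#' Convenience constructor: both compartments at voltage `V` with every gate
#' at its steady-state value, the standard initial condition.
#'
#' @param V Voltage (mV) applied to both compartments.
#' @return A named list usable as `state` in [fsi_rhs()].
#' @export
fsi_state_at <- function(V = -70) {
  k <- fsi_gating_rates(V)
  list(V_soma = V, V_dend = V,
       h_s = k$h_inf, n_s = k$n_inf, a_s = k$a_inf, b_s = k$b_inf,
       h_d = k$h_inf, n_d = k$n_inf, a_d = k$a_inf, b_d = k$b_inf)
}

#' SPN single-cell right-hand side
#'
#' Derivative of the single-compartment SPN state with sodium (m^3 h),
#' potassium (n^4), leak and M-type (w) currents; the M-current reverses at
#' `E_K` and its kinetics carry the Qs temperature factor.
#'
#' @param state Named list: `V`, `m`, `h`, `n`, `w` (gates in \[0,1\]).
#' @param params An [spn_params()] object.
#' @param I_syn GABA-A current (uA/cm^2, outward positive).
#' @param I_app Applied (background) current (uA/cm^2).
#' @return Named list of derivatives.
#' @export
spn_rhs <- function(state, params = spn_params(), I_syn = 0, I_app = 0) {
  p <- params
  gates <- unlist(state[c("m", "h", "n", "w")])
  if (any(gates < 0) || any(gates > 1)) stop("gating variables outside [0,1]", call. = FALSE)
  Qs <- qs_factor(p$Q10, p$T_body, p$T_ref)
  k <- spn_gating_rates(state$V, Qs)
  I_Na <- p$g_Na * state$m^3 * state$h * (state$V - p$E_Na)
  I_K  <- p$g_K * state$n^4 * (state$V - p$E_K)
  I_L  <- p$g_L * (state$V - p$E_L)
  I_M  <- p$g_M * state$w * (state$V - p$E_K)
  list(V = (-I_Na - I_K - I_L - I_M - I_syn + I_app) / p$c_m,
       m = k$alpha_m * (1 - state$m) - k$beta_m * state$m,
       h = k$alpha_h * (1 - state$h) - k$beta_h * state$h,
       n = k$alpha_n * (1 - state$n) - k$beta_n * state$n,
       w = k$alpha_w * (1 - state$w) - k$beta_w * state$w)
}

#' SPN state at gating steady state for a given voltage
#'
#' @param V Voltage (mV).
#' @param params An [spn_params()] object (sets the Qs factor).
#' @return A named list usable as `state` in [spn_rhs()].
#' @export
spn_state_at <- function(V = -70, params = spn_params()) {
  Qs <- qs_factor(params$Q10, params$T_body, params$T_ref)
  k <- spn_gating_rates(V, Qs)
  ss <- function(a, b) a / (a + b)
  list(V = V, m = ss(k$alpha_m, k$beta_m), h = ss(k$alpha_h, k$beta_h),
       n = ss(k$alpha_n, k$beta_n), w = ss(k$alpha_w, k$beta_w))
}
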