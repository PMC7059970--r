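# Shared small simulations, built once per test run and reused across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

tiny_sim <- function() {
  cached("tiny_sim", {
    fx <- make_fixture("tiny")
    simulate_network(fx$spec, fx$condition, fx$settings, fx$noise,
                     record_gates = TRUE)
  })
}

# noise-free bursting FSI, 2 s
fsi_burst_sim <- function() {
  cached("fsi_burst", simulate_fsi(
    8, settings = integration_settings(t_total = 4000, t_transient = 500,
                                       seed = 1)))
}

# R-side full-state derivative assembled from the package's pure-R cell and
# synapse right-hand sides, for cross-checking the compiled engine
r_reference_rhs <- function(y, cfg, fsi_drive, spn_drive) {
  nf <- cfg$n_fsi; ns <- cfg$n_d1 + cfg$n_d2
  syn <- cfg$syn
  sp <- synapse_params(g_fsi_fsi = syn$g_fsi_fsi, tau_i = syn$tau_i,
                       tau_r = syn$tau_r, E_i = syn$E_i, g_gj = syn$g_gj)
  unpack <- function(y) {
    list(vs = y[1:nf], hs = y[nf + 1:nf], ns_ = y[2 * nf + 1:nf],
         as = y[3 * nf + 1:nf], bs = y[4 * nf + 1:nf],
         vd = y[5 * nf + 1:nf], hd = y[6 * nf + 1:nf], nd = y[7 * nf + 1:nf],
         ad = y[8 * nf + 1:nf], bd = y[9 * nf + 1:nf],
         vspn = y[10 * nf + 1:ns], m = y[10 * nf + ns + 1:ns],
         h = y[10 * nf + 2 * ns + 1:ns], n = y[10 * nf + 3 * ns + 1:ns],
         w = y[10 * nf + 4 * ns + 1:ns],
         Sf = y[10 * nf + 5 * ns + 1:nf], Ss = y[10 * nf + 5 * ns + nf + 1:ns])
  }
  rhs <- function(y) {
    s <- unpack(y)
    fsi_p <- fsi_params()
    spn_p <- spn_params()
    dy <- numeric(length(y))
    gj_cur <- gap_junction_currents(s$vd, cfg$conn$gj, syn$g_gj)
    i_ff <- synaptic_current(s$Sf, cfg$conn$fsi_inh, syn$g_fsi_fsi, s$vs, syn$E_i)
    for (i in seq_len(nf)) {
      st <- list(V_soma = s$vs[i], V_dend = s$vd[i],
                 h_s = s$hs[i], n_s = s$ns_[i], a_s = s$as[i], b_s = s$bs[i],
                 h_d = s$hd[i], n_d = s$nd[i], a_d = s$ad[i], b_d = s$bd[i])
      d <- fsi_rhs(st, fsi_p, I_syn_soma = i_ff[i], I_syn_dend = gj_cur[i],
                   I_ext = fsi_drive[i])
      dy[i] <- d$V_soma; dy[nf + i] <- d$h_s; dy[2 * nf + i] <- d$n_s
      dy[3 * nf + i] <- d$a_s; dy[4 * nf + i] <- d$b_s
      dy[5 * nf + i] <- d$V_dend; dy[6 * nf + i] <- d$h_d
      dy[7 * nf + i] <- d$n_d; dy[8 * nf + i] <- d$a_d; dy[9 * nf + i] <- d$b_d
      dy[10 * nf + 5 * ns + i] <- gaba_gate_rhs(s$Sf[i], s$vs[i], "fsi-source", sp)
    }
    ad_fs <- rbind(cbind(cfg$conn$fsi_d1, cfg$conn$fsi_d2))
    i_fs <- synaptic_current(s$Sf, ad_fs, syn$g_fsi_spn, s$vspn, syn$E_i)
    n1 <- cfg$n_d1
    ss_adj <- matrix(0, ns, ns)
    ss_adj[1:n1, 1:n1] <- cfg$conn$d1_d1
    ss_adj[n1 + 1:cfg$n_d2, n1 + 1:cfg$n_d2] <- cfg$conn$d2_d2
    i_ss <- synaptic_current(s$Ss, ss_adj, syn$g_spn_spn, s$vspn, syn$E_i)
    for (j in seq_len(ns)) {
      st <- list(V = s$vspn[j], m = s$m[j], h = s$h[j], n = s$n[j], w = s$w[j])
      d <- spn_rhs(st, spn_p, I_syn = i_fs[j] + i_ss[j], I_app = spn_drive[j])
      dy[10 * nf + j] <- d$V; dy[10 * nf + ns + j] <- d$m
      dy[10 * nf + 2 * ns + j] <- d$h; dy[10 * nf + 3 * ns + j] <- d$n
      dy[10 * nf + 4 * ns + j] <- d$w
      dy[10 * nf + 5 * ns + nf + j] <- gaba_gate_rhs(s$Ss[j], s$vspn[j],
                                                     "spn-source", sp)
    }
    dy
  }
  rhs(y)
}

r_reference_step <- function(y, cfg, dt, fsi_drive, spn_drive) {
  rk4_step(y, function(yy) r_reference_rhs(yy, cfg, fsi_drive, spn_drive), dt)
}
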