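test_that("FSI gating steady states hit their half-activation voltages", {
  expect_equal(fsi_gating_rates(-24)$m_inf, 0.5)
  expect_equal(fsi_gating_rates(-58.3)$h_inf, 0.5)
  expect_equal(fsi_gating_rates(-60)$tau_h, 0.5 + 14 / 2)
  expect_equal(fsi_gating_rates(-50)$a_inf, 0.5)
  expect_equal(fsi_gating_rates(-70)$b_inf, 0.5)
  expect_error(fsi_gating_rates(NaN), "finite")
})

test_that("SPN rate functions evaluate their removable singularities by limits", {
  expect_equal(spn_gating_rates(-54)$alpha_m, 0.32 * 4)
  expect_equal(spn_gating_rates(-50)$alpha_h, 0.128)
  expect_equal(spn_gating_rates(-27)$beta_h, 2)
  expect_equal(spn_gating_rates(-52)$alpha_n, 0.032 * 5)
  qs <- qs_factor()
  expect_equal(spn_gating_rates(-30)$alpha_w, qs * 1e-4 * 9)
  expect_equal(spn_gating_rates(-30)$beta_w, qs * 1e-4 * 9)
  # continuity across the guard (limit vs value just off the singular point)
  for (v0 in c(-54, -52, -27, -30)) {
    lim <- spn_gating_rates(v0)
    near <- spn_gating_rates(v0 + 1e-5)
    expect_equal(unlist(near[-1]), unlist(lim[-1]), tolerance = 1e-4)
  }
})

test_that("temperature factor matches its closed form and limits", {
  expect_equal(qs_factor(2.3, 37, 23), 2.3^1.4)
  expect_equal(qs_factor(2.3, 37, 23), 3.209, tolerance = 1e-3)
  expect_equal(qs_factor(3.1, 25, 25), 1)
  expect_equal(qs_factor(4, 33, 23), 4)
  # Q10 = 1 leaves M-current rates unscaled
  r1 <- spn_gating_rates(-45, Qs = qs_factor(1 + 1e-12, 37, 23))
  r0 <- spn_gating_rates(-45, Qs = 1)
  expect_equal(r1$alpha_w, r0$alpha_w, tolerance = 1e-9)
})

test_that("FSI compartment coupling currents are equal and opposite", {
  st <- fsi_state_at(-70)
  st$V_soma <- -60; st$V_dend <- -75
  p <- fsi_params()
  gc <- p$g_compartment
  expect_equal(gc * (st$V_dend - st$V_soma), -gc * (st$V_soma - st$V_dend))
  # equal voltages: zero coupling flux, so soma and dendrite derivatives
  # differ only through the dendritic conductance scaling and drive
  st_eq <- fsi_state_at(-70)
  d <- fsi_rhs(st_eq, p)
  d_scaled <- fsi_rhs(st_eq, fsi_params(dendrite_scale = 1))
  expect_equal(d$V_soma, d_scaled$V_soma)
  expect_equal(d_scaled$V_dend, d_scaled$V_soma)  # identical compartments
})

test_that("cell right-hand sides vanish at numerically located fixed points", {
  # FSI: relax the noise-free subthreshold cell and confirm stationarity
  sim <- simulate_fsi(1, settings = integration_settings(
    t_total = 2000, t_transient = 100, seed = 3))
  expect_equal(nrow(sim$spikes), 0)
  nfin <- length(sim$time)
  vS <- sim$v_fsi_soma[nfin, 1]; vD <- sim$v_fsi_dend[nfin, 1]
  kS <- fsi_gating_rates(vS); kD <- fsi_gating_rates(vD)
  st <- list(V_soma = vS, V_dend = vD,
             h_s = kS$h_inf, n_s = kS$n_inf, a_s = kS$a_inf, b_s = kS$b_inf,
             h_d = kD$h_inf, n_d = kD$n_inf, a_d = kD$a_inf, b_d = kD$b_inf)
  d <- fsi_rhs(st, I_ext = 1)
  expect_lt(max(abs(unlist(d))), 0.01)

  # SPN fixed point at low drive
  simS <- simulate_spn_population(n = 1, I_app = 0.5, noise = noise_spec(on = FALSE),
                                  settings = integration_settings(
                                    t_total = 2000, t_transient = 100, seed = 3))
  v <- simS$v_spn[length(simS$time), 1]
  d2 <- spn_rhs(spn_state_at(v), I_app = 0.5)
  expect_lt(abs(d2$V), 0.05)
  expect_error(fsi_rhs(within(fsi_state_at(-70), h_s <- 1.5)), "\\[0,1\\]")
})

test_that("compiled engine matches the pure-R right-hand sides", {
  spec <- network_spec(n_fsi = 2, n_d1 = 2, n_d2 = 2, p_fsi_gj = 1,
                       p_fsi_inh = 1, p_fsi_spn = 1, seed = 5)
  conn <- build_connectivity(spec)
  cond <- dopamine_condition("baseline")
  syn <- synapse_params(g_fsi_fsi = cond$g_fsi_fsi, n_spn = 2, g_gj = cond$g_gj)
  cfg <- striatr:::engine_config(spec, conn, cond, fsi_params(), spn_params(), syn)
  set.seed(9)
  y <- striatr:::initial_state(cfg)
  # put gates mid-range so synapses carry current
  nf <- 2; ns <- 4
  y[(10 * nf + 5 * ns) + seq_len(nf + ns)] <- runif(nf + ns, 0.2, 0.8)
  fsi_drive <- c(7, 7); spn_drive <- rep(1.19, 4)
  dy_cpp <- striatr:::engine_rhs(cfg, y, fsi_drive, spn_drive)
  dy_ref <- r_reference_rhs(y, cfg, fsi_drive, spn_drive)
  expect_equal(dy_cpp, dy_ref, tolerance = 1e-10)
})
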