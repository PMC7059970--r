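test_that("rk4_step reproduces the linear test equation to fifth order", {
  y1 <- rk4_step(1, function(y) -y, 0.01)
  expect_equal(y1, exp(-0.01), tolerance = 1e-12)
  err <- abs(rk4_step(1, function(y) -y, 0.1) - exp(-0.1))
  expect_lt(err, 0.1^5)
  expect_equal(rk4_step(c(a = 2, b = -1), function(y) y * 0, 0.5),
               c(a = 2, b = -1))
  st <- list(u = 1, v = 0)
  out <- rk4_step(st, function(s) list(u = s$v, v = -s$u), 0.01)
  expect_equal(out$u, cos(0.01), tolerance = 1e-10)
})

test_that("integrator self-converges at fourth order on the noise-free FSI", {
  # subthreshold trajectory (smooth) from a perturbed initial condition
  run_dt <- function(dt) {
    sim <- simulate_fsi(4, settings = integration_settings(
      dt = dt, t_total = 100, t_transient = 50, record_stride = round(0.4 / dt),
      seed = 2))
    sim$v_fsi_soma[, 1]
  }
  ref <- run_dt(0.0025)
  dts <- c(0.08, 0.04, 0.02, 0.01)
  errs <- vapply(dts, function(dt) max(abs(run_dt(dt) - ref)), numeric(1))
  slope <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(slope, 3.5)
  expect_lt(slope, 4.5)
  # halving dt from the default changes the trace by well under 1e-3 mV
  expect_lt(max(abs(run_dt(0.01) - run_dt(0.005))), 1e-3)
})

test_that("poisson drive has the right mass and degenerate limits", {
  set.seed(1)
  z <- poisson_drive(0, t_total = 500)
  expect_true(all(z$current == 0))
  tr <- poisson_drive(500, amplitude = 2, kernel = "step", dt = 0.01,
                      t_total = 10000)
  expect_lt(abs(attr(tr, "n_events") - 5000), 4 * sqrt(5000))
  # mean charge per second = rate * amplitude * kernel integral
  reps <- replicate(50, {
    x <- poisson_drive(200, amplitude = 3, kernel = "exp", dt = 0.05,
                       t_total = 1000, tau = 1)
    sum(x$current) * 0.05 / 1  # charge over 1 s
  })
  expect_equal(mean(reps), 200 * 3 * 1 / 1000 * 1000, tolerance = 0.05)
})

test_that("simulation is bitwise deterministic given config and seed", {
  fx <- make_fixture("tiny")
  a <- simulate_network(fx$spec, fx$condition, fx$settings, fx$noise)
  b <- simulate_network(fx$spec, fx$condition, fx$settings, fx$noise)
  expect_identical(a$v_fsi_soma, b$v_fsi_soma)
  expect_identical(a$v_spn, b$v_spn)
  expect_identical(a$spikes, b$spikes)
  fx2 <- make_fixture("tiny", seed = 999)
  c2 <- simulate_network(fx2$spec, fx2$condition, fx2$settings, fx2$noise)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("with all conductances off, voltage integrates the applied current", {
  spec <- network_spec(n_fsi = 1, n_d1 = 1, n_d2 = 1, p_fsi_gj = 0,
                       p_fsi_inh = 0, p_fsi_spn = 0, p_spn_spn = 0, seed = 1)
  spn0 <- spn_params(g_Na = 0, g_K = 0, g_L = 0, g_M = 0)
  sim <- simulate_network(spec, dopamine_condition("baseline", I_app_d1 = 0.5),
                          integration_settings(t_total = 200, t_transient = 100,
                                               seed = 1),
                          noise_spec(on = FALSE), spn = spn0,
                          populations = "spn_only",
                          spn_I_app_cell = c(0.5, 0))
  v <- sim$v_spn[, 1]
  # dV/dt = I_app / c_m = 0.5 mV/ms exactly
  slope <- coef(lm(v ~ sim$time))[2]
  expect_equal(unname(slope), 0.5, tolerance = 1e-8)
})

test_that("gates stay inside [0,1] along full network trajectories", {
  sim <- tiny_sim()
  expect_gte(sim$gate_range[1], 0)
  expect_lte(sim$gate_range[2], 1)
  # recorded gate trajectories (record_gates = TRUE for the tiny fixture)
  nf <- sim$spec$n_fsi; ns <- sim$spec$n_d1 + sim$spec$n_d2
  gate_cols <- c(nf + seq_len(4 * nf), 6 * nf + seq_len(4 * nf),
                 10 * nf + ns + seq_len(4 * ns),
                 10 * nf + 5 * ns + seq_len(nf + ns))
  gates <- sim$states[, gate_cols]
  expect_gte(min(gates), 0)
  expect_lte(max(gates), 1)
})

test_that("spike tables are consistent: sorted, refractory, per population", {
  sim <- tiny_sim()
  by_cell <- split(sim$spikes$time, sim$spikes$cell)
  for (tt in by_cell) {
    expect_false(is.unsorted(tt, strictly = TRUE))
    if (length(tt) > 1) expect_gte(min(diff(tt)), 2)
  }
  expect_true(all(sim$spikes$population %in% c("fsi", "d1", "d2")))
})

test_that("gap-junction current traces sum to zero across the network", {
  sim <- tiny_sim()
  net_sum <- rowSums(sim$i_gj)
  expect_lt(max(abs(net_sum)), 1e-9)
})

test_that("parameter sweeps resolve paths, repeat deterministically, handle empties", {
  expect_equal(nrow(run_sweep(numeric(), "condition.I_app_fsi")), 0)
  fx <- make_fixture("tiny")
  sw <- run_sweep(c(0, 6), "fsi.g_D",
                  spec = fx$spec, settings = fx$settings,
                  noise = noise_spec(on = FALSE),
                  condition = dopamine_condition("baseline", I_app_fsi = 8),
                  populations = "fsi_only", n_repeats = 2, seed = 5)
  expect_equal(nrow(sw), 4)
  expect_true(all(c("parameter", "value", "rate_fsi", "intraburst_rate") %in%
                    names(sw)))
  sw2 <- run_sweep(c(0, 6), "fsi.g_D",
                   spec = fx$spec, settings = fx$settings,
                   noise = noise_spec(on = FALSE),
                   condition = dopamine_condition("baseline", I_app_fsi = 8),
                   populations = "fsi_only", n_repeats = 2, seed = 5)
  expect_identical(sw, sw2)
  expect_error(run_sweep(1, "nonexistent.path", spec = fx$spec), "unknown")
})

test_that("pulse protocols inject current where and when specified", {
  spec <- network_spec(n_fsi = 1, n_d1 = 2, n_d2 = 1, p_fsi_gj = 0,
                       p_fsi_inh = 0, p_fsi_spn = 0, p_spn_spn = 0, seed = 4)
  pp <- pulse_protocol("d1", 1, onset = 100, duration = 20, amplitude = 0.3)
  sim <- simulate_network(spec, dopamine_condition("baseline"),
                          integration_settings(t_total = 300, t_transient = 50,
                                               seed = 4),
                          noise_spec(on = FALSE), populations = "spn_only",
                          spn_I_app_cell = c(0.5, 0.5, 0.5), pulses = pp)
  # pulsed cell depolarizes relative to the unpulsed one during the pulse
  during <- sim$time >= 110 & sim$time < 120
  late <- sim$time >= 250
  gap_during <- mean(sim$v_spn[during, 1] - sim$v_spn[during, 2])
  expect_gt(gap_during, 0.5)
  # after the pulse the cells relax back together
  expect_lt(abs(mean(sim$v_spn[late, 1] - sim$v_spn[late, 2])),
            0.2 * gap_during)
  expect_error(as_pulse_matrix <- striatr:::as_pulse_matrix(
    pulse_protocol("d1", 5, 100), spec), "outside")
})
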