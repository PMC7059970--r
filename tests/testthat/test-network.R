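test_that("connectivity respects degenerate probabilities and symmetry", {
  empty <- build_connectivity(network_spec(n_fsi = 6, n_d1 = 4, n_d2 = 4,
                                           p_fsi_gj = 0, p_fsi_inh = 0,
                                           p_fsi_spn = 0, p_spn_spn = 0))
  expect_equal(sum(empty$gj) + sum(empty$fsi_inh) + sum(empty$fsi_d1) +
                 sum(empty$fsi_d2) + sum(empty$d1_d1) + sum(empty$d2_d2), 0)

  full <- build_connectivity(network_spec(n_fsi = 3, n_d1 = 3, n_d2 = 3,
                                          p_fsi_gj = 1, p_fsi_inh = 1,
                                          p_fsi_spn = 1))
  ones_off_diag <- matrix(1L, 3, 3) - diag(1L, 3)
  expect_equal(unname(full$gj), ones_off_diag)
  expect_equal(unname(full$d1_d1), ones_off_diag)  # all-to-all, no autapses
  expect_true(all(full$fsi_d1 == 1))

  cm <- build_connectivity(network_spec(seed = 42))
  expect_true(isSymmetric(unname(cm$gj)))
  expect_true(all(diag(cm$gj) == 0) && all(diag(cm$fsi_inh) == 0))
  expect_error(network_spec(p_fsi_gj = 1.2), "probabilities")
})

test_that("connectivity is seed-reproducible and counts are binomial-plausible", {
  a <- build_connectivity(network_spec(seed = 7))
  b <- build_connectivity(network_spec(seed = 7))
  expect_identical(a$gj, b$gj)
  expect_identical(a$fsi_d1, b$fsi_d1)
  c2 <- build_connectivity(network_spec(seed = 8))
  expect_false(identical(a$gj, c2$gj))

  # realized counts within 4 binomial SDs of expectation (default spec)
  n_pairs <- 50 * 49 / 2
  expect_lt(abs(sum(a$gj) / 2 - n_pairs * 0.33), 4 * sqrt(n_pairs * 0.33 * 0.67))
  n_fs <- 50 * 100
  expect_lt(abs(sum(a$fsi_d1) - n_fs * 0.375), 4 * sqrt(n_fs * 0.375 * 0.625))
  # expected FSI in-degree per SPN under the defaults
  expect_equal(50 * 0.375, 18.75)
  expect_lt(abs(mean(colSums(a$fsi_d1)) - 18.75), 4 * sqrt(50 * 0.375 * 0.625 / 100))
})

test_that("GABA gate kinetics: silence decays, hyperpolarized sources do not open", {
  sp <- synapse_params()
  expect_lt(abs(gaba_gate_rhs(0, -80, "spn-source", sp)), 1e-8)
  expect_equal(gaba_gate_rhs(1, -80, "fsi-source", sp), -1 / sp$tau_i,
               tolerance = 1e-4)
  # open rates at characteristic voltages
  expect_equal(striatr:::gaba_open_rate(0, "spn-source"), 2)
  expect_equal(striatr:::gaba_open_rate(0, "fsi-source", sp), 1 / sp$tau_r)
  expect_error(gaba_gate_rhs(1.2, -60, "spn-source", sp), "\\[0,1\\]")
  # gates stay in [0,1]: rhs is positive at 0 and negative at 1 for any V
  for (V in seq(-90, 40, by = 10)) {
    expect_gte(gaba_gate_rhs(0, V, "fsi-source", sp), 0)
    expect_lte(gaba_gate_rhs(1, V, "spn-source", sp), 0)
  }
})

test_that("postsynaptic currents follow g * sum(S) * (V - E)", {
  adj <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  expect_equal(synaptic_current(c(0, 0), adj, 0.1, c(-60, -60, -60)),
               c(0, 0, 0))
  expect_equal(synaptic_current(c(0.5, 0.5), adj, 0.1, rep(-80, 3), E_i = -80),
               c(0, 0, 0))
  expect_equal(synaptic_current(0.5, matrix(1, 1, 1), 0.006, -60),
               0.006 * 0.5 * 20)
  expect_error(synaptic_current(c(0.5), adj, 0.1, rep(-60, 3)), "shape")
})

test_that("gap-junction currents are pairwise antisymmetric and conserve charge", {
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  cur <- gap_junction_currents(c(-60, -70), adj, 0.3)
  expect_equal(cur, c(-3, 3))
  expect_equal(sum(cur), 0)
  set.seed(1)
  n <- 20
  a <- matrix(rbinom(n * n, 1, 0.4), n, n); a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  v <- runif(n, -90, -40)
  expect_equal(sum(gap_junction_currents(v, a, 0.15)), 0, tolerance = 1e-12)
  expect_equal(gap_junction_currents(rep(-65, n), a, 0.15), rep(0, n))
  expect_error(gap_junction_currents(v, matrix(c(0, 1, 0, 0), 2, 2), 0.3),
               "symmetric")
})

test_that("dopamine conditions carry the full parameter bundles", {
  base <- dopamine_condition("baseline")
  high <- dopamine_condition("high")
  expect_equal(base[c("I_app_fsi", "g_gj", "g_fsi_fsi", "I_app_d1", "I_app_d2")],
               list(I_app_fsi = 7, g_gj = 0.15, g_fsi_fsi = 0.1,
                    I_app_d1 = 1.19, I_app_d2 = 1.19))
  expect_equal(high[c("I_app_fsi", "g_gj", "g_fsi_fsi", "I_app_d1", "I_app_d2")],
               list(I_app_fsi = 14, g_gj = 0.3, g_fsi_fsi = 0.005,
                    I_app_d1 = 1.29, I_app_d2 = 1.09))
  diffs <- names(which(mapply(function(a, b) !identical(a, b),
                              base[-1], high[-1])))
  expect_setequal(diffs, c("I_app_fsi", "g_gj", "g_fsi_fsi", "I_app_d1",
                           "I_app_d2"))
  expect_error(dopamine_condition("medium"))
  expect_equal(dopamine_condition("high", I_app_fsi = 10)$I_app_fsi, 10)
  expect_error(dopamine_condition("high", nonsense = 1), "unknown")
})

test_that("synapse conductance normalization preserves the 6:1 strength ratio", {
  for (n in c(10, 100, 250)) {
    sp <- synapse_params(n_spn = n)
    expect_equal(sp$g_fsi_spn / sp$g_spn_spn, 6)
    expect_equal(sp$g_fsi_spn, 0.6 / n)
  }
  expect_equal(synapse_params(n_spn = 100)$g_fsi_spn, 0.006)
  expect_equal(synapse_params(n_spn = 100)$g_spn_spn, 0.001)
  expect_error(synapse_params(tau_i = 0.1), "tau_i > tau_r")
})

test_that("edge lists round-trip connectivity exactly", {
  cm <- build_connectivity(network_spec(n_fsi = 8, n_d1 = 6, n_d2 = 6, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(cm, path)
  back <- read_edges(path)
  for (m in c("gj", "fsi_inh", "fsi_d1", "fsi_d2", "d1_d1", "d2_d2")) {
    expect_equal(unname(back[[m]]), unname(cm[[m]]), info = m)
  }
})

test_that("configuration files round-trip through YAML", {
  fx <- make_fixture("tiny")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(fx, path)
  back <- read_config(path)
  expect_equal(back$spec$n_fsi, fx$spec$n_fsi)
  expect_equal(back$condition$I_app_fsi, fx$condition$I_app_fsi)
  expect_equal(back$settings$dt, fx$settings$dt)
  expect_equal(back$noise$fsi_poisson_amplitude, fx$noise$fsi_poisson_amplitude)
  expect_equal(back$fsi$g_D, fx$fsi$g_D)
})
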