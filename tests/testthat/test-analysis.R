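test_that("spike detector finds threshold crossings and honours refractory", {
  t <- seq(0, 1000, by = 0.1)
  expect_length(detect_spikes(rep(-70, length(t)), t), 0)
  # template insertion: 40 Hz spikes
  v <- rep(-70, length(t))
  for (t0 in seq(10, 990, by = 25)) v[t >= t0 & t < t0 + 1] <- 30
  spk <- detect_spikes(v, t)
  expect_equal(length(spk) / 1, 40, tolerance = 0.05)
  expect_length(detect_spikes(v, t, threshold = 50), 0)
  expect_error(detect_spikes(v, cumsum(runif(length(t)))), "uniform")
  # refractory collapses doublets
  v2 <- rep(-70, 101); v2[c(20, 25)] <- 10  # 0.4 ms apart at dt 0.1
  expect_length(detect_spikes(v2, seq(0, 10, by = 0.1), refractory = 2), 1)
})

test_that("DPSS tapers are orthonormal and match a dense eigensolver oracle", {
  n <- 128; nw <- 4; k <- 7
  tp <- dpss(n, nw, k)
  expect_equal(crossprod(tp), diag(k), tolerance = 1e-8)
  # independent oracle: dense symmetric tridiagonal eigendecomposition
  W <- nw / n
  d <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  Tm <- diag(d)
  for (i in 1:(n - 1)) Tm[i, i + 1] <- Tm[i + 1, i] <- e[i]
  eg <- eigen(Tm, symmetric = TRUE)
  for (j in 1:k) {
    ref <- eg$vectors[, j]
    expect_equal(abs(sum(tp[, j] * ref)), 1, tolerance = 1e-7)
  }
})

test_that("multitaper PSD locates pure tones and is Parseval-consistent", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  x <- sin(2 * pi * 60 * t)
  ps <- multitaper_psd(x, fs = fs)
  pk <- ps$peaks
  expect_equal(pk$peak_frequency[pk$band == "gamma_wide"], 60,
               tolerance = 0.05)
  expect_true(all(ps$psd$power >= 0))
  expect_equal(sum(ps$psd$power) * ps$meta$df, var(x), tolerance = 0.05)

  set.seed(4)
  wn <- rnorm(3000)
  pw <- multitaper_psd(wn, fs = fs)
  expect_equal(sum(pw$psd$power) * pw$meta$df, var(wn), tolerance = 0.05)
  r <- pw$peaks$peak_power / pw$peaks$median_power
  expect_true(all(r < 5))  # flat spectrum: no band stands out strongly

  # band peaks always lie inside their bands
  expect_true(all(pk$peak_frequency >= pk$f_lo & pk$peak_frequency <= pk$f_hi,
                  na.rm = TRUE))
  expect_error(multitaper_psd(1:4, fs = 10), "short")
})

test_that("PSD of a regular spike train peaks at the firing rate", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  v <- rep(-70, length(t))
  v[seq(1, length(t), by = 20)] <- 30  # 50 Hz
  spk <- detect_spikes(v, t * 1000)
  rate <- length(spk) / 4
  ps <- multitaper_psd(v, fs = fs,
                       bands = band_definitions("fund", 30, 70))
  expect_equal(ps$peaks$peak_frequency, rate, tolerance = ps$meta$df * 1.5)
})

test_that("spectrogram tracks stationary and switching tones", {
  fs <- 500
  t1 <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t1)
  sg <- mt_spectrogram(x, fs = fs, window = 400, step = 200)
  ridge <- dplyr::summarise(dplyr::group_by(sg, time),
                            f = frequency[which.max(power)])
  expect_true(all(abs(ridge$f - 40) < 4))
  xs <- c(sin(2 * pi * 20 * t1), sin(2 * pi * 80 * t1))
  sg2 <- mt_spectrogram(xs, fs = fs, window = 400, step = 200)
  ridge2 <- dplyr::summarise(dplyr::group_by(sg2, time),
                             f = frequency[which.max(power)])
  expect_true(all(abs(ridge2$f[ridge2$time < 1800] - 20) < 5))
  expect_true(all(abs(ridge2$f[ridge2$time > 2400] - 80) < 8))
  expect_error(mt_spectrogram(x, fs = fs, window = 0), "positive")
})

test_that("burst statistics segment trains by the ISI threshold", {
  trip <- as.vector(outer(c(0, 10, 20), seq(0, 4500, by = 500), "+"))
  bs <- burst_stats(trip)
  expect_equal(bs$n_bursts, 10)
  expect_equal(bs$intraburst_rate, 100)
  expect_equal(bs$interburst_freq, 2)
  expect_equal(bs$mean_burst_spikes, 3)
  expect_false(bs$tonic)

  tonic <- burst_stats(seq(0, 1000, by = 20))
  expect_equal(tonic$n_bursts, 1)
  expect_true(tonic$tonic)
  expect_true(is.na(tonic$interburst_freq))

  empty <- burst_stats(numeric())
  expect_equal(empty$n_bursts, 0)
  expect_error(burst_stats(c(5, 1, 10)), "sorted")
  # intraburst rate >= interburst frequency whenever bursts exist
  expect_gte(bs$intraburst_rate, bs$interburst_freq)
})

test_that("surrogate LFP is linear in the cell selection and respects trimming", {
  sim <- tiny_sim()
  nf <- sim$spec$n_fsi
  l_fsi <- surrogate_lfp(sim, "fsi", trim = FALSE)
  l_spn <- surrogate_lfp(sim, "spn", trim = FALSE)
  l_all <- surrogate_lfp(sim, "all", trim = FALSE)
  expect_equal(as.numeric(l_all), as.numeric(l_fsi) + as.numeric(l_spn))
  sel <- surrogate_lfp(sim, c(1, 3), trim = FALSE)
  s1 <- surrogate_lfp(sim, 1, trim = FALSE)
  s3 <- surrogate_lfp(sim, 3, trim = FALSE)
  expect_equal(as.numeric(sel), as.numeric(s1) + as.numeric(s3))
  trimmed <- surrogate_lfp(sim, "all")
  expect_gte(min(attr(trimmed, "time")), sim$settings$t_transient)
  expect_error(surrogate_lfp(sim, integer()), "empty")
  # zero-conductance network: identically zero LFP
  spec0 <- network_spec(n_fsi = 2, n_d1 = 2, n_d2 = 2, p_fsi_gj = 0,
                        p_fsi_inh = 0, p_fsi_spn = 0, p_spn_spn = 0, seed = 2)
  sim0 <- simulate_network(spec0, dopamine_condition("baseline"),
                           integration_settings(t_total = 300,
                                                t_transient = 100, seed = 2),
                           noise_spec(on = FALSE))
  expect_equal(max(abs(surrogate_lfp(sim0, "all"))), 0)
})

test_that("wavelet band traces isolate in-band energy with stable envelopes", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  beta <- wavelet_band_trace(x, c(8, 30), fs = fs)
  core <- beta[beta$time > 0.5 & beta$time < 3.5, ]
  expect_lt(sd(core$envelope) / mean(core$envelope), 0.05)
  # amplitude approximately recovered
  expect_equal(mean(core$envelope), 1, tolerance = 0.25)
  gamma <- wavelet_band_trace(x, c(40, 100), fs = fs)
  gcore <- gamma[gamma$time > 0.5 & gamma$time < 3.5, ]
  expect_lt(mean(gcore$envelope), 0.05 * mean(core$envelope))
  expect_error(wavelet_band_trace(x, c(100, 400), fs = fs), "Nyquist")
})

test_that("phase modulation summarises envelope-phase coupling", {
  ph <- seq(-pi, pi, length.out = 2000)
  flat <- phase_modulation(ph, rep(1, 2000) + 0.001 * sin(7 * ph))
  expect_lt(flat$depth, 0.05)
  locked <- phase_modulation(ph, 1 + cos(ph))
  expect_equal(locked$preferred_phase, 0, tolerance = 0.02)
  expect_gt(locked$depth, 0.3)
  expect_error(phase_modulation(ph, rep(1, 2000)), "degenerate")
  expect_error(phase_modulation(ph, 1:5), "grid")
})

test_that("spike synchrony index separates coincident from independent trains", {
  sync <- tibble::tibble(cell = rep(1:4, each = 10),
                         time = rep(seq(100, 1000, by = 100), 4))
  expect_equal(spike_synchrony(sync, 1:4, c(0, 1100)), 1)
  set.seed(2)
  async <- tibble::tibble(cell = rep(1:4, each = 10),
                          time = as.vector(replicate(4, sort(runif(10, 0, 5000)))))
  expect_lt(spike_synchrony(async, 1:4, c(0, 5000), window = 2),
            0.5)
  expect_true(is.na(spike_synchrony(sync[sync$cell == 1, ], 1:4, c(0, 1100))))
})
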