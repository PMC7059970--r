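#' Frequency band definitions
#'
#' Default analysis bands: delta/theta 1-10 Hz (wide enough to cover the 2-6
#' Hz network rhythm and the <10 Hz robustness criterion), beta 8-30 Hz,
#' low gamma 40-60 Hz, high gamma 60-100 Hz, and a wide gamma band 40-100 Hz.
#'
#' @param name,f_lo,f_hi Vectors defining custom bands (Hz), `0 < f_lo <
#'   f_hi`.
#' @return A tibble with columns `band`, `f_lo`, `f_hi`.
#' @export
band_definitions <- function(name = NULL, f_lo = NULL, f_hi = NULL) {
  if (is.null(name)) {
    return(tibble::tibble(
      band = c("delta_theta", "beta", "low_gamma", "high_gamma", "gamma_wide"),
      f_lo = c(1, 8, 40, 60, 40),
      f_hi = c(10, 30, 60, 100, 100)))
  }
  if (any(f_lo <= 0) || any(f_hi <= f_lo)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  tibble::tibble(band = name, f_lo = f_lo, f_hi = f_hi)
}

#' Detect spikes by threshold crossing
#'
#' Upward crossings of `threshold` separated by at least `refractory` ms, on
#' a uniformly sampled voltage trace.
#'
#' @param voltage Voltage trace (mV). @param time Matching time grid (ms),
#'   uniformly spaced.
#' @param threshold Crossing level (mV). @param refractory Minimum separation
#'   (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(voltage, time, threshold = 0, refractory = 2) {
  dt <- diff(time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("time grid must be uniform", call. = FALSE)
  }
  up <- which(voltage[-1] >= threshold & voltage[-length(voltage)] < threshold) + 1
  if (!length(up)) return(numeric())
  times <- time[up]
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce refractory sequentially (diff-based pruning can chain)
  out <- times[1]
  for (tt in times[-1]) if (tt - out[length(out)] >= refractory) out <- c(out, tt)
  out
}

#' Surrogate local field potential
#'
#' The LFP proxy is the sum of synaptic currents over a set of cells: by
#' default the chemical (GABA-A) currents only; gap-junction currents can be
#' included with `include_gap_junctions = TRUE`.
#'
#' @param sim A `striatal_sim`.
#' @param population `"fsi"`, `"d1"`, `"d2"`, `"spn"` (both subtypes), or
#'   `"all"`; alternatively an integer vector of global cell indices.
#' @param trim Drop the transient window (default `TRUE`).
#' @param include_gap_junctions Add gap-junction currents for FSI dendrites.
#' @return Numeric LFP time series (uA/cm^2); attribute `fs` gives the
#'   sampling rate in Hz, `time` the matching time grid (ms).
#' @export
surrogate_lfp <- function(sim, population = "all", trim = TRUE,
                          include_gap_junctions = FALSE) {
  nf <- sim$spec$n_fsi; n1 <- sim$spec$n_d1; n2 <- sim$spec$n_d2
  idx <- if (is.numeric(population)) as.integer(population) else switch(
    population,
    fsi = seq_len(nf),
    d1 = nf + seq_len(n1),
    d2 = nf + n1 + seq_len(n2),
    spn = nf + seq_len(n1 + n2),
    all = seq_len(nf + n1 + n2),
    stop("unknown population selector: ", population, call. = FALSE))
  if (!length(idx)) stop("empty population selection", call. = FALSE)
  lfp <- rowSums(sim$i_gaba[, idx, drop = FALSE])
  if (include_gap_junctions) {
    gj_idx <- idx[idx <= nf]
    if (length(gj_idx)) lfp <- lfp + rowSums(sim$i_gj[, gj_idx, drop = FALSE])
  }
  tgrid <- sim$time
  if (trim) {
    keep <- tgrid >= sim$settings$t_transient
    lfp <- lfp[keep]; tgrid <- tgrid[keep]
  }
  fs <- 1000 / (sim$settings$dt * sim$settings$record_stride)
  structure(lfp, fs = fs, time = tgrid)
}

#' Population mean voltage
#'
#' Mean somatic voltage over a population, the observable used for SPN
#' network spectra and FSI-network parameter sweeps.
#'
#' @inheritParams surrogate_lfp
#' @return Numeric series with `fs` and `time` attributes.
#' @export
mean_voltage <- function(sim, population = "fsi", trim = TRUE) {
  v <- switch(population,
    fsi = rowMeans(sim$v_fsi_soma),
    d1 = rowMeans(sim$v_spn[, seq_len(sim$spec$n_d1), drop = FALSE]),
    d2 = rowMeans(sim$v_spn[, sim$spec$n_d1 + seq_len(sim$spec$n_d2), drop = FALSE]),
    spn = rowMeans(sim$v_spn),
    stop("unknown population selector: ", population, call. = FALSE))
  tgrid <- sim$time
  if (trim) {
    keep <- tgrid >= sim$settings$t_transient
    v <- v[keep]; tgrid <- tgrid[keep]
  }
  fs <- 1000 / (sim$settings$dt * sim$settings$record_stride)
  structure(v, fs = fs, time = tgrid)
}

#' Slepian (DPSS) tapers
#'
#' First `k` discrete prolate spheroidal sequences of length `n` at
#' time-bandwidth `nw`, unit-energy normalised, computed from the symmetric
#' tridiagonal formulation.
#'
#' @param n Series length. @param nw Time-bandwidth product. @param k Number
#'   of tapers (typically `2 nw - 1`).
#' @return An `n` x `k` matrix; columns are orthonormal.
#' @export
dpss <- function(n, nw = 4, k = 2 * nw - 1) {
  dpss_tapers(as.integer(n), nw, as.integer(k))
}

decimate_series <- function(x, fs, target_fs) {
  if (fs <= target_fs) return(list(x = x, fs = fs))
  by <- max(1L, floor(fs / target_fs))
  # moving-average anti-alias then subsample; adequate for narrowband
  # oscillatory traces well below the decimated Nyquist
  xf <- stats::filter(x, rep(1 / by, by), sides = 2)
  idx <- seq(ceiling(by / 2), length(x), by = by)
  xf <- xf[idx]
  ok <- !is.na(xf)
  list(x = as.numeric(xf[ok]), fs = fs / by)
}

#' Multitaper power spectral density
#'
#' Thomson multitaper PSD: the demeaned series is multiplied by each of `k`
#' orthonormal DPSS tapers, periodograms are averaged, and the one-sided
#' density is returned. Integrated over frequency it equals the series
#' variance (Parseval). Traces sampled faster than `max_fs` are decimated
#' first, since all rhythms of interest lie below 100 Hz.
#'
#' @param x Numeric series, or a series with an `fs` attribute as returned by
#'   [surrogate_lfp()] / [mean_voltage()].
#' @param fs Sampling rate (Hz); defaults to the `fs` attribute.
#' @param nw Time-bandwidth product. @param k Number of tapers.
#' @param bands Band definitions for peak extraction.
#' @param max_fs Decimation target (Hz).
#' @return An object of class `spectral_summary`: tibble `psd` (columns
#'   `frequency`, `power`), tibble `peaks` (per-band `peak_frequency`,
#'   `peak_power`, `band_power`, `median_power`), and metadata.
#' @examples
#' x <- sin(2 * pi * 60 * seq(0, 2, by = 1e-3))
#' multitaper_psd(x, fs = 1000)$peaks
#' @export
multitaper_psd <- function(x, fs = attr(x, "fs"), nw = 4, k = 7,
                           bands = band_definitions(), max_fs = 1000) {
  if (is.null(fs)) stop("sampling rate fs required", call. = FALSE)
  x <- as.numeric(x)
  dec <- decimate_series(x, fs, max_fs)
  x <- dec$x - mean(dec$x)
  fs <- dec$fs
  n <- length(x)
  if (n < 8) stop("series too short for spectral analysis", call. = FALSE)
  tapers <- dpss(n, nw, k)
  nfft <- n
  spec <- matrix(0, nfft, k)
  for (j in seq_len(k)) {
    spec[, j] <- Mod(stats::fft(tapers[, j] * x))^2
  }
  pwr <- rowMeans(spec) / fs  # two-sided density
  nyq <- floor(nfft / 2)
  freq <- (0:nyq) * fs / nfft
  one_sided <- pwr[1:(nyq + 1)]
  if (nfft %% 2 == 0) {
    one_sided[2:nyq] <- 2 * one_sided[2:nyq]
  } else {
    one_sided[2:(nyq + 1)] <- 2 * one_sided[2:(nyq + 1)]
  }
  psd <- tibble::tibble(frequency = freq, power = one_sided)
  peaks <- band_peaks(psd, bands)
  structure(list(psd = psd, peaks = peaks,
                 meta = list(nw = nw, k = k, fs = fs, n = n,
                             df = fs / nfft, variance = stats::var(x))),
            class = "spectral_summary")
}

#' Per-band peak extraction from a PSD table
#'
#' @param psd Tibble with `frequency`, `power`.
#' @param bands Band definitions ([band_definitions()]).
#' @return Tibble with one row per band: `peak_frequency` (argmax within the
#'   band), `peak_power`, `band_power` (integrated), `median_power`.
#' @export
band_peaks <- function(psd, bands = band_definitions()) {
  df <- diff(psd$frequency[1:2])
  purrr::pmap_dfr(bands, function(band, f_lo, f_hi) {
    sel <- psd$frequency >= f_lo & psd$frequency <= f_hi
    if (!any(sel)) {
      return(tibble::tibble(band = band, f_lo = f_lo, f_hi = f_hi,
                            peak_frequency = NA_real_, peak_power = NA_real_,
                            band_power = NA_real_, median_power = NA_real_))
    }
    p <- psd$power[sel]; f <- psd$frequency[sel]
    tibble::tibble(band = band, f_lo = f_lo, f_hi = f_hi,
                   peak_frequency = f[which.max(p)], peak_power = max(p),
                   band_power = sum(p) * df, median_power = stats::median(p))
  })
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> n =", x$meta$n, "fs =", x$meta$fs, "Hz, NW =",
      x$meta$nw, ",", x$meta$k, "tapers\n")
  print(x$peaks[, c("band", "peak_frequency", "peak_power")])
  invisible(x)
}

#' @rdname tidy.striatal_sim
#' @method tidy spectral_summary
#' @export
tidy.spectral_summary <- function(x, ...) x$peaks

#' @method glance spectral_summary
#' @export
glance.spectral_summary <- function(x, ...) {
  tibble::tibble(n = x$meta$n, fs = x$meta$fs, nw = x$meta$nw, k = x$meta$k,
                 df = x$meta$df, variance = x$meta$variance,
                 total_power = sum(x$psd$power) * x$meta$df)
}

#' Sliding-window multitaper spectrogram
#'
#' @param x Series with or without an `fs` attribute.
#' @param fs Sampling rate (Hz).
#' @param window Window length (ms). @param step Hop (ms).
#' @param nw,k Multitaper settings per window.
#' @param max_fs Decimation target (Hz).
#' @return A tibble with columns `time` (window centre, ms), `frequency`,
#'   `power`.
#' @export
mt_spectrogram <- function(x, fs = attr(x, "fs"), window = 500, step = 100,
                           nw = 3, k = 5, max_fs = 1000) {
  if (is.null(fs)) stop("sampling rate fs required", call. = FALSE)
  if (window <= 0 || step <= 0) stop("window and step must be positive", call. = FALSE)
  tgrid <- attr(x, "time")
  x <- as.numeric(x)
  dec <- decimate_series(x, fs, max_fs)
  x <- dec$x; fs <- dec$fs
  wlen <- round(window / 1000 * fs)
  if (wlen > length(x)) stop("window longer than series", call. = FALSE)
  hops <- seq(1, length(x) - wlen + 1, by = max(1, round(step / 1000 * fs)))
  t0 <- if (!is.null(tgrid)) tgrid[1] else 0
  purrr::map_dfr(hops, function(i) {
    seg <- x[i:(i + wlen - 1)]
    ps <- multitaper_psd(seg, fs = fs, nw = nw, k = k, max_fs = fs)
    tibble::tibble(time = t0 + (i - 1 + wlen / 2) / fs * 1000,
                   frequency = ps$psd$frequency, power = ps$psd$power)
  })
}

#' Burst statistics from a spike train
#'
#' Spikes separated by no more than `max_intraburst_isi` belong to one burst.
#' The intraburst rate is the reciprocal of the mean within-burst
#' inter-spike interval; the interburst frequency is the reciprocal of the
#' mean interval between burst onsets.
#'
#' @param spike_times Sorted spike times (ms).
#' @param max_intraburst_isi Segmentation threshold (ms); 25 ms separates
#'   gamma-rate intraburst intervals from delta/theta interburst gaps.
#' @param min_spikes Minimum spikes for a group to count as a burst.
#' @return A one-row tibble: `n_bursts`, `intraburst_rate` (Hz),
#'   `interburst_freq` (Hz), `mean_burst_spikes`, `tonic` (TRUE when the
#'   whole train collapses into a single "burst", leaving the interburst
#'   frequency undefined).
#' @examples
#' trip <- as.vector(outer(c(0, 10, 20), seq(0, 2000, by = 500), "+"))
#' burst_stats(trip)  # 100 Hz within bursts recurring at 2 Hz
#' @export
burst_stats <- function(spike_times, max_intraburst_isi = 25, min_spikes = 2) {
  empty <- tibble::tibble(n_bursts = 0L, intraburst_rate = NA_real_,
                          interburst_freq = NA_real_,
                          mean_burst_spikes = NA_real_, tonic = FALSE)
  if (length(spike_times) < min_spikes) return(empty)
  if (is.unsorted(spike_times)) stop("spike times must be sorted", call. = FALSE)
  isi <- diff(spike_times)
  grp <- cumsum(c(1, isi > max_intraburst_isi))
  sizes <- tabulate(grp)
  bursts <- which(sizes >= min_spikes)
  if (!length(bursts)) return(empty)
  intra_isi <- isi[isi <= max_intraburst_isi]
  onsets <- vapply(bursts, function(b) spike_times[match(b, grp)], numeric(1))
  tonic <- length(bursts) == 1 && sizes[bursts] == length(spike_times)
  tibble::tibble(
    n_bursts = length(bursts),
    intraburst_rate = if (length(intra_isi)) 1000 / mean(intra_isi) else NA_real_,
    interburst_freq = if (length(onsets) > 1) 1000 / mean(diff(onsets)) else NA_real_,
    mean_burst_spikes = mean(sizes[bursts]),
    tonic = tonic
  )
}

#' Minimum firing rate of the noise-free FSI
#'
#' Sweeps tonic drive upward over `I_grid` and reports the firing rate at the
#' smallest drive that elicits sustained spiking: for a burst-structured
#' train the intraburst rate, for tonic firing the mean rate. With the
#' default D-current conductance this minimum sits near 40 Hz; with the
#' D-current removed the rate grows continuously from zero.
#'
#' @param fsi An [fsi_params()] object.
#' @param I_grid Applied-current grid (uA/cm^2), spanning sub- to
#'   suprathreshold.
#' @param t_total,t_transient Simulation and discard windows (ms).
#' @param min_spikes Minimum post-transient spikes counting as sustained.
#' @param refine Bisect the drive between the last silent and first spiking
#'   grid values (12 iterations) and report the rate just above the refined
#'   rheobase. With the D-current present the rate barely moves (that is the
#'   minimum-rate phenomenon); without it the onset rate falls towards zero.
#' @return A list: `rate` (Hz), `rheobase` (first spiking drive), `stats`
#'   (the burst statistics at rheobase), `grid` (tibble of rate vs drive).
#' @export
minimum_firing_rate <- function(fsi = fsi_params(),
                                I_grid = seq(0, 15, by = 0.1),
                                t_total = 3000, t_transient = 500,
                                min_spikes = 3, refine = FALSE) {
  I_grid <- sort(I_grid)
  rows <- list()
  first <- NULL
  for (I in I_grid) {
    sim <- simulate_fsi(I, fsi = fsi,
                        settings = integration_settings(t_total = t_total,
                                                        t_transient = t_transient,
                                                        seed = 1L))
    spk <- sim$spikes$time[sim$spikes$population == "fsi"]
    spk <- spk[spk >= t_transient]
    sustained <- length(spk) >= min_spikes &&
      max(spk) > t_transient + 0.5 * (t_total - t_transient)
    bs <- burst_stats(spk)
    rate <- if (!sustained) NA_real_
            else if (!is.na(bs$intraburst_rate)) bs$intraburst_rate
            else length(spk) / ((t_total - t_transient) / 1000)
    rows[[length(rows) + 1]] <- tibble::tibble(I_app = I, rate = rate,
                                               n_spikes = length(spk),
                                               sustained = sustained)
    if (sustained && is.null(first)) {
      first <- list(rate = rate, rheobase = I, stats = bs)
      # continue a little beyond for the grid record, then stop scanning
    }
    if (!is.null(first) && I > first$rheobase + 1) break
  }
  if (is.null(first)) stop("no sustained spiking anywhere on the drive grid",
                           call. = FALSE)
  if (refine) {
    probe <- function(I) {
      sim <- simulate_fsi(I, fsi = fsi,
                          settings = integration_settings(t_total = t_total,
                                                          t_transient = t_transient,
                                                          seed = 1L))
      spk <- sim$spikes$time[sim$spikes$time >= t_transient]
      sustained <- length(spk) >= min_spikes &&
        max(spk) > t_transient + 0.5 * (t_total - t_transient)
      list(sustained = sustained, spikes = spk)
    }
    lo <- first$rheobase - 0.1
    hi <- first$rheobase
    for (i in seq_len(12)) {
      mid <- (lo + hi) / 2
      if (probe(mid)$sustained) hi <- mid else lo <- mid
    }
    res <- probe(hi)
    bs <- burst_stats(res$spikes)
    first$rheobase <- hi
    first$stats <- bs
    first$rate <- if (!is.na(bs$intraburst_rate)) bs$intraburst_rate
                  else length(res$spikes) / ((t_total - t_transient) / 1000)
  }
  c(first, list(grid = dplyr::bind_rows(rows)))
}

#' Morlet wavelet band trace
#'
#' Band-limited reconstruction of a series via the continuous wavelet
#' transform (analytic Morlet, omega0 = 6) over log-spaced scales covering
#' the band, with the standard reconstruction constants. Returns the
#' band-passed signal, its amplitude envelope, and its instantaneous phase.
#'
#' @param x Series (optionally with `fs` attribute). @param fs Sampling rate
#'   (Hz).
#' @param band Two-element numeric `c(f_lo, f_hi)` or a one-row band tibble.
#' @param n_scales Scales per band (log-spaced).
#' @param max_fs Decimation target (Hz).
#' @return A tibble: `time` (s, from 0), `filtered`, `envelope`, `phase`.
#' @export
wavelet_band_trace <- function(x, band, fs = attr(x, "fs"), n_scales = 16,
                               max_fs = 1000) {
  if (is.null(fs)) stop("sampling rate fs required", call. = FALSE)
  if (is.data.frame(band)) band <- c(band$f_lo[1], band$f_hi[1])
  if (band[2] >= fs / 2 && fs > 2 * band[2]) band[2] <- fs / 2
  x <- as.numeric(x)
  dec <- decimate_series(x, fs, max_fs)
  x <- dec$x - mean(dec$x); fs <- dec$fs
  if (band[2] >= fs / 2) stop("band extends beyond the Nyquist frequency", call. = FALSE)
  n <- length(x)
  omega0 <- 6
  dt <- 1 / fs
  # angular frequency grid of the FFT
  wk <- 2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / (n * dt)
  X <- stats::fft(x)
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = n_scales))
  scales <- 1 / (fourier_factor * freqs)
  dj <- if (n_scales > 1) diff(log2(1 / rev(scales)))[1] else 0.1
  acc <- complex(length.out = n, real = 0)
  for (s in scales) {
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-0.5 * (s * wk - omega0)^2) * (wk > 0)
    W <- stats::fft(X * psi_hat, inverse = TRUE) / n
    acc <- acc + W / sqrt(s)
  }
  # Torrence & Compo reconstruction for Morlet(6): C_delta = 0.776,
  # psi0(0) = pi^(-1/4)
  recon <- dj * sqrt(dt) / (0.776 * pi^(-0.25)) * acc
  tibble::tibble(time = (seq_len(n) - 1) / fs,
                 filtered = Re(recon),
                 envelope = Mod(recon),
                 phase = Arg(recon))
}

#' Phase-amplitude modulation summary
#'
#' Quantifies how the amplitude envelope of a fast rhythm is distributed over
#' the phase of a slow rhythm: the envelope-weighted mean resultant vector of
#' the slow phase. Depth 0 means the envelope is independent of phase;
#' depth near 1 means it is concentrated at the preferred phase.
#'
#' @param slow_phase Instantaneous phase of the slow band (radians), e.g.
#'   from [wavelet_band_trace()].
#' @param fast_envelope Amplitude envelope of the fast band, same grid.
#' @return A one-row tibble: `preferred_phase` (radians), `depth` in \[0,1\].
#' @export
phase_modulation <- function(slow_phase, fast_envelope) {
  if (length(slow_phase) != length(fast_envelope)) {
    stop("series must share a time grid", call. = FALSE)
  }
  if (stats::sd(fast_envelope) == 0) stop("degenerate (constant) envelope", call. = FALSE)
  w <- fast_envelope / sum(fast_envelope)
  z <- sum(w * exp(1i * slow_phase))
  tibble::tibble(preferred_phase = Arg(z), depth = Mod(z))
}

#' Pairwise spike-time synchrony index
#'
#' Mean over cell pairs of the fraction of spikes coincident within
#' `window` ms, computed on a restricted time interval; used to summarise
#' assembly coherence after a pulse.
#'
#' @param spikes Spike tibble (`cell`, `time`).
#' @param cells Cells to include (global ids).
#' @param t_range Two-element interval (ms).
#' @param window Coincidence window (ms).
#' @return Scalar synchrony in \[0,1\] (NA when fewer than two cells spike).
#' @export
spike_synchrony <- function(spikes, cells, t_range, window = 5) {
  sel <- spikes[spikes$cell %in% cells &
                  spikes$time >= t_range[1] & spikes$time < t_range[2], ]
  trains <- split(sel$time, factor(sel$cell, levels = cells))
  trains <- trains[lengths(trains) > 0]
  if (length(trains) < 2) return(NA_real_)
  pairs <- utils::combn(length(trains), 2)
  coinc <- apply(pairs, 2, function(p) {
    a <- trains[[p[1]]]; b <- trains[[p[2]]]
    hits <- sum(vapply(a, function(t) any(abs(b - t) <= window), logical(1)))
    hits / max(length(a), length(b))
  })
  mean(coinc)
}
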