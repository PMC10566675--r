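# WAV I/O, onset detection, coherent summation, spectra, peaks, maps

test_that("WAV files round-trip at every supported encoding", {
  set.seed(11)
  x <- matrix(stats::runif(2 * 4800, -0.9, 0.9), nrow = 2)
  for (bits in c(16L, 24L, 32L)) {
    path <- tempfile(fileext = ".wav")
    write_wav(x, 48000, path, bits = bits)
    back <- read_wav(path)
    expect_equal(back$rate, 48000)
    expect_equal(back$bits, bits)
    tol <- switch(as.character(bits), "16" = 2 / 32767, "24" = 2 / 8388607,
                  "32" = 1e-7)
    expect_lt(max(abs(back$samples - x)), tol)
    unlink(path)
  }
})

test_that("tap onsets are found within a millisecond of truth", {
  synth <- fx_mini_synth(seed = 5)
  rec <- synth$recordings[[1]]
  truth <- synth$truth$locations[[1]]$onsets
  got <- detect_taps(rec)
  expect_length(got, length(truth))
  expect_lt(max(abs(got - truth)), 48)   # 1 ms at 48 kHz
})

test_that("onset detection rejects pure noise and merges close impulses", {
  set.seed(2)
  noise <- tap_recording(matrix(rnorm(48000, sd = 1e-3), 1), 48000,
                         mics = data.frame(mic_id = 1, mic_direction = "a"))
  expect_error(detect_taps(noise), "no taps")
  # two impulses 5 ms apart with a 50 ms refractory: one onset
  x <- numeric(24000)
  x[c(4800, 4800 + 240)] <- 1
  rec <- tap_recording(matrix(x + rnorm(24000, sd = 1e-5), 1), 48000,
                       mics = data.frame(mic_id = 1, mic_direction = "a"))
  expect_length(detect_taps(rec, refractory_ms = 50), 1L)
})

test_that("coherent sum is linear and needs two onsets", {
  # N identical noiseless segments stack to N times one segment
  seg <- sin(2 * pi * 700 * (0:4799) / 48000) * exp(-(0:4799) / 2000)
  x <- numeric(48000 * 2)
  onsets <- c(1, 24001, 48001, 72001)
  for (o in onsets) x[o:(o + 4799)] <- x[o:(o + 4799)] + seg
  rec <- tap_recording(matrix(x, 1), 48000,
                       mics = data.frame(mic_id = 1, mic_direction = "a"))
  ens <- coherent_sum(rec, onsets, window_s = 0.1, align = FALSE)
  expect_equal(ens$n_taps, 4L)
  expect_lt(max(abs(ens$stacked[1, ] - 4 * seg)), 1e-9)
  expect_error(coherent_sum(rec, onsets[1]), "at least 2")
  expect_error(coherent_sum(rec, onsets, window_s = 2), "overlaps")
})

test_that("a common integer lag leaves the stacked spectrum unchanged", {
  synth <- fx_mini_synth(seed = 6)
  rec <- synth$recordings[[1]]
  onsets <- synth$truth$locations[[1]]$onsets
  ens0 <- coherent_sum(rec, onsets, window_s = 0.2)
  lag <- 37L
  ens1 <- coherent_sum(rec, onsets + lag, window_s = 0.2)
  p0 <- power_spectrum(ens0, norm_freq = 15000)
  p1 <- power_spectrum(ens1, norm_freq = 15000)
  # planted peaks sit in the same bins with nearly the same power
  band <- p0$freq > 300 & p0$freq < 4000
  i0 <- which(band)[which.max(p0$power[1, band])]
  i1 <- which(band)[which.max(p1$power[1, band])]
  expect_equal(i0, i1)
  expect_lt(abs(p1$power[1, i1] / p0$power[1, i0] - 1), 0.05)
})

test_that("power spectrum: Fourier pair, normalization, linearity", {
  t <- (0:23999) / 48000
  x <- matrix(sin(2 * pi * 1000 * t), 1)
  ps <- power_spectrum(x, rate = 48000, norm_freq = 15000, normalize = FALSE)
  expect_lt(abs(ps$freq[which.max(ps$power[1, ])] - 1000), ps$bin_width_hz)
  # normalization bin equals exactly 1 after division
  xn <- x + 0.01 * sin(2 * pi * 15000 * t)
  psn <- power_spectrum(xn, rate = 48000, norm_freq = 15000)
  expect_identical(psn$power[1, psn$norm_bin], 1)
  # scaling the waveform scales un-normalized power by a^2, normalized not at all
  ps3 <- power_spectrum(3 * xn, rate = 48000, norm_freq = 15000,
                        normalize = FALSE)
  ps1 <- power_spectrum(xn, rate = 48000, norm_freq = 15000,
                        normalize = FALSE)
  expect_rel(ps3$power[1, ps3$norm_bin], 9 * ps1$power[1, ps1$norm_bin], 1e-9)
  psn3 <- power_spectrum(3 * xn, rate = 48000, norm_freq = 15000)
  expect_equal(psn3$power, psn$power)
  # normalizing an already normalized spectrum changes nothing: dividing by
  # the (unit) normalization bin again is the identity
  expect_identical(psn$power / psn$power[, psn$norm_bin], psn$power)
  expect_error(power_spectrum(x, rate = 48000, norm_freq = 30000), "Nyquist")
})

test_that("planted damped modes appear as local maxima within a bin", {
  synth <- fx_mini_synth(seed = 9)
  rec <- synth$recordings[[1]]
  ens <- coherent_sum(rec, detect_taps(rec), window_s = 0.125)
  ps <- power_spectrum(ens)
  pk <- pick_peaks(average_spectra(list(ps), over = "microphones"),
                   band_hz = c(100, 6000), min_prominence = 6)
  for (f0 in c(500, 1200, 3000)) {
    err <- min(abs(pk$peaks$frequency_hz - f0))
    expect_lte(err, ps$bin_width_hz)
  }
})

test_that("average_spectra is an identity on one spectrum and a plain mean", {
  synth <- fx_mini_synth(seed = 10, mics = 2)
  rec <- synth$recordings[[1]]
  ps <- power_spectrum(coherent_sum(rec, detect_taps(rec), window_s = 0.2))
  one <- average_spectra(list(ps), over = "locations")
  expect_equal(one$power, ps$power)
  dup <- average_spectra(list(ps, ps), over = "locations")
  expect_equal(dup$power, ps$power)
  # brute-force bin-wise mean over perturbed copies
  ps2 <- ps; ps2$power <- ps$power * 2
  avg <- average_spectra(list(ps, ps2), over = "locations")
  expect_equal(avg$power, (ps$power + ps2$power) / 2)
  mics <- average_spectra(list(ps), over = "microphones")
  expect_equal(mics$power, matrix(colMeans(ps$power), 1))
  bad <- ps; bad$freq <- bad$freq * 1.001
  expect_error(average_spectra(list(ps, bad)), "different frequency grids")
})

test_that("peak picking: flat spectra, planted modes, merged pairs", {
  flat <- structure(list(freq = seq(0, 24000, by = 10),
                         power = matrix(1, 1, 2401), norm_freq = 15000,
                         norm_bin = 1501, bin_width_hz = 10, rate = 48000,
                         mics = NULL, tap_location_id = NA, n_averaged = 1),
                    class = "averaged_spectrum")
  expect_equal(nrow(pick_peaks(flat, c(100, 6000))$peaks), 0L)

  # planted modes at the measured low-mode frequencies of a real ear bone
  t <- (0:47999) / 48000
  x <- 0
  for (f0 in c(180, 270, 880)) x <- x + sin(2 * pi * f0 * t) * exp(-t * 40)
  x <- x + 0.05 * sin(2 * pi * 15000 * t)
  ps <- power_spectrum(matrix(x, 1), rate = 48000)
  pk <- pick_peaks(ps, band_hz = c(100, 6000), min_prominence = 6)
  expect_equal(nrow(pk$peaks), 3L)
  expect_true(all(abs(pk$peaks$frequency_hz - c(180, 270, 880)) <
                    ps$bin_width_hz))
  expect_false(any(pk$peaks$merged))

  # two undamped tones closer than two bin widths: one peak, flagged merged
  # (window an exact power of two so no zero-padding interpolation ripples)
  n <- 32768
  bw <- 48000 / n
  t2 <- (seq_len(n) - 1) / 48000
  y <- sin(2 * pi * 1000 * t2) + sin(2 * pi * (1000 + 1.8 * bw) * t2) +
    0.05 * sin(2 * pi * 15000 * t2)
  ps2 <- power_spectrum(matrix(y, 1), rate = 48000)
  pk2 <- pick_peaks(ps2, band_hz = c(800, 1200), min_prominence = 6)
  near <- pk2$peaks[abs(pk2$peaks$frequency_hz - 1000) < 6 * bw, ]
  expect_equal(nrow(near), 1L)
  expect_true(near$merged)
  expect_error(pick_peaks(ps2, band_hz = c(0, 1e6)), "band outside")
})

test_that("amplitude maps read the right bins and rank locations correctly", {
  synth <- fixture("map_synth", function() {
    freqs <- c(500, 1200)
    set.seed(31)
    w <- cbind(runif(12, 0.2, 2), runif(12, 0.2, 2))
    w[4, ] <- c(4, 4)                   # one clearly hottest location
    g <- matrix(runif(12 * 3, 0.5, 1), 12, 3)
    spec <- tap_synth_spec(freqs, zeta = 0.01, weights = w, mic_gains = g,
                           snr_db = 30, seed = 13)
    mics <- data.frame(mic_id = 1:3, mic_direction = c("a", "b", "c"))
    list(out = synth_tap_recordings(spec, mics = mics, write_wav = FALSE),
         w = w)
  })
  spectra <- lapply(synth$out$recordings, function(rec)
    power_spectrum(coherent_sum(rec, detect_taps(rec), window_s = 0.2)))
  # query at the normalization frequency: every entry is 1
  m15 <- amplitude_map(spectra, 15000)
  expect_true(all(abs(m15$values$amplitude - 1) < 1e-12))
  # the planted hottest location is maximal at the mode frequency
  m500 <- amplitude_map(spectra, 500)
  loc_amp <- apply(m500$matrix, 1, max)
  expect_equal(unname(which.max(loc_amp)), 4L)
  # rank correlation with planted weights
  expect_gt(cor(loc_amp, synth$w[, 1], method = "spearman"), 0.9)
  expect_error(amplitude_map(spectra, 1e6), "outside")
})

test_that("planted peaks recover within one bin in >= 95% of seeded runs", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    synth <- fx_mini_synth(seed = seed, n_modes = 2, snr_db = 20)
    rec <- synth$recordings[[1]]
    ens <- coherent_sum(rec, detect_taps(rec), window_s = 0.2)
    ps <- power_spectrum(ens)
    pk <- pick_peaks(average_spectra(list(ps), over = "microphones"),
                     band_hz = c(100, 6000), min_prominence = 6)
    for (f0 in c(500, 1200)) {
      total <- total + 1L
      if (min(abs(pk$peaks$frequency_hz - f0)) <= ps$bin_width_hz)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
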