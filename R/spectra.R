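## Tap-excitation spectral pipeline ------------------------------------------
##
## Raw multichannel recordings of repeated taps are segmented at detected
## onsets, time-aligned and coherently summed (raising the planted-peak
## power against incoherent noise by ~10 log10(N) dB), Fourier transformed,
## and normalized at a reference frequency where the structural modes no
## longer contribute (15 kHz by convention). Normalized spectra feed peak
## picking and per-location amplitude maps.

#' Construct a tap recording
#'
#' @param samples channels x time numeric matrix (arbitrary linear units).
#' @param rate sample rate in Hz.
#' @param mics data.frame with mic_id and mic_direction, one row per channel
#'   (see [default_microphones()]).
#' @param tap_location_id integer tap-location label (1-89 convention).
#' @return an object of class `tap_recording`.
#' @export
tap_recording <- function(samples, rate, mics = default_microphones(),
                          tap_location_id = NA_integer_) {
  samples <- as.matrix(samples)
  if (!is.numeric(rate) || rate <= 0) stop2("rate must be positive")
  if (nrow(samples) < 1L) stop2("recording needs at least one channel")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop2("recording contains non-finite samples")
  if (nrow(mics) != nrow(samples))
    stop2("mics table must have one row per channel")
  structure(list(samples = samples, rate = rate, mics = mics,
                 tap_location_id = as.integer(tap_location_id)),
            class = "tap_recording")
}

#' Read a tap recording from a WAV file
#'
#' @param path WAV file (8 channels, or combined per the manifest).
#' @param mics channel metadata (see [default_microphones()]).
#' @param tap_location_id tap-location label.
#' @return a [tap_recording()].
#' @export
read_tap_recording <- function(path, mics = default_microphones(),
                               tap_location_id = NA_integer_) {
  w <- read_wav(path)
  tap_recording(w$samples, w$rate, mics, tap_location_id)
}

#' Detect tap onsets
#'
#' The channel-summed absolute signal is smoothed with a 1 ms moving
#' average; onsets are the rising crossings of median + threshold_k * MAD,
#' merged within the refractory interval.
#'
#' @param rec a [tap_recording()].
#' @param threshold_k MAD multiplier (default 8).
#' @param refractory_ms merge interval in milliseconds (default 100).
#' @return integer vector of onset sample indices (strictly increasing).
#' @export
detect_taps <- function(rec, threshold_k = 8, refractory_ms = 100) {
  env <- colSums(abs(rec$samples))
  if (nrow(rec$samples) == 1L) env <- abs(rec$samples[1, ])
  wlen <- max(1L, round(rec$rate / 1000))
  kern <- rep(1 / wlen, wlen)
  env <- as.numeric(stats::filter(env, kern, sides = 1))
  env[is.na(env)] <- 0
  med <- stats::median(env)
  madv <- stats::mad(env)
  thr <- med + threshold_k * madv
  thr_low <- med + 0.5 * threshold_k * madv
  above <- env > thr
  rising <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(rising)) stop2("no taps detected above threshold")
  refr <- round(refractory_ms / 1000 * rec$rate)
  # hysteresis: a new onset requires a genuinely quiet stretch since the
  # previous one, so the oscillating ring-down of a low mode is not
  # re-counted. "Quiet" = a 5 ms block whose maximum envelope stays below
  # the re-arm level (5 ms spans at least one oscillation peak for modes
  # above ~110 Hz).
  bsize <- max(2L, round(5 * rec$rate / 1000))
  nb <- ceiling(length(env) / bsize)
  padded <- c(env, rep(Inf, nb * bsize - length(env)))
  block_max <- apply(matrix(padded, nrow = bsize), 2, max)
  quiet_block <- block_max < thr_low
  onsets <- rising[1]
  for (r in rising[-1]) {
    last <- onsets[length(onsets)]
    if (r - last < refr) next
    b0 <- min(nb, (last - 1L) %/% bsize + 2L)   # first full block after last
    b1 <- max(1L, (r - 1L) %/% bsize)           # last full block before r
    if (b1 < b0 || !any(quiet_block[b0:b1])) next
    onsets <- c(onsets, r)
  }
  # back off by the smoothing delay so onsets sit at the rise, not the mean
  pmax(onsets - wlen %/% 2L, 1L)
}

# integer + parabolic sub-sample lag of y relative to x by cross-correlation
.xcorr_lag <- function(x, y, max_lag) {
  n <- next_pow2(length(x) + max_lag)
  X <- stats::fft(c(x, numeric(n - length(x))))
  Y <- stats::fft(c(y, numeric(n - length(y))))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE))
  lags <- c(0:(n %/% 2 - 1), -(n %/% 2):-1)
  ok <- abs(lags) <= max_lag
  cci <- cc[ok]; li <- lags[ok]
  imax <- which.max(cci)
  lag <- li[imax]
  # parabolic refinement on the circular neighbors
  ip <- which(lags == (lag + 1) %% n | lags == ((lag + 1 + n) %% n) - n)[1]
  im <- which(lags == (lag - 1) %% n | lags == ((lag - 1 + n) %% n) - n)[1]
  y0 <- cc[which(lags == lag)[1]]
  yp <- cc[ip]; ym <- cc[im]
  den <- ym - 2 * y0 + yp
  frac <- if (is.finite(den) && abs(den) > 0) 0.5 * (ym - yp) / den else 0
  if (!is.finite(frac) || abs(frac) > 1) frac <- 0
  lag + frac
}

# shift a signal by a (possibly fractional) delay via FFT phase rotation
.frac_shift <- function(x, lag) {
  if (lag == 0) return(x)
  n <- length(x)
  X <- stats::fft(x)
  freq <- c(0:(n %/% 2), -(n - n %/% 2 - 1):-1) / n
  x2 <- Re(stats::fft(X * exp(2i * pi * freq * lag), inverse = TRUE)) / n
  x2
}

#' Coherently sum aligned tap segments
#'
#' Fixed-length windows starting at each onset are aligned to the first
#' segment by cross-correlation (integer lag plus parabolic sub-sample
#' refinement, applied as an FFT phase shift) and summed per channel.
#'
#' @param rec a [tap_recording()].
#' @param onsets onset sample indices from [detect_taps()].
#' @param window_s window length in seconds; default 0.5 s or the smallest
#'   inter-onset gap, whichever is shorter.
#' @param align sub-sample alignment on (default) or off.
#' @return an object of class `tap_ensemble`: `segments` (list of channels x
#'   window matrices), `stacked` (channels x window), `onsets`, `window`,
#'   `rate`, `mics`, `tap_location_id`, `n_taps`.
#' @export
coherent_sum <- function(rec, onsets, window_s = NULL, align = TRUE) {
  onsets <- as.integer(onsets)
  if (length(onsets) < 2L) stop2("need at least 2 onsets to stack")
  if (any(diff(onsets) <= 0)) stop2("onsets must be strictly increasing")
  gaps <- diff(onsets)
  wmax <- min(gaps)
  window <- if (is.null(window_s)) min(round(0.5 * rec$rate), wmax)
            else round(window_s * rec$rate)
  if (window > wmax)
    stop2("window of %d samples overlaps onsets (min gap %d)", window, wmax)
  window <- min(window, ncol(rec$samples) - max(onsets) + 1L)
  if (window < 2L) stop2("recording too short for the stacking window")
  nch <- nrow(rec$samples)
  segments <- lapply(onsets, function(o)
    rec$samples[, o:(o + window - 1L), drop = FALSE])
  # signed channel sum: rectified envelopes are ambiguous at half-period
  # lags (a half-period shift aligns |x| but inverts x and cancels the sum)
  chsum <- function(seg) if (nrow(seg) == 1L) seg[1, ] else colSums(seg)
  ref <- chsum(segments[[1]])
  max_lag <- max(1L, window %/% 4L)
  stacked <- segments[[1]]
  for (s in seq_along(segments)[-1]) {
    seg <- segments[[s]]
    if (align) {
      lag <- .xcorr_lag(ref, chsum(seg), max_lag)
      if (lag != 0)
        seg <- t(apply(seg, 1, .frac_shift, lag = -lag))
      segments[[s]] <- seg
    }
    stacked <- stacked + seg
  }
  structure(list(segments = segments, stacked = stacked, onsets = onsets,
                 window = window, rate = rec$rate, mics = rec$mics,
                 tap_location_id = rec$tap_location_id,
                 n_taps = length(onsets)),
            class = "tap_ensemble")
}

#' Normalized power spectrum of a stacked waveform
#'
#' Squared-magnitude FFT per channel (rectangular window, FFT length the
#' next power of two), one-sided, each channel divided by its own value at
#' the bin nearest `norm_freq`.
#'
#' @param stacked channels x time matrix (e.g. `$stacked` of
#'   [coherent_sum()]), or a `tap_ensemble`.
#' @param rate sample rate in Hz (taken from the ensemble if omitted).
#' @param norm_freq normalization frequency in Hz (default 15000).
#' @param normalize divide by the normalization-bin value (default TRUE).
#' @return an object of class `averaged_spectrum`: `freq` (Hz), `power`
#'   (channels x bins), `norm_freq`, `norm_bin`, `bin_width_hz`, `rate`,
#'   `mics`, `tap_location_id`, `n_averaged`.
#' @export
power_spectrum <- function(stacked, rate = NULL, norm_freq = 15000,
                           normalize = TRUE) {
  mics <- NULL; tap_id <- NA_integer_; n_avg <- 1L
  if (inherits(stacked, "tap_ensemble")) {
    rate <- stacked$rate; mics <- stacked$mics
    tap_id <- stacked$tap_location_id; n_avg <- stacked$n_taps
    stacked <- stacked$stacked
  }
  stacked <- as.matrix(stacked)
  if (is.null(rate)) stop2("rate required")
  if (norm_freq >= rate / 2) stop2("norm_freq must be below Nyquist")
  n <- ncol(stacked)
  nfft <- next_pow2(n)
  nbin <- nfft %/% 2 + 1L
  freq <- (seq_len(nbin) - 1) * rate / nfft
  power <- t(apply(stacked, 1, function(x) {
    X <- stats::fft(c(x, numeric(nfft - n)))
    Mod(X[seq_len(nbin)])^2
  }))
  if (nrow(stacked) == 1L) power <- matrix(power, nrow = 1)
  norm_bin <- which.min(abs(freq - norm_freq))
  if (normalize) {
    nv <- power[, norm_bin]
    if (any(nv <= 0)) stop2("zero power at the normalization bin")
    power <- power / nv
  }
  structure(list(freq = freq, power = power, norm_freq = norm_freq,
                 norm_bin = norm_bin, bin_width_hz = rate / nfft,
                 rate = rate, mics = mics, tap_location_id = tap_id,
                 n_averaged = n_avg),
            class = "averaged_spectrum")
}

#' Average spectra across locations and/or microphones
#'
#' Arithmetic mean of normalized power per bin, in the linear power domain
#' (convert to dB only for display).
#'
#' @param spectra list of [power_spectrum()] results on a common grid.
#' @param over `"locations"` (mean across spectra, channels kept),
#'   `"microphones"` (mean across channels within each spectrum), or
#'   `"both"`.
#' @return an `averaged_spectrum` (single-row power for `"microphones"` /
#'   `"both"`).
#' @export
average_spectra <- function(spectra, over = c("locations", "microphones", "both")) {
  over <- match.arg(over)
  if (inherits(spectra, "averaged_spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop2("no spectra to average")
  f0 <- spectra[[1]]$freq
  for (s in spectra)
    if (!isTRUE(all.equal(s$freq, f0)))
      stop2("spectra are on different frequency grids")
  if (over == "microphones" || over == "both") {
    spectra <- lapply(spectra, function(s) {
      s$power <- matrix(colMeans(s$power), nrow = 1)
      s$mics <- NULL
      s
    })
  }
  if (over == "locations" || over == "both") {
    acc <- spectra[[1]]
    if (length(spectra) > 1) {
      p <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
      acc$power <- p
    }
    acc$tap_location_id <- NA_integer_
    acc$n_averaged <- length(spectra)
    return(acc)
  }
  if (length(spectra) == 1L) spectra[[1]] else spectra
}

# topographic prominence of local maxima of y (same units as y)
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    hp <- y[p]
    # walk left until a higher point or the edge; track the minimum
    lmin <- hp; i <- p - 1
    while (i >= 1 && y[i] <= hp) { lmin <- min(lmin, y[i]); i <- i - 1 }
    if (i < 1) lmin <- min(y[1:p])
    rmin <- hp; i <- p + 1
    while (i <= length(y) && y[i] <= hp) { rmin <- min(rmin, y[i]); i <- i + 1 }
    if (i > length(y)) rmin <- min(y[p:length(y)])
    hp - max(lmin, rmin)
  }, numeric(1))
}

#' Pick resonance peaks from a spectrum
#'
#' Local maxima of the channel-mean power (in dB) within `band_hz`, filtered
#' by topographic prominence. Raw maxima closer than `merge_bins` bins are
#' clustered into a single reported peak flagged `merged` — two modes
#' separated by less than the spectral resolution cannot be told apart.
#'
#' @param spec an `averaged_spectrum`.
#' @param band_hz length-2 frequency interval (default c(100, 6000)).
#' @param min_prominence minimum prominence in dB (default 6).
#' @param merge_bins cluster distance in bins (default 2).
#' @return an object of class `peak_set`: data.frame `peaks` (frequency_hz,
#'   power, prominence_db, merged) in ascending frequency, plus `band_hz`,
#'   `bin_width_hz`.
#' @export
pick_peaks <- function(spec, band_hz = c(100, 6000), min_prominence = 6,
                       merge_bins = 2L) {
  if (band_hz[1] < spec$freq[1] || band_hz[2] > spec$freq[length(spec$freq)])
    stop2("band outside the spectrum range")
  y_lin <- colMeans(spec$power)
  in_band <- which(spec$freq >= band_hz[1] & spec$freq <= band_hz[2])
  y <- 10 * log10(pmax(y_lin[in_band], .Machine$double.xmin))
  n <- length(y)
  if (n < 3L)
    return(structure(list(peaks = data.frame(frequency_hz = numeric(0),
                                             power = numeric(0),
                                             prominence_db = numeric(0),
                                             merged = logical(0)),
                          band_hz = band_hz,
                          bin_width_hz = spec$bin_width_hz),
                     class = "peak_set"))
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  raw <- which(is_max)
  merged_flag <- logical(0)
  reps <- integer(0)
  if (length(raw)) {
    cl <- cumsum(c(1L, as.integer(diff(raw) > merge_bins)))
    for (g in unique(cl)) {
      members <- raw[cl == g]
      reps <- c(reps, members[which.max(y[members])])
      merged_flag <- c(merged_flag, length(members) > 1L)
    }
  }
  prom <- .peak_prominence(y, reps)
  keep <- prom >= min_prominence
  reps <- reps[keep]; prom <- prom[keep]; merged_flag <- merged_flag[keep]
  ord <- order(reps)
  idx <- in_band[reps[ord]]
  structure(list(peaks = data.frame(frequency_hz = spec$freq[idx],
                                    power = y_lin[idx],
                                    prominence_db = prom[ord],
                                    merged = merged_flag[ord]),
                 band_hz = band_hz, bin_width_hz = spec$bin_width_hz),
            class = "peak_set")
}

#' @exportS3Method base::print
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peak(s) in [%g, %g] Hz (bin %.3g Hz)\n",
              nrow(x$peaks), x$band_hz[1], x$band_hz[2], x$bin_width_hz))
  print(x$peaks)
  invisible(x)
}

#' Per-location, per-microphone amplitude map at a query frequency
#'
#' The normalized power at the bin nearest `query_freq`, for every
#' (tap location, microphone) pair — the machine-readable form of the
#' "plus formation" amplitude overlays.
#'
#' @param spectra list of per-location [power_spectrum()] results on a
#'   common grid (channels = microphones).
#' @param query_freq frequency in Hz (must be inside the band).
#' @return an object of class `amplitude_map`: data.frame `values`
#'   (tap_location_id, mic_id, mic_direction, frequency_hz, amplitude) and
#'   `matrix` (locations x mics), plus `query_freq`, `bin_freq`.
#' @export
amplitude_map <- function(spectra, query_freq) {
  if (inherits(spectra, "averaged_spectrum")) spectra <- list(spectra)
  f0 <- spectra[[1]]$freq
  if (query_freq < f0[1] || query_freq > f0[length(f0)])
    stop2("query frequency outside the spectrum band")
  bin <- which.min(abs(f0 - query_freq))
  rows <- list()
  mat <- NULL
  for (s in spectra) {
    if (!isTRUE(all.equal(s$freq, f0))) stop2("spectra grids differ")
    amp <- s$power[, bin]
    mic_id <- if (!is.null(s$mics)) s$mics$mic_id else seq_along(amp)
    mic_dir <- if (!is.null(s$mics)) s$mics$mic_direction else
      as.character(seq_along(amp))
    rows[[length(rows) + 1L]] <- data.frame(
      tap_location_id = s$tap_location_id, mic_id = mic_id,
      mic_direction = mic_dir, frequency_hz = f0[bin], amplitude = amp)
    mat <- rbind(mat, amp)
  }
  values <- do.call(rbind, rows)
  rownames(mat) <- vapply(spectra, function(s)
    as.character(s$tap_location_id), character(1))
  structure(list(values = values, matrix = mat, query_freq = query_freq,
                 bin_freq = f0[bin]),
            class = "amplitude_map")
}
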