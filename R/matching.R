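## Matching measured peaks to simulated modes --------------------------------

#' Map tap locations to surface vertices
#'
#' Nearest-vertex assignment of tap-location coordinates (same units and
#' frame as the mesh).
#'
#' @param surface a [surface_extract()] result.
#' @param coords data.frame with tap_location_id, x, y, z (meters).
#' @param warn_dist warn when a location lies farther than this from its
#'   vertex (default 5 mm).
#' @return data.frame: tap_location_id, vertex (surface-vertex id),
#'   distance_m.
#' @export
map_tap_locations <- function(surface, coords, warn_dist = 0.005) {
  if (!nrow(coords)) stop2("no tap locations supplied")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  v <- surface$vertices
  out <- t(vapply(seq_len(nrow(xyz)), function(i) {
    d2 <- (v[, 1] - xyz[i, 1])^2 + (v[, 2] - xyz[i, 2])^2 +
          (v[, 3] - xyz[i, 3])^2
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, numeric(2)))
  if (any(out[, 2] > warn_dist))
    warning(sprintf("%d tap location(s) farther than %g m from the surface",
                    sum(out[, 2] > warn_dist), warn_dist))
  data.frame(tap_location_id = coords$tap_location_id,
             vertex = as.integer(out[, 1]), distance_m = out[, 2])
}

#' Spatial agreement between an amplitude map and a simulated mode
#'
#' Spearman rank correlation between the per-location received amplitude
#' (reduced over microphones) and the simulated |phi . n| at the mapped
#' surface vertices. Rank correlation is used because radiated amplitude
#' and surface displacement are monotonically, not linearly, related.
#'
#' @param map an [amplitude_map()].
#' @param field a [normal_displacement()] matrix (vertices x modes).
#' @param pointmap a [map_tap_locations()] result.
#' @param mode simulated mode index (column of `field`).
#' @param reduce `"max"` (default) or `"mean"` over microphones.
#' @return Spearman correlation in [-1, 1].
#' @export
spatial_correlation <- function(map, field, pointmap,
                                mode, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  locs <- rownames(map$matrix)
  idx <- match(as.integer(locs), pointmap$tap_location_id)
  if (anyNA(idx)) stop2("amplitude map contains unmapped tap locations")
  if (length(idx) < 3L) stop2("need at least 3 locations to correlate")
  amp <- apply(map$matrix, 1, if (reduce == "max") max else mean)
  sim <- field[pointmap$vertex[idx], mode]
  stats::cor(amp, sim, method = "spearman")
}

#' Match experimental peaks against a simulated material sweep
#'
#' Ascending peaks are assigned, order-preserving, to ascending simulated
#' modes. A peak matches mode m when it falls within the sweep's
#' [min, max] frequency range for mode m inflated by `tolerance_pct` on
#' both sides. Each peak and each mode is used at most once; the assignment
#' maximizes the number of matches (order-preserving alignment).
#'
#' @param peaks a [pick_peaks()] result (or data.frame with frequency_hz).
#' @param sweep list of [solve_modes()] results (a material sweep), or a
#'   single solution.
#' @param tolerance_pct range inflation in percent (default 10).
#' @param scale_factors optional numeric vector of uniform geometric scale
#'   factors; the sweep ranges are extended by the frequency scalings 1/s
#'   (a scaled mesh lowers every frequency by the scale factor).
#' @return an object of class `mode_match_report`: data.frame `matches`
#'   (mode, peak_hz, sim_min_hz, sim_max_hz, matched), `unmatched_peaks_hz`,
#'   `tolerance_pct`.
#' @export
match_modes <- function(peaks, sweep, tolerance_pct = 10,
                        scale_factors = NULL) {
  pk <- if (inherits(peaks, "peak_set")) peaks$peaks else as.data.frame(peaks)
  if (inherits(sweep, "modal_solution")) sweep <- list(sweep)
  if (!length(sweep)) stop2("empty sweep")
  if (!nrow(pk))
    return(structure(list(matches = data.frame(mode = integer(0),
                                               peak_hz = numeric(0),
                                               sim_min_hz = numeric(0),
                                               sim_max_hz = numeric(0),
                                               matched = logical(0)),
                          unmatched_peaks_hz = numeric(0),
                          tolerance_pct = tolerance_pct),
                     class = "mode_match_report"))
  k <- min(vapply(sweep, function(s) length(s$frequencies_hz), integer(1)))
  fmat <- vapply(sweep, function(s) s$frequencies_hz[seq_len(k)], numeric(k))
  fmat <- matrix(fmat, nrow = k)
  lo <- apply(fmat, 1, min)
  hi <- apply(fmat, 1, max)
  if (!is.null(scale_factors)) {
    fac <- 1 / as.numeric(scale_factors)
    lo <- lo * min(c(1, fac))
    hi <- hi * max(c(1, fac))
  }
  lo_t <- lo * (1 - tolerance_pct / 100)
  hi_t <- hi * (1 + tolerance_pct / 100)
  f_pk <- sort(pk$frequency_hz)
  np <- length(f_pk)
  # order-preserving maximum matching by dynamic programming
  ok <- outer(seq_len(np), seq_len(k),
              function(i, m) f_pk[i] >= lo_t[m] & f_pk[i] <= hi_t[m])
  best <- matrix(0L, np + 1L, k + 1L)
  for (i in seq_len(np)) for (m in seq_len(k)) {
    best[i + 1, m + 1] <- max(best[i, m + 1], best[i + 1, m],
                              best[i, m] + as.integer(ok[i, m]))
  }
  assign_peak <- rep(NA_integer_, k)   # mode -> peak index
  i <- np; m <- k
  while (i > 0 && m > 0) {
    if (ok[i, m] && best[i + 1, m + 1] == best[i, m] + 1L) {
      assign_peak[m] <- i; i <- i - 1; m <- m - 1
    } else if (best[i, m + 1] >= best[i + 1, m]) i <- i - 1 else m <- m - 1
  }
  matches <- data.frame(mode = seq_len(k),
                        peak_hz = f_pk[assign_peak],
                        sim_min_hz = lo, sim_max_hz = hi,
                        matched = !is.na(assign_peak))
  structure(list(matches = matches,
                 unmatched_peaks_hz = f_pk[setdiff(seq_len(np),
                                                   stats::na.omit(assign_peak))],
                 tolerance_pct = tolerance_pct),
            class = "mode_match_report")
}

#' @exportS3Method base::print
print.mode_match_report <- function(x, ...) {
  cat(sprintf("mode_match_report: %d of %d mode(s) matched (tolerance %g%%)\n",
              sum(x$matches$matched), nrow(x$matches), x$tolerance_pct))
  print(x$matches)
  if (length(x$unmatched_peaks_hz))
    cat("unmatched peaks (Hz):",
        paste(round(x$unmatched_peaks_hz, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Left-right frequency offsets per mode
#'
#' For each mode, left - right in Hz and as a percentage of the right
#' frequency. (Measured ear bones show a systematic offset between the two
#' sides; e.g. a mode measured at 880 Hz on the left and 790 Hz on the
#' right is offset by +90 Hz = +11.4%.)
#'
#' @param left,right matched peak frequency vectors (or `peak_set`s) of
#'   equal length, mode-aligned.
#' @return data.frame: mode, left_hz, right_hz, offset_hz, offset_pct.
#' @export
left_right_offset <- function(left, right) {
  fl <- if (inherits(left, "peak_set")) left$peaks$frequency_hz else
    as.numeric(left)
  fr <- if (inherits(right, "peak_set")) right$peaks$frequency_hz else
    as.numeric(right)
  if (length(fl) != length(fr))
    stop2("left and right peak lists differ in length (%d vs %d)",
          length(fl), length(fr))
  data.frame(mode = seq_along(fl), left_hz = fl, right_hz = fr,
             offset_hz = fl - fr, offset_pct = 100 * (fl - fr) / fr)
}
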