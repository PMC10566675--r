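## Synthetic fixtures with ground truth --------------------------------------
##
## Two mesh generators (an analytic-oracle cantilever beam and a toy
## ear-bone complex) and a modal-superposition tap-recording synthesizer.
## Meshes are built on an integer voxel lattice: every occupied cell is split
## into the six Kuhn tetrahedra sharing the cell's main diagonal, which is
## conforming across neighboring cells by construction, so multi-component
## assemblies need no node merging and every label is exact.

# Kuhn subdivision: for each permutation of the axes, the path from the cell
# min-corner to the max-corner; tets share the main diagonal.
.kuhn_paths <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(seq_len(nrow(perms)), function(p) {
    e <- diag(3)[perms[p, ], , drop = FALSE]
    v0 <- c(0, 0, 0)
    v1 <- v0 + e[1, ]; v2 <- v1 + e[2, ]; v3 <- c(1, 1, 1)
    rbind(v0, v1, v2, v3)
  })
})

# cells: n x 3 integer min-corner indices; h: length-3 cell size (m);
# labels: component/region per cell. Returns a T4 tet_mesh plus the lattice
# coordinate of every node (integer grid units, for predicate-based sets).
lattice_tet_mesh <- function(cells, h, component, region, origin = c(0, 0, 0)) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  n <- nrow(cells)
  if (anyDuplicated(paste(cells[, 1], cells[, 2], cells[, 3])))
    stop2("duplicate lattice cells")
  # gather the 8 corner lattice points of every cell
  corners_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  pts <- do.call(rbind, lapply(1:8, function(cix)
    sweep(cells, 2, corners_off[cix, ], "+")))
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  ukey <- unique(key)
  node_id <- matrix(match(key, ukey), nrow = n)   # cell x corner -> node
  upts <- pts[match(ukey, key), , drop = FALSE]
  nodes <- sweep(upts * rep(h, each = nrow(upts)), 2, origin, "+")
  # corner index (1..8) for an offset triple
  off_ix <- function(o) as.integer(1L + o[1] + 2L * o[2] + 4L * o[3])
  elements <- matrix(0L, 6L * n, 4L)
  for (t in 1:6) {
    ids <- vapply(1:4, function(v) off_ix(.kuhn_paths[[t]][v, ]), integer(1))
    elements[seq_len(n) + (t - 1L) * n, ] <- node_id[, ids, drop = FALSE]
  }
  comp_el <- rep(component, times = 6L)
  reg_el <- rep(region, times = 6L)
  # fix orientation where the Kuhn path gives negative volume
  m <- tet_mesh(nodes, elements, comp_el, reg_el, validate = FALSE)
  v <- element_volumes(m)
  flip <- v < 0
  if (any(flip)) {
    el <- m$elements
    el[flip, c(3, 4)] <- el[flip, c(4, 3)]
    m <- tet_mesh(nodes, el, comp_el, reg_el, validate = FALSE)
  }
  m$lattice <- upts
  m
}

#' Structured cantilever-beam mesh (analytic oracle fixture)
#'
#' A box of `L x W x H` meters meshed with `divisions` cells per axis, each
#' split into 6 tetrahedra. Single component `"beam"`, region `"stiff_bone"`.
#' The `x = 0` face is the clamp: its node ids are returned in `base_nodes`.
#'
#' @param L,W,H beam dimensions in meters.
#' @param divisions integer length-3: cells along x, y, z.
#' @param order 4 (linear) or 10 (quadratic) node tetrahedra.
#' @return a [tet_mesh()] with extra field `base_nodes`.
#' @export
make_beam_mesh <- function(L = 1, W = 0.05, H = 0.05,
                           divisions = c(24L, 2L, 2L), order = 10L) {
  if (any(c(L, W, H) <= 0)) stop2("beam dimensions must be positive")
  divisions <- as.integer(divisions)
  if (length(divisions) != 3L || any(divisions < 1L))
    stop2("divisions must be 3 positive integers")
  if (!order %in% c(4L, 10L)) stop2("order must be 4 or 10")
  cells <- as.matrix(expand.grid(0:(divisions[1] - 1L),
                                 0:(divisions[2] - 1L),
                                 0:(divisions[3] - 1L)))
  h <- c(L, W, H) / divisions
  m <- lattice_tet_mesh(cells, h, rep("beam", nrow(cells)),
                        rep("stiff_bone", nrow(cells)))
  if (order == 10L) m <- promote_to_t10(m)
  m$base_nodes <- which(abs(m$nodes[, 1]) < 1e-12)
  validate_mesh(m)
  m
}

#' Parameters of the toy ear-bone complex
#'
#' The toy emulates the load path of the tympanoperiotic complex: a fixed
#' slab (periotic) carrying, through two slender flexible struts (the
#' pedicles), a stiff open-top shell (the bulla) with a raised ridge (the
#' sigmoid process), plus a three-ossicle chain (malleus fused to the shell
#' wall, then incus and stapes joined by stiff ligaments, the stapes seated
#' on a flexible annular ligament). All dimensions in meters.
#'
#' @param h lattice cell size (default 0.01, i.e. a 8 x 6 x 9 cm structure).
#' @param refine integer subdivision of each lattice cell (resolution knob).
#' @param dome_depth downward bulge of the shell floor, breaks the box
#'   symmetry so eigenvalues are simple (default 0.8 * h).
#' @param wall_frac shell wall/floor thickness as a fraction of `h` (default
#'   0.5); thinner walls bring the first dozen shell plate modes into the
#'   few-kHz band where real ear-bone resonances sit.
#' @param order element order, 4 or 10 (default 10).
#' @param n_tap_locations number of tap points sampled on the outer shell
#'   (default 89, the number of designated tap stickers in the measured
#'   protocol).
#' @return list of parameters for [make_toy_tpc()].
#' @export
toy_tpc_params <- function(h = 0.01, refine = 1L, dome_depth = 0.8 * h,
                           wall_frac = 0.5, order = 10L,
                           n_tap_locations = 89L) {
  if (h <= 0) stop2("h must be positive")
  if (wall_frac <= 0 || wall_frac > 1) stop2("wall_frac must be in (0, 1]")
  if (!order %in% c(4L, 10L)) stop2("order must be 4 or 10")
  list(h = h, refine = as.integer(refine), dome_depth = dome_depth,
       wall_frac = wall_frac, order = as.integer(order),
       n_tap_locations = as.integer(n_tap_locations))
}

# integer cell layout of the toy complex, in h units
.toy_tpc_cells <- function() {
  cells <- list()
  add <- function(ijk, component, region) {
    cells[[length(cells) + 1L]] <<-
      cbind(as.data.frame(ijk), component = component, region = region)
  }
  grid3 <- function(is, js, ks) {
    g <- expand.grid(i = is, j = js, k = ks)
    as.matrix(g)
  }
  # bulla: open-top box shell, outer 8 x 6 footprint, floor k = 0, walls to k = 4
  floor_cells <- grid3(0:7, 0:5, 0)
  wall <- grid3(0:7, 0:5, 1:4)
  wall <- wall[wall[, "i"] %in% c(0L, 7L) | wall[, "j"] %in% c(0L, 5L), ]
  ridge <- grid3(4:5, -1, 2:4)          # sigmoid-like ridge on the j = 0 wall
  add(rbind(floor_cells, wall, ridge), "bulla", "stiff_bone")
  # pedicles: 1-cell cross-section struts from the shell rim up to the slab
  add(grid3(0, 2, 5:6), "anterior_pedicle", "flexible_bone")
  add(grid3(7, 3, 5:6), "posterior_pedicle", "flexible_bone")
  # periotic: fixed slab covering the footprint
  add(grid3(0:7, 0:5, 7:8), "periotic", "stiff_bone")
  # ossicular chain inside the cavity, hanging off the j = 0 wall
  add(grid3(3, 1, 3), "malleus", "stiff_bone")
  add(grid3(4, 1, 3), "ligament_malleoincudal", "stiff_ligament")
  add(grid3(5, 1, 3), "incus", "stiff_bone")
  add(grid3(6, 1, 3), "ligament_incudostapedial", "stiff_ligament")
  add(grid3(6, 1, 2), "stapes", "stiff_bone")
  add(grid3(6, 1, 1), "ligament_annular", "flexible_ligament")
  do.call(rbind, cells)
}

#' Generate the toy ear-bone complex with ground truth
#'
#' See [toy_tpc_params()] for what the geometry emulates. The returned
#' ground truth is sufficient to score every downstream operation: exact
#' per-component element counts, the fixed-base node set, and tap-location
#' coordinates sampled on the outer shell surface.
#'
#' @param params from [toy_tpc_params()].
#' @param seed integer seed for the tap-location sample.
#' @return list: `mesh` (labeled [tet_mesh()]), `base_nodes` (periotic slab
#'   top face), `component_elements` (named element counts),
#'   `tap_locations` (data.frame tap_location_id, x, y, z, surface vertex id).
#' @export
make_toy_tpc <- function(params = toy_tpc_params(), seed = 1L) {
  spec <- .toy_tpc_cells()
  cells <- as.matrix(spec[, c("i", "j", "k")])
  comp <- as.character(spec$component)
  reg <- as.character(spec$region)
  r <- params$refine
  if (r > 1L) {
    sub <- as.matrix(expand.grid(0:(r - 1L), 0:(r - 1L), 0:(r - 1L)))
    n <- nrow(cells)
    cells <- do.call(rbind, lapply(seq_len(nrow(sub)), function(s)
      sweep(cells * r, 2, sub[s, ], "+")))
    comp <- rep(comp, times = nrow(sub))
    reg <- rep(reg, times = nrow(sub))
  }
  m <- lattice_tet_mesh(cells, rep(1, 3), comp, reg)
  # nonuniform lattice pitch: shell walls and floor are thin (wall_frac * h),
  # every other cell layer has full pitch h
  wf <- params$wall_frac
  pitch_of <- list(function(i) ifelse(i %in% c(0L, 7L), wf, 1),
                   function(j) ifelse(j %in% c(-1L, 0L, 5L), wf, 1),
                   function(k) ifelse(k == 0L, wf, 1))
  for (ax in 1:3) {
    idx <- m$lattice[, ax]                  # refined node-plane indices
    rng <- min(idx):max(idx)
    parent <- floor(rng / r)                # refined cell -> parent cell
    pit <- pitch_of[[ax]](parent) * params$h / r
    pos <- cumsum(c(0, pit[-length(pit)]))
    m$nodes[, ax] <- pos[match(idx, rng)] + min(idx) * params$h / r
  }
  # physical position of a lattice plane (cell-unit index, before refine)
  plane <- function(ax, cell_idx) {
    hit <- which(m$lattice[, ax] == cell_idx * r)[1]
    m$nodes[hit, ax]
  }
  rim_top <- plane(3, 5)
  cavity <- list(x = c(plane(1, 1), plane(1, 7)),
                 y = c(plane(2, 1), plane(2, 5)),
                 z_floor = plane(3, 1))
  # dome the shell floor downward (mild symmetry-breaking bulge)
  z <- m$nodes[, 3]
  xr <- range(m$nodes[, 1]); yr <- range(m$nodes[, 2])
  bump <- sinpi((m$nodes[, 1] - xr[1]) / diff(xr)) *
          sinpi((m$nodes[, 2] - yr[1]) / diff(yr))
  fade <- pmax(0, 1 - z / rim_top)
  m$nodes[, 3] <- z - params$dome_depth * bump * fade
  m <- tet_mesh(m$nodes, m$elements, m$component, m$region, validate = FALSE)
  if (params$order == 10L) m <- promote_to_t10(m)
  validate_mesh(m)
  if (max(mesh_fragments(m$elements)) != 1L)
    stop2("toy mesh is disconnected; bad parameter combination")
  # ground truth: fixed base = slab top face
  ztop <- max(m$nodes[, 3])
  periotic_nodes <- sort(unique(as.vector(
    m$elements[m$component == "periotic", , drop = FALSE])))
  base_nodes <- periotic_nodes[abs(m$nodes[periotic_nodes, 3] - ztop) < 1e-12]
  # tap locations: outer shell vertices (bulla-owned boundary, below the rim,
  # not shared with other components), sampled with the seed
  surf <- surface_extract(m)
  bulla_tri <- which(m$component[surf$element] == "bulla")
  vb <- unique(as.vector(surf$triangles[bulla_tri, ]))
  other_tri <- which(m$component[surf$element] != "bulla")
  vb <- setdiff(vb, unique(as.vector(surf$triangles[other_tri, ])))
  # outer only: drop cavity-facing vertices (inside the wall footprint and
  # above the floor)
  vx <- surf$vertices[vb, , drop = FALSE]
  eps <- 1e-9
  inner <- vx[, 1] > cavity$x[1] - eps & vx[, 1] < cavity$x[2] + eps &
           vx[, 2] > cavity$y[1] - eps & vx[, 2] < cavity$y[2] + eps &
           vx[, 3] > cavity$z_floor - params$dome_depth - eps
  vb <- vb[!inner]
  n_tap <- min(params$n_tap_locations, length(vb))
  picked <- with_seed(seed, sort(sample(vb, n_tap)))
  tap <- data.frame(tap_location_id = seq_len(n_tap),
                    x = surf$vertices[picked, 1],
                    y = surf$vertices[picked, 2],
                    z = surf$vertices[picked, 3],
                    surface_vertex = picked)
  list(mesh = m, base_nodes = base_nodes,
       component_elements = table(m$component),
       tap_locations = tap, surface = surf, seed = seed)
}

## ---- tap-recording synthesis ----------------------------------------------

#' Specification of a synthetic multi-tap recording session
#'
#' The forward model is modal superposition: each tap at location l excites
#' every mode k with weight `weights[l, k]` (proportional to |phi_k . n| at
#' the tap point), observed at microphone m with gain `mic_gains[l, m]`, as
#' an exponentially damped sinusoid
#'   a e^(-zeta_k w_k t) sin(w_k sqrt(1 - zeta_k^2) t),
#' plus a deterministic broadband contact click (a damped tone at the
#' normalization frequency) and white Gaussian noise at `snr_db` relative to
#' the first tap's peak.
#'
#' @param frequencies_hz planted mode frequencies (below Nyquist).
#' @param zeta damping ratios, scalar or per mode, in (0, 1); default 0.01.
#' @param weights locations x modes excitation matrix (nonnegative).
#' @param mic_gains locations x mics gain matrix.
#' @param rate sample rate Hz (default 48000, so 15 kHz is in band).
#' @param taps_per_location number of taps (default 20).
#' @param tap_interval_s mean inter-tap interval (default 0.6).
#' @param jitter_s uniform inter-tap jitter (default 0.05).
#' @param amp_range min and max of the uniform per-tap strike-strength
#'   factor (default c(0.8, 1.2); use c(1, 1) for identical taps).
#' @param snr_db signal-to-noise ratio (default 20).
#' @param click_freq_hz,click_gain,click_tau_s contact-click tone (defaults
#'   15 kHz, unit relative amplitude, 20 ms decay); gives every channel a
#'   coherent reference well above the noise at the normalization frequency.
#' @param seed RNG seed; recordings are byte-identical for a fixed seed.
#' @return an object of class `tap_synth_spec`.
#' @export
tap_synth_spec <- function(frequencies_hz, zeta = 0.01, weights, mic_gains,
                           rate = 48000, taps_per_location = 20L,
                           tap_interval_s = 0.6, jitter_s = 0.05,
                           amp_range = c(0.8, 1.2),
                           snr_db = 20, click_freq_hz = 15000,
                           click_gain = 1, click_tau_s = 0.02, seed = 1L) {
  frequencies_hz <- as.numeric(frequencies_hz)
  k <- length(frequencies_hz)
  zeta <- rep_len(zeta, k)
  if (any(zeta <= 0 | zeta >= 1)) stop2("zeta must lie in (0, 1)")
  if (any(frequencies_hz >= rate / 2) || click_freq_hz >= rate / 2)
    stop2("planted frequencies must be below Nyquist (%g Hz)", rate / 2)
  weights <- as.matrix(weights)
  mic_gains <- as.matrix(mic_gains)
  if (ncol(weights) != k) stop2("weights must have one column per mode")
  if (nrow(mic_gains) != nrow(weights))
    stop2("weights and mic_gains must have one row per tap location")
  if (taps_per_location < 2L) stop2("need at least 2 taps per location")
  structure(list(frequencies_hz = frequencies_hz, zeta = zeta,
                 weights = weights, mic_gains = mic_gains, rate = rate,
                 taps_per_location = as.integer(taps_per_location),
                 tap_interval_s = tap_interval_s, jitter_s = jitter_s,
                 amp_range = amp_range,
                 snr_db = snr_db, click_freq_hz = click_freq_hz,
                 click_gain = click_gain, click_tau_s = click_tau_s,
                 seed = as.integer(seed)),
            class = "tap_synth_spec")
}

#' Default microphone arrangement
#'
#' Eight directions around a ventral-side-up ear bone: anterior/posterior
#' (+/- x), lateral (+y), proximal (-y), and four ventral mics on a tilted
#' downward-facing plane.
#'
#' @return data.frame: mic_id, mic_direction, dx, dy, dz (unit vectors).
#' @export
default_microphones <- function() {
  d <- rbind(
    anterior = c(1, 0, 0), posterior = c(-1, 0, 0),
    lateral = c(0, 1, 0), proximal = c(0, -1, 0),
    ventral_1 = c(0.35, 0.35, -1), ventral_2 = c(-0.35, 0.35, -1),
    ventral_3 = c(0.35, -0.35, -1), ventral_4 = c(-0.35, -0.35, -1))
  d <- d / sqrt(rowSums(d^2))
  data.frame(mic_id = seq_len(nrow(d)), mic_direction = rownames(d),
             dx = d[, 1], dy = d[, 2], dz = d[, 3], row.names = NULL)
}

#' Microphone gains from surface normals
#'
#' Crude radiation directivity: |cos| between the mic direction and the
#' outward surface normal at the tap point, floored at 0.1.
#'
#' @param surface a [surface_extract()] result.
#' @param tap_vertices surface-vertex ids of the tap locations.
#' @param mics data.frame as [default_microphones()].
#' @param floor minimum gain (default 0.1).
#' @return locations x mics gain matrix.
#' @export
mic_gain_matrix <- function(surface, tap_vertices, mics = default_microphones(),
                            floor = 0.1) {
  nrm <- surface$vertex_normals[tap_vertices, , drop = FALSE]
  dirs <- as.matrix(mics[, c("dx", "dy", "dz")])
  pmax(abs(nrm %*% t(dirs)), floor)
}

#' Planted excitation weights from a modal solution
#'
#' weight[l, k] = |phi_k . n| at the surface vertex of tap location l.
#'
#' @param solution a [solve_modes()] result.
#' @param surface the matching [surface_extract()].
#' @param tap_vertices surface-vertex ids of the tap locations.
#' @return locations x modes weight matrix.
#' @export
mode_excitation_weights <- function(solution, surface, tap_vertices) {
  nd <- normal_displacement(solution, surface)
  nd[tap_vertices, , drop = FALSE]
}

# single-tap template: modes + click, one row per mic, length n samples
.tap_template <- function(spec, loc, n) {
  t <- (seq_len(n) - 1) / spec$rate
  w <- 2 * pi * spec$frequencies_hz
  modes <- vapply(seq_along(w), function(k)
    exp(-spec$zeta[k] * w[k] * t) * sin(w[k] * sqrt(1 - spec$zeta[k]^2) * t),
    numeric(n))                                   # n x k
  base <- modes %*% spec$weights[loc, ]           # n x 1
  click <- spec$click_gain *
    exp(-t / spec$click_tau_s) * sin(2 * pi * spec$click_freq_hz * t)
  outer(spec$mic_gains[loc, ], as.numeric(base + click))   # mics x n
}

#' Synthesize multichannel tap recordings
#'
#' One multichannel recording per tap location, written as WAV (32-bit
#' float) plus a manifest CSV and a machine-readable ground-truth JSON.
#' Deterministic: identical bytes for identical seeds.
#'
#' @param spec a [tap_synth_spec()].
#' @param out_dir output directory (created if needed).
#' @param mics data.frame as [default_microphones()].
#' @param write_wav write WAV files (default TRUE); when FALSE the
#'   recordings are only returned in memory.
#' @param sink optional function `f(recording, location_id)` called with
#'   each recording as it is generated; when supplied, recordings are NOT
#'   accumulated in the return value (a full 89-location session holds
#'   several GB, so stream it).
#' @return list: `recordings` (list of `tap_recording` objects, or NULLs
#'   when `sink` is used), `truth` (onsets, planted
#'   frequencies/damping/weights per location), `manifest` (data.frame),
#'   `dir`.
#' @export
synth_tap_recordings <- function(spec, out_dir = NULL, mics = NULL,
                                 write_wav = !is.null(out_dir),
                                 sink = NULL) {
  n_loc <- nrow(spec$weights)
  if (is.null(mics)) {
    mics <- default_microphones()
    if (ncol(spec$mic_gains) < nrow(mics))
      mics <- mics[seq_len(ncol(spec$mic_gains)), , drop = FALSE]
  }
  n_mic <- nrow(mics)
  if (ncol(spec$mic_gains) != n_mic)
    stop2("mic_gains has %d columns but %d mics supplied",
          ncol(spec$mic_gains), n_mic)
  if (write_wav) {
    if (is.null(out_dir)) stop2("out_dir required to write WAV files")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  # template long enough for the slowest decay (to 1e-4) or 0.5 s
  wmin <- 2 * pi * min(spec$frequencies_hz)
  t_dec <- log(1e4) / (min(spec$zeta) * wmin)
  n_tpl <- ceiling(min(max(t_dec, 0.1), 0.5) * spec$rate)
  recordings <- vector("list", n_loc)
  truth_loc <- vector("list", n_loc)
  manifest <- vector("list", n_loc)
  with_seed(spec$seed, {
    for (loc in seq_len(n_loc)) {
      gaps <- spec$tap_interval_s +
        stats::runif(spec$taps_per_location, -spec$jitter_s, spec$jitter_s)
      onsets <- round(cumsum(c(0.2, gaps[-1])) * spec$rate) + 1L
      amps <- stats::runif(spec$taps_per_location,
                           spec$amp_range[1], spec$amp_range[2])
      n_total <- max(onsets) + n_tpl + round(0.2 * spec$rate)
      tpl <- .tap_template(spec, loc, n_tpl)
      sig <- matrix(0, n_mic, n_total)
      for (tap in seq_along(onsets)) {
        idx <- onsets[tap]:(onsets[tap] + n_tpl - 1L)
        sig[, idx] <- sig[, idx] + amps[tap] * tpl
      }
      # per-channel SNR: each microphone's noise floor scales with the peak
      # of its own first-tap signal
      peak_ch <- apply(abs(amps[1] * tpl), 1, max)
      noise_sd <- pmax(peak_ch, 1e-12) * 10^(-spec$snr_db / 20)
      sig <- sig + matrix(stats::rnorm(length(sig)), nrow = n_mic) * noise_sd
      rec <- tap_recording(sig, spec$rate, mics, tap_location_id = loc)
      if (is.null(sink)) recordings[[loc]] <- rec else sink(rec, loc)
      truth_loc[[loc]] <- list(tap_location_id = loc, onsets = onsets,
                               amplitudes = amps,
                               weights = spec$weights[loc, ],
                               mic_gains = spec$mic_gains[loc, ])
      if (write_wav) {
        f <- file.path(out_dir, sprintf("tap_location_%03d.wav", loc))
        write_wav(sig, spec$rate, f, bits = 32L)
        manifest[[loc]] <- data.frame(
          file = basename(f), tap_location_id = loc,
          mic_id = mics$mic_id, mic_direction = mics$mic_direction)
      }
    }
  })
  truth <- list(frequencies_hz = spec$frequencies_hz, zeta = spec$zeta,
                rate = spec$rate, snr_db = spec$snr_db, seed = spec$seed,
                click_freq_hz = spec$click_freq_hz,
                locations = truth_loc)
  manifest <- if (write_wav) do.call(rbind, manifest) else NULL
  if (write_wav) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(frequencies_hz = spec$frequencies_hz, zeta = spec$zeta,
           rate = spec$rate, snr_db = spec$snr_db, seed = spec$seed),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recordings, truth = truth, manifest = manifest,
       dir = if (write_wav) out_dir else NULL)
}
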