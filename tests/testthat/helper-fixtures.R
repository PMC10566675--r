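# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder())
  .fx[[name]]
}

# one reference tetrahedron with mild distortion (not axis-aligned)
fx_single_tet <- function() {
  nodes <- rbind(c(0, 0, 0), c(1.1, 0.1, 0), c(0.2, 0.9, -0.1),
                 c(0, 0.2, 1.2)) * 0.1
  tet_mesh(nodes, matrix(1:4, 1), "part", "stiff_bone")
}

fx_unit_material <- function()
  list(stiff_bone = material_card(1000, 1e9, 0.3))

# small quadratic cantilever for eigen-oracle tests
fx_beam <- function() fixture("beam", function() {
  make_beam_mesh(L = 1, W = 0.05, H = 0.05, divisions = c(24, 2, 2),
                 order = 10)
})

fx_beam_solve <- function() fixture("beam_solve", function() {
  beam <- fx_beam()
  mats <- list(stiff_bone = material_card(2400, 25e9, 0.3))
  sys <- assemble_system(beam, mats, beam$base_nodes)
  list(sys = sys, sol = solve_modes(sys, k = 8), mats = mats)
})

# the toy ear-bone complex (quadratic, default params)
fx_toy <- function() fixture("toy", function() {
  make_toy_tpc(toy_tpc_params(), seed = 101)
})

# quick linear-order toy for sweep-style tests
fx_toy_t4 <- function() fixture("toy_t4", function() {
  make_toy_tpc(toy_tpc_params(order = 4), seed = 101)
})

fx_toy_solve <- function() fixture("toy_solve", function() {
  toy <- fx_toy()
  mats <- tpc_reference_materials()
  sys <- assemble_system(toy$mesh, mats, toy$base_nodes)
  list(toy = toy, mats = mats, sys = sys, sol = solve_modes(sys, k = 16))
})

# ablated (incus + stapes removed) toy and its solve
fx_toy_ablated <- function() fixture("toy_ablated", function() {
  toy <- fx_toy()
  mats <- tpc_reference_materials()
  ab <- suppressMessages(remove_components(toy$mesh, c("incus", "stapes")))
  sys <- assemble_system(ab$mesh, mats, ab$node_map[toy$base_nodes])
  list(toy = toy, mats = mats, removal = ab, sys = sys,
       sol = solve_modes(sys, k = 12),
       surface = surface_extract(ab$mesh))
})

# synthetic single-location recording with known taps
fx_mini_synth <- function(seed = 5, n_modes = 3, snr_db = 20, mics = 1) {
  freqs <- c(500, 1200, 3000)[seq_len(n_modes)]
  w <- matrix(c(1, 0.5, 0.25)[seq_len(n_modes)], 1)
  g <- matrix(rep(1, mics), 1)
  spec <- tap_synth_spec(freqs, zeta = 0.01, weights = w, mic_gains = g,
                         snr_db = snr_db, seed = seed)
  synth_tap_recordings(spec, write_wav = FALSE)
}

expect_rel <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x / y - 1)), tol)
}
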