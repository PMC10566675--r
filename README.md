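# tpcresonance

Modal analysis and tap-test spectroscopy of multi-component ear-bone
structures, built around the tympanoperiotic complex (TPC) — the whale
ear-bone unit whose resonances between ~100 Hz and 6 kHz shape
low-frequency hearing in baleen whales.

The package couples two measurements of the same physics:

* **Simulation** — a multi-material tetrahedral finite-element modal
  solver for small-strain isotropic elasticity,
  `K φ = ω² M φ`, with fixed-base (skull-attachment) constraints,
  consistent mass, material sweeps, uniform geometric scaling, component
  ablation (e.g. removing incus and stapes), modal-assurance-criterion
  (MAC) mode tracking, and surface-normal displacement fields `|φ·n|`.
* **Measurement** — an impact ("tap") excitation pipeline: onset
  detection, coherent summation of ≥20 aligned taps (≈ +13 dB against
  incoherent noise), power spectra normalized per channel at 15 kHz,
  prominence-based peak picking in the 100 Hz–6 kHz band, and
  per-tap-location amplitude maps.
* **Comparison** — order-preserving matching of measured peaks against
  the frequency ranges of a simulated material sweep, Spearman rank
  correlation between amplitude maps and simulated `|φ·n|`, and per-mode
  left/right frequency offsets.
* **Synthetic ground truth** — parametric labeled meshes (an
  Euler–Bernoulli-verifiable cantilever and a toy ear-bone complex with
  fixed periotic slab, flexible pedicle hinges, ridge-bearing shell and
  a three-ossicle chain) plus multichannel tap recordings synthesized by
  modal superposition of damped sinusoids, so every stage is scored
  against known truth.

Mesh I/O covers Gmsh MSH 4.1 ASCII and legacy VTK ASCII (labels embedded
as physical groups or in a CSV sidecar, mm→m conversion on request);
recordings are WAV (PCM 16/24-bit, float 32-bit); modal solutions persist
to HDF5 + CSV.

## Worked example

```r
library(tpcresonance)

# toy ear-bone complex with ground truth (quadratic tets, 1 cm pitch)
toy <- make_toy_tpc(toy_tpc_params(), seed = 1)
mats <- tpc_reference_materials()   # stiff bone 2400 kg/m^3, 25 GPa; ...

sys <- assemble_system(toy$mesh, mats, toy$base_nodes)
sol <- solve_modes(sys, k = 6)
round(sol$frequencies_hz, 1)
#> [1]  124.2  382.3  689.5 1040.2 1244.6 1306.9

# frequencies scale exactly as 1/s under uniform geometric scaling
sol12 <- solve_modes(assemble_system(scale_mesh(toy$mesh, 1.2), mats,
                                     toy$base_nodes), k = 6)
round(sol$frequencies_hz / sol12$frequencies_hz, 6)
#> [1] 1.2 1.2 1.2 1.2 1.2 1.2
```

The first line is the natural-frequency ladder of the clamped toy
complex: a ~126 Hz hinge ("door-swing") mode on the pedicles, followed by
twisting and shell modes. The second shows the scaling experiment: after
scaling all coordinates by 1.2, every natural frequency drops by exactly
that factor — the basis for comparing a CT-derived mesh against a larger
physical specimen.

Synthetic tap session and full recovery loop:

```r
ab  <- remove_components(toy$mesh, c("incus", "stapes"))   # chain ablation
sys <- assemble_system(ab$mesh, mats, ab$node_map[toy$base_nodes])
sol <- solve_modes(sys, k = 12)
surf <- surface_extract(ab$mesh)
pm <- map_tap_locations(surf, toy$tap_locations)
spec <- tap_synth_spec(
  sol$frequencies_hz, zeta = 0.01,
  weights  = mode_excitation_weights(sol, surf, pm$vertex),
  mic_gains = mic_gain_matrix(surf, pm$vertex), snr_db = 20, seed = 1)
spectra <- vector("list", 89)
synth_tap_recordings(spec, write_wav = FALSE, sink = function(rec, loc) {
  spectra[[loc]] <<- power_spectrum(
    coherent_sum(rec, detect_taps(rec), window_s = 0.0625))
})
avg <- average_spectra(spectra, over = "locations")
pick_peaks(average_spectra(list(avg), over = "microphones"),
           band_hz = c(50, 9000))
```

which recovers all 12 planted resonances within one FFT bin and matches
them back to the generating modes (`match_modes()`), with location-wise
amplitude maps rank-correlating with `|φ·n|` at ρ ≥ 0.9.

## Command line

```sh
Rscript inst/cli/tpc simulate -c config.yaml   # or: sweep, synth, analyze, match
```

(after installation: `Rscript $(Rscript -e 'cat(system.file("cli", "tpc",
package = "tpcresonance"))')`). YAML config; exit 0 on success, 2 on
validation errors; outputs stamped with the config hash and seed.

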