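---
title: "Modal analysis and tap-test spectroscopy of ear-bone structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal analysis and tap-test spectroscopy of ear-bone structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The tympanoperiotic complex (TPC) — the whale ear-bone unit of periotic,
tympanic bulla, suspensory pedicles and ossicular chain — resonates in the
low-frequency band where baleen whales hear. Two complementary measurements
probe those resonances: a finite-element modal model of the bone assembly
with its periotic base clamped to the skull, and a physical tap test in
which the bulla is struck repeatedly at marked locations while microphones
record the radiated sound. This package implements both halves and the
comparison between them, exercised end to end on synthetic structures and
synthetic recordings with complete ground truth.

## The modal model

The structure is an assembly of isotropic linear-elastic regions on a
labeled tetrahedral mesh (4-node or 10-node elements). Small-strain
elasticity with a consistent mass matrix gives the generalized symmetric
eigenproblem

$$K\,\phi_k = \omega_k^2\, M\,\phi_k,$$

with frequencies $f_k = \omega_k/2\pi$ and mass-normalized shapes
($\Phi^\top M \Phi = I$). Clamping is imposed by eliminating the three
displacement DOFs of every fixed node, which preserves symmetry and makes
$K$ positive definite.

**Element integration.** For straight-sided tetrahedra every entry of the
element stiffness and consistent mass matrix is a polynomial in the
barycentric coordinates, so we integrate exactly with
$\int_T \lambda^{\alpha}\,dV = 6V\,\alpha_1!\alpha_2!\alpha_3!\alpha_4!/(|\alpha|+3)!$
instead of quadrature tables. The consistent mass is therefore exact for
both element orders; quadratic (T10) elements are the default because
linear tetrahedra are artificially stiff in the bending-dominated modes
that matter here. T10 geometry is treated as straight-sided (midside nodes
at edge midpoints); curved quadratic faces are out of scope.

**Eigensolver.** $M = L L^\top$ (sparse Cholesky) reduces the pencil to a
standard symmetric problem whose smallest eigenvalues are obtained by
Lanczos iteration on $(L^\top K^{-1} L)$ through a CHOLMOD factorization of
$K$ — shift-invert about $\sigma = 0$. A free-free diagnostic mode adds a
small spectral shift $\sigma = 10^{-6}\,\mathrm{tr}(K)/\mathrm{tr}(M)$ so
the six rigid-body modes of an unconstrained body are computable. The
Lanczos start vector is a fixed deterministic sequence, so repeated solves
are bit-stable. Every solution stores its orthonormality error
($\le 10^{-8}$) and per-mode relative residuals ($\le 10^{-6}$), asserted
by the test suite.

**Materials.** Four regions with literature values: stiff bone (periotic,
bulla wall, ossicles; $\rho$ = 2300/2400/2500 kg/m³, $E$ = 10–25 GPa,
$\nu$ = 0.3), flexible bone (pedicles; $\rho$ = 2000 kg/m³, $E$ = 5/7/9
GPa), stiff ligaments ($E$ = 1 MPa, $\nu$ = 0.3) and the flexible annular
ligament ($E$ = 1 MPa, $\nu$ = 0.45). `sweep_materials()` runs the
factorial grid; frequencies respond monotonically (raising any region's
$E$ is a Loewner increase of $K$, so no ordered frequency can fall;
raising a density can only lower them), which the acceptance suite checks
both on ordered and on MAC-tracked modes. Note that undamped elasticity
bounds the density sensitivity at $f \propto \rho^{-1/2}$ — about a 2%
drop for a 4% density increase; a quoted one-to-one (4%→4%)
correspondence is not reproducible within this model class and no attempt
is made to match it.

**Mode tracking.** Modes are paired across parameter changes by the modal
assurance criterion
$\mathrm{MAC}(\phi_a,\phi_b) = (\phi_a^\top M \phi_b)^2 / ((\phi_a^\top M \phi_a)(\phi_b^\top M \phi_b))$,
assigned greedily in descending MAC with ties broken by frequency gap and
a 0.7 acceptance threshold. Across meshes (e.g. before/after ablation) the
identity-weighted MAC on the shared nodes is used instead, since the mass
matrices differ.

## The toy structure

The measured specimens and CT meshes behind the original study are not
deposited, so validation runs on a parametric *toy* ear-bone complex that
reproduces the load path rather than the anatomy: a fixed slab (periotic)
carries, through two slender flexible struts (pedicles), a stiff open-top
shell (bulla) with a raised ridge (sigmoid process); a malleus block is
fused to the shell wall and continues through stiff ligaments to incus and
stapes, the stapes resting on a soft annular ligament.

The geometry is a voxel lattice whose occupied cells are split into six
Kuhn tetrahedra. This construction is exactly conforming across component
boundaries — no node merging, no tolerance games — and every label,
element count, base node and tap-location coordinate is known by
construction. The deliberate departures from a "real" bulla and their
reasons:

* **Box shell, not hemisphere.** A curved-shell union mesh would need
  node matching across non-matching interfaces; the box shell has the same
  topology (stiff bowl on flexible hinges) and the same modal taxonomy.
  A smooth downward doming of the floor (default 0.8 of a cell) breaks
  the box symmetry so eigenvalues are simple and MAC tracking is
  unambiguous.
* **Wall thickness 0.5 of the lattice pitch** (4–5 mm at the default
  1 cm pitch). This places the first dozen shell plate modes between
  ~120 Hz and ~8 kHz — the band where the measured resonances sit —
  rather than pushing them above 10 kHz as full-pitch walls would.
* **Single-cell ossicles on single-cell ligaments.** With the literature
  ligament stiffness (1 MPa) this yields many chain-localized modes
  interleaved with the structural ones — which is exactly the situation
  the original analysis deals with by defining its mode numbering on the
  modes *present with and without the ossicular chain*. The ablation
  machinery (`remove_components()`, `strain_energy_fractions()`,
  `ablation_compare()`) classifies them the same way: modes holding
  ≥ 90% of their strain energy in the chain disappear when incus and
  stapes are removed; modes with ≤ 10% persist with MAC ≥ 0.9 and
  frequency shifts below 5%.
* **Ablation convention.** Removing `{incus, stapes}` also drops the
  ligament elements that lose a bony anchor and any fragment disconnected
  from the main body; without this the reduced model contains floating
  soft bodies and the constrained stiffness matrix is singular. This
  mirrors the physical specimens, whose inter-ossicle ligaments were
  absent.
* **89 tap locations** are sampled on the outer shell surface — the
  number of designated tap stickers in the measured protocol.

## The tap-test pipeline

A recording session is, per tap location, at least 20 strikes observed by
8 microphones (anterior, posterior, lateral, proximal, four ventral).
Processing follows the measurement convention: detect onsets, coherently
sum the aligned tap segments, Fourier transform, normalize each channel at
15 kHz, and average normalized power across locations in the *linear*
power domain (dB only at display time — the averaging domain is not stated
by the original description and is a declared choice here).

Numerical choices that matter:

* **Onset detection**: channel-summed absolute signal smoothed 1 ms;
  threshold median + 8·MAD; 100 ms refractory. A hysteresis gate requires
  one quiet 5 ms block (maximum envelope below median + 4·MAD) between
  onsets, because the slowly decaying oscillatory ring-down of a
  ~100 Hz mode re-crosses any simple threshold for hundreds of
  milliseconds. The 5 ms block spans at least one oscillation peak for
  modes above ~110 Hz, the band of interest.
* **Alignment**: integer-lag cross-correlation to the first segment with
  parabolic sub-sample refinement applied as an FFT phase shift. Stacking
  N repetitions raises the planted-peak power against incoherent noise by
  ~10·log₁₀N (≈ 13 dB for N = 20), which the acceptance suite measures
  over 20 seeds.
* **Windows and bins**: rectangular window, default 0.5 s or the smallest
  inter-onset gap; FFT length the next power of two; readouts by nearest
  bin. The end-to-end recovery loop uses a 62.5 ms window (11.7 Hz bins):
  at the synthetic damping $\zeta = 0.01$ a peak at frequency $f$ has
  half-power width $2\zeta f$ (≈ 160 Hz at 8 kHz), so fine bins add
  variance but no information, and coarse bins make the one-bin recovery
  criterion meaningful across the whole ladder.
* **Peak picking** runs on the channel-mean power in dB with a
  topographic-prominence threshold (default 6 dB). Raw maxima closer than
  2 bins collapse into a single peak flagged `merged` — two modes inside
  the resolution limit cannot be told apart, and the flag records that.
* **Amplitude maps** read the normalized power at the bin nearest the
  query frequency, per (location, microphone) — no bandwidth integration.

## The synthetic forward model

`synth_tap_recordings()` builds each tap as a modal superposition
$\sum_k a_k(\mathrm{loc})\, g(\mathrm{loc},\mathrm{mic})\,
e^{-\zeta_k\omega_k t}\sin(\omega_k\sqrt{1-\zeta_k^2}\,t)$
plus a deterministic "contact click" — a damped 15 kHz tone (20 ms decay)
that stands in for the broadband content of a real impact and guarantees a
coherent, noise-dominating reference at the normalization frequency on
every channel. Excitation weights $a_k$ are $|\phi_k\cdot n|$ at the tap
vertex; microphone gains are $\max(|\cos\theta|, 0.1)$ between mic
direction and surface normal — a crude directivity stand-in that is
adequate for rank-correlation scoring, not a radiation model. White
Gaussian noise is added per channel at the specified SNR *relative to that
channel's own first-tap peak* (each microphone keeps the stated SNR;
modeling a channel-independent noise floor instead makes oblique
microphones dominated by normalization noise). Damping exists only in this
forward model — the FEM is undamped — with default $\zeta = 0.01$ for
realistic peak widths; the frequency bias $\sqrt{1-\zeta^2}$ is below
$10^{-4}$.

What a green end-to-end test establishes: the pipeline recovers planted
frequencies to one bin, matches them to the generating modes, and ranks
tap locations consistently with $|\phi\cdot n|$ (Spearman ≥ 0.9, using
rank correlation because radiated amplitude and surface displacement are
monotonically, not linearly, related). What it does not establish:
agreement with any real specimen's absolute frequencies, real radiation
physics, or microphone calibration.

## Scaling, and what is deliberately out of scope

Uniform geometric scaling by $s$ multiplies $K$ by $s$ and $M$ by $s^3$,
so every frequency divides by $s$ exactly — the basis of the 1.2-scaling
experiment, reproduced here to $10^{-6}$ relative. Mode shapes are
unchanged (MAC ≥ 0.999).

Not modeled: damped or complex modes, prestress, anisotropy, acoustic
radiation and room acoustics, CT segmentation/meshing, microphone
calibration, and statistical testing of left/right offset direction. The
left/right machinery (`left_right_offset()`) only quantifies per-mode
offsets between two matched peak lists.

## Known limitations

* The fixed-base selector ("nodes of the periotic within δ of its base
  plane", δ defaulting to 5% of the component's bounding-box diagonal) is
  a declared convention; the original study does not state which nodes
  were clamped.
* Lattice geometry quantizes component shapes to the voxel pitch; the toy
  is a physics fixture, not an anatomical model.
* T10 accuracy claims hold for straight-sided elements only.
* The merged-peak flag is a resolution heuristic (cluster distance of two
  bins); heavily overlapped Lorentzians that produce a single raw maximum
  are reported as one unflagged peak.
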