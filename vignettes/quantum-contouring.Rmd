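---
title: "Quantum contouring methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum contouring methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qontour)
```

qontour implements three quantum formulations of grayscale organ contouring
as exact classical simulations. This vignette is the package's account of
the underlying models, the parameters that matter, the numerical choices
made where the published descriptions are ambiguous, and what the synthetic
phantoms can and cannot tell you about clinical data.

## Raster conventions

All arrays are 1-based and ordered (row, column) in 2D and
(row, column, slice) in 3D. Voxel spacing is carried in millimetres;
NIfTI-1 is the interchange format (masks as unsigned 8-bit 0/1), PNG is
accepted for 2D toys. `zscore_normalize()` uses the population
(divide-by-N) standard deviation. Connected components use 8-connectivity
in 2D / 26 in 3D; hole filling uses the complementary 4/6 background
connectivity, so a closed foreground surface and the cavity it encloses are
never simultaneously "connected" across a diagonal.

## The synthetic phantoms

The reference data for methods of this kind are abdominal MR volumes, which
are not redistributable; the generator emulates their statistical structure:
one bright ellipsoidal organ (mean 200, arbitrary units) over darker tissue
(mean 80), additive Gaussian noise, a smooth multiplicative bias field (a
product of half-period cosines per axis, rescaled to `1 ± amplitude`), an
optional distractor sphere, and three contrast phases implemented as organ
intensity multipliers (pre-contrast 1.0, arterial 1.3, venous 1.15 — fixture
constants, not claims about MR physics). Markers standing in for an external
AI prediction corrupt the ground truth by erosion, dilation, or seeded flips
of exactly `round(error_rate × n_boundary)` boundary voxels; flips are drawn
as a prefix of one seeded permutation, so marker quality degrades
monotonically in the error rate.

What the phantoms deliberately lack: anatomical texture, multiple organs
with overlapping intensity distributions, partial-volume boundaries, and
scanner-dependent artefacts. Passing recovery tests on phantoms therefore
demonstrates algorithmic correctness and the methods' *relative* behaviour,
not clinical performance; on real abdominal MR both intensity-only methods
(QIS-Net, QCuts) are known to degrade far more than any phantom shows.

The package's *standard cohort* (`standard_cohort()`) fixes the study
conditions for method comparison: 48×48 slices, noise sd 15, 15% bias, and
a second near-liver-intensity structure (mean 185) that emulates the
neighbouring-organ isointensity which defeats intensity-only segmentation;
phases cycle across cases. These values were chosen once as a plausible
"hard but solvable" regime and are not tuned per experiment.

## QIS-Net

The network maps each pixel and its eight neighbours into a qutrit-like
three-level system via a **multi-class gray-level transition row**
(`qisnet_transition_table()`): intensity is min-max scaled to `[0, 1]`,
quantized into 8 levels, and translated to angles
`a = (π/2)·F[level]`. Per pixel the features are the membership angles
`α_j = π/2 − (a_k − a_j)` (the edge detector: `π/2` in flat regions), the
threshold angle `γ = 2π Σ_j a_j`, the frequency
`ω = 2π(2π − Σ_j (a_j − a_k))`, the 3×3 cardinality `B` with amplitude
`A = 2πB`, the aggregated input `x = Σ_j a_j cos(ω − A)`, and the per-pixel
gray-level index `λ_ω`.

Several of the published index conventions are internally inconsistent; the
package fixes one reading and keeps it auditable:

* **Neighbourhood sums** run over the eight 3×3 offsets (the text's
  `j ∈ {1…8}`), with border pixels given eight neighbours by edge
  replication.
* **λ_ω** is the transition-row interval width selected by the quantization
  bin of the 8-neighbour sum, rescaled by the row's largest interval onto
  `(0, 1]` and floored at `1e-6` so the activation
  `σ(x) = 1/(λ_ω + e^{−ν(x−β)})` stays finite.
* **The input–output relation** of the two rotation layers is implemented in
  a single internal function (`qisnet_coupling`):
  `z_t = σ(x_t) · (1/8) Σ_j cos(α_{t,j} − γ_t) e^{i s_j}`, where `s_j` is
  the neighbour's previous population; the measured population is `|z_t|²`
  clamped to `[0, 1]`. The `1/8` normalization keeps the population scale
  commensurate with the unit interval.
* **Translated angles feed γ and α.** Using raw binary intensities would
  make `γ` an exact multiple of `2π` on two-level images and the coupling
  identically zero — a dead network; the translation step is precisely what
  the transition table is for.
* **β defaults to 0.5** (the sigmoid midpoint after min-max scaling); no
  published value exists. `ν` defaults to 0.04 and is swept over
  `{0.02, 0.03, 0.04, 0.05}` with per-case selection by Dice, mirroring the
  published per-patient optimization.
* **Convergence**: stop when the mean absolute population change drops
  below `1e-4`, or after 50 iterations. On constant inputs the dynamics
  reach a fixed point after one iteration because the population magnitude
  is phase-invariant there.
* **Transition rows**: the eleven published rows are shipped verbatim; the
  row reported as consistently best (`0, 0.04, 0.28, …`) differs from
  printed row 2 (`0.14` vs `0.04`) and is shipped additionally as row 12,
  the default. Neither variant is guessed to be a typo of the other.
* **3D volumes** are processed slice-wise (the network is defined on 2D
  8-neighbourhoods) and restacked before 3D post-processing.

Binarization takes the highest of a 4-level Otsu split of the converged
population map; an empty result returns an empty mask with a warning
attribute rather than an error. Because inputs are min-max scaled first, the
output is invariant to adding a constant to the raw image.

## NAQSS encoding and Grover search

`naqss_encode()` quantizes intensities to `M` levels (uniform min-max
binning, default `M = 256`), maps level `i` to `a_i = (π/2)(i−1)/(M−1)`,
and normalizes into amplitudes `θ_i = a_i/√(Σ a²)`. Location basis states
concatenate per-axis coordinate bits (each axis padded to the next power of
two, first axis most significant); padded states carry amplitude 0 and
label 0. An all-minimum image has no normalizable encoding and raises a
degenerate-encoding error. A label qubit `χ_i` marks candidate foreground
from the supplied marker.

`grover_iterate()` simulates amplitude amplification on the real amplitude
vector: phase-flip of marked amplitudes followed by reflection about the
mean. No gate decomposition is simulated in the main path — the published
experiments themselves ran the algebraic form classically — but an
independent statevector oracle (Hadamard tensor powers, diagonal Z-oracle,
`H^{⊗n}(2|0⟩⟨0|−I)H^{⊗n}` diffusion) exists for cross-checking at ≤ 12
qubits, and the test suite verifies the simulated success probability
against the analytic rotation `sin²((2k+1)·asin√(r/N))` to `1e-9` across
`N ∈ {4,…,64}`.

The published expression for the initial angle is typographically garbled;
the package uses `φ = arctan((A₀/L₀)·√(r/(N−r)))`, the only reading that
reduces to the textbook rotation for uniform amplitudes (`A₀ = L₀` gives
`φ = α`, hence `t ≈ (π/4)√(N/r)`, e.g. `t = 25` at `N = 1024, r = 1`).
Fractional `t` is rounded half-up and floored at 0; `r = N` short-circuits
to `t = 0`.

**Recovery** follows the structure of the encoding: measuring the label
qubit projects onto the marked subspace (the foreground state
`|ψ_g⟩ = Σ_{i∈A} a_i |i⟩|1⟩`), and within it states with squared amplitude
above the uniform level `1/N` are kept. Consequently unmarked states are
never recovered, and marked states whose amplitude stays at zero (exact
minimum intensity) are dropped — which is why a slightly corrupted marker
can yield *higher* Dice after Grover than the marker itself: dark false
marks vanish. With a `superpixel_graph` the encoding runs at superpixel
granularity (a superpixel is marked when the marker covers the majority of
its voxels) and recovered labels broadcast back to member voxels.

## QCuts

`build_superpixels()` partitions the volume by Lloyd k-means over
`(intensity, compactness-scaled coordinates)` with deterministic
regular-grid initial centres (the published work names no superpixel
algorithm); empty clusters are dropped, so the final count is approximately
the requested `n`. The graph is fully connected with Gaussian weights; the
bandwidth `σ` defaults to the standard deviation of pairwise mean
differences, falling back to 1 for constant images.

The energy is implemented exactly as the quadratic form whose Rayleigh
quotient it is: `E(y) = yᵀ(U + λ(D − W))y / yᵀy`, with `U` the diagonal
seed indicator, `D` the weighted degree matrix, and the binary term summed
over ordered pairs (the brute-force oracle in the tests uses the same
convention). `λ = 1` by default, per the published assumption. The printed
unary term does not state how the indicator interacts with `z`; the
quadratic-form reading was chosen because it makes the eigen route and the
discrete enumeration minimize the *same* functional, so the relaxation gap
is well-defined and is reported (`solution$energy` vs the enumerated
minimum; the continuous Rayleigh value is a certified lower bound).

The smallest eigenvector `z` is oriented so the mean seed component is
non-negative; labels are `y_i = 0` for `|z_i| < 1e-12`, else `+1`/`−1` by
the highest 4-level Otsu split of `z²` (largest-gap midpoint when `z²` has
fewer than four distinct values). Since the unary term *penalizes*
amplitude on seeds, the minimizer concentrates `z` away from them, and the
**foreground is the label class holding the majority of the seeds** (the
low-`z²` side). Seeds default to `max(1, 5%)` of superpixels with the
lowest mean intensity — the published rule, suited to dark targets; the
`invert_seeds` flag selects the highest-mean superpixels instead for bright
organs. For the noiseless recovery experiment the seed count is set to
roughly the organ's superpixel share (16 of 64): with only a handful of
seeds, the many exactly-identical background superpixels of a noiseless
two-level image make the ground state degenerate and the cut arbitrary;
covering the organ resolves the degeneracy. This is an experiment
configuration, not a change to the defaults.

## Post-processing and metrics

Every method ends with largest-connected-component extraction (ties broken
toward the smallest linear voxel index) and hole filling; both operators
are idempotent and the result has at most one component. Dice is defined 1
for two empty masks; the Hausdorff distance is the max of the two directed
boundary-set distances (Euclidean, voxel units unless spacing is supplied,
`Inf` with an empty mask). The 4-level Otsu threshold maximizes
between-class variance exactly, via dynamic programming over a 256-bin
histogram — equivalent to exhaustive search over all threshold triples.

## Resource accounting

`naqss_qubits()` reports `⌈log₂(Π dims)⌉ + 1` qubits,
`classical_storage()` uses decimal megabytes (`8×10⁶` bits), and
`annealer_logical_qubits()` is the identity on the superpixel count. These
reproduce the published figures for 1024×1024×72 (28 qubits, ~2.42 Gb,
~302 MB) and 64×64 (13 qubits). Physical-qubit embedding on real annealer
topologies is out of scope.

## Problem sizes and determinism

The shipped tests and the acceptance script use 48×48 (2D) and small 3D
phantoms, 64-superpixel graphs, Grover grids up to `N = 1024`, and
enumeration oracles up to 8 graph nodes / `3^8` labelings — sizes at which
every oracle is exact and the full suite runs in well under a minute.
Every stochastic component (phantom noise, marker flips, cohort seeds) is
driven by explicit integer seeds; all three segmentation methods are
deterministic given their inputs.

## Known limitations

* QIS-Net's converged population map is near-binary on phantoms but highly
  sensitive to noise and to the transition row; this fragility is a
  property of the method, observed in the original evaluation as well, and
  the cohort comparison reflects it.
* The Grover path recovers essentially the marker it is given (that is the
  algorithm's published behaviour — search, not discovery); its value is
  the encoding/retrieval demonstration and the resource arithmetic.
* QCuts sees only superpixel mean intensities: structures isointense with
  the organ are indistinguishable before post-processing, and the
  eigen-relaxation can be loose on adversarial graphs — the gap is always
  reported, never hidden.
* The phantom generator does not simulate MR acquisition; absolute Dice
  values on phantoms say nothing about clinical accuracy.
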