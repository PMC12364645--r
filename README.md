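# qontour

Classically simulated quantum and quantum-inspired contouring algorithms for
grayscale medical images, with synthetic abdominal phantoms, shared
post-processing, Dice/Hausdorff evaluation, and quantum-resource accounting.

## The problem

Auto-contouring of organs (here, the liver in abdominal MR) is a routine step
in radiotherapy treatment planning. Several quantum formulations of the
segmentation problem exist, each targeting a different hardware paradigm, but
none can be meaningfully run at clinical scale on today's devices. This
package implements three of them as exact classical simulations so that
medical-physics and imaging researchers can study their behaviour,
hyperparameters and failure modes on reproducible synthetic data:

1. **QIS-Net** (quantum-inspired): a self-supervised qutrit fuzzy network.
   Each pixel neighbourhood is translated into a three-level quantum-like
   system through a multi-class gray-level transition row
   `F ∈ [0, π/2]`; membership angles `α_j = π/2 − (a_k − a_j)` couple a pixel
   to its eight neighbours, and the population `|⟨z|z⟩|²` of the output
   neuron is measured after a forward/backward rotation pair `R(θ), R(−θ)`.
   Foreground/background is decided by the quantum sigmoid
   `σ(x) = 1 / (λ_ω + e^{−ν(x−β)})` with a per-patient sweep of the
   steepness factor `ν ∈ {0.02, 0.03, 0.04, 0.05}`.
2. **NAQSS + Grover** (gate-based): the image is encoded as a Normal
   Arbitrary Quantum Superposition State, `|φ_χ⟩ = Σ_i θ_i |i⟩|χ_i⟩`, with
   `θ_i = a_i / √(Σ a²)`, `a_i = (π/2)(i−1)/(M−1)`, one label qubit `χ_i`
   marking candidate foreground (an external marker standing in for an AI
   prediction), so an image with `2^n` pixels needs `n + 1` qubits. Grover
   amplitude amplification (oracle phase flip + reflection about the mean)
   is run for `t = round((π/2 − φ)/ω)` iterations, `ω = cos⁻¹(1 − 2r/N)`,
   and the marked set is recovered from the amplified amplitudes.
3. **QCuts** (annealing-style): superpixels become nodes of a fully
   connected graph with Gaussian intensity-similarity weights
   `w_ij = (σ√2π)⁻¹ e^{−|S_i−S_j|²/2σ²}`; segmentation minimizes
   `E(y) = E_unary(y) + λ E_binary(y)` with the binary term
   `Σ w_ij (z_j² − z_i z_j) / Σ z²`. The ground state is found by taking the
   smallest eigenvector of the energy matrix — the classical stand-in for
   quantum annealing — and labels come from `y = z ∘ z`.

All three share the published post-processing (largest connected component,
hole filling, 4-level Otsu thresholding with the highest threshold) and are
evaluated by the Sørensen–Dice coefficient `DSC = 2|X∩Y|/(|X|+|Y|)` and the
Hausdorff distance between boundary sets.

Because the clinical dataset behind the original study is restricted, the
package ships a seeded phantom generator: a bright ellipsoidal "liver" over
darker tissue with additive noise, a smooth multiplicative bias field,
contrast-phase intensity scalings, and optional distractor structures, plus
corrupted marker masks (eroded / dilated / boundary-noise) standing in for
AI predictions.

## Worked example

```r
library(qontour)

ph <- generate_phantom(phantom_spec(shape = c(48, 48), noise_sd = 12,
                                    bias_amplitude = 0.1,
                                    phase = "arterial", seed = 42))
ph$image
#> <image_volume> 48 x 48 | spacing (mm): 1, 1 | range: [36.74523, 325.1491]

marker <- make_marker(ph$truth, marker_spec("noisy", error_rate = 0.1,
                                            seed = 42))
res <- grover_segment(ph$image, marker)
res$plan
#> <grover_plan> N = 4096, r = 650 | omega = 0.8194583, phi = 1.387672 -> t = 0

eval_record("grover", res$mask, ph$truth, case_id = "demo")[,
  c("case_id", "method", "dice", "hausdorff")]
#> # A tibble: 1 × 4
#>   case_id method  dice hausdorff
#>   <chr>   <chr>  <dbl>     <dbl>
#> 1 demo    grover 0.995         1
```

The plan says the 48×48 slice pads to `N = 4096` basis states of which
`r = 650` are marked; the marked amplitudes already dominate the encoding
(`φ` close to `π/2`), so zero amplification rounds are needed, and the
recovered mask agrees with the ground truth at Dice 0.995 — slightly above
the raw marker, because near-zero-amplitude false marks are dropped.

Resource accounting for a full clinical volume:

```r
resource_report(c(1024, 1024, 72), bit_depth = 32, n_superpixels = 256)
#> # A tibble: 1 × 6
#>   n_pixels location_qubits total_qubits storage_bits storage_megabytes
#>      <dbl>           <int>        <int>        <dbl>             <dbl>
#> 1 75497472              27           28   2415919104              302.
#>   annealer_logical_qubits
#> 1                     256
```

i.e. ~2.42 Gigabits (~302 MB) classically versus 28 NAQSS qubits, and 256
annealer variables at 256 superpixels.

The other two methods run the same way: `qisnet_sweep(img, truth)` returns
the best-Dice mask over the `ν` sweep, and
`qcuts_segment(img, n_superpixels, invert_seeds = TRUE)` points the seed
rule at a bright organ. `run_cohort(standard_cohort())` compares all methods
on a noisy phantom cohort and returns tidy per-case records
(`tidy()`/`glance()`/`autoplot()`).

A thin CLI wrapping these functions lives at `inst/cli/qontour.R`
(subcommands `generate`, `qisnet`, `grover`, `qcuts`, `eval`, `resources`,
`cohort`).

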