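# polstates

Conformational-state analysis of single-molecule fluorescence polarization
recordings.

Membrane transporters such as the arginine/agmatine antiporter AdiC cycle
through several conformations whose structural differences amount to helix
rotations of tens of degrees — angstrom-scale motions on millisecond
timescales. A bifunctional rhodamine cross-linked to a surface helix
reports these motions through the orientation (θ, φ) of its emission
dipole, which a TIRF polarization microscope encodes in four
simultaneously recorded polarized intensities I₀, I₄₅, I₉₀, I₁₃₅.

`polstates` implements the complete analysis from camera counts to an
energetic model of the protein:

1. **Camera calibration and photon conversion** — EMCCD gain/offset from
   the I·Δt = 2G·SNR² + offset line; counts → photons with background
   subtraction and quantum-efficiency correction.
2. **Changepoint detection** — orientation transitions found by a
   four-channel binned-photon log-likelihood-ratio test with recursive
   bisection; thresholds calibrated by null simulation to a 5% per-trace
   false-positive rate.
3. **Orientation solving** — closed-form inversion of the polarized
   intensity model with corrections for photon collection (α), polarizer
   extinction (f), probe wobble (δ = 22.5°) and channel response (g);
   per-event angles from dwell-averaged photons.
4. **State identification** — events embedded on the unit sphere and
   sorted by k-means with simulated annealing and Nelder–Mead refinement;
   the number of resolvable states chosen by the 2.5σ separation
   criterion; false-positive transitions merged; states indexed by the
   shortest-path rule.
5. **Local-frame alignment** — each molecule rotated into the common frame
   defined by its C₁ and C₄ states (mean φ₁ = 0°, θ₁ = θ₄ = 90°), so
   event distributions pool across randomly oriented molecules.
6. **Equilibrium fit** — the eight-state model (four apo + four
   ligand-bound conformations) fitted globally to state probabilities
   across a ligand series by multinomial maximum likelihood:

   p_i(L) = (K_i,1 + ᴸK_i,1·L/K_D1) / (Σ K_j,1 + Σ ᴸK_j,1·L/K_D1),

   with per-state dissociation constants K_Di = K_D1·K_i,1/ᴸK_i,1 and
   parametric-bootstrap 95% intervals.
7. **Structure matching** — conformational states related to structural
   states (E_O, E_X, I_O, I_X) by rigid-rotation least squares over all 24
   assignments.

A synthetic-data generator reproduces the recordings' statistical
structure (10 ms frames, ~92 photons/frame over four channels, SNR ≈ 7,
exponential dwells, EMCCD excess noise, single-step bleaching, random
molecule orientation), so every stage is verifiable end to end without
experimental data.

## Worked example

```r
library(polstates)

ep <- equilibrium_params(K = c(2.566, 0.923, 0.729),
                         LK = c(1.795, 1.782, 1.250), KD1 = 49)
round(state_probabilities(ep, c(0, 49, Inf)), 3)
#>         p1    p2    p3    p4
#> [1,] 0.192 0.492 0.177 0.140
#> [2,] 0.181 0.395 0.245 0.179
#> [3,] 0.172 0.308 0.306 0.215
round(ep$KD, 1)
#> [1] 49.0 70.0 25.4 28.6
```

At zero ligand the transporter spends half its time in C₂; saturating
arginine shifts occupancy toward C₃ while the occluded states C₁ and C₄
barely move — yet their dissociation constants (49 and 29 µM) are still
determined, because the seven constants are over-determined by the four
binding curves jointly.

A miniature end-to-end run over synthetic recordings:

```r
cfg <- run_config(seed = 5, n_per_conc = 2,
                  concentrations_uM = c(0, 100, 1000), duration_s = 3,
                  n_sim_threshold = 200, n_boot = 10)
m <- run_pipeline(cfg)
m$camera_fit
#> $G
#> [1] 145.9494
#> $offset
#> [1] 223.0565
```

The `analysis/` directory holds the full study as numbered scripts
(`01_simulate.R` … `06_match_structures.R`): simulate a
multi-concentration ensemble, calibrate the camera and the changepoint
thresholds, detect events and sort states per molecule, align and pool
molecules, fit the eight-state model with bootstrap intervals, and match
the recovered state geometry to a structural vector set. Each script
writes its tables under `results/`.

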