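---
title: "Resolving transporter conformations from four-channel fluorescence polarization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving transporter conformations from four-channel fluorescence polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polstates)
```

# The measurement and its model

A membrane protein such as the arginine/agmatine antiporter AdiC moves
between conformational states by reorienting its secondary structure on
angstrom and millisecond scales. A bifunctional rhodamine cross-linked to a
surface helix reports the helix orientation through its emission dipole,
described by an inclination `theta` from the optical axis and an in-plane
rotation `phi`. A TIRF polarization microscope splits the collected
fluorescence into four polarized components (0, 45, 90, 135 degrees)
recorded simultaneously on an EMCCD camera; the four intensities jointly
encode the full 3D dipole orientation.

The forward model for the expected intensity in channel `psi` is

$$I_\psi = \tfrac14 g_\psi I_{tot}\left[X_4(\delta)\left(\sin^2\theta\,
\big(f_\psi X_1(\alpha)\cos 2(\phi-\psi) + X_2(\alpha)\big)
 - \tfrac23 X_2(\alpha)\right) + X_3(\alpha)\right]$$

with corrections for incomplete photon collection by the objective
(coefficients `X1`-`X3`, closed forms in the collection half-angle
`alpha`), polarizer extinction (`f_psi`, one per channel), sub-frame wobble
of the probe in a cone of half-angle `delta` (`X4 = cos d (1+cos d)/2`),
and unequal channel response (`g_psi`, the 90-degree channel being the
reference). `delta` defaults to 22.5 degrees, its experimentally estimated
value for this label chemistry; `alpha` has no default because it is an
instrument property (the synthetic instrument in this package uses 70
degrees; an NA 1.49 oil objective corresponds to roughly 79 degrees).

## Inversion

`phi` has a closed-form arctangent solution in the two channel differences.
Given `phi`, the forward model is linear in `(I_{tot}, I_{tot} X_4
\sin^2\theta)`, so the package solves the remaining two unknowns by linear
least squares over the four channels. This is the exact algebraic inverse
for noiseless input and a natural estimator when photon noise makes the
4-by-2 system inconsistent; it also remains defined at in-plane angles
where individual channel-pair formulas degenerate. When noise pushes
`sin^2 theta` above 1 the event is reported at `theta = 90` and flagged;
the measured angles carry the four-fold degeneracy
`(theta, 180-theta) x (phi, 180+phi)`, resolved per molecule by minimizing
the angular variance of its events and mapping the result into one quarter
sphere.

A key property the tests exercise heavily: the inversion is exact to 1e-6
over the whole angle grid for any valid parameter set, and `theta`
precision degrades sharply as `theta` approaches 90 degrees, where
`sin^2 theta` saturates. The synthetic molecule orientations are therefore
drawn with substantial tilts (uniform 15-45 degrees by default), matching
flexibly tethered molecules whose inclination "varies considerably".

# Camera model

EMCCD counts relate to photoelectrons by `I dt = G N + offset`; electron
multiplication adds multiplicative noise that scales the shot-noise
standard deviation by `sqrt(2)`, so the effective SNR of a frame with `N`
photons is `sqrt(N/2)` and `I dt = 2 G SNR^2 + offset`. The generator
implements the excess noise by drawing per-electron Gamma gain (shape 1,
mean `G`), which reproduces the `2 G^2 N` count variance exactly.
Calibration fits the `I dt` versus `SNR^2` line; the offset is carried by
the dim illumination levels, so the fit weights levels by the inverse
photon rate, and the packaged calibration design uses 1-20 photons/frame.
Conversion back to photons subtracts the offset and background and divides
by the gain and quantum efficiency (0.95); negative per-frame photon
estimates are retained so event averages stay unbiased.

# Changepoint detection

Orientation changes are detected from the binned photon counts of all four
channels with a log-likelihood-ratio test: for a segment of `T` frames
with channel totals `N_r` and cumulative counts `m_r` before candidate
frame `tau`,

$$LLR(\tau) = \sum_{r=1}^{4} m_r\ln\frac{m_r}{\tau}
 + (N_r - m_r)\ln\frac{N_r-m_r}{T-\tau} - N_r\ln\frac{N_r}{T}.$$

Detection is recursive: the trace-wide argmax is accepted if it exceeds a
threshold, then both sides are searched, until no supra-threshold point
remains. Ties break toward the earlier frame. Thresholds are calibrated by
simulation of constant-orientation traces at the working SNR — including
the EMCCD excess noise, which roughly doubles LLR values relative to pure
Poisson counts — so that the per-trace false-positive rate is 5%;
the thresholds are tabulated over a grid of segment lengths, interpolated
in log-length, and forced monotone in length (an extreme-value property of
the null maximum). Detection runs on unfiltered photon counts; the 7.5 Hz
zero-phase Gaussian filter (`gaussian_smooth`) is for display only, and is
applied only after temporal information has been extracted.

With exponential dwell times a sizeable fraction of dwells is only a few
frames long; those transitions are genuinely missed at any threshold that
maintains the 5% false-positive rate, and the affected events carry
mixed-state averages. Downstream steps are designed to tolerate this
contamination (robust widths, outlier set-aside, event merging).

# State identification

Event orientations are embedded on the unit sphere
(`x = sin t cos p, y = sin t sin p, z = cos t`) so that both angles
contribute with equal weight, and partitioned by nearest-neighbour distance
to `k` unit-norm cluster means, minimizing the summed squared Euclidean
distance. The optimizer couples k-means descent with simulated annealing
restarts (geometric cooling 0.95 over up to 50 temperatures, 20 restarts;
improving moves are polished by short k-means descents and a stagnating
walk stops early) and a final Nelder-Mead refinement over the means'
spherical coordinates; on problems small enough to enumerate it matches the
exhaustive optimum, and it is deterministic given a seed.

## How many states?

`k` is examined one value at a time; the largest `k` wins for which every
pair of state populations is separated by at least 2.5 pooled sigma. Two
implementation decisions matter here, and both were made on statistical
grounds:

* **Directional width.** `theta` and `phi` are measured with very
  different precision, so a pair of states separated cleanly along the
  precise direction must not be vetoed by noise in the orthogonal one. The
  pairwise criterion therefore measures the pooled width of the two
  populations along the direction connecting their means (a tail-robust
  MAD-based spread of the projected deviations).
* **Measurement floor.** With a few dozen events per molecule, a chance
  pair of tight sub-clusters inside one true state can look "separated";
  but no state population can be narrower than the angle-measurement noise
  of its events. Each state's directional width is therefore floored at a
  parametric Monte-Carlo estimate of the solver's sampling spread for a
  typical member event (Poisson photons, EMCCD excess noise, re-solved and
  folded onto the nearest degeneracy branch). The Monte-Carlo route is
  essential near `theta = 90`, where a delta-method (linearized) error
  estimate diverges while the actual estimator spread stays bounded.

Clusters stranded with fewer than 3 events are treated as stray
contaminated dwells: they are set aside (at most 30% of events, matching the contamination level implied by the detector's miss rate on short dwells) and the
remaining events are refitted, so a real state is not starved of a cluster
by a handful of mixed-average events. Consecutive events assigned to the
same state are merged — such transitions are the expected changepoint
false positives — with photon-weighted means and re-solved orientations.
When no photon-level measurement model is available (geometry-only use),
the criterion falls back to an isotropic pooled width estimated from the
global spread minus the between-means term, which is immune to the
assignment-truncation bias that otherwise understates widths for
marginally separated or over-split populations.

States are indexed by the shortest-path rule: among all orderings of the
`k` means, the one minimizing the excess of the cumulative adjacent-state
path over the end-to-end distance. The two traversal directions tie
exactly; the endpoint with the larger z-component becomes state 1. This
makes indexing reproducible across molecules; biological identity is
assigned later by structure matching.

# Local-frame alignment

Each molecule sits on the coverslip in its own orientation, so lab-frame
state angles cannot be pooled across molecules. The package rotates each
4-state molecule into a local frame defined by its own ordered state
means: local x along the state-1 mean, the state-1/state-4 plane as the
x-y plane, z perpendicular. By construction, mean `phi_1 = 0` and mean
`theta_1 = theta_4 = 90` in every molecule, and all local-frame statistics
are invariant to arbitrary lab-frame rotations (property-tested with
random rotations). Pooling is event-level by default, with a per-molecule-
mean variant and optional dwell weighting. `phi` uses circular statistics;
`theta` arithmetic ones.

Two degeneracy consequences surface here and are handled explicitly.
First, event-level branch resolution can strand an entire state in the
mirrored branch when states are tens of degrees apart; after clustering,
each state's events are re-folded through the branch that brings the state
mean closest to the resultant of the other states
(`repair_state_branches`). Second, the handedness and traversal direction
of one molecule's state sequence are fundamentally unobservable from
polarization alone, so roughly half of the molecules come out indexed
backwards; `harmonize_molecules` registers every molecule against the
ensemble consensus over the eight-element relabel/mirror/in-plane-flip
group before pooling or occupancy statistics. The consensus itself is
still only defined up to one global reversal — with real data, structure
matching assigns the absolute identity; the synthetic study registers the
direction against the generator's ground truth. Pairwise state geometry is summarized by the
direct angles `Omega = acos(v_i . v_j)`, and a rotation `Omega` of a site
`r` from the pivot corresponds to a chord displacement `2 r sin(Omega/2)`
(1.7 and 3.5 Angstrom for 5 and 10 degrees at 20 Angstrom).

# Equilibrium model

With four conformations that all bind ligand, the minimal scheme has eight
states: apo `C1..C4` with constants `K_{i,1} = [Ci]/[C1]` and bound forms
with constants `LK_{i,1}`, connected by per-state dissociation constants
`K_{Di} = K_{D1} K_{i,1} / LK_{i,1}` (thermodynamic cycle). The
probability of conformation `i` at ligand concentration `L` is

$$p_i(L) = \frac{K_{i,1} + LK_{i,1}\, L/K_{D1}}
  {\sum_j K_{j,1} + \sum_j LK_{j,1}\, L/K_{D1}},$$

interpolating monotonically between `p_i(0) = K_{i,1}/\sum K` and
`p_i(\infty) = LK_{i,1}/\sum LK`. The seven free parameters (three `K`,
three `LK`, `K_{D1}`) are fitted globally to all four occupancy curves at
once by maximizing the multinomial log-likelihood of the per-concentration
state counts, in log space (positivity) from multiple random starts. The
system is overdetermined, so the `K_D` of states whose occupancy barely
moves with ligand is still constrained by the curved states. Probabilities
are dwell-time-weighted occupancies by default (event-count fractions as an
option; which estimator the original analysis used is not stated).
Confidence intervals are parametric bootstrap: `n_boot` datasets simulated
from the fitted model at the observed per-concentration totals, refitted,
percentile 2.5/97.5. Model-based simulation is our reading of
"bootstrapped simulated data"; the resulting intervals are strongly
asymmetric for the `K_D`s, as expected when a midpoint is constrained by a
handful of concentrations.

# Structure matching

To relate conformational states to structural states (externally
open/occluded, internally open/occluded — `E_O, E_X, I_O, I_X`), the four
local-frame state vectors are fitted to four structural helix-axis unit
vectors by a rigid rotation (orthogonal Procrustes with determinant +1, no
reflection, no scaling) for each of the 24 possible assignments; the
assignment with the largest `1/LSc` wins. Structural vectors are inputs
(CSV of labelled vectors); extracting helix axes from atomic coordinates
is out of scope. Since the deposited structural vectors are not bundled
with this package, the shipped analysis plants a known permutation in a
synthetic structural set and verifies it is recovered.

# The synthetic-data generator

Every stage is validated against simulations that emulate the recordings'
statistical structure:

* 10 ms frames; 92 detected photons per frame summed over four channels
  (effective SNR about 7), constant per molecule, scaled by the stationary
  state mixture;
* per-state expected channel intensities from the forward model at the
  lab-frame orientation of the current state, plus optional background;
* Poisson photoelectrons with per-electron Gamma gain (EMCCD excess
  noise), gain 146, offset 220, QE 0.95;
* four dipole orientations in the local frame with pairwise separations of
  16-40 degrees (within the 10-40 degree range typical of helix
  reorientations and above the 2.5-sigma resolution limit of roughly 10
  degrees at sigma 4, so that a correct pipeline is expected to resolve
  all four); the middle states differ slightly in inclination so the state
  sequence direction is identifiable (a perfectly palindromic arrangement
  would make it unobservable);
* a reversible continuous-time Markov chain whose stationary law equals
  the eight-state model probabilities at the trace's concentration
  (detailed-balance rates proportional to `sqrt(p_j/p_i)`); dwell times
  are exponential with a 350 ms mean (the dwell distribution is not
  reported and is configurable; 350 ms yields roughly 20 events in a 7.2 s
  recording). Four arbitrary per-state dwell means cannot coexist with
  detailed balance, so the rate scale matches the occupancy-weighted mean
  dwell;
* single-step photobleaching at an exponential time, after which only
  background is emitted;
* random in-plane molecule rotation plus a uniform 15-45 degree tilt of
  the molecule axis (flexible tether; this also keeps dipoles away from
  the `theta = 90` rim where inclination precision collapses);
* default ligand series 0, 10, 25, 50, 100, 250, 750, 3000 uM, log-spaced
  around the reference `K_D` range, with the reference equilibrium
  constants (2.566, 0.923, 0.729; 1.795, 1.782, 1.250; `K_{D1}` 49 uM) as
  ground truth.

What the generator does **not** emulate: spatial image formation (traces
are already particle-integrated), background fluorophores and spectral
crosstalk, intensity drift and blinking, molecule-to-molecule brightness
variation, and any intra-state orientational heterogeneity beyond the fast
wobble absorbed into `X4`. Passing tests therefore demonstrate that the
algorithms recover what the model of the measurement contains; they do not
certify performance on artefacts the model omits.

## Study sizes and numeric choices

The bundled studies use sizes chosen to make their Monte-Carlo error small
relative to the tolerances they are checked against: 2000 simulated events
for angle precision; 2000 training plus 2000 independent test traces of
720 frames for the false-positive rate (binomial s.e. about 0.5 points at
5%); 20 ensembles of 30 molecules, 12 s each, for state-count recovery
(about 30 usable events per molecule; equal state occupancies, the neutral
choice when no concentration is singled out); 1000 bootstrap replicates
for the equilibrium intervals in the full analysis and 120-200 in
fast-running checks. Thresholds: LLR ties break early; `0 ln 0 = 0`;
cumulative counts are clamped to `[0, N]` so camera-noise-negative photon
estimates cannot produce NaNs; `phi` at `theta = 0` is set to 0 and
flagged; events shorter than 3 frames and theta-clipped events are kept in
the event table but excluded from state identification.

# Known limitations

* Kinetics are out of scope: dwell-time distributions and rate constants
  are neither estimated nor modelled beyond the equilibrium stationary
  law.
* Per-molecule resolvability depends on where the tether tilt places the
  states relative to the `theta = 90` rim; molecules whose states land
  near the rim legitimately fail the 2.5-sigma criterion, which is why
  ensemble state-count recovery is defined by the modal `k` across
  molecules.
* The changepoint detector misses short dwells by construction at a fixed
  false-positive budget; dwell-weighted occupancies are slightly biased
  toward long-dwell states as a result.
* The structural-state assignment is only as good as the supplied
  structural vectors; with fewer than four distinct orientations the 24
  assignments degenerate.
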