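---
title: "Models and methods: HYSCORE analysis of low-spin ferric heme centers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: HYSCORE analysis of low-spin ferric heme centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyscoreR)
```

## The physical problem

A low-spin Fe(III) heme center is an S = 1/2 electron spin with a strongly
rhombic g-tensor whose principal axes are anchored to the molecular frame:
g_z lies approximately along the heme normal, g_x and g_y in the heme
plane. Nuclei near the iron — the axial water protons, the cysteine
beta proton, the four pyrrole nitrogens, and (in inhibited enzyme) the
coordinating imidazole nitrogen — are coupled to the electron spin through
hyperfine (and, for I = 1 nuclei, nuclear-quadrupole) interactions far too
small to resolve in a CW-EPR spectrum. Hyperfine sublevel correlation
(HYSCORE) spectroscopy recovers them: a four-pulse two-dimensional ESEEM
experiment correlates nuclear transition frequencies across the two
electron-spin manifolds, and the resulting cross-peak pattern, recorded at
several fields across the powder pattern, determines full interaction
tensors. From the tensors follow distances and angles: the package
implements the complete inference chain from spin-Hamiltonian parameters
to active-site geometry, and its inverse stages.

## Spin Hamiltonian and nuclear sub-problems

The simulation model is the standard S = 1/2 Hamiltonian with electron
Zeeman, nuclear Zeeman, hyperfine and (for I > 1/2) nuclear-quadrupole
terms. At the fields involved (0.28–1.2 T) the electron Zeeman term is
four orders of magnitude larger than any hyperfine coupling here
(≤ 10 MHz), so the electron spin is treated to first order: its
quantization axis is u = g·B̂/|g·B̂|, and within each electron manifold
(m_S = ±1/2) the nucleus evolves under the effective Hamiltonian

H(m_S)/h = m_S (uᵀA)·I − ν_I B̂·I + I·Q·I,

which is diagonalized exactly (2×2 for I = 1/2, 3×3 for I = 1). For I = 1
the two single-quantum transitions and the double-quantum (dq) transition
are labeled; the dq frequency is the sum of the sq splittings by
construction. Two well-known closed forms serve as independent
cross-checks and live alongside the exact path:

* `closed_form_I12()` — the axial two-spin expressions
  ν_{α,β} = √[(ν_I ∓ A(θ)/2)² + (B(θ)/2)²] with
  A(θ) = a_iso + T(3cos²θ − 1), B(θ) = 3T sinθ cosθ; the test suite
  requires 1e-9 agreement with the exact diagonalization over random
  parameters.
* `dq_estimate()` — the strong-coupling estimate
  ν_dq± = 2√[(ν_I ± A/2)² + K²(3 + η²)], used to seed and sanity-check the
  exact dq frequencies (5% agreement enforced where |A| > 4ν_I and the
  quadrupole is small).

Tensor orientations use passive z-y-z Euler angles: the g-frame matrix of
a tensor with principal values d is Rᵀ·diag(d)·R with
R = R_z(γ)R_y(β)R_z(α). Under this convention an α = 90° rotation
interchanges the x and y principal values in the g-frame, which is how the
two chemically equivalent but 90°-rotated sets of heme nitrogens are
encoded, and it is the convention in which the published tensor tables for
this system were fitted. Axis naming fixes x to the smallest and z to the
largest principal g-value; inputs in another order are re-sorted with a
warning.

Hyperfine coupling signs are not observable in ESEEM frequencies; the
tables' negative nitrogen couplings are carried as given, and
`isotope_rescale()` reports magnitudes with the g-factor ratio sign as an
attribute.

## Orientation selection

At a fixed observer field only molecules whose effective g-value resonates
within the excitation bandwidth contribute. `select_orientations()` draws
orientations from a deterministic equal-area hemispherical grid (no random
numbers, so simulations are exactly reproducible at fixed settings),
computes g_eff per direction, and weights each orientation by its
solid-angle measure times a Gaussian resonance window centred at the
microwave frequency. The window profile was a genuinely open choice — the
original study does not state its selection model — and a Gaussian was
chosen over a boxcar to avoid hard selection edges that imprint artificial
ridge terminations; its FWHM defaults to 25 MHz, the approximate
excitation bandwidth of the 16 ns π-pulse used in the experiments, and is
user-settable. At the extreme g-values this yields the "single-crystal"
cones around the z (or x) axis; at the intermediate g_y position it yields
the closed belt of orientations through the y axis whose polar angle runs
from 90° down to arccos√[(g_y²−g_x²)/(g_z²−g_x²)]. g-strain is not
modeled: the paper reports no strain parameters, and selection widths here
are dominated by the pulse bandwidth.

## Four-pulse engine

`time_domain()` synthesizes normalized echo amplitudes for the sequence
π/2–τ–π/2–t₁–π–t₂–π/2–τ–echo with ideal pulses. Within one orientation the
nuclear propagators U_α(t), U_β(t) of the two manifolds are built either
analytically (Pauli closed form, I = 1/2) or by eigendecomposition
(I = 1), multiple nuclei are combined exactly in the product space (their
manifold Hamiltonians commute across nuclei), and the echo modulation is
the trace of the pathway-selected propagator product. Only the
echo-forming coherence-transfer pathway is retained — electron coherence
of opposite order during the two τ intervals, populations during t₁/t₂
with manifolds exchanged by the π pulse; the counter-rotating pathway
dephases under the inhomogeneous electron linewidth in any real
measurement. With no coupled nuclei the echo is identically 1. τ-dependent
blind spots (suppression ∝ sin(πν₁τ)sin(πν₂τ), helper
`blind_spot_factor()`) emerge from the formula rather than being imposed,
and summing magnitude spectra over several τ values (`sum_spectra()`)
restores suppressed correlations, mirroring experimental practice.

Because multi-nucleus propagation is exact, multi-spin combination
features — e.g. the 2·dq sum peaks of the two equivalent heme nitrogens
near (14, 3.7) MHz — appear in the synthesized traces only when two
equivalent nuclei are actually present; `combination_peaks()` enumerates
the same coordinates from single-nucleus frequencies by rule
(2dq of an equivalent pair, dq sums of distinct pairs, Larmor ± dq
combinations).

Frequency-domain peak maps (`cross_peaks()`) bypass time-domain synthesis:
per orientation and nucleus all cross-manifold correlations are emitted
with amplitudes from the I = 1/2 modulation depth
k = (ν_I B/(ν_α ν_β))² or, for I = 1, eigenvector-overlap products.
Positions are the quantitative contract; I = 1 amplitudes are internally
consistent but not calibrated to published figure intensities, which the
source does not quantify. Quadrants follow the coupling regime
(`classify_regime()`): (+,+) for weak coupling (|A| < 2ν_I), (−,+) for
strong, with a near-cancellation band (default ±25%) around |A| ≈ 2ν_I.

## Processing chain

`process_2d()` reproduces the standard HYSCORE processing sequence:
third-order polynomial baseline subtraction per time trace (first along
t₁, then along t₂ — the order is a documented choice, the published
description does not fix it), Hamming apodization, zero-filling to the
next power of two times a factor (default 2), 2D FFT, magnitude. The
magnitude spectrum of a real trace is centro-symmetric, so `pick_peaks()`
reads the non-negative half-plane; quadrant signs are a matter of
interpretation via the coupling regime, not of the transform.

## Dikanov ridge analysis

For an axial hyperfine tensor both squared correlation frequencies are
linear in cos²θ, so a powder ridge maps to a straight line in the
(ν_α², ν_β²) plane:

ν_α² = Q ν_β² + G, Q = (2a + T − 4ν_I)/(2a + T + 4ν_I),
G = (ν_I − (a−T)/2)² − Q(ν_I + (a−T)/2)².

`fit_ridge()` fits this line by total least squares — both coordinates are
measured quantities, so ordinary regression on either axis would bias the
slope — and inverts (Q, G) to (a_iso, T). The inversion is quadratic, and
the α/β assignment of the two coordinates is unknown, so all algebraically
admissible branches are returned; each is scored by regenerating its ridge
and measuring the RMS distance to the data, and the global sign of
(a_iso, T) is genuinely undetermined by ridge data alone (the
sign-flipped pair generates the identical ridge), exactly as in the
original analysis where signs were assigned later by simulation. The
inversion formulas are not trusted blindly: tests verify them against
brute-force simulate-and-match recovery over random parameters
(a_iso ∈ [−3, 3], T ∈ [0.5, 8], ν_I ∈ [5, 55] MHz; recovery within
0.15 MHz and 2%).

Two degenerate regimes are handled explicitly: a T = 0 ridge collapses to
a point and is rejected ("ridge too short for unique fit"), and as both
couplings vanish the line tends to slope −1 with intercept 2ν_I² — the
ridge shrinks onto the squared antidiagonal through the Larmor point.

Ridge-point selection from a processed spectrum (which cells count as "the
ridge") is not specified in the source and is left to the caller; the
pipeline and tests use local maxima in the band around the proton
antidiagonal, excluding a margin along the diagonal. Two caveats, both
verified numerically and worth knowing before trusting a one-shot fit:
with a strongly rhombic g the quantization-axis projection (uᵀA with
u ≠ B̂) displaces ridge points off the ideal axial line, so Dikanov
estimates from such data are first approximations to be refined by forward
simulation, which is how the original study used them; and when
|a_iso| < |T| the secular coupling A(θ) changes sign across the powder, the
α/β pairing crosses the diagonal at the magic angle, and the squared-plane
ridge becomes two line segments — fitting a contiguous single-side segment
is then essential.

## Point-dipole geometry

With the unpaired electron localized on the iron, the anisotropic part of
a proton hyperfine coupling is the classical point-dipole interaction
T = (μ₀/4π)(g_e μ_B g_N μ_N)/(h r³), A_dip(θ) = T(3cos²θ − 1). Inverting
the fitted T gives the Fe–H distance; the Euler angles of the axial tensor
frame give the placement — θ = β from the heme normal, φ = α from g_x in
the heme plane. Three conventions are fixed here: the free-electron
g-value is used in the prefactor (this is what reproduces the published
distances; using an effective heme g would change them by ~10%), distances
below 2.5 Å trigger a warning because spin delocalization makes the
point-dipole picture unreliable there, and angles are folded to
θ ∈ [0°, 90°], φ ∈ (−90°, 90°] since the dipolar interaction cannot
distinguish the symmetry-related positions. `isotope_rescale()` transfers
tensors between isotopes of an element by the nuclear g-factor ratio
(¹H→²H: ×0.1535; ¹⁴N→¹⁵N: ×(−1.403)). For coordinated imidazole the
smallest-magnitude quadrupole principal axis is normal to the ring plane,
so the tensor's α angle fixes the ring orientation:
`imidazole_plane_angle()` maps α′ to the plane's own projection angle,
α′ − 90° wrapped into (−90°, 90°].

## Crystal-field analysis

`taylor_crystal_field()` implements the one-hole t₂g model for low-spin
ferric heme: V/ξ = g_x/(g_z+g_y) + g_y/(g_z−g_x) and
Δ/ξ = g_x/(g_z+g_y) + g_z/(g_y−g_x) − V/2ξ, with inputs canonicalized to
descending order and near-degenerate triples rejected (the model is
undefined for axial g). Only ratios to the spin-orbit constant ξ are
reported. A caution for users reproducing the published imidazole-complex
table: evaluating these formulas on each imidazole g-set yields the
crystal-field values printed alongside the other set — the table's row
labels appear interchanged — so this package computes from g-values only
and never hard-codes a row assignment.

`decompose_mixture()` quantifies multi-species CW spectra by non-negative
least squares against simulated rhombic powder basis patterns
(first-derivative, Gaussian-broadened; linewidths are user parameters, as
the source reports none). Fractions are normalized, and a relative
residual above 0.5 flags the result unreliable (e.g. pure noise input).

## Synthetic data and what the tests do (and do not) show

`heme_fixture()` ships the five published parameter sets (substrate-free
in H₂O and D₂O, the two imidazole-bound species, and the ¹⁵N-imidazole
variant) with observers at the three principal-g positions of a 9.68 GHz
spectrum and the τ values of the corresponding published panels.
`simulate_dataset()` and `cw_powder_spectrum()` add white Gaussian noise
under a caller-supplied seed; regeneration with the same seed is
bit-identical. The noise model is additive white Gaussian on the
time-domain echo (the source does not characterize its noise), temperature
enters only as metadata, and relaxation, pulse imperfections, deadtime and
g-strain are not emulated. Passing end-to-end tests therefore demonstrate
the correctness of the inference chain on data obeying the stated spin
Hamiltonian — not robustness to instrumental artifacts of real
spectrometers.

The end-to-end recovery test (generate → process → pick → ridge-fit →
invert, distance recovered within 0.05 Å at SNR 20, where SNR is the
echo-modulation amplitude over the noise standard deviation) runs on a
near-isotropic-g powder with a_iso > T, for the two reasons detailed in
the ridge section: full-sphere excitation makes the ridge a complete,
single-branch line, isolating pipeline fidelity from the g-projection
model distortion that real heme data adds on top.

Problem sizes throughout the suite (orientation grids of 7–19 polar rings,
64–128-point time grids, 512–1024-point field grids) were chosen as the
smallest that keep simulated peak positions within one frequency bin of
the exact transition frequencies; they are the package's default test
scale, and all are plain function arguments that scale up directly.

## Known limitations

* Electron spin restricted to S = 1/2, one unpaired electron; no
  zero-field or exchange terms, no S > 1/2 multiplets.
* First-order electron treatment: no second-order electron-spin shifts
  (negligible at ≥ 0.28 T for ≤ 10 MHz couplings, but not checked beyond
  that regime).
* I = 1 cross-peak amplitudes are heuristic (eigenvector overlaps);
  time-domain amplitudes are exact within the ideal-pulse model.
* Exact single-orientation frequencies reproduce published experimental
  peak maxima only to ~0.1–0.2 MHz — printed coordinates are powder-ridge
  maxima read off processed spectra, not single-crystal frequencies.
* No vendor binary file readers; interchange is CSV/JSON only.
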