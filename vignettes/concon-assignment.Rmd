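---
title: "Models and methods behind conconnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conconnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conconnmr)
```

`conconnmr` simulates, reconstructs and scores the carbonyl–nitrogen
("CON–CON") sequential-assignment strategy for intrinsically disordered
proteins (IDPs). This vignette is the package's own account of its models:
what is simulated, which knobs matter, which behaviours of real data are and
are not captured, and where the design was genuinely open.

## 1. Pulse-level calculator

The calculator is closed-form algebra for rectangular pulses.

* `pulse_duration(flip, nu1)` inverts flip = 360·ν₁·τ. With the published
  MOCCA-XY16 carbonyl RF fields of 4.68 and 6.23 kHz it returns 106.8 and
  80.3 µs for the 180° pulse — the printed 107.0/80.2 µs to within their
  3-significant-figure rounding. A relative tolerance of 0.5 % is used in all
  tests against printed values; it absorbs both possible rounding directions
  (RF rounded from duration, or duration from RF).
* `effective_rotation(x, flip)` is the static effective-field model: a spin
  offset by Δν = x·ν₁ rotates by flip·√(1+x²) about the tilted axis. The
  MOCCA calibration chooses x = √15 so each CO 180° pulse is an effective
  720° rotation for CA (x = √3 would give 360° at higher RF power). No pulse
  shape is integrated; the model is exact for rectangular pulses and that is
  all the rule needs.
* `selective_rf(dOmega, flip)` encodes the band-selective calibration
  ν₁ = |ΔΩ|/√15 (90°) and |ΔΩ|/√3 (180°). The CA–CO offset itself is not a
  published number; it is derived from the MOCCA condition
  |ΔΩ| = √15·ν₁(MOCCA), ≈ 18.1 kHz at 600 MHz and ≈ 24.1 kHz at 800 MHz
  (≈ 120 ppm of ¹³C), which reproduces all six printed rectangular durations
  simultaneously — the self-consistency that motivated this choice. The
  sinc-shaped durations (87.8/78.4 and 65.8/58.8 µs) are stored as scheme
  constants because the sinc time–bandwidth factor is not derivable from the
  rectangular algebra.
* `sct_delays(t, t_max, delta, mode)` implements the semi-constant-time and
  constant-time delay triplets; both satisfy a + b − c = t to machine
  precision, and constant-time mode keeps the total duration equal to the
  transfer delay independent of t.

## 2. CO–CO mixing model

In-phase transfer under ideal isotropic mixing is modelled as a continuous
quantum walk on the chain of sequential carbonyls: the Hamiltonian is the
symmetric tridiagonal matrix with nearest-neighbour elements πJ, the
propagator its matrix exponential over the mixing time (computed by symmetric
eigendecomposition), and the transferred fraction the squared modulus of the
propagator element, windowed to ±2 neighbours of the source and damped by a
single envelope exp(−R·t_mix). For two spins this reduces exactly to the
TOCSY closed form (cos², sin²)(πJt)·e^(−Rt), which is the oracle the tests
check against (an independent series matrix exponential covers longer
chains). The model deliberately omits the XY16 supercycle, offset-dependent
mixing efficiency and Hartmann–Hahn mismatch: only orderings and trends are
asserted downstream, never absolute transfer amplitudes.

Defaults and why:

* `J_hz = 1` — the effective CO–CO coupling is not a published number; any
  value ≤ 2 Hz makes a 250 ms mixing time transfer more than 150 ms, the
  direction the published mixing-time comparison shows.
* `t_mix_ms = 250` — the published working point.
* `R600_per_s = 1.43` — chosen so the envelope at 250 ms is ≈ 0.70; exposed
  in the config. Relaxation during mixing is dominated by chemical shift
  anisotropy, so the applied rate is `R600 · (B0/600)²`; this makes the
  600 MHz cross fraction strictly exceed the 800 MHz one at any positive
  mixing time, the direction seen in the published field comparison.

## 3. Synthetic shift generator

`generate_shifts()` draws every backbone shift (HN, N, CO, CA, HA) from a
Gaussian centred on a bundled random-coil mean for the residue type. The
means are standard literature-style random-coil values; they are
configuration data of the generator, not fitted quantities. The per-nucleus
standard deviations (HN 0.25, N 2.0, CO 0.8, CA 0.6, HA 0.15 ppm, all scaled
by `dispersion_scale`) emulate the residue-type-dominated dispersion of an
IDP: narrow overall windows, heavy clustering of common residue types, and —
important for realism — occasional near-degenerate CON pairs, which are the
genuine overlap challenge for the assignment stage. Draws are truncated at
three standard deviations and clamped to per-nucleus plausibility windows
(HN 6–11, N 100–140, CO 165–185, CA 40–70, HA 3–6 ppm), so every generated
peak provably fits the spectral windows of Section 5. Prolines and the
N-terminal residue carry no amide proton.

What the generator does *not* emulate: sequence-neighbour corrections to
random-coil shifts (a hook exists but is off by default), temperature and pH
dependence, exchange broadening, and the ¹H dimension's role in resolving
overlap (Section 5). Passing tests therefore demonstrate the machinery on
IDP-like dispersion statistics, not performance on any particular real
protein.

## 4. Experiments and peak content

Five experiments are supported, all anchored on the HNCO triple
(HN(k), N(k), CO(k−1)) of each non-proline residue k ≥ 2:

* `HNCO_3D` — the anchor spectrum itself, one unit peak per anchor.
* `HNCOCONH_5D` — amide-proton start. For each anchor k and pair residue
  i ∈ {k−1, k, k+1}, a peak at the resolved pair (CO(i−1), N(i)) with
  amplitude equal to the mixing transfer from CO(i−1) to CO(k−1), times an
  optional per-residue amide-exchange attenuation. Proline pairs are never
  emitted (the start requires an amide proton on residue i).
* `HACACONCOCONH_5D` — HA/CA start on residue i−1: proline pairs are
  emitted and no exchange factor applies. This is the experiment that walks
  chains through prolines.
* The two `1+3` 4D experiments are exact projections of the HA/CA 5D onto a
  single resolved dimension (CO(i−1) or N(i)); the package enforces this as
  an invariant.

The transfer window is limited to i ∈ {k−1, k, k+1}: the mixing time is tuned
for i ± 1 connectivities, and more distant transfers are deliberately not
emitted. Peaks below 1 % of the strongest (configurable) are dropped.

## 5. Time-domain model and reconstruction

The simulated data set spans the indirect dimensions only. Two modelling
decisions matter:

* **Anchor axes are full Nyquist grids; resolved axes are NUS.** The anchor
  coordinates (N(k), CO(k−1)) are resolved information — they come from a
  conventionally analysed 3D HNCO — so the synthetic data carries them on
  complete grids, while the newly resolved CO/N dimensions carry the
  non-uniform schedule (uniform random points, zero-time always included,
  seeded). Quoted NUS point counts (e.g. 1100) therefore refer to the
  resolved grid, and the stored data is a (grid cells × scheduled points)
  complex matrix.
* **The detected amide-proton dimension is not simulated.** Its information
  content here is only to separate anchors, and the well-dispersed (N, CO)
  anchor pair already does most of that. The consequence is a harder problem
  than reality in one specific way: two anchors close in both N and CO leak
  into each other's strips with no ¹H dimension to separate them. The linking
  stage is built to tolerate this (Section 6).

Each peak contributes a separable complex exponential with per-axis decay
(default R₂ = 2/t_max, i.e. a linewidth of about two grid cells); quadrature
is ideal complex sampling in every dimension, so no conjugate symmetry holds
and none is assumed. Out-of-window peaks are an error — folding is not
modelled. Complex Gaussian noise is added per stored point; the pipeline
derives its standard deviation from a requested section-level SNR of the
*weakest* emitted peak (default 20), computed analytically from amplitudes
and mean decay.

`cross_section()` evaluates S(ω) = (1/M)·Σ d(t)·e^(−2πi(ν_anchor·t_anchor +
ω·t_res)) on a dense frequency grid (default 2× Nyquist oversampling),
anchors evaluated at their exact frequencies. On fully sampled data this
equals the dense FFT plane to machine precision — the oracle invariant in the
test suite. Magnitude is displayed; the synthetic model is ideally phased, so
magnitude mode merely avoids zero-order phase bookkeeping. An optional
half-cosine apodization (`apodize = "cosine"`, the pipeline default)
suppresses truncation sidelobes, which otherwise reach ~12–30 % of a peak and
flood the picker; the plain transform remains the default of the standalone
function so the FFT equivalence holds verbatim.

Peak picking takes local maxima above `threshold ×` the sampling-noise level
(the median cross-section magnitude far from all true peaks), greedily with
an exclusion radius, refined by three-point parabolic interpolation per axis.
The threshold default of 5 is a calibration choice standing in for the
published workflow's manual analysis; a relative floor (pipeline default 10 %
of the section maximum) guards the noiseless limit, where the off-peak median
is numerically zero and the threshold rule degenerates.

## 6. Linking, bridging, scoring

`build_links()` identifies each strip's diagonal (nearest pick to the
anchor's own pair), then matches the remaining picks to other anchors' pairs
under the normalized distance √((ΔCO/tol_CO)² + (ΔN/tol_N)²) ≤ 1, with
defaults tol_CO = 0.05 ppm and tol_N = 0.2 ppm — a few times the parabolic
interpolation error on the default grids, and small enough to keep most
anchor pairs unambiguous at IDP-like dispersion. Ambiguity is rejected, not
guessed: if the second-closest anchor is within a distance ratio of 1.2 the
pick is recorded and discarded, mirroring an analysis workflow that resolves
such cases with information (the ¹H dimension) this model does not carry.

Two departures from naive nearest-distance matching proved necessary and are
deliberate design choices:

* **Mutual support outranks distance.** Anchors that overlap in (N, CO) leak
  copies of their peaks into each other's strips; a leaked diagonal can sit
  *exactly* on its own anchor's pair and beat the true sequential cross-peak
  on distance. A true link k → j is reciprocated by a cross-peak on strip j
  pointing back at k; leaked copies are not. Per strip and direction the
  accepted edge is therefore the best *supported* candidate, falling back to
  distance.
* **Bridges prefer partners two residues apart.** Cross-peaks matching no
  anchor are cross-matched between strips into bridge nodes — this is how
  proline pairs (which have no strip) enter the graph. A bridge spans exactly
  one missing strip, so candidate partners with a residue gap of 2 are taken
  first; without this prior, leaked duplicates steal bridge partners.

`assemble_chains()` turns edges into succession assertions (a forward edge
from k to j and a backward edge from j to k both assert "j follows k"),
resolves conflicts by support count (ties drop all competitors and are
flagged — this is what exposes swapped near-degenerate assignments), walks
maximal paths, and treats bridge successions as fallback only. Anchors whose
strip produced no picks at all cannot be walked through; their HNCO pair
still serves as a match target, so a deleted interior strip splits the chain
in two rather than being silently bridged.

`score_links()` reports, per direction, matched over linkable pairs in the
published `"NN % (m/e)"` format. Eligibility is direction-specific: a forward
link for pair i needs strip i−1 and a match target (anchor i, or both
flanking strips for a proline pair); backward is the mirror image. Published
link statistics for this strategy quote one denominator for both rows, but a
single observable count would make even a perfect run score below 100 % (the first pair has no
preceding strip), so the per-direction count is used; `eligible_pairs()`
retains the observable-pair count with its start-scheme rules (amide start
excludes proline pairs; both schemes require some anchor within reach).

## 7. Problem sizes and determinism

The test suite runs entirely on synthetic data built at test time: unit
oracles on 16–64-point grids, and one end-to-end run with 100 residues
(10 prolines), 64-point anchor and resolved grids, an 1100-point NUS schedule
and weakest-peak SNR 20 — about half a minute — where ≥ 95 % of linkable
pairs must be recovered in both directions, every proline bridged, and the
amide-start variant must recover no proline pair. Every random draw
(sequence, shifts, schedule, noise, probe positions) derives from a single
seed through fixed stream offsets, so identical configs give identical
outputs byte for byte.

## 8. Known limitations

* No folding/aliasing, no shaped-pulse (Bloch) simulation, no phase cycling
  or gradient selection — acquisition-side details are documented, not
  simulated.
* Artefact-cleaning reconstruction algorithms are out of scope; thresholded
  picking on the plain (optionally apodized) sparse FT stands in for them,
  with the threshold as the exposed control.
* The ¹H dimension is not simulated, so anchor overlap is *harsher* than in
  real spectra; conversely the synthetic lineshapes are ideal, which is
  kinder. Neither effect is calibrated against measured spectra.
* Amplitudes are model-nominal: diagonal-to-cross ratios in real spectra are
  not quantified here, and the mixing model asserts orderings, not absolute
  efficiencies.
* Residue-type identification and mapping of chains onto the sequence are
  out of scope; scoring uses the generator's ground truth.
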