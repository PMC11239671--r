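---
title: "Models and methods in golphkit"
author: "golphkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in golphkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golphkit)
```

# Scope

golphkit analyzes the quantitative behavior of GolpHCat (TMEM87A), a
voltage-dependent, inwardly rectifying, nonselective cation channel of the
Golgi membrane. The package covers six connected analyses: single-channel
gating kinetics, whole-cell I-V / permeability / inhibition analysis,
boost-potential mechanics for Gaussian-accelerated sampling, linear
interaction energy (LIE) binding free energies, lipid-binding-state
geometry, and ratiometric organelle-pH analysis. Because no raw recordings
or trajectories are publicly deposited for this channel, a synthetic-data
generator with known ground truth is a first-class component: every
analysis is validated by recovering the parameters that generated its
input.

# Single-channel gating

## The gating model

A channel is modeled as a finite-state continuous-time Markov chain
(`GatingModel`): states are labeled `closed`, `open` or `sub`
(subconductance), each state carries a conductance (pS, closed = 0), and
the transition-rate matrix $Q(V)$ (1/ms) may depend on the holding
potential. The unitary current in state $s$ is Ohmic,
$i_s = g_s (V - E_{rev}) \cdot 10^{-3}$ pA.

`defaultGatingModel()` encodes the channel's signature U-shaped
voltage-dependent open probability: the opening rate scales linearly to
zero at 0 mV (no openings at the resting potential) and the dwell kinetics
are anchored to the measured time constants — mean open/closed 26/41 ms at
+90 mV and 421/505 ms at $-150$ mV. A half-conductance subconductance
level is reachable from the open state at positive potentials only,
mirroring the observation that subconductance openings occur at +90 mV but
not at negative potentials; no subconductance rates have been published,
so those two rates are plain arguments with modest defaults (0.02 and
0.1 /ms).

One inconsistency in the published numbers is worth stating plainly: at
+90 mV the dwell time constants 26/41 ms imply a two-state stationary open
probability of $26/(26+41) \approx 0.39$, while the reported maximum Po is
about 0.6. The two cannot hold simultaneously in a two-state chain (the
real channel presumably has multi-component kinetics). golphkit therefore
never pins both at once: `twoStateGatingModel(tauOpenMS=, tauClosedMS=)`
anchors the dwell times, and `twoStateGatingModel(tauOpenMS=, po=)`
anchors the stationary open fraction by adjusting the closed dwell. Tests
and the acceptance analyses use whichever anchor the quantity under test
requires.

## Simulation

`simulateGating()` is an exact event-driven (Gillespie) realization:
exponential holding times from each state's total exit rate, categorical
jumps proportional to the outgoing rates. A fixed-step discretization was
rejected because downstream dwell-time recovery tests require exactly
exponential dwell distributions. The chain starts in the closed state (the
conventional assumption for a channel at rest); for the minute-long
records used here the starting-state bias is negligible. A state with no
exit path (the 0 mV case) yields a single event spanning the whole record
rather than an error.

`renderTrace()` adds independent Gaussian recording noise after the
piecewise-constant current and can apply a moving-average low-pass filter
(after the noise, as a recording chain would), emulating the 2 kHz
filtering of the published recordings. Sampling must be at least twice the
filter cutoff.

## Idealization and kinetics

`idealize()` uses the field-standard half-amplitude threshold (the
published analysis was done in a commercial package without stating the
algorithm). Two numerical choices matter:

* **Hysteresis** of $0.1 \times$ the unitary amplitude around the
  threshold suppresses noise chatter; classification is
  last-state-carried-forward for samples inside the band.
* **Dead time**: runs shorter than `deadTimeMS` are merged into their
  neighbors, shortest first.

Dwell-time constants are estimated by maximum likelihood on event
durations rather than histogram fitting (unbiased, no binning choices).
For exponential dwells left-truncated at dead time $d$, memorylessness
gives the closed form $\hat\tau = \bar t - d$. Truncated first and last
events are censored and dropped by `dwellDurations()`.

Subconductance occupancy counts as "open" for Po (`openProbability()`),
with a flag to restrict to the full level and `stateOccupancy()` for
per-level fractions; the published analysis does not state its convention.

Amplitude histograms are fitted with a sum of Gaussians
(`amplitudeHistogramFit()`) by expectation-maximization with k-means
initialization plus five seeded random restarts. The EM is written out
rather than delegated so that degenerate inputs behave predictably (a
noiseless single-level trace returns one dominant component instead of
failing); an independent mixture fitter (mclust) serves as an oracle in
the test suite. An SD floor of $10^{-6}\sigma_x$ guards against component
collapse.

The unitary I-V relation is fitted with a degree-3 polynomial by default
(the published figure says only "a polynomial"; degree is an argument).
`reconstructMacroscopic()` forms $i(V) \times P_o(V)$, which converts the
weakly rectifying unitary curve into the strongly rectifying whole-cell
profile, and reports the rectification index
$|I(-150)|/|I(+100)|$ of the product.

# Whole-cell analysis

`rampToIV()` maps sample times of a descending voltage ramp (default
+100 to $-150$ mV in 1000 ms) onto command voltages and averages repeated
ramps. `reversalPotential()` interpolates the zero-current crossing
linearly and, when a curve crosses zero several times, returns the
crossing nearest 0 mV with a warning.

## Permeability ratios

Under the bi-ionic design used for this channel — the 150 mM external Na+
replaced by 150 mM of test cation with the internal solution fixed — the
GHK relation reduces to

$$\frac{P_X}{P_{Na}} = \exp\!\left(\frac{F\,\Delta E_{rev}}{RT}\right),
\qquad \Delta E_{rev} = E_{rev,X} - E_{rev,Na}.$$

The printed full two-term equation contains internal-solution terms and
what we read as a typesetting error in one denominator ($P_{Cl}[Na^+]_i$);
the bi-ionic reduction is the primary implementation, and
`ghkPermeabilityRatioFull()` exposes the two-term form for complete
solution data. Temperature defaults to 298.15 K ($RT/F \approx 25.7$ mV);
the recordings were made at unspecified room temperature, and the
$P_K/P_{Na} = 1.4$ result is insensitive across 22-25 °C. From the
published mean reversal potentials the Cs+ ratio evaluates to about 1.18,
not the printed 1.6; per-cell paired shifts may underlie the printed
value. This is documented, not reconciled.

## Inhibition curves

`hillFit()` fits $Y = 100/(1 + (IC_{50}/X)^h)$ by Levenberg-Marquardt
least squares with a multi-start grid (geometric IC50 grid over the
concentration range crossed with slopes $\pm\{0.5, 1, 2\}$). The Hill
slope keeps its sign exactly as published ($h$: gadolinium $-1.498$,
gluconate $-1.301$) instead of re-parameterizing inhibition with positive
slopes. The generator applies multiplicative Gaussian noise
(coefficient-of-variation parameterized), the simplest model consistent
with the published scatter.

## Junction potentials

`hendersonLJP()` evaluates the Henderson equation with limiting
equivalent conductivities shipped in `ionMobilityTable()` (CRC values for
inorganic ions; gluconate, isethionate, HEPES and NMDG from the standard
patch-clamp junction-potential tables). The sign convention is the
patch-clamp one: the returned value is the correction added to the command
potential ($V_m = V_{cmd} - LJP$). For the K-gluconate pipette against
the NaCl bath the computed value is $+15.6$ mV against the conventional
$+13$ mV correction — within the spread expected from mobility-table
choices. The published $-11.6$ mV value for the Na-isethionate bath is
not reproducible by the Henderson equation from the stated compositions
(we obtain about $+6$ mV) and is not asserted anywhere; antisymmetry under
solution exchange and the zero for identical solutions hold exactly.

# Boost-potential mechanics and the Langevin demonstrator

The Gaussian-accelerated boost raises the potential only below a
reference energy $E$:

$$\Delta V(r) = \tfrac12 k\,(E - V(r))^2 \; [V < E], \qquad
V^*(r) = V(r) + \Delta V(r),$$

subject to $V_{max} \le E \le V_{min} + 1/k$. Within that bound
$dV^*/dV = 1 - k(E - V) \ge 0$, so the boost never reorders potential
levels. `selectBoostParams()` implements the canonical parameterization
of the published method: $k_0 = \min(1, (\sigma_0/\sigma_V)(V_{max} -
V_{min})/(V_{max} - V_{avg}))$ with $k = k_0/(V_{max}-V_{min})$ and
$E = V_{max}$ at the lower bound; at the upper (more aggressive) bound,
used for the production simulations with $\sigma_0 = 6.0$ kcal/mol,
$k_0 = (1 - \sigma_0/\sigma_V)(V_{max}-V_{min})/(V_{avg}-V_{min})$ when
feasible, otherwise the lower-bound choice. Energies are carried with
explicit unit tags; boost parameters default to kcal/mol (matching the
published $\sigma_0$) and LIE results are in kJ/mol (matching the
published $\Delta F$), with the exact 4.184 conversion.

All-atom dynamics are out of scope. The demonstrator `runToyGaMD()` is
overdamped Langevin (Euler-Maruyama) on a 1-D quartic double well — the
smallest system exhibiting barrier crossing — with reduced units
($k_BT = 1$, friction 1, dt 0.005, barrier 4-5 $k_BT$ in the tests). The
property asserted is the method's defining one: with matched seeds, the
boosted trajectory crosses the barrier at least as often as the unboosted
one in at least 95% of seed pairs. Reweighting of boosted statistics
(cumulant expansion) is deliberately excluded — the production analysis
did not use it — and only a single total-potential boost is implemented;
the published "dual-boost" variant adds a dihedral-term boost whose
parameters were not reported, a simplification noted here.

# LIE binding free energies

`energyComponents()` averages per-frame coulombic and van der Waals
interaction energies for the five subsystems of the thermodynamic cycle —
protein-lipid complex (p-L), bare protein (p*), lipid reference (L(g)),
membrane-lipid (m-L), bare membrane (m*) — after discarding a leading
burn-in fraction (default 0.1, matching the 100 ns discarded from 1 µs
production trajectories). `lieFreeEnergy()` then forms

$$\Delta E^{Q,vdW}_{L\to p} = E_{p\text{-}L} - E_{p^*} - E_{L(g)}, \quad
\Delta E^{Q,vdW}_{L\to m} = E_{m\text{-}L} - E_{m^*} - E_{L(g)},$$
$$\Delta E_{m\to p} = \Delta E_{L\to p} - \Delta E_{L\to m}, \qquad
\Delta F_{m\to p} = 0.5\,\Delta E^{Q}_{m\to p} +
0.16\,\Delta E^{vdW}_{m\to p},$$

with the 0.5/0.16 coefficients fixed by the LIE model. The class validity
enforces the $\Delta F$ identity exactly, and a brute-force recomputation
from raw frames is the oracle in the tests. The published PE and PC
binding free energies ($-32.4$ and $-13.2$ kJ/mol, difference 19.2) are
reproduced by this arithmetic from components constructed to match.

# Lipid-binding geometry

The binding coordinate system is the transmembrane domain's
smallest-moment principal axis: the eigenvector of the smallest eigenvalue
of the mass-weighted inertia tensor about the selection's center of mass
(the bundle's elongation axis), sign-fixed toward +z.
Distances `dP` (lipid phosphorus) and `dR2Cent` (R2-fatty-acid-chain
center of mass) are perpendicular point-to-line distances — the published
definition says only "to the axis", and the perpendicular reading is the
geometric default. Near-spherical selections (eigenvalue gap below
tolerance) are rejected as ambiguous rather than silently returning an
arbitrary axis.

`stateHistogram()` bins the (dP, dR2-Cent) series at 0.5 Å and finds
states as local maxima above 1% of the frame count with a two-bin minimum
separation, labeled S1 (most populated) downward — a deterministic
reading of "highly populated states" that avoids the initialization
sensitivity of clustering. State populations are frame counts under
nearest-center assignment, which also drives `classifyFrames()` (visit
order, dwell totals, and the first-passage path to S1, e.g. the stepwise
S4 → S3 → S1 entry of the lipid into the cavity).

Whether the published histograms pool frames before or after
per-trajectory alignment is unstated; golphkit computes the axis per
frame (`axisDistanceSeries()` with `axis = NULL`), which is
alignment-free, and accepts a fixed axis as the alternative.

# Ratiometric pH analysis

The 405:475 excitation ratio of the Golgi-targeted ratiometric pHluorin
is mapped to pH through a Boltzmann sigmoid

$$\mathrm{pH}(r) = \mathrm{pH}_{min} +
\frac{\mathrm{pH}_{max}-\mathrm{pH}_{min}}{1 + e^{(r_{1/2}-r)/s}},$$

the field-standard calibration model for pHluorin-family sensors (the
publication names only "a standard curve"). The curve is fitted to
standards by Levenberg-Marquardt (`fitCalibration()`), monotonicity is
verified over the standards' range, and the inverse is analytic. The
NH4Cl buffering response (`bufferingResponse()`) takes the resting pH as
the mean over the 10 s preceding the 30 s stimulus onset and the
post-stimulus pH 10 s after onset by default; the publication fixes only
the 30 s onset, so both windows are arguments. The calibration was
published for a plasma-membrane-targeted sensor and applied to the Golgi
construct; any spectral offset between the constructs is not modeled.

The generator (`genPhTraces()`) emulates a clean step response with
multiplicative channel noise: default resting pH 6.3 (the usual Golgi
luminal value) and a +0.8 pH step upon 50 mM NH4Cl — a weak base entering
the acidic lumen — at 30 s.

# What the synthetic data do and do not show

The generators emulate the statistical structure the analyses rely on:
exponential dwell mixtures, Ohmic unitary currents with Gaussian noise
and optional low-pass filtering, Hill-exact dose-response tables with
multiplicative noise, Gaussian interaction-energy series,
piecewise-stationary 2-D Gaussian binding states, and clean step pH
responses. They deliberately omit recording artifacts — capacitance
transients, baseline drift, 50/60 Hz hum, missed-event statistics beyond
a fixed dead time, series-resistance and leak errors — so a passing
recovery test demonstrates the correctness of the estimators under the
stated noise models, not robustness to every artifact of real rigs.
Inward current is negative throughout; units are fixed project-wide to
pA, mV, ms, pS, kHz, Å and kJ/mol.

# Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen so the
statistical bounds are meaningful while the whole suite completes in
seconds: dwell-recovery records of ≥ 5,000 events (tolerance
$3\tau/\sqrt{n}$), 60 s single-channel records at 10 kHz for Po recovery
(tolerance 0.03), 25-point dose-response tables (5 concentrations × 5
replicates, 5% noise, 15% IC50 tolerance; noise-free fits are exact to
optimizer precision), Langevin runs of $10^4$ steps × 20 seed pairs, and
lipid series of a few thousand frames. Geometry invariants are asserted
to $10^{-9}$ Å, the calibration round trip to $10^{-6}$ pH, and the LIE
identity to $10^{-9}$.

# Known limitations

* No hidden-Markov idealization, multi-exponential dwell mixtures, or
  missed-event corrections beyond the fixed dead time.
* No Boltzmann activation-curve fitting, series-resistance or
  leak-subtraction corrections.
* The Langevin demonstrator is 1-D and overdamped; no force fields,
  thermostat variants, or trajectory-format parsing.
* PDB reading is coordinate-only and single-model; no trajectory
  alignment or RMSD fitting.
* Image processing (ROI segmentation, background subtraction) is out of
  scope; pH inputs are per-cell intensity traces.
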