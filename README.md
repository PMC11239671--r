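# golphkit

Analysis toolkit for GolpHCat (TMEM87A), a voltage-dependent, inwardly
rectifying, nonselective cation channel of the Golgi membrane. Golgi
luminal pH shapes protein glycosylation, trafficking and Golgi
morphology, and this channel's unusual gating — a U-shaped
voltage-dependent open probability centered on 0 mV, with no openings at
the resting potential — makes its quantitative characterization worth
doing carefully. golphkit is written for electrophysiologists and
computational biophysicists who need the full chain from raw traces (or
simulated ground truth) to the published summary statistics.

The package implements, with a synthetic-data generator backing every
stage:

* **Single-channel kinetics** — exact continuous-time Markov (Gillespie)
  gating simulation with closed/open/subconductance states; trace
  rendering with Ohmic unitary currents $i = g\,(V - E_{rev})$, Gaussian
  noise and low-pass filtering; half-amplitude idealization with
  hysteresis and dead time; open probability $P_o$; maximum-likelihood
  exponential dwell fits ($\hat\tau = \bar t - d$ under dead-time
  truncation); Gaussian-mixture amplitude histograms; polynomial unitary
  I-V fits and the macroscopic reconstruction $i(V)\,P_o(V)$.
* **Whole-cell analysis** — ramp-to-I-V conversion, reversal potentials,
  the bi-ionic GHK permeability ratio
  $P_X/P_{Na} = \exp(F\,\Delta E_{rev}/RT)$, Hill inhibition fits
  $Y = 100/(1+(IC_{50}/X)^h)$ with signed slope, pH normalization,
  Henderson liquid-junction potentials, current densities.
* **Boost-potential mechanics** — the harmonic boost
  $\Delta V = \tfrac12 k (E-V)^2$ for $V<E$ with the
  $V_{max} \le E \le V_{min} + 1/k$ criterion, canonical parameter
  selection, and a 1-D overdamped-Langevin double-well demonstrator of
  enhanced barrier crossing.
* **LIE binding free energies** —
  $\Delta F_{m\to p} = 0.5\,\Delta E^Q + 0.16\,\Delta E^{vdW}$ from
  averaged subsystem interaction energies with burn-in handling.
* **Lipid-binding geometry** — smallest-moment principal axis of the
  transmembrane domain, perpendicular (dP, dR2-Cent) distance series,
  2-D state histograms with S1…Sn labeling, frame classification and
  first-passage paths.
* **Ratiometric pH analysis** — 405:475 ratios, Boltzmann calibration
  curves, and the NH4Cl buffering response of the Golgi lumen.

## Worked example

Simulate a minute of single-channel activity at +90 mV with the measured
fast gating (mean open 26 ms, mean closed 41 ms), render it at 10 kHz
with 0.1 pA noise, idealize, and recover the kinetics:

```r
library(golphkit)

m  <- twoStateGatingModel(tauOpenMS = 26, tauClosedMS = 41)
ev <- simulateGating(m, voltageMV = 90, durationMS = 60000, seed = 1)
tr <- renderTrace(ev, m, 90, noiseSdPA = 0.1, samplingKHz = 10, seed = 2)
id <- idealize(tr, unitaryAmpPA = 5.4, deadTimeMS = 0.3)

openProbability(id)
#> [1] 0.393
fitDwellExponential(dwellDurations(id, "open"))
#> DwellFit: tau = 27.481 ms (n = 859, dead time 0 ms)
fitDwellExponential(dwellDurations(id, "closed"))
#> DwellFit: tau = 42.352 ms (n = 858, dead time 0 ms)
```

The recovered open probability matches the two-state stationary value
$26/(26+41) = 0.388$ and both dwell constants sit within sampling error
of the generating 26 and 41 ms.

Permeability and inhibition from published summary inputs:

```r
ghkPermeabilityRatio(erevNaMV = -7.7, erevXMV = 0.5)$ratio
#> [1] 1.375969        # P_K/P_Na = 1.4 at one decimal

dr <- genDoseResponse(0.10, -1.301, c(0.01, 0.03, 0.1, 1, 10),
                      replicates = 5, noiseCV = 0.05, seed = 7)
hillFit(dr)
#> HillFit: IC50 = 0.1038 uM, h = -1.3972 (residual SD 3.89)
```

The fitted IC50 recovers the generating 0.10 µM gluconate value within
4% under 5% multiplicative noise.

## Documentation

The methods vignette (`vignettes/golphkit-methods.Rmd`) describes the
models, the numerical choices (idealization thresholds, EM
initialization, calibration model, boost-parameter selection), what the
synthetic generators do and do not emulate, and known limitations.
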