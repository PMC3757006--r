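---
title: "Methods: cytochrome redox state and myoglobin oxygenation from heart Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytochrome redox state and myoglobin oxygenation from heart Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Excitation at 532 nm falls inside the Q-band absorption of heme, so heme
proteins dominate the Raman scatter of heart tissue even though they are a
small fraction of its mass. Two further facts make the spectrum a redox and
oxygenation meter:

* only the *reduced* (Fe²⁺) forms of the mitochondrial cytochromes scatter
  appreciably at this wavelength, so cytochrome band heights track the
  reduction state of the electron transport chain; and
* several myoglobin modes shift with O₂ binding, most usefully the ν₄
  symmetric pyrrole half-ring mode: 1377 cm⁻¹ when oxygenated (oMb),
  1358 cm⁻¹ when deoxygenated (dMb).

The band library shipped with the package encodes the assignment table for
heart tissue: 604 cm⁻¹ (unique to reduced c-type cytochromes), 750 cm⁻¹
(shared, dominated by c-type), 1127 cm⁻¹ (shared, dominated by b-type),
1300/1310 cm⁻¹ (b-type/c-type; in tissue the c-type band sits at 1310,
downshifted from its 1313 cm⁻¹ position in purified cytochrome c by overlap
with the b-type 1300 cm⁻¹ band — `default_band_library("purified")` restores
1313), 1337 cm⁻¹ (unique to reduced b-type), the ν₄ pair 1358/1377, the
methine-bridge pairs 1556/1587 and 1606/1640 (dMb/oMb), 1582 cm⁻¹ (shared
cytochrome band) and the amide I protein band at 1658 cm⁻¹.

## From raw spectrum to indices

### Baseline

Tissue fluorescence produces a background one to several times the height of
the strongest band. `subtract_baseline()` removes it with an adaptive
asymmetric-least-squares estimator: a Whittaker smoother (second-difference
penalty, weight `smoothness`, default 1e7) is fitted iteratively, and points
whose residual exceeds a band threshold are down-weighted to `asymmetry`
(default 0.001) so the curve passes beneath the bands, bridging them
smoothly. The threshold is `2 * mad(residual over background points) +
0.005 * range(intensity)`: the first term adapts to detector noise, the
absolute floor stops the small smooth residual that a stiff smoother leaves
on a curved but band-free background from being mistaken for band signal
(without it, iterative masking ratchets the baseline downwards on such
inputs). The spectrum is Savitzky-Golay presmoothed (window `presmooth`,
default 11 points) for the *estimation* only; the baseline is subtracted
from the raw intensities, so `corrected + baseline` reproduces the input
exactly and corrected intensities may be negative. Convergence is declared
when the weights and the curve stop changing (relative change below 1e-8);
exceeding `max_iter` raises an error carrying the iteration count.

These defaults were fixed against two synthetic oracles: a pure cubic
fluorescence-like background must be removed to below 1% of its maximum,
and a Lorentzian band riding on such a background must keep its height
within 5%. Both checks run in the test suite.

### Band amplitudes

`band_amplitude()` offers two definitions:

* **height** — the maximum baseline-corrected intensity within
  `center ± window` (window default 8 cm⁻¹), negative values clipped to
  zero. This mirrors how peak intensities are conventionally read off, and
  it is the function's default.
* **fit** — the band's coefficient in a joint non-negative least-squares
  decomposition of its overlap cluster into fixed-center, fixed-width
  Lorentzians (FWHM default 14 cm⁻¹, a typical heme resonance-Raman
  linewidth; 25 cm⁻¹ for the broad amide I band). Clusters are maximal
  groups of library bands closer than 40 cm⁻¹, extended by two FWHM on
  either side.

The decomposition (`decompose_region()`) also fits an unconstrained local
linear background per region, profiled out exactly before the NNLS solve
(Frisch-Waugh: minimizing over non-negative amplitudes and a free linear
term jointly equals NNLS on the residualized problem). This term absorbs
the small residual the global baseline leaves under crowded regions and is
what makes fit-mode amplitudes essentially unbiased there; `background =
"none"` gives the bare Lorentzian model. If two bands sit closer than the
grid step the design is singular at the data's resolution: the solver warns
and returns a ridge-regularized solution flagged `regularized = TRUE` (the
*sum* of such amplitudes remains well determined).

The analysis pipeline quantifies **all** bands in fit mode. Height is kept
as the user-facing default of `band_amplitude()` because it is the
conventional operation, but it is a maximum over noisy points and therefore
biased upward by one to two noise standard deviations — enough to distort
small markers (1358, 1337, 604 cm⁻¹) and to leak the 1377 cm⁻¹ tail into
the 1358 cm⁻¹ window when myoglobin is fully oxygenated. The joint fit has
neither problem, and on noise-free simulator output it reproduces the
generator's amplitudes to within 2% for all major bands (test
`the analysis recovers the generator's ground truth without noise`).

### Indices

With `I_sum = total_intensity()` — the sum of corrected intensities over the
analysis window, default 520–1750 cm⁻¹ (the window covering every library
band; fixing it makes the normalization reproducible, since "the whole
spectrum" is otherwise instrument-dependent) — the per-spectrum indices are:

* `norm_<band> = amplitude / I_sum`, dimensionless, invariant under global
  intensity scaling;
* `ratio_c_b = I750 / I1127`, the reduced c-type vs b-type balance;
* `f_dmb = q·I1358 / (q·I1358 + I1377)`, the deoxymyoglobin fraction.

The ν₄ efficiency constant `q` is the ratio of ν₄ scattering of fully
oxygenated to fully deoxygenated myoglobin at matched concentration. The
package ships the literature value `calibration_constant(q = 1.55, se =
0.10, n = 3)` and can recalibrate from data: `calibrate_q()` quantifies
1377 cm⁻¹ in fully oxygenated hearts and 1358 cm⁻¹ in dithionite-reduced
hearts, sum-normalizing each intensity within its own spectrum before
ratioing (raw counts are not comparable across acquisitions; every other
quantity in the analysis is normalized the same way). Equal-sized groups
are treated as paired experiments (mean ± SE over per-pair ratios);
otherwise the ratio of group means is used with a delta-method SE. With
`q > 1`, equal amounts of oMb and dMb give `f_dmb = 0.5` by construction,
and the algebraic complement identity `f(a, b, q) + f(b, a, 1/q) = 1` holds
exactly (property-tested on random inputs).

### Statistics

`group_compare()` reports per-group mean ± SE, the Kruskal-Wallis omnibus
p-value, and Dunn's post hoc pairwise z-tests on the joint ranks with tie
correction, Bonferroni-adjusted over the number of pairs — the conventional
nonparametric workflow for small per-condition samples. No further
multiple-testing correction is applied. Degenerate input (all observations
identical) short-circuits to p = 1 rather than an error. For two groups
without ties, the squared Dunn z equals the Kruskal-Wallis H, which the test
suite uses as an internal cross-check.

A replicate whose fitted 1127 cm⁻¹ amplitude is exactly zero (possible at
the noise floor) has no defined redox ratio; `spectrum_indices()` reports
`NA` for that spectrum and downstream summaries drop it, rather than
aborting the run.

## The synthetic-data generator

No raw spectra are distributed with the study this package operationalizes,
so the generator is the package's test bed: it must produce spectra whose
*analysis* behaves like the reported experiments, with every ground-truth
quantity known.

`synth_heart_spectrum(state, grid, seed)` builds, on a default grid of
520–1750 cm⁻¹ at 1 cm⁻¹:

```
baseline + mb_scale·[(1−f_dmb)·q_true·oMb + f_dmb·dMb]
         + cyt_scale·[r_c·cytC + r_b·cytB] + amide_amp·amideI + noise
```

with each pure-component profile a sum of Lorentzians peak-normalized to 1.
Design choices, made once:

* **Within-profile amplitudes.** The c-type profile carries 750 cm⁻¹ at
  relative 1.0 and 1127 cm⁻¹ at 0.05; the b-type profile mirrors it. The
  20:1 dominance keeps each marker essentially species-pure, which is what
  the reported behavior shows: doubling the reduced c-type pool doubles the
  normalized 750 cm⁻¹ intensity while moving 1127 and 1337 cm⁻¹ by well
  under 15%. A 1:0.35 cross-contribution — a plausible reading of
  "dominated by" — would drag 1127 cm⁻¹ up by nearly 30% under the same
  change, contradicting the observed stability; the profiles are plain
  data.frames and can be edited. The oMb and dMb profiles are mirror images
  (ν₄ at relative 0.35, methine bands at 1.0 and 0.55) so that the
  whole-profile factor `q_true` carries the entire oxy/deoxy scattering
  difference and the `f_dmb` estimator is exactly consistent with the
  generator.
* **Abundance scalars.** `mb_scale = 1`, `cyt_scale = 0.29`,
  `amide_amp = 4.0`. The broad 1658 cm⁻¹ band stands for the aggregate
  non-heme protein scatter (amide I plus the unassigned tissue modes that
  are not modelled individually), and with these values roughly two thirds
  of the integrated intensity is non-heme — as in real tissue, where heme
  bands ride on a large protein/lipid background. `cyt_scale` is set so
  that the total integrated intensity of a fully oxygenated heart and a
  dithionite-reduced heart agree: the Mb pool loses the factor `q_true` of
  scatter on deoxygenation while the cytochrome pool gains scatter on full
  reduction. That balance is a physical requirement for the sum-normalized
  calibration to be meaningful at all — and published control and SDT
  spectra are drawn on a common intensity scale — so the generator's
  noise-free calibration reproduces `q = 1.55` through the measurement
  procedure itself. True Mb:cytochrome signal ratios in heart are not
  quantified anywhere; these scalars are explicit, documented placeholders.
* **Baseline.** A positive, monotonically decreasing cubic
  (`baseline_amp` at the low-shift edge, default 3 a.u., about twice the
  strongest band), emulating fluorescence decay.
* **Noise.** Additive Gaussian with sd `noise_sd` (default 0.02) times the
  strongest *heme* band of the noise-free mixture. Referencing the heme
  signal rather than the non-heme envelope keeps the markers'
  signal-to-noise independent of the envelope's (placeholder) magnitude and
  consistent with what the emulated experiments could resolve — the
  604 cm⁻¹ band is detectable in a single reduced-heart spectrum, and n = 3
  suffices for significant FCCP effects.
* **Determinism.** `(state, seed)` fully determines the output;
  `synth_scenario()` derives per-replicate seeds from the master seed, so a
  dataset is reproducible from one integer.

`preset_states()` encodes the emulated conditions: control hearts nearly
fully oxygenated (f_dmb = 0.05, consistent with ≥90% oxygenation in
arrested perfused hearts) with r_c = r_b = 0.4; FCCP states with unchanged
myoglobin and reduced fractions *solved* (deterministic fixed point on the
noise-free model, `solve_fccp_state()`) so the sum-normalized 750 and
1127 cm⁻¹ intensities land at the tabulated 56.7%/42.3% (5 min) and
61.5%/37.3% (10 min) of control; ischemia states with f_dmb rising to 0.5
and r_c doubling at 30 min with r_b unchanged; reperfusion identical to
control; and dithionite with everything reduced and deoxygenated.

**What the generator does not model:** Poisson/CCD-specific noise, cosmic
ray spikes, self-absorption and depth-of-focus effects, contraction
artifacts, the unassigned 900–1300 cm⁻¹ bands, and any between-heart
biological variability beyond the seeded noise. Recovery results on this
simulator therefore demonstrate the correctness and calibration of the
*estimators* under the stated model, not the accuracy of the method on real
tissue.

## Verification sizes

The acceptance checks run the full analysis at the emulated study's scale
(three replicates per condition) and average over independent master seeds
to measure systematic behavior rather than single-draw noise: 10
experiments for the q calibration, 10 seeds per level for the
deoxygenation sweep, 30 seeds for the ischemia/reperfusion time course and
10 for FCCP. Reversion after reperfusion is asserted for the indices the
time course actually tracks (normalized 750, 1127, 1337, 1377 cm⁻¹, the
redox ratio, and the dMb fraction on an absolute ±0.05 scale); the 604 and
1358 cm⁻¹ bands are excluded from *relative* reversion checks because their
control-state amplitude is near zero — both appear only under
reduction/hypoxia — making a percent change of their estimate noise over
noise.

## Known limitations

* Band centers and widths are fixed during fitting; genuine frequency
  shifts (temperature, conformation) would alias into amplitude changes.
* The baseline estimator assumes the background is smooth on a ~100 cm⁻¹
  scale; structured backgrounds (etaloning) would leak into band regions.
* `f_dmb` inherits the calibration constant's uncertainty; with
  `q = 1.55 ± 0.10`, the induced uncertainty at f = 0.5 is about ±0.016,
  small against the noise-driven spread.
* Sum normalization assumes the full 520–1750 cm⁻¹ window is acquired;
  truncated acquisitions require setting `isum_range` consistently across
  all spectra being compared.
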