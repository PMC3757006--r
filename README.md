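# ramanredox

Quantitative analysis of 532 nm resonance Raman spectra of perfused heart
tissue: the redox state of mitochondrial c- and b-type cytochromes and the
oxygenation of myoglobin, read out band-by-band from a single spectrum of the
beating (or arrested) organ's surface.

At 532 nm excitation only the **reduced** (Fe²⁺) cytochromes scatter
appreciably, so the heights of their marker bands track the reduction state
of the electron transport chain: 750 cm⁻¹ (mainly cytochromes *c*/*c₁*),
1127 cm⁻¹ (mainly *b*-type), 604 cm⁻¹ (unique to reduced *c*-type) and
1337 cm⁻¹ (unique to reduced *b*-type). Myoglobin reports its O₂ binding
through the ν₄ pair 1377 cm⁻¹ (oMb) / 1358 cm⁻¹ (dMb) and the methine pairs
1587/1556 and 1640/1606 cm⁻¹.

The package implements the full measurement model:

- **I/O** — two-column text and JCAMP-DX spectra (`read_spectrum()`,
  `write_spectrum()`), linear resampling, an editable band library shipping
  the heart assignment table (`default_band_library()`).
- **Baseline** — adaptive asymmetric-least-squares removal of the
  fluorescence background (`subtract_baseline()`), a Whittaker smoother with
  iteratively reweighted band suppression.
- **Band quantification** — windowed peak height, or joint non-negative
  least-squares decomposition of overlap clusters into fixed-center
  Lorentzians with a free local linear background (`band_amplitude()`,
  `decompose_region()`).
- **Indices** — sum-normalized intensities `I_band / I_sum`
  (`normalized_intensity()`), the c-type/b-type redox ratio
  `I750 / I1127` (`c_to_b_ratio()`), and the calibrated deoxymyoglobin
  fraction

  ```
  f_dMb = q · I1358 / (q · I1358 + I1377)
  ```

  where `q` is the ν₄ scattering-efficiency ratio of oMb to dMb, calibrated
  from fully oxygenated vs dithionite-reduced hearts (`calibrate_q()`;
  shipped literature value 1.55 ± 0.10).
- **Statistics** — per-condition mean ± SE, Kruskal-Wallis omnibus test with
  Dunn's post hoc (`group_compare()`), percent-of-control series.
- **Synthetic data** — a seeded generator of heart spectra with known ground
  truth (`synth_heart_spectrum()`, `synth_scenario()`) and presets for
  control, FCCP uncoupling, stop-flow ischemia/reperfusion and dithionite
  full reduction (`scenario_presets()`).
- **Pipeline & CLI** — `run_pipeline()` drives manifest → baseline → bands →
  indices → statistics → CSV/JSON report; `raman_cli()` (or
  `inst/scripts/ramanredox.R`) exposes `analyze`, `simulate`, `calibrate`
  and `bands` subcommands.

## Worked example

Simulate one stop-flow ischemia experiment (control, 15/30 min ischemia,
5/30 min reperfusion; three hearts per timepoint) and analyze it end to end:

```r
library(ramanredox)

dir <- file.path(tempdir(), "ischemia_demo")
synth_scenario(scenario_presets()$ischemia, seed = 1, dir = dir)

cfg <- pipeline_config(manifest = file.path(dir, "manifest.csv"), q = 1.55)
report <- run_pipeline(cfg)

subset(report$summaries, index %in% c("norm_750", "f_dmb"))
```

```
      condition    index n     mean       se
        control norm_750 3 0.000717 4.25e-05
        control    f_dmb 3 0.061229 1.15e-02
    ischemia_15 norm_750 3 0.000983 3.95e-05
    ischemia_15    f_dmb 3 0.249610 1.71e-02
    ischemia_30 norm_750 3 0.001281 1.01e-05
    ischemia_30    f_dmb 3 0.512775 1.08e-02
  reperfusion_5 norm_750 3 0.000631 2.18e-05
  reperfusion_5    f_dmb 3 0.051141 1.78e-02
 reperfusion_30 norm_750 3 0.000729 8.08e-05
 reperfusion_30    f_dmb 3 0.041738 2.10e-02
```

Reading the report: the sum-normalized 750 cm⁻¹ intensity (reduced
cytochromes *c*/*c₁*) roughly doubles by 30 min of ischemia (179% of control
in this run, Kruskal-Wallis p = 0.022 across conditions) while the estimated
deoxymyoglobin fraction climbs from ~0.06 to 0.51 — half the myoglobin pool
deoxygenated — and both revert to control levels within 5 min of
reperfusion. `report$percent_of_control`, `report$comparisons` and the
files `indices.csv` / `report.json` / `calibration.json` in the output
directory carry the same numbers in machine-readable form.

The same run from a shell:

```sh
Rscript inst/scripts/ramanredox.R simulate --scenario ischemia --out demo --seed 1
Rscript inst/scripts/ramanredox.R analyze --config demo_config.yaml
```

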