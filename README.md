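# ovosex

Non-invasive in ovo chicken egg sexing from bioimpedance ratio spectra.

Billions of day-old male chicks are culled annually in laying-hen
hatcheries; determining an embryo's sex *before* hatch, without opening the
shell, removes the need. This package implements the analysis behind an
impedance-spectroscopy approach: four surface electrodes per egg (1/2 at
the broad/narrow ends, 3/4 across the width), daily sweeps of 20 Hz–10 MHz
during incubation, and a statistic that is robust to egg-to-egg scale —
the **self-normalized ratio**

    r(f) = |Z_2-3(f)| / |Z_2-4(f)|,

the impedance of pair 2–3 divided by the simultaneously measured impedance
of pair 2–4. Instrument gain and egg size cancel in the ratio. From
incubation day 9, male eggs hold r > 1 and female eggs r < 1 over a stable
high-frequency band, which supports both a discovery analysis and a simple
classifier:

- a **day × frequency scan** of Welch two-sample t-tests (male vs female
  ratios) with a **persistence rule** — a frequency is discriminative from
  day d only if p < 0.05 on every day from d through day 13 — which
  locates the discriminative band (376 kHz–2.79 MHz) and its onset (day 9);
- a **threshold classifier**: read r at day 9 near 376 kHz, call male if
  r > 1, female if r < 1, indeterminate at the boundary;
- **PCR ground truth** from CHD-locus gel bands (552 bp = male,
  552 + 358 bp = female) and an evaluation report against it;
- electrode-repeatability QC (RSD < 5% above 100 Hz) and the resistivity
  model of the carbon-epoxy electrodes;
- a **Cole-model synthetic cohort generator** calibrated to the bundled
  reference cohort's day-9 ratio distributions, so the whole pipeline is
  testable without any instrument data.

See `vignette("ovosex-methods")` for the model, assumptions, and design
choices.

## Worked example

Simulate a labeled 20 + 20-egg cohort, run the scan, and classify at the
default operating point:

```r
library(ovosex)

sim    <- simulate_cohort(cohort_sim_config(n_male = 20, n_female = 20, seed = 1))
ratios <- ratio_dataset(sim$sweeps)          # pair 2-3 over pair 2-4
result <- scan(ratios, sim$labels)
result
#> <scan_result: 13 days x 100 frequencies, alpha = 0.05>
#>   onset day 9; band 3.638e+05 Hz .. 2.657e+06 Hz; best 2.657e+06 Hz
```

The scan recovers the planted structure: significance appears on day 9 and
persists through day 13 over a contiguous band whose edges are the grid
points nearest 376 kHz and 2.79 MHz (the 100-point log grid has no point at
exactly 376 kHz; `nearest_grid_frequency()` maps it to 363.8 kHz).

```r
op    <- nearest_grid_frequency(attr(ratios, "grid"), 376e3)
calls <- classify_eggs(ratios, classifier_config(day = 9, frequency = op$frequency))
evaluate(calls, sim$labels)
#> <evaluation_report>
#>         predicted
#> truth    male female
#>   male     16      4
#>   female    8     12
#>   accuracy 0.700 | balanced 0.700 | male sens 0.800 | female sens 0.600
#>   indeterminate 0 | excluded (not M/F truth) 0
```

Per-egg accuracy is modest by construction: the calibrated male/female
ratio distributions overlap, and the closed-form normal model
(`expected_accuracy(1.122262, 0.112674, 0.953107, 0.124892)`) predicts
sensitivities of about 0.861 (male) and 0.646 (female) at threshold 1 —
the group-level separation is much stronger than any single-egg call.

The bundled reference cohort's per-day summaries reproduce the familiar
day-by-day table, with persistence stars on exactly days 9–13:

```r
ref <- reference_daily_summaries()
daily_ratio_table(data.frame(day = ref$day,
  male_mean = ref$male_mean, male_sd = ref$male_sd, n_male = ref$n_male,
  female_mean = ref$female_mean, female_sd = ref$female_sd,
  n_female = ref$n_female))[, c("day", "male_mean", "female_mean", "p_value", "star")]
#>    day male_mean female_mean    p_value  star
#> 1    1  1.125607    0.950940 0.02446030 FALSE
#> ...
#> 9    9  1.122262    0.953107 0.01310316  TRUE
#> 10  10  1.083995    0.928134 0.01257227  TRUE
#> 11  11  1.077437    0.946580 0.02376436  TRUE
#> 12  12  1.131611    0.961139 0.03092292  TRUE
#> 13  13  1.087150    0.959394 0.01602719  TRUE
```

A thin command-line front-end over the same functions lives in
`exec/ovosex` (`ovosex simulate`, `normalize`, `scan`, `classify`,
`evaluate`, `label-pcr`, `qc`, `validate`, `run config=run.yaml`), and
`run_pipeline()` orchestrates the full chain from a single YAML/JSON
config, writing `ratios.csv`, `scan.json`, `calls.csv`, `report.json` and a
run log with the config hash.

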