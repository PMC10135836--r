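---
title: "Impedance-based in ovo egg sexing: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impedance-based in ovo egg sexing: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovosex)
```

## The measurement and the statistic

An incubating chicken egg is measured with four surface electrodes: 1 and 2
at the broad and narrow ends (the height axis), 3 and 4 diametrically
opposite on the width circumference. An impedance analyzer sweeps 20 Hz to
10 MHz (100 log-spaced points, 100 mV rms, 80 ms per point) between chosen
electrode pairs on each incubation day. Electrically the egg behaves like a
giant cell: the shell and membranes are capacitive, the albumen conductive,
so |Z| falls from a low-frequency plateau to a high-frequency one. Low
frequencies are largely blocked by the shell, which is why sweeps are much
noisier below roughly 200 kHz.

Raw |Z| differs between eggs for reasons that have nothing to do with sex —
egg size, shell thickness, electrode contact. The analysis therefore never
compares raw spectra. Its core statistic is the **self-normalized ratio**

$$r(f) = \frac{|Z_{2\text{-}3}(f)|}{|Z_{2\text{-}4}(f)|},$$

two simultaneous measurements on the same egg in the same session. Any
multiplicative factor common to both pairs — instrument gain, egg scale —
cancels, leaving a dimensionless spectrum comparable across eggs
(`ratio_spectrum()`, `ratio_dataset()`). The empirical finding this package
operationalizes is that from incubation day 9, male eggs hold $r > 1$ and
female eggs $r < 1$ over a stable high-frequency band.

## The day-by-frequency scan and the persistence rule

`scan()` runs an independent two-sample t-test (male vs female ratio
values) in every (day, frequency) cell. The default is Welch's unequal-
variance test, two-tailed: recomputing the reference cohort's per-day
p-values from its printed group means and SDs reproduces the reported
two-tailed values to within a few percent for twelve of thirteen days only
under the Welch form, which is what fixes the default (the pooled-variance
and one-tailed variants remain selectable). Day 9 is the known exception:
its reported p (0.006125) is not reproducible from its own printed
summaries (a two-tailed Welch recomputation gives ≈ 0.013; one-tailed gives
≈ 0.0066). The discrepancy is carried as-is — this package documents it and
excludes that single value from exact verification rather than resolving
it.

No multiplicity correction is applied by default, mirroring the original
per-cell α = 0.05 analysis. The guard against the 13 × 100 cells is the
**persistence rule** (`persistence_onset()`): a frequency counts as
discriminative from day d only if p < α on *every* day from d through the
final day (13). The scan reports the earliest such onset day, the maximal
contiguous frequency band persistent from it, and the frequency minimizing
p on the onset day, with ties broken toward the lower frequency. A
Bonferroni option exists (`scan_config(bonferroni = TRUE)`) but is off by
default. Applied to the reference cohort's 13 reported p-values, the rule
dates the discriminative window to day 9; applied to recomputed Welch
p-values, `daily_ratio_table()` stars exactly days 9–13.

Degenerate cells (zero variance in both groups) return p = 1 with a
warning — equal constant groups carry no evidence — rather than aborting a
whole scan; the pathological zero-variance-but-unequal-means case returns
the smallest positive double to preserve p ∈ (0, 1].

## The classifier

`classify_eggs()` thresholds the ratio at a single operating point —
default day 9, the grid point nearest 376 kHz, threshold 1. The nominal
376 kHz is not a point of the default log grid; `nearest_grid_frequency()`
maps it (in log-frequency distance) to 363.8 kHz, index 75. Ratios exactly
at the threshold (or within an optional ± margin) are called indeterminate
rather than forced: the male and female distributions overlap, and "almost
always below 1" is not "always". A band-average variant (mean ratio over
376 kHz–2.79 MHz) is provided since the ratio is stable across that band.

Under a normal model for the day-9 ratio — male
$\mathcal{N}(1.122262, 0.112674^2)$, female
$\mathcal{N}(0.953107, 0.124892^2)$, the reference cohort's day-9 values —
the threshold classifier's sensitivities have the closed form
$\Phi((\mu_M - 1)/\sigma_M) \approx 0.861$ and
$\Phi((1 - \mu_F)/\sigma_F) \approx 0.646$ (`expected_accuracy()`),
balanced accuracy ≈ 0.754. These are model-implied values computed here,
not measured accuracies from any real cohort: the reference study
demonstrated group-level significance, not per-egg classification
performance.

## PCR ground truth

Sex labels come from CHD-locus PCR on a 2% agarose gel: one ~552 bp
fragment = male (ZZ), fragments at ~552 and ~358 bp = female (ZW).
`call_sex_from_bands()` matches observed fragment sizes within a
configurable tolerance (default 15 bp — gels are read approximately; only
nominal marker sizes are published). A record with no matching bands is
"unknown" unless its survival flag marks the egg unfertilized. The bundled
17-egg reference records (8 male, 8 female, 1 unfertilized) ship verbatim
in `inst/extdata/reference_pcr_records.csv`; the companion banding file is
*reconstructed* from those calls through the band rule (no per-egg gel
sizes were published) and is documented as such.

## The synthetic cohort generator

No raw sweeps are deposited anywhere, so the generator
(`simulate_cohort()`) is what makes the pipeline testable end to end. It
emulates:

- **Spectra**: a Cole dispersion
  $Z = R_\infty + (R_0 - R_\infty)/(1 + (i\omega\tau)^\alpha)$ with
  illustrative defaults $R_0 = 10\,\mathrm{k\Omega}$,
  $R_\infty = 200\,\Omega$, $\tau = 1\,\mu s$, $\alpha = 0.85$ — chosen
  once to give a falling spectrum with its dispersion inside the sweep
  range. No published numeric |Z| values exist to calibrate them against;
  they are explicitly illustrative, and nothing downstream depends on them
  because the analysis works on ratios.
- **Noise**: multiplicative log-normal, SD 0.15 (log scale) below 200 kHz
  and 0.02 above, independent across frequencies — the observed
  heteroscedasticity pattern. Multiplicative noise can never produce a
  non-positive |Z|.
- **The sex effect**: injected at the *ratio* level, because the per-day
  ratio summary table is the only quantitative calibration available —
  inventing circuit-level sex differences would be invented precision.
  Each egg draws one effect ratio from its sex's day-9 distribution
  (defaults above) and carries it at every in-band grid point from the
  onset day (9) through day 13: the sex signature is an egg property, so
  it persists across days. Before onset and outside the band each
  (egg, day) draws a baseline ratio from
  $\mathcal{N}(1, 0.12)$ — session-to-session variation with no sex
  information, with dispersion in line with the reference cohort's
  pre-onset rows. Draws are truncated to [0.5, 2] as a physicality guard
  (never triggered at the defaults without extreme seeds; truncation is
  logged).
- **Band snapping**: the requested effect band (default 376 kHz–2.79 MHz)
  is realized on the measured grid by snapping each edge to its
  log-nearest grid point (indices 75–90, 363.8 kHz–2.66 MHz on the default
  grid). This keeps the classifier's default operating point inside the
  planted band.
- **Reproducibility**: each egg consumes its own PRNG substream (derived
  from the cohort seed), so identical seeds give bit-identical datasets.

What the generator does **not** emulate: frequency-correlated noise (an
AR-type structure in log-frequency would be more realistic; noise here is
independent per point), electrode drift and detachment, the repeating
spectral peaks visible in real sweeps, embryo mortality mid-incubation, or
any circuit-level sex difference. Passing tests on synthetic cohorts
therefore demonstrate that the *statistical machinery* recovers what was
planted under realistic dispersions and noise — not that real eggs are
classifiable at any particular accuracy.

## Statistical power under the study conditions

A point worth stating plainly: with 8 male and 8 female eggs and the day-9
effect size above, the Welch test's noncentrality is ≈ 2.84, i.e. per-day
power ≈ 0.76 at α = 0.05. Because the simulated sex signature persists
across days, a cohort whose day-9 test succeeds usually stays significant
through day 13 — but a cohort with an unlucky draw (e.g. a female group
mean 1.5 SE high) fails on *every* day. Simulated recovery of the planted
onset day and band at n = 8 + 8 therefore succeeds in roughly 70% of
seeds, not ~95%: at this sample size the original discovery was, on the
numbers, somewhat fortunate, and the package's tests report the measured
recovery rate rather than tuning the generator to hide it. At n = 20 + 20
(noncentrality ≈ 4.5) recovery is near-certain, which is the cohort size
the deterministic end-to-end pipeline test uses.

## Numerical and interface choices

- **Grid**: "100 points over 20 Hz–10 MHz" is realized logarithmically
  (standard for impedance analyzers spanning six decades); linearly spaced
  data remain loadable because `read_sweeps()` can infer any strictly
  increasing grid. Point k (0-based) is $20 \cdot (10^7/20)^{k/99}$.
- **Days** are integers 0–13; day 0 is the pre-incubation baseline, the
  scan uses days 1–13.
- **|Z| only**: phase is carried through I/O but unused — the analysis is
  defined on impedance magnitude. Whether the analyzer reported |Z|, the
  real part, or series-equivalent values is not recorded; |Z| is assumed.
- **Electrode pairs** are canonicalized to `a-b` with a < b on input.
- **SDs** use the n−1 (sample) denominator everywhere, consistent with the
  spreadsheet convention the reference summaries were produced with.
- **Electrode model**: the resistivity relation ρ = R·A/l gives
  R = ρ·l/A + contact; defaults (ρ = 40 Ω·cm, l = 0.05 cm, A = 1 cm²,
  0.05 Ω contact) reproduce the nominal 2.05 Ω. The stated 40 µL drop over
  1 cm² geometrically implies l = 0.04 cm (→ 1.65 Ω); both are reachable
  through parameters and the inconsistency is simply documented.
- **Repeatability QC** (`rsd_across_repeats()`): per-frequency RSD% across
  repeat sweeps, pass iff < 5% at every point ≥ 100 Hz (electrode
  polarization makes the lowest decades intrinsically unstable).
- **CSV I/O** writes doubles with 17 significant digits, so
  write-then-read is bit-exact.
- **Problem sizes in tests** were chosen to characterize each property
  adequately: 1,000 random samples for the dual-route t-test equivalence,
  2,000 null replicates for the type-I-error check, 100 seeded cohorts for
  band recovery, and a 10,000-egg single-day cohort for the classifier's
  law-of-large-numbers check.

## Limitations

The package analyzes one small reference cohort's summary statistics plus
synthetic data; nothing here validates per-egg classification accuracy on
real eggs. The day-9 reported p-value inconsistency is documented, not
resolved. The Cole circuit defaults are illustrative. The persistence rule
controls multiplicity only heuristically; a formal FWER/FDR treatment is
deliberately out of scope beyond the Bonferroni switch.
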