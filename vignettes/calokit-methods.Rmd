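---
title: "Methods and design of calokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of calokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calokit)
```

`calokit` analyses indirect calorimetry (IC) data: per-animal time series of
oxygen consumption (V̇O2) and carbon-dioxide production (V̇CO2) recorded in
metabolic cages, plus covariate channels (beam-break activity, food and
water intake, ambient temperature) and per-animal metadata. This vignette
explains the models and procedures the package implements, the tunable
parameters and their defaults, the design decisions taken where several
reasonable choices existed, and what the synthetic test bed does and does
not demonstrate.

## The canonical data model

Every stage operates on the `calorimetry_frame`: one row per
(animal, timestamp) sample, gases normalized to ml/h, optional channels
carried alongside, provenance (source file, dialect) in columns.
Timestamps are parsed into a single timezone-naive clock (stored as UTC):
cage experiments run under one local clock, and daylight-saving arithmetic
would corrupt interval logic, so no timezone conversion is ever applied.

Vendor exports differ in header structure, delimiter, decimal mark,
timestamp format and gas units. Because the proprietary formats are not
publishable as fixtures, the package defines five precise, documented text
dialects that mimic the structural variety of the common platforms —
`tse_v1` (semicolon, decimal comma, key–value header, split date/time
columns, ml/h), `clams_v1` (one file per animal, subject id in the header,
ml/min), `sable_v1` (tab-separated with interleaved event rows, l/h),
`cosmed_v1` (generic subject/time/gas table, ml/min, no activity channels)
and `calr_csv` (single-header CSV, also the canonical re-ingestable export).
The registry is extensible at runtime (`register_dialect()`), with the
constraint that first-line signatures stay disjoint so `detect_dialect()` is
deterministic. Unit conversion is a pure multiplicative mapping to ml/h
(ml/min × 60, l/h × 1000); gas values are stored at the precision read, and
fixtures are written at 12 significant digits so write→read round-trips stay
well inside 1e-9 relative error.

## Metadata harmonization

Multi-cohort studies rarely agree on labels ("KO" vs "knockout",
"BodyMass" vs "Weight"). `harmonize_labels()` unifies factor names and
levels in three tiers: trim + case-fold, a small built-in synonym core
(genotype/sex/diet aliases and id/body-mass column aliases) extensible by
user dictionaries, and explicit user overrides, which win over everything
and are logged as such. Every applied rule is recorded in a harmonization
map, the mapping is a function (one canonical label per raw label), and the
operation is idempotent — harmonizing harmonized metadata changes nothing,
which the tests assert as a property. Two *distinct* factors collapsing
onto one canonical name is treated as an error rather than silently merged.

When no photoperiod is defined anywhere, stages that need one fall back to
12:12 with lights-on 07:00 — a common vivarium schedule — accompanied by a
prominent warning, so the assumption is visible rather than silent.

Zeitgeber time is ZT = (clock − lights_on) mod 24 h; ZT0 is light onset,
the light phase spans [0, dark_onset) and the dark phase the remainder,
where dark_onset = (lights_off − lights_on) mod 24 h. All phase
aggregation and day partitioning uses ZT, not the wall clock, unless
calendar days are explicitly requested.

## Curation

Curation separates *flagging* from *removal*. The pre-defined consistency
checks (negative gas values, animals sampled faster than a threshold,
incomplete days, implausible ambient temperatures — default plausible range
20–26 °C, configurable) only count and report; removal happens through
explicit corrective actions so the audit report always reconciles:
input rows − output rows = Σ n_removed across the report. Resampling, the
one step that changes row counts by aggregation rather than deletion, books
its row-count reduction in the same column and is labelled as aggregation.

The chain runs in a fixed, documented order: checks → exclusions → z-score
outlier removal → trimming → day selection → resampling.

* **z-score removal** is single-pass: within each scope group (per animal
  by default — between-animal level differences would dominate pooled
  scores) the mean and sd are computed once on the pre-removal data and
  samples with |z| above the threshold (default 3) are removed. No
  iterative re-scoring: a single pass is reproducible and directly
  checkable against a brute-force oracle. A consequence worth knowing:
  re-applying the filter to its own output recomputes mean/sd on the
  cleaned data and can, on rare borderline configurations, remove further
  points; the pipeline-idempotence property therefore holds for the
  deterministic steps (trimming, day selection, resampling, exclusion) by
  construction, and for z-score removal in the typical regime where the
  cleaned data contains no further exceedances.
* **Trimming** removes habituation/handling segments at the start and end.
  Trims are anchored to the per-animal experiment span recorded at ingest,
  not to whatever survives earlier filters, so the same trim applied twice
  changes nothing.
* **Day selection** partitions each animal's trace into days — zeitgeber
  days starting at ZT0 (default whenever a photoperiod is known) or
  calendar days starting at midnight — and keeps days whose observed
  sample count reaches a fraction (default 0.95, tolerating isolated
  dropped samples) of the expected count, 24 h divided by the animal's
  median sampling interval.
* **Resampling** aggregates to a coarser uniform grid aligned to each
  animal's first sample: intensive channels (gases, temperature) are
  averaged, per-interval quantities (activity counts, food, water) are
  summed. Refining below the native interval is an error, not an
  interpolation.

## Energetics

**EE equation.** The package implements the Heldmaier caloric-equivalent
form in its additive reading,

EE [kJ/h] = (4.44 + 1.43·RER) · V̇O2 [ml/h] · 3.6/1000,

where 4.44 + 1.43·RER is the caloric equivalent in mW per (ml O2/h) and
3.6/1000 converts mW·(ml/h-basis) to kJ/h. The additive form is the only
dimensionally and physiologically coherent one: a multiplicative
combination of the two coefficients would make EE vanish at RER = 0 and
could not represent an oxygen-only caloric equivalent. A Weir-type
equation (3.941 kcal/L O2 + 1.106 kcal/L CO2, converted to kJ/h) is
registered as `"weir"`; the registry is user-extensible.

**Substrate oxidation** uses Frayn-type non-protein stoichiometry,
fat_ox = 1.67·(V̇O2 − V̇CO2)/1000 and cho_ox = (4.55·V̇CO2 − 3.21·V̇O2)/1000
g/h, with the coefficients centralized in one constants table so a
different stoichiometry can be substituted. Negative rates (RER outside
the non-protein band) are flagged, never clamped — they carry information
about protein oxidation or measurement problems. A soft consistency check
in the test suite verifies that fat_ox·39.6 + cho_ox·16.7 kJ/g tracks EE
within 5% for RER in [0.71, 1.0]; the closure degrades toward ~6% at
RER = 1.0 exactly, which is why the band is asserted on synthetic traces
(RER 0.75–0.95) rather than at the boundary.

**RER band.** Values outside [0.5, 1.3] are physiologically implausible
for rodents and are flagged; the band is never used as a filter.

**RMR from signal variability.** The resting metabolic rate is the level
of the quietest sustained segment of the EE trace. A window of
`window_length` (default 30 min — long enough to exclude transient
plateaus between activity bouts at typical 1–10 min cage sampling) slides
over each animal's EE series at single-sample steps, optionally restricted
to one photoperiod phase; windows with coefficient of variation
(sd/mean) ≤ `cov_threshold` (default 5%) qualify, and RMR is the minimum
qualifying window mean. If no window qualifies (relentlessly active
traces), RMR falls back to the mean of the lowest `fallback_percentile`
(default 5%) of samples, and the result records which method was used.
TEE = 24·mean(EE) is computed over the curated trace — running the
complete-day filter first avoids partial-day bias — and AEE = TEE − 24·RMR.
A negative AEE (possible when the fallback overestimates RMR, or on
near-resting traces) is flagged, never clamped.

**Locomotion density** is the joint 2-D histogram of the per-sample
(activity_x, activity_y) beam-break coordinates, each sample weighted by
its total count, normalized to unit mass over bins spanning the observed
range.

## Statistics

Per-animal summaries (one value per animal — RMR, TEE, AEE, phase means)
enter ANOVA/ANCOVA (gaussian, least squares) or Poisson GLMs (maximum
likelihood) with the harmonized factors and numeric covariates such as
body mass. Factorial terms are tested with Type-II sums of squares by
default — robust to the mild imbalance that real cohorts always have, and
respecting marginality — implemented by nested model comparisons (each term
tested against the model containing all terms that do not contain it, F
against the full-model residual mean square; likelihood-ratio chi-square
for Poisson). Type-III with sum-to-zero contrasts is available via
`ss_type = 3`. The test suite cross-checks the Type-II tables against an
independent reference implementation (`car::Anova`) to 1e-6 on random
unbalanced designs, keeping implementation and oracle separate.

Assumption checks are Shapiro–Wilk on the *model residuals* (testing
per-group would multiply tests and lose power at cage-study sample sizes;
residual-based testing matches the model actually fitted) and
median-centered Levene across the factor-level groups, each summarized as
a pass/fail check-mark at α = 0.05. α is fixed, not configurable, so
check-marks stay comparable across reports. Tests whose prerequisites are
not met (fewer than 3 residuals, groups of size 1) are reported as *not
computable*, never as failed.

Post-hoc contrasts are all pairwise level comparisons of one factor:
Tukey HSD (the default for a single factor) or pooled-sd pairwise t tests
with Holm (default), Bonferroni or Benjamini–Hochberg correction.
Asterisks follow the conventional thresholds (0.05 / 0.01 / 0.001).
ANCOVA results additionally report covariate-adjusted group means
(predictions at the grand covariate mean).

## The synthetic cohort generator

The generator is first-class, tested code: it emulates exactly the
features the analysis stages are sensitive to, with known ground truth.
Per animal, EE(t) = RMR + dark_increment·s(t) + Σ bursts(t) + ε, where
s(t) is a dark-phase indicator smoothed by a 30-min linear ramp (avoiding
discontinuity artifacts in window statistics), bursts are Poisson events
(80% of the rate in the dark phase) with exponentially decaying amplitude,
and ε is Gaussian measurement noise. RER drifts between a light-phase and
a dark-phase value along s(t), and the gas traces are obtained by
*inverting* the EE equation — so recomputing EE from the generated gases
reproduces the ground truth to floating-point precision, an identity the
tests assert.

Defaults describe a mouse-scale nocturnal animal under 12:12 light:
RMR 8 kJ/h, dark increment 6 kJ/h, 2% measurement noise (0.16 kJ/h),
5-min sampling, 3-day recordings, 25 g body mass, RER 0.75 light / 0.95
dark. Cohorts add a two-group structure: an additive group effect on RMR,
a body-mass slope of 0.25 kJ/h per g around the 25 g cohort mean, and
animal-level jitter of 1 kJ/h. Seeding is hierarchical (cohort seed →
per-animal seeds), so adding an animal never perturbs the others.
`simulate_cohort(..., timeseries = FALSE)` returns only the animal-level
summaries and metadata — distributionally identical at the animal level by
construction — which is what the repeated-simulation calibration studies
(type-I error over 500 null cohorts, CI coverage over 200) use; full gas
time series for those studies would add runtime without exercising any
additional code path in the model-fitting stage. Single full-time-series
cohorts (2–6 animals per group, 2–3 days) are used everywhere the
measurement pipeline itself is under test.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: thermoregulatory coupling between ambient
temperature and EE, food-intake/EE coupling, instrument drift and
calibration offsets, missing-data bursts from cage openings, and
protein oxidation. Conclusions about those belong to real-data validation.

## Export

All tabular artifacts export to UTF-8 CSV with ISO-8601 timestamps and
"." decimals at 15 significant digits, and re-import to equal objects.
The consolidated multi-sheet workbook (Data, EnergyTrace, RMR, Stats,
Curation, Metadata, Config) is written as SpreadsheetML 2003 XML — a
plain-text multi-sheet format that Excel and LibreOffice open natively and
that keeps the artifact fully text-based and diffable. Figures
(time series with shaded dark phases, box/bar with significance stars,
locomotion density maps, ZT profiles) are static SVG/PDF/PNG rendered with
base graphics; given the same data and style they are deterministic.

The `cmd_analyze()` pipeline is referentially transparent: identical
config + inputs (+ seed) produce byte-identical CSV outputs, which the
tests verify literally. On a stage error, partial outputs are deleted and
the failing stage is named in the condition message.

## Numerical choices and degenerate inputs

* Fixture numbers are written at 12 significant digits (round-trip error
  ≲ 5e-12, asserted bound 1e-9); canonical CSV at 15.
* Zero-variance groups in the z-score filter produce a warning and no
  removals (a z-score is undefined there).
* A constant response in the model fit yields statistic 0 and p = 1
  rather than 0/0.
* `vo2 ≤ 0` yields a missing RER with a flag — curation should have
  caught it, and energetics refuses to invent a number.
* Degenerate selection rectangles and empty exclusion lists are no-ops
  with zero counts, not errors; excluding *every* animal is an error.
* The RMR window is re-expressed in samples (≥ 3) from the animal's median
  interval; traces shorter than twice the window are rejected.

## Known limitations

* The dialect registry mimics vendor structure but is not validated
  against proprietary binary exports; real-file conformance requires
  adding a dialect spec per local export flavour.
* Flat key–value metadata only; no ontology-backed hierarchies.
* No mixed-effects/repeated-measures models; one summary value per animal
  enters the statistics stage.
* The CoV-window RMR method is one defensible operationalization of
  variability-based RMR extraction; its parameters are exposed precisely
  because conventions differ between labs.
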