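---
title: "Methods: Transwell barrier assay analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Transwell barrier assay analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barriertools)
```

This vignette documents the models, conventions and design choices behind
`barriertools`. The package analyses in vitro blood–brain-barrier (BBB)
Transwell experiments: endothelial cells grown on a permeable coated
filter separate an apical ("blood", 500 µL) from a basolateral ("brain",
1500 µL) compartment, and everything the package computes derives from
tracer movement between the two.

## The two-compartment sink model

All permeability estimates assume a two-compartment system under sink
conditions: the donor concentration `C_d` is treated as constant over the
assay, and the receiver concentration stays far below equilibrium, so the
flux is constant and the transported amount is linear in time,
`Q(t) = PS · C_d · t`, with `PS` the permeability–surface-area product
(µL·min⁻¹).

Two features of the clearance protocol support the sink assumption. First,
the insert is transferred to a fresh receiver well every 20 min, resetting
the receiver to zero concentration. Second, the mass-balance QC
(`mass_balance()`, 80–120 % recovery inclusive) rejects wells where the
dose bookkeeping is off by more than 20 %; with the default control-level
permeabilities the donor loses only a few percent of its content over
60 min, so treating `C_d` as the nominal dose is accurate to well under the
noise floor.

**Clearance curve.** `cleared_volume_series()` converts each interval's
receiver signal into a cleared volume
`(signal / calibration) · V_receiver / C_donor` and accumulates the
intervals, prepending the origin. Fluorescence is assumed linear in
concentration after blank subtraction, with one `signal_per_conc`
calibration factor per plate.

**Slope fitting.** `fit_ps()` is ordinary least squares of cleared volume
against time with a free intercept, the origin `(0, 0)` included as an
ordinary data point. The protocol defines the curve from time zero but
does not prescribe the intercept treatment; fitting a free intercept and
using only the slope makes the estimate robust to a small mixing or
temperature-equilibration offset at the start of the assay, while the
origin point anchors short series. Only the slope enters downstream
quantities; intercept and r² are reported for QC.

**Filter correction.** The coated filter and the monolayer are barriers in
series, so resistances (reciprocal PS values) add:

\[ \frac{1}{PS_t} = \frac{1}{PS_e} + \frac{1}{PS_f}
   \quad\Longrightarrow\quad
   PS_e = \left(\frac{1}{PS_t} - \frac{1}{PS_f}\right)^{-1} . \]

`correct_series_resistance()` uses this subtractive form by default, which
guarantees `PSe ≥ PSt` and errors when `PSt ≥ PSf` (an insert with cells
cannot out-conduct the blank filter; in practice this means swapped
inputs). Some reports quote the relation with a `+` sign; that additive
variant is available as `form = "as_printed"` for comparison, but it makes
the monolayer appear more permeable than the whole insert and is not the
default. A corollary worth stating because it is easy to get backwards:
at a *fixed measured* `PSt`, a larger `PSf` yields a *smaller* corrected
`PSe` — if the blank filter was leakier, more of the observed resistance
must have come from the cells.

**Units.** Internal canonical units are µL, min, cm and cm²;
`pe_from_ps()` converts `Pe = PSe·10⁻³ / S` into cm·min⁻¹ with
`S = 1.12 cm²` (the 12-well insert) by default. Summaries carry `*_scaled`
columns in the conventional reporting units (Pe ×10⁻³, Papp ×10⁻⁶
cm·min⁻¹).

## Pathway decomposition

At 4 °C all active (vesicular, receptor-mediated) transport stops, so the
cold-assay Pe isolates the paracellular route and

`Pe_transcellular = Pe(37 °C) − Pe(4 °C)`

exactly, by construction (`decompose_pathways()`). A negative difference
is physically suspect and is returned unclamped with a warning flag, so
that downstream averaging is not biased by silent truncation. 4 °C runs
are corrected with filter-only controls measured at 4 °C; 37/4 °C pairing
is by `condition_id`. Per-condition Pe is computed per filter and then
summarised as mean ± SEM across (at least) triplicate filters.

## Transport quotients

`compute_papp()` implements the standard single-interval apparent
permeability `Papp = Q/(t · A · C0)` (30 min by default). The
tracer-specific transcytosis quotient divides the tracer's Papp by that of
co-dosed FITC-inulin *on the same filter*; `analyze_transport()` averages
the per-filter ratios rather than taking the ratio of condition means.
The two aggregations differ slightly in general; per-filter ratios cancel
filter-to-filter geometry and seeding variation, which is also the
signature visible in published control values (the quoted quotients differ
from the ratio of the quoted mean Papps). Direction bookkeeping swaps the
donor/receiver volumes (500 ↔ 1500 µL) and nothing else. A co-run
integrity tracer can veto leaky inserts via `integrity_flag()` (control
mean + 3 SD, requiring ≥ 3 control replicates).

## qPCR, densitometry, viability, images

* **ΔΔCt** (`ddct_fold()`, `analyze_qpcr()`): technical (triplicate-well)
  Cts are averaged per sample first, then per-sample
  `ΔCt = Ct_target − Ct_reference` is anchored on the mean control ΔCt;
  per-sample folds `2^(−ΔΔCt)` are summarised as mean ± SEM. Averaging Cts
  before the Δ step, and computing per-sample folds before averaging, are
  the two points where conventions diverge silently between labs; both
  choices are stated here and fixed. No primer-efficiency correction is
  applied — the plain `2^(−ΔΔCt)` form is used and efficiencies are QC
  metadata (`efficiency_qc()`, accepted band 85–115 %, spanning the
  validated primer panel of the target model, 86.1–112.3 %).
* **NRT/NTC gate**: a gene fails plate QC when any no-RT or no-template
  control amplifies within 5 cycles of the sample mean. The 5-cycle value
  is a configurable convention (≈ 97 % of the signal being genuine), not a
  published constant.
* **Densitometry** (`densitometry_pct_of_control()`): band densities are
  divided by same-lane β-actin, then referenced to the control lane ratio.
* **MTT** (`mtt_viability()`): exactly
  `100 · (OD570 − OD630)_condition / (OD570 − OD630)_control`.
* **Area fraction** (`area_fraction()`, `count_nuclei()`): fraction of
  stain pixels at/above a per-stain constant threshold, normalized by the
  nuclei count of the paired DAPI channel. Nuclei are 8-connected
  components above a threshold with a minimum area (default 20 px) to
  reject specks. Because acquisition thresholds are fixed per stain within
  an experiment but not comparable across stains or instruments, area
  fractions are only meaningful as percent of control, which is what
  `summarize_area_fractions()` reports.

## Statistics

`mann_whitney()` enumerates the exact null distribution of the U statistic
(count recurrence, no ties, `n + m ≤ 16`) and reports the two-sided
`p = min(1, 2·P(U ≤ U_obs))` with `U_obs` the smaller of the two one-sided
counts; with ties or larger samples it switches to mid-ranks with the
tie-corrected normal approximation and continuity correction, and records
which method ran. Exactness matters here because typical group sizes are
n = 3 filters, where the normal approximation is meaningless and the most
extreme achievable two-sided p is 0.1. `t_unpaired()` is the
pooled-variance two-sample t (a Welch switch is provided), with explicit
handling of zero-variance degenerate groups: p = 1 for equal means, p = 0
with a degeneracy flag otherwise. Significance labels use strict
thresholds (`*` < 0.05, `**` < 0.01, `***` < 0.001). No multiple-testing
correction is applied anywhere, matching the reporting conventions of the
assay field this package serves.

## The synthetic generator

`sim_config()` + `simulate_*()` forward-simulate every assay with known
ground truth. The defaults *are* the study conditions of the target BLEC
model: control Pe 0.54 / 0.18 / 0.36 ×10⁻³ cm·min⁻¹
(total / paracellular / transcellular), filter-only PS 2.0 µL·min⁻¹
(back-calculated from those control values through the series formula),
control Papp pairs 5.14/1.67 and 4.47/1.41 ×10⁻⁶ cm·min⁻¹, cytokine
multipliers reproducing the published percent effects (TNF-α:
transcellular ×1.401, paracellular ×2.752, specific efflux ×0.731;
IL-1β: ×1.942, ×1.413, ×0.741), junctional-gene fold changes, 73.5 %
viability under 10 % DMSO, and triplicate filters per condition.

**Noise model.** Every simulated reading gets independent multiplicative
Gaussian noise with a configurable CV (default 3 %, a typical
plate-reader figure; the underlying protocols publish no noise model).
For qPCR the noise acts on the linear expression scale, i.e. inside the
`log2`, so a global Ct shift leaves folds invariant by construction.

**Donor bookkeeping.** The generator computes interval fluxes under the
same constant-donor sink assumption the analysis makes, and books the
donor's final reading as dose minus everything transferred. This makes
the noiseless mass balance exactly 100 % *and* the noiseless pipeline
recover the configured truth to numerical precision — the round trip that
anchors the test suite. A `deplete_donor = TRUE` option instead updates
the donor concentration after each transfer; it is more faithful to the
physical experiment, and the resulting sink-assumption bias (pipeline
under-reads truth by < 3 % at default settings) is itself verified by a
property test.

**Images.** Nuclei are non-overlapping bright disks on a jittered grid
(about 50 per image, matching typical field density); junctional stain is
painted as cell-border lattice lines, widened borders, then scattered
cytoplasmic dots — the order mimicking the continuous-junction versus
delocalized-dot phenotypes — with the painted pixel count cut exactly at
`round(fraction · n_pixels)`, so the noiseless area fraction is exact by
construction. Generator intensities are background 50, stain 800, nuclei
1000; quantification uses thresholds 400/500.

**Determinism.** Each assay draws from its own substream
(`seed + fixed offset`), so assays can be simulated alone or together,
in any order, with identical results; generators restore the caller's
random-number state.

**What passing tests do and do not show.** Noiseless round-trips prove
the analysis inverts the generator's data model exactly; noisy recovery
(e.g. mean control Pe within 2 % of truth at 3 % CV, n = 3, over 200
seeded runs) shows the estimators are unbiased under that noise model.
Real plates violate the model in ways the generator deliberately omits:
tracer binding to plastic, edge effects, temperature drift, pipetting
covariance between compartments, non-Gaussian imaging noise and uneven
illumination. Agreement with the configured truths is therefore a
software correctness statement, not an empirical claim about BLEC
biology.

## Configuration and interfaces

Run configurations are plain YAML files mirroring `sim_config()`'s
arguments (`read_run_config()`); tables are YAML record lists. All
analysis functions take plain long-format data frames (CSV-roundtrippable
via `read_plate_csv()`/`write_plate_csv()`), return tibbles, and have
`autoplot()` methods; a thin command-line wrapper with `simulate`,
`permeability`, `transport`, `qpcr`, `viability` and `report` subcommands
ships in `inst/scripts/barrier-cli.R`.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at the
study's own scale — 3 conditions × 2 temperatures × 3 filters for
clearance, 3 × 2 × 3 wells × 3 tracers for transport, 6 genes × 3
samples × 3 technical replicates for qPCR, 3 images of 192² px — which
keeps the full suite under a minute apart from the deliberately exhaustive
checks (exact-test enumeration up to 8 + 8 samples; 200 seeded noisy
recoveries). Numerical conventions: mass-balance and efficiency bounds are
inclusive; Mann–Whitney exactness requires tie-free data and `n + m ≤ 16`;
negative transcellular Pe and degenerate t tests are flagged, never
silently altered; QC-failing wells are excluded from condition means but
reported in `n_qc_fail`.

## Known limitations

* No modelling of tracer–plastic binding, multi-compartment kinetics
  beyond the two-compartment sink model, or TEER.
* The donor compartment is sampled only at the end of the assay; the data
  model has no per-transfer donor readings.
* No receptor-level kinetics of Aβ transport and no aggregation modelling;
  quotients are purely ratio-metric.
* Image quantification is whole-image area fraction per nucleus — no cell
  segmentation, junction-continuity scoring or colocalization.
* The exact Mann–Whitney path requires tie-free data; tied small samples
  fall back to the (approximate) normal method, which is conservative at
  n = 3.
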