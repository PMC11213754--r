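---
title: "Models and methods behind biodeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind biodeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodeg)
```

This vignette documents the models, conventions and design choices the
package rests on — the things a reviewer of a biodegradation study
would want to know before trusting the numbers.

## 1. Stoichiometric potentials

Anaerobic mineralization of a repeat unit
$\mathrm{C_xH_yO_zN_dS_e}$ is balanced by the Buswell equation; the
methane coefficient $n_{CH_4} = x/2 + y/8 - z/4 - 3d/8 - e/4$ gives the
theoretical biochemical methane potential per gram,

$$\mathrm{BMP_{theoric}} = \frac{22.4\,n_{CH_4}}{M_r},$$

and complete aerobic mineralization of a C/H/O polymer requires

$$\mathrm{ThOD} = \frac{31.9988}{M_r}\,(c + 0.25h - 0.5o)
\quad\text{g O}_2\text{ per g.}$$

**Mass conventions.** $M_r$ uses the integer atomic masses 12, 1, 16,
14, 32. Two deliberate asymmetries: the molar gas volume is exactly
22.4 L/mol (not 22.414), and oxygen *mass* conversions use the exact
O$_2$ molar mass 31.9988 g/mol. These match the forms in which the two
formulas are conventionally printed, so the package reproduces standard
tabulated values to the digit (PE 1.20 and 3.43, PET 0.58 and 1.67, PCL
0.74 and 2.11). Some printed versions of the per-gram Buswell formula
carry a typographical *12* as the oxygen mass in the denominator; only
16 reproduces the tabulated potentials (with 12, PCL would give 0.79
L/g instead of 0.74), so 16 is used and the discrepancy is noted in the
code.

Internal values are kept at full precision; rounding (half-even, two
decimals) happens only at report time. Formulas are repeat units over
C, H, O, N, S only — no parentheses, hydrates, charges or halogens
(PVC-type polymers are out of scope). A formula too oxidized to yield
methane is flagged, not rejected; ThOD is defined only for $d = e = 0$
and errors otherwise.

## 2. From headspace readings to cumulative curves

Headspace gas inventories use ideal-gas accounting at the incubation
temperature: $n = \phi\,P\,V_{hs}/(RT)$ with $\phi$ the measured mole
fraction. Choices a user should know:

* **Pressure.** Per-timepoint pressures are rarely recorded in this
  assay type, so the default assumes the headspace stays at the
  configured initial pressure (anaerobic) or the per-segment fill
  pressure (aerobic); a `pressure_pa` column on readings overrides
  this per reading.
* **Anchoring.** The first reading (at or near day 0) anchors the
  initial inventory, so every curve starts at (0, 0). Gas removed by
  sampling and gas dissolved in the medium are neglected — headspace
  quantification only, stated as an assumption rather than corrected.
* **Flush accounting (aerobic).** Consumption within an inter-flush
  segment is segment-start moles minus moles at each reading; segments
  are summed. A flush closes the running segment at the last reading
  before it (consumption between that reading and the flush is
  unobservable and counted as zero — flushing immediately after a
  measurement makes this exact), and the next segment starts from the
  post-flush composition and pressure, so replenished O$_2$ is never
  counted as consumed.
* **Blank correction** subtracts the time-wise mean of the blank
  curves, linearly interpolated onto the sample grid. Negative
  corrected values are reported and flagged, never clipped. Blanks not
  covering the sample range are an error unless end-hold is explicitly
  enabled.
* **No smoothing, no kinetic fit.** Measured curves are used as-is;
  interpolation is linear. Decreases beyond 2% of the running maximum
  *and* 2 mL (STP) raise a data-quality warning — the absolute floor
  keeps instrument-level scatter on near-zero curves from being
  reported as anomalies — but are never silently repaired.
* **STP basis** is 0 °C, 1 atm with 22.4 L/mol; O$_2$ mass uses
  31.9988 g/mol, consistent with the potentials above.

## 3. Percent biodegradation

Per replicate, the endpoint of the blank-corrected curve (the last
time point — a plateau detector would annotate, never change, the
number) is divided by the plastic mass and by the theoretical
potential. The group result is the replicate mean ± SD (n−1). The
theoretical anaerobic ratio carries no blank term, but early methane in
these assays comes from residual substrate in the inoculum that blanks
share, so blank correction is applied by default under both bases (a
switch disables it). Values above 100% — which real replicate scatter
produces — are flagged and reported unmodified. Only replicate scatter
enters the SD; $M_r$ and the molar volume are treated as exact.

**Inoculum validation.** Anaerobic cellulose controls must convert
82–95% of theory, endpoints inclusive (the conservative reading of a
band stated without strictness). No comparable band is established for
aerobic controls, so they are reported descriptively with `pass = NA`.

## 4. Community summaries

Counts are aggregated to the requested rank; taxa unassigned there are
pooled under their deepest assigned rank and labelled (e.g. `"Bacteria
(kingdom)"` — kingdom-only assignments are a large fraction of real
leachate data sets and are shown, not hidden). The percentage
denominator is each sample's reads classified at least at kingdom
level; fully unclassified reads are excluded and their count logged.
The display threshold is strict (`> 1%`, so a taxon at exactly 1% is
pooled into the residual bucket), and every emitted profile sums to
100% including that bucket. Prokaryote (16S) and eukaryote (18S)
tables are processed separately — never merged into one denominator.
The kingdom split (`domain_split()`) is computed over all reads, with
non-Bacteria/Archaea and unassigned kingdoms bucketed as "other". No
diversity indices, ordination or differential abundance: relative
abundances only.

## 5. The synthetic-data generator

The generator exists so that every pipeline stage is testable without
laboratory data; its defaults *are* the study design it emulates:
120 mL bottles with 45 mL (anaerobic, N$_2$/CO$_2$ 80:20 at
1.7×10⁵ Pa) or 50 mL (aerobic, air at atmospheric pressure) of medium,
55 °C, 62.5 mg plastic, triplicate samples and blanks, twice-weekly
sampling over 60 days.

* **Curve family.** Cumulative gas follows a modified Gompertz curve —
  lag (default 10 d, the adaptation period typical of these assays),
  maximum rate, asymptote $f \cdot \text{potential} \cdot \text{mass}$
  where $f$ is the true biodegraded fraction. The default rate,
  asymptote/15 per day, reaches >99.9% of plateau within the 60-day
  horizon; the pipeline never fits this model, so the choice cannot
  bias the analysis.
* **Blank realism.** A shared residual-substrate component
  (default 5 mL STP per bottle, saturating with a 5-day time constant)
  is added to samples and blanks alike, so blank correction removes it
  exactly in the noise-free limit.
* **Noise** is multiplicative Gaussian on mole fractions (GC-like,
  default 2%), truncated to [0, 1].
* **Aerobic O2 limitation.** Demand above the O$_2$ present is carried
  over — degradation pauses when the bottle runs out of oxygen and
  resumes after the next flush, as in a real O$_2$-limited incubation.
  A flush is triggered at a reading when the headspace O$_2$ fraction
  falls below 0.05, and the syringe-injected fresh air pressurizes the
  bottle (default 1.7×10⁵ Pa): with twice-weekly sampling and
  atmospheric refills alone, a 120 mL bottle could not supply the
  ~130 mg of O$_2$ that full PCL mineralization demands within the
  incubation — the pressurized refill is the physically consistent
  reading of re-flushing in this design.
* **Determinism.** Every generator takes a seed, restores the caller's
  RNG state, and records the seed in its ground-truth manifest.

What a green test on synthetic data does **not** establish: real GC
noise is not exactly multiplicative, real headspace pressure drifts
with biogas production and sampling, polymer crystallinity and particle
size alter kinetics, and real blanks are not distributionally identical
to samples. The generator validates the *accounting*, not the biology.

Taxon tables are drawn multinomially from Dirichlet-perturbed target
compositions (concentration parameter 500 by default — visible but
modest between-sample variation); the shipped preset emulates a
thermophilic methanogenic community with a dominant hydrogenotrophic
methanogen genus, a 77/23 Bacteria/Archaea split and a ~31%
kingdom-only fraction.

## 6. Acceptance-test interpretation

The headline percentages of the study this design mirrors rest on
laboratory gas measurements that are not available as raw data, so the
acceptance suite checks *parameter recovery* instead: for true
fractions {0.03, 0.78, 0.87, 0.99} at 2% noise with triplicates, the
pipeline's grand mean over eight seeded repeat assays must lie within
three standard errors of $100f$. Repeats are used because a standard
error estimated from a single triplicate has only two degrees of
freedom — a "within 3 SE" check at that df fails ~10% of the time for a
perfectly unbiased pipeline; pooling 24 replicates makes the check a
genuine bias test. Recovery simulations here measure bias below 0.3
percentage points everywhere on this grid.

## 7. Known limitations

* Constant-pressure headspace accounting ignores biogas overpressure;
  with per-reading pressures supplied the limitation disappears.
* No CO$_2$ correction of measured O$_2$ fractions (respiratory CO$_2$
  accumulating in the headspace is not modelled; no correction is
  applied by default since the assay convention is silent on it).
* The endpoint is the final time point; assays stopped mid-rise
  under-report (the generator warns when a schedule cannot contain
  lag + rise).
* Run configurations are JSON (no YAML reader in the dependency
  footprint); the structure is a direct mirror of what a YAML config
  would hold.
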