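---
title: "Methods: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chelaweather)
```

This vignette documents the quantitative models behind each module,
where every default parameter comes from, what the synthetic-data
generators do and do not emulate, and the numerical and design
decisions a reviewer would want spelled out.

# 1. Omics quantification

## Model

A read of length $L$ bp matching a protein of length $S$ aa contributes
$L / (3S)$ **full-length copies** of the gene (3 bp per codon). Summing
over a sample's reads gives raw copies per orthologue; dividing by the
sample's full-length copies of **rpoA** — the RNA-polymerase alpha
subunit, universally single-copy in bacterial genomes — converts to
*copies per genome* (metagenomes) or *transcripts per rpoA transcript*
(metatranscriptomes). The normalization is exactly invariant to
sequencing depth: duplicating every read changes nothing.

## Assumptions and choices

- Hits are expected **one per read** (best hit). Duplicated read IDs
  within a sample are resolved by keeping the lowest E-value, with a
  warning — they indicate an upstream problem, not a normal input.
- Annotation is assumed to have been run at a permissive E-value cutoff
  (1e-3); the analysis applies a stricter post hoc cutoff of **1e-5**
  (`filter_hits()` default). Both are conventional homology-search
  thresholds.
- Genus-level desB/rpoA ratios estimate the fraction of genomes in a
  genus carrying the gene. Genera with marker copies below 0.1
  full-length copies are *flagged*, not dropped: at that depth the
  ratio's denominator is a fraction of one observed gene and the ratio
  is essentially noise.
- Substrate contrasts use Welch's t-test by default (no equal-variance
  assumption between, say, grain-surface and bulk-soil communities) and
  report raw p-values; multiplicity correction is left to the caller
  because the panel size is analysis-specific.

# 2. CAS and bioassay calibration

The chrome azurol S assay reads absorbance at 630 nm, which *decreases*
as siderophores strip Fe(III) from the dye complex. Calibration is a
straight line of response on concentration, fit separately for a low
range (0, 1, 3, 5, 7.5, 12.5 µM desferrioxamine-B equivalents) and a
high range (15, 20, 25, 30 µM); strong samples are read sixfold diluted
and scaled back. Inversion is the closed-form
$c = d \,(A - b)/m$ for dilution $d$, intercept $b$, slope $m$.

Readings whose back-calculated value falls outside the fitted standards
are **flagged as extrapolated rather than rejected** — the flag travels
with the value so downstream code can decide. A constant-response
curve is rejected as non-invertible. No sign is imposed on the slope,
so the same contract serves growth-based bioassays (positive slope).

# 3. Dissolution kinetics

## Model

Measured (diluted) concentrations are corrected as
$c = d \cdot c_\mathrm{meas} - c_\mathrm{blank}$, clipped at zero with a
flag (concentrations are physical). Release rates are
$R_X = c\,V / (m\,t)$ in mol g⁻¹ h⁻¹ with defaults $m = 0.05$ g basalt,
$V = 10$ mL, $t = 90$ h — a typical small-batch grain-dissolution
frame. The whole-rock rate is the exact sum over Mg, Ca, Na, Si, Al,
Ti, Fe; Mn is measured but excluded by default (configurable).

## Concentration-response selection

Ligand-promoted dissolution is first-order in dissolved ligand at low
surface coverage and saturates as reactive sites fill, so a
quadratic-with-negative-curvature polynomial often beats a straight
line. Both are fit by OLS and compared with AIC in the residual
sum-of-squares form

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k,$$

$k = 3$ (linear) or $4$ (quadratic), counting the error variance. Two
guards make the comparison total: an exact fit (RSS = 0) gets
$-\infty$, and ties — including $-\infty$ vs $-\infty$ on noise-free
linear data, which both models fit perfectly — go to the **simpler**
model. The quadratic is only a candidate with ≥ 4 distinct
concentrations (otherwise it is saturated or unidentifiable). This RSS
form ranks models identically to the likelihood-based AIC for a shared
$n$, which is all that selection needs.

# 4. Carbonate chemistry and CDR accounting

Speciation uses the closed form
$\alpha_{HCO_3} = \left(1 + [H^+]/K_1 + K_2/[H^+]\right)^{-1}$
with $pK_1 = 6.35$, $pK_2 = 10.33$ (freshwater, 25 °C). These
constants shift with temperature and ionic strength; both $K$s are
arguments, so users with site-specific constants can supply them.

Charge balance compares cation equivalents $2([Ca]+[Mg])$ (+ monovalents
where present) against anion equivalents
($[HCO_3^-] + [Cl^-] + $ chelator anion charge). Potassium adsorption
to exchange sites is inferred as $K_\mathrm{initial} - K_\mathrm{final}$,
floored at zero with a flag.

CO2-removal potential follows weathering stoichiometry: **2 mol CO2 per
mol divalent cation, 1 per monovalent**, mass basis × 44.01 g/mol.
Negative cation deltas (net adsorption/precipitation) propagate with a
flag rather than being clipped — silently zeroing them would bias CDR
upward.

# 5. Soil incubations

Design emulated: *soil* vs *soil + basalt* microcosms at 0/100/425/750
µM EDDHA, destructively sampled in triplicate at days 0/3/10/20;
exchangeable cations by 1 M ammonium acetate (pH 7).

The **CDR-gain statistic** is, per EDDHA level and element,
$\Delta_\mathrm{net} = \Delta(\text{soil+basalt}) - \Delta(\text{soil})$
over day 0 → 20 (mg/kg), converted to mol/kg and then to CO2 potential,
expressed as a fold over the 0 µM level. Deltas are deliberately *not*
divided per day: no uniform rate is assumed over the window. SEMs
propagate as $\sqrt{SEM_0^2 + SEM_{20}^2}$. Constant offsets in any
element cancel exactly — the statistic sees only changes.

Trend tests are Pearson correlations run on **replicate-level** values
(per-sample degrees of freedom), not level means, which would overstate
confidence. The prebound-Fe contrast is a two-way ANOVA of hot-water
Fe on prebound Fe:DFOB status and substrate; noise-free fixtures make
the residual mean square exactly zero, so the implementation classifies
the degenerate cases explicitly (no effect → $F = 0$, exact planted
effect → $F = \infty$) using a tolerance relative to the data's scale.

# 6. Techno-economics

All monetary and emission figures trace to five printed per-hectare
anchors for a 750 µM, 20 %-moisture scenario: dose 77.5 kg/ha, K
co-input 23.5 kg/ha, gross cost \$209/ha, fertilizer offset \$38/ha,
production emissions ≈ 1 t CO2/ha. Several scenario constants are
**calibrated** — back-derived so the model reproduces those anchors —
rather than primary data, and each field's provenance
(`printed` / `calibrated` / `derived` / `user`) is recorded on the
scenario object and shown by `print()`:

- *dry plough-layer soil mass* 1008 t/ha reproduces the 77.5 kg/ha
  dose (≈ 25 cm at bulk density ≈ 1.3 g/cm³ — a plausible plough
  layer, which is the sanity check, not the derivation);
- *chelator price* \$2.70/kg = 209/77.5, *K value* \$1.62/kg = 38/23.5,
  *LCA factor* 12.9 kg CO2/kg = 1000/77.5;
- *CDR fold at target* $(3.3 + 1.0)/3.8 + 1 \approx 2.13$ inverts
  "net additional CDR = baseline × (fold − 1) − LCA" with baseline
  3.8 t/ha/yr and net additional 3.3 t/ha/yr;
- molar mass 512.7 g/mol is the tetra-potassium EDDHA salt
  (C₁₈H₁₆N₂O₆K₄).

The equivalent rock rate solves
$\text{rate} \times \frac{\text{baseline}}{\text{reference rate}}
\times \text{fold} - \text{LCA} = \text{target}$, giving ≈ 29.6 t/ha/yr
to match a 50 t/ha/yr unamended benchmark. Cost per tonne spreads the
baseline cost plus the net chelator cost over the enlarged CDR.

Soil-moisture uncertainty is propagated by evaluating every
moisture-dependent output on a **uniform 31-point grid** over the
moisture range (default 10–25 % w/w), reporting central/min/max/SD.
A grid, not Monte Carlo: every output is monotone in moisture, so the
extremes are exact, the result is deterministic, and no distributional
assumption on moisture is smuggled in. The reported SD is simply the
grid SD — a scale indicator, not a calibrated standard error.

# 7. Synthetic-data generators

Raw reads and ICP-MS exports for this kind of study are generally not
deposited, so the generators produce each input *format* with planted
ground truth.

**Omics** (`simulate_hit_table()`): per sample, reads hitting
orthologue $g$ are Poisson with mean
$G \cdot \mathrm{copies}(g) \cdot 3 S_g / \bar L$, where $G$ (genome
equivalents) is scaled so expected total reads equal the sequencing
depth; read lengths are truncated-normal (floor 50 bp); true-hit
E-values are log-uniform below 1e-6 and optional decoys sit strictly
between 1e-5 and 1e-3 so the analysis filter has real work. Expected
length-normalized copies equal $G \cdot \mathrm{copies}(g)$ and rpoA is
planted at 1 copy/genome, so normalization recovers the planted copies
per genome. In *expectation mode* each (sample, gene, genus) emits one
aggregate row whose real-valued query length encodes the exact expected
copies — a machine-precision oracle device, not a realistic read. The
default depth of 5000 reads/sample is an **arbitrary documented
choice** (real depths for such libraries are unreported) large enough
for 10 % parameter recovery; the default panel's basalt/soil contrasts
(e.g. desB 0.50 vs 0.19, desD 0.25 vs 0.045 copies/genome) plant
2.6-fold and 5.6-fold enrichments of the headline hydroxamate genes.

*Not emulated*: sequence content, alignment scores beyond uniform
bitscores, chimeras, strain variation, or compositional coupling
between genes.

**Dissolution** (`simulate_dissolution_panel()`): true released
concentration per element is linear or quadratic-saturating in ligand
concentration; blanks are added and values divided by the dilution
factor so blank-and-dilution correction recovers the truth exactly in
noise-free mode; noise is multiplicative (relative SD, default 5 %,
typical of ICP-MS precision). *Not emulated*: drift, spectral
interferences, detection limits.

**Incubation** (`simulate_incubation_dataset()`): concentrations follow
`baseline + (day/day_max) × [soil_drift + basalt × (basalt_effect +
eddha_slope × level)]` plus additive noise. The default EDDHA slope is
`1.5 × basalt_effect / 750` per element, planting a **2.5-fold CDR
gain at 750 µM** exactly. *Not emulated*: nonlinear time courses,
plant uptake, microbial immobilization.

All generators draw from deterministic substreams of one global seed
(distinct large offsets, reduced mod 2147483587) so modules are
independently reproducible and never share a stream.

# 8. Numerical choices

- Exact ties and exact zeros are handled by explicit branches (AIC
  ties, RSS = 0, zero-variance correlations, zero-residual ANOVA,
  flat standard curves) instead of relying on floating-point
  comparisons to fall the right way.
- Physical floors (concentrations, adsorbed K) clip *with flags*;
  sign-carrying quantities (cation deltas) are never clipped.
- Unit conversions go through a single molar-mass table; element
  symbols are validated at entry so a typo fails loudly.
- Statistical machinery is base R (`lm`, `t.test`, `cor.test`, `aov`);
  only the RSS-form AIC is hand-rolled because its tie rules and
  RSS = 0 guard are part of the model contract.

# 9. Problem sizes and runtime

Unit tests run on fixtures of 2–100 hits, 5–6 concentration levels × 4
replicates, and 2 × 4 × 4 × 3 incubation grids. Recovery and power
tests use depth-5000 hit tables and 100-seed sweeps. The full suite
runs in well under a minute on one CPU; the acceptance script is
deterministic and sub-second.

# 10. Limitations

- The carbonate module is a two-constant freshwater model: no ionic
  strength corrections, ion pairing, or temperature dependence beyond
  user-supplied constants.
- The economic model is a per-hectare point model; it has no discount
  rates, logistics, or spatial variability, and its calibrated
  constants inherit the rounding of the printed anchors they reproduce.
- The CDR-gain statistic equates exchangeable-cation accumulation with
  eventual bicarbonate export; field drainage and riverine losses are
  out of scope.
- Parameter-recovery tests demonstrate the pipeline recovers *planted*
  truths; they cannot validate the generators against unavailable raw
  data.
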