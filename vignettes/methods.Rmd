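---
title: "Models and methods behind hergtraffick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hergtraffick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hergtraffick)
```

# The scientific problem

hERG (Kv11.1, the *KCNH2* gene product) carries the rapid delayed-rectifier
potassium current that repolarizes the cardiac action potential. Most
loss-of-function hERG variants causing Long QT Syndrome type 2 act by
mistrafficking: the mutant subunit folds poorly, is retained by endoplasmic
reticulum quality control, and never reaches the cell surface. Because the
channel is a tetramer and patients are heterozygous, the clinically relevant
quantity is not the homozygous trafficking defect but what happens when WT
and variant subunits co-assemble: variant subunits can drag WT subunits
down (a dominant-negative effect) and WT subunits can partially rescue the
variant.

This package implements the quantitative analysis chain for plate-based
On-Cell/In-Cell western assays of exactly this question, plus a synthetic
data generator with known ground truth so that every stage is testable
without access to raw scanner exports.

# Normalization by sum

Raw inputs are per-well two-channel arbitrary fluorescence intensities from
an infrared plate scanner: the 800 channel reads the anti-HA (On-Cell,
surface only) or pan-hERG (In-Cell, total protein) antibody; the 700 channel
reads a WGA-680 cell stain proportional to cell number. `normalize_plate()`
computes, per well, the ratio `ch800 / ch700` (cell-number correction),
averages the two duplicate technical-replicate wells of each condition, and
divides by the total summed raw 800-channel signal of the plate.

Two interpretive choices are explicit options rather than silent defaults:

* **Denominator.** "Total summed signal" is read as the sum of *raw* ch800
  intensities over all wells of the plate, empty-vector wells included
  (`denominator = "raw_ch800"`, `include_empty = TRUE`). This choice yields
  dimensionless values of order 1e-8, matching the axis scale such assays
  report; summing duplicate-averaged ratios instead is available as
  `denominator = "mean_ratio"` for comparison.
* **Background and percentages.** Background (empty-vector) subtraction and
  percent-of-control scaling operate on repeat-aggregated means, with SEMs
  propagated to first order
  (`p * sqrt((sem/a)^2 + (sem_ctrl/ctrl)^2)`). Per-repeat recomputation is
  possible from the per-repeat value tables the pipeline writes, but the
  aggregated-mean route is the default because the published summary tables
  are stated as background-subtracted aggregated means.

The normalized values are invariant to any uniform rescaling of the 800
channel (gain changes cancel between numerator and denominator); a uniform
rescaling of the 700 channel by `c` scales all values by `1/c`. Both facts
are asserted in the test suite.

Repeat-level statistics follow the standard design of four independent
repeats: `summarize_conditions()` reports mean, SEM (sample SD over repeats
divided by `sqrt(n)`), and n. With a single repeat the SEM is `NA` with a
warning, never silently 0. `anova_bonferroni()` runs an ordinary one-way
ANOVA over all groups and unconditional pairwise two-sided t comparisons on
the pooled within-group variance for an *explicit* comparison family
(each condition against its design's control, as figure legends declare),
with Bonferroni adjustment by the family size, capped at 1. Zero-variance
degenerate inputs give p = 1 with a warning.

# The tetramer-assembly generator (the stated world)

`simulate_repeat()` generates raw plates from first principles:

* **Co-assembly** is binomial: with variant fraction `f_var` in the subunit
  pool (taken as the variant's plasmid mass share among hERG-encoding
  plasmids), a tetramer contains `k` variant subunits with probability
  `choose(4,k) f^k (1-f)^(4-k)`. Partial exclusion of a variant from
  tetramers (plausible for proline substitutions such as T473P) is
  expressible through `pool_weight < 1`, which down-weights the variant
  mass share; the default is 1.
* **Trafficking** of a tetramer with `k` variant subunits happens with
  probability `t[k+1]`. The default world
  (`default_assembly_params()`) encodes the heterotetramer interpretation
  of the measured data: tetramers with at most one variant subunit traffic
  like WT (`t1 = t0`), tetramers with two or more do not (`t2 = t3 = 0`),
  and the variant homotetramer probability is scaled from the packaged
  measured table, `t4 = t0 * homo_cse / 100`.
* **WT mid-equilibrium.** `t0 = 0.5`: the WT subunit itself sits mid-way in
  its folding-unfolding equilibrium. This is forced by the observation that
  a pharmacological chaperone increases WT surface expression ~1.87-fold —
  impossible if `t0` were near 1 — and leaves exactly the headroom the
  measured WT drug response requires (`0.5 * 1.868 = 0.934 <= 1`).
* **Detection.** On-Cell signal counts HA epitopes per surface tetramer
  (`4-k`, `k`, or 4 depending on which class is tagged, scaled by the tag
  fraction within each class when tagged and untagged versions of the same
  subunit are co-transfected). In-Cell signal counts all four subunits per
  tetramer-equivalent regardless of tag or trafficking outcome, so the
  "no In-Cell differences at equal plasmid load" synthesis-control contract
  of the assay holds by construction and is asserted as a property test.
* **Drug.** A chaperone multiplies every `t[k]` by `drug_boost`, clipped at
  1 — an equilibrium shift common to all subunits, consistent with the
  thermodynamic model below. Boost values are inputs, not fits.
* **Saturation.** An optional single-parameter hyperbolic map
  `S -> S * capacity / (S + capacity)` applied to the total surface signal
  before tag apportioning. The data motivating it (suppression of tagged WT
  by untagged WT) do not characterize its form, so it is off by default and
  never calibrated.
* **Noise.** A per-well lognormal cell density (CV `cv_stain` = 0.08)
  multiplies both channels — which is precisely why the ratio step works —
  and per-well synthesis carries lognormal noise with CV
  `cv_expression` = 0.10, a typical well-to-well variability for transient
  transfection. Background (`background_800` = 0.05 on the 0–4 signal
  scale) is additive in the 800 channel and scales with cell density.
  Gains (1e6 / 1e5) only set the raw-count scale and cancel in
  normalization.

What a green test on synthetic data does establish: the arithmetic of every
stage, exact recovery of programmed truth at zero noise, and estimator
behaviour at realistic noise (±15 percentage points at 10% CV). What it
does not establish: that real assemblies are binomial, that real noise is
lognormal, or the actual composition rules of traffic-competent
heterotetramers — those are modelling assumptions the generator states, not
findings.

# Rescue metrics and the regression

`build_rescue_table()` assembles the per-variant table of
background-subtracted, control-scaled percentages: homozygous CSE and CSE
under drug (HA-WT alone = 100), total co-expression CSE (HA-WT alone =
100), residual WT CSE under untagged-variant co-expression and WT rescue of
the variant (HA-WT + untagged WT = 100). `fit_rescue_regression()` fits
ordinary least squares of drug rescue on WT rescue, unweighted (the
published fit is a plain regression line), excluding WT and the pore
variant L615F — an outlier whose poor drug response is attributed to the
mutation sitting in the drug-binding region of the pore, not to
unrescuability. The remaining nine VSD variants reproduce the published
coefficients to better than 0.5%:

```{r}
fit_rescue_regression(herg_table1(), exclude = c("WT", "L615F"))
```

# The folding-equilibrium energy model

A variant subunit's trafficking competence is modelled by a two-state
folding (F) - unfolding (U) equilibrium with constant K_FU. A drug that
binds the assembled tetramer and enhances trafficking by a factor dK_FU has
stabilized each subunit by

dG_subunit = −R·T·ln(dK_FU),

and, since one drug molecule binds per tetramer, the per-tetramer binding
free energy is 4× that. Constants default to R = 8.314 J mol⁻¹ K⁻¹ and
T = 310.15 K (37 °C, the expression temperature). The assumption that 5 µM
drug is saturating is taken as given — no dose-response correction is
applied. For the six variants with clear rescue:

```{r}
six <- c("N470D", "I400N", "H402R", "T474I", "V483F", "H492L")
tt <- thermo_table(herg_table1())
tt[tt$variant %in% six, ]
```

Per-subunit energies span −7.4 to −4.6 kJ/mol (per-tetramer −29 to −18),
an order of magnitude below cell-surface binding energies from inhibitory
constants (`dg_from_ki(10e-9)` ≈ −47 kJ/mol at standard state c0 = 1 M) —
consistent with much weaker drug binding in the ER environment where
folding and assembly happen. Ki values are user inputs: the package ships
no affinity data, so the experimental comparator range is illustrative,
not a reproducible target. Folds below ~1.5 (|dG| < 1 kJ/mol, well under
RT ≈ 2.6 kJ/mol) are flagged `negligible`: at that scale the "rescue" is
indistinguishable from assay noise.

# Residue tolerance mapping

`categorize_residue()` reduces multiplexed variant-effect (MAVE) surface
expression scores to per-residue tolerance classes. Scores are
dichotomized at 40% of WT (inclusive); substitutions are conservative when
ref and alt share a group in a standard physicochemical grouping
(aliphatic/aromatic/hydroxyl/amide/acidic/basic, with G, P, C singletons) —
a config object, not hard-coded, because published schemes differ in
detail. Categories, first match wins: no data → `no_data`; no passes →
`intolerant`; all passes conservative with at least one non-conservative
tested and failing → `conservative_only`; pass fraction > 0.75 →
`exchangeable`; ≤ 0.25 → `low_tolerance`; otherwise `moderate`.

Two deliberate design choices:

* **Totality.** `moderate` is the fall-through, so every residue with data
  gets exactly one category for any count tuple.
* **Tolerance ordering.** For the monotonicity guarantee ("raising a score
  never strictens a category") the ordering is `intolerant <
  conservative_only < low_tolerance < moderate < exchangeable`. Placing
  `conservative_only` below `low_tolerance` is the only ordering under
  which the rules are provably monotone: raising a non-conservative
  variant past threshold at a mostly-intolerant residue moves it from
  `conservative_only` to `low_tolerance`, and a residue where a
  non-conservative substitution is tolerated is genuinely more
  exchangeable than one where only like-for-like swaps survive. The
  converse transitions (`low_tolerance`/`moderate`/`exchangeable` →
  `conservative_only`) are impossible because raising scores can only add
  non-conservative passes, never remove them. A 300-case randomized
  property test asserts the guarantee.

Display codes keep the conventional color-legend order (0 grey no-data,
1 red, 2 orange, 3 yellow, 4 cyan, 5 blue); `write_structure_annotation()`
emits a viewer-consumable TSV and can paint codes into the B-factor column
of a PDB file with fixed-width columns preserved, coding structure
residues without data as 0 and warning about categorized positions missing
from the structure (e.g. the S2-S3 loop stretch absent from the published
screen; no imputation is attempted).

# Numerical and degenerate-input policy

* Wells with `ch700 <= 0` are hard errors naming the well (the ratio is
  undefined), as are wells missing from either of a layout/intensity file
  pair, unknown condition ids, and plasmid mixes not totalling 1 µg.
* Background-subtracted means may be negative; they are reported as-is
  with a warning rather than clamped, so downstream error propagation
  stays honest.
* Percent-of-control requires a strictly positive control;
  fold-enhancement a strictly positive untreated value (otherwise no
  equilibrium shift can be formed).
* OLS is delegated to `stats::lm` and cross-checked in the test suite
  against hand-written normal equations at 1e-10; <3 points or zero
  x-variance are errors.
* All simulation randomness flows from one integer seed through
  fixed per-(repeat, assay-type) derived seeds kept within 32-bit range;
  identical configs give byte-identical outputs, recorded as MD5s in the
  pipeline manifest.

# Configuration

The pipeline config is JSON (read with jsonlite); this package prefers one
structured-text format everywhere over adding a YAML dependency. All
interpretive options above (`denominator`, `include_empty`, regression
exclusions, thermodynamic constants, the assembly world `t0`/`t1_factor`,
noise CVs) are config fields with the defaults stated here.

# Known limitations

* The generator's binomial/well-mixed-pool assumption ignores co-assembly
  kinetics, ER retention dynamics and glycosylation state entirely.
* Measured summary percentages ship as a packaged fixture because the
  underlying raw plate exports are not publicly deposited; everything
  downstream of that table is recomputed, the table itself is not.
* SEM propagation for derived percentages is first-order and ignores the
  correlation induced by the shared plate-sum denominator; with four
  repeats this is well inside the reported uncertainty.
* The conservative grouping and category thresholds are declared defaults
  consistent with the two published worked calls (V→I conservative, R→C
  non-conservative), not a byte-for-byte reimplementation of any specific
  supplementary scheme.
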