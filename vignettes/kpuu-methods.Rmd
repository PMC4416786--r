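---
title: "Methods: brain distribution metrics, binding assays and targeted proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain distribution metrics, binding assays and targeted proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpuu)
```

## The problem

How much of a drug crosses the blood-brain barrier (BBB), and is its entry
actively restricted?  The total brain-to-plasma ratio
$K_p = C_{brain}/C_{plasma}$ (ml/g) answers neither question on its own:
it confounds transport with nonspecific brain tissue binding and plasma
protein binding.  The pharmacologically meaningful quantity is the unbound
partition coefficient

$$K_{p,uu} = \frac{K_p}{V_{u,brain} \times f_{u,p}},$$

the ratio of unbound drug in brain interstitial fluid to unbound drug in
plasma.  $K_{p,uu} < 1$ indicates net efflux at the BBB (e.g. by
P-glycoprotein, P-gp), $K_{p,uu} > 1$ net active uptake.  This package
implements the full computational chain for studies that compare wild-type,
Mdr1a/1b-knockout and MDR1-humanized mice: per-animal $K_p$ with
residual-blood correction, the two binding assays that calibrate it
($f_{u,p}$ and $V_{u,brain}$), group statistics, and selective absolute
quantification of the transporter proteins themselves from SRM/MRM data.

## Distribution metrics

Brains are not perfused before homogenization, so the homogenate contains
drug carried in residual intravascular blood.  The corrected amount per g
tissue is

$$A_{brain} = \frac{C_{brain,h} - V_{eff}\,C_{plasma}}{1 - V_{water}},
\qquad
V_{eff} = f_{u,p} V_{water} + (1 - f_{u,p}) V_{protein},$$

where $C_{brain,h}$ is the homogenate concentration converted to per g
tissue (the measured concentration times the total homogenization fold,
e.g. 5 for 4 added volumes w/v — the fold is a per-record data field, not
a constant), and $V_{water}$, $V_{protein}$ are the apparent vascular
spaces of plasma water and plasma proteins.  $V_{eff}$ is a convex
combination of the two spaces: strongly bound drug travels with plasma
protein, unbound drug with plasma water.

Three numerical choices deserve note:

* **Vascular spaces are configuration, not constants.**  The package
  defaults are literature estimates for rodent brain,
  $V_{water} = 0.0103$ and $V_{protein} = 0.0080$ ml/g
  (`vascular_params()`); both must be below 1 and should be replaced by
  study-specific values when available.
* **The denominator $1 - V_{water}$** treats the numeric value of
  $V_{water}$ (ml/g) as a tissue fraction.  This is how the correction is
  conventionally written and applied; the package implements it as
  printed and documents the unit looseness here rather than silently
  "fixing" it.
* **Negative corrected amounts** can arise when plasma levels are high
  and brain levels near zero (strong efflux plus noise).  A physical
  amount cannot be negative, so the correction clamps to zero and sets a
  `clamped` flag instead of propagating a negative value.

$K_p = A_{brain}/C_{plasma}$ has units ml/g; in the $K_{p,uu}$ ratio it is
treated as dimensionless against $V_{u,brain}$ (ml/g), with $f_{u,p}$
dimensionless.

Report tables round $K_{p,uu}$ to three decimals below 1 and three
significant figures otherwise (`round_kpuu()`); rounding is strictly a
presentation step and rounded values never feed back into computation.

```{r}
# digoxin in wild-type mice: strong P-gp efflux
compute_kpuu(0.05, 44.8, 0.594)
round_kpuu(compute_kpuu(0.05, 44.8, 0.594))
```

## Binding assays

**Fraction unbound in plasma** comes from equilibrium dialysis: at
equilibrium the buffer side holds only unbound drug at the unbound plasma
concentration, so each replicate estimates
$f_{u,p} = C_{buffer}/C_{plasma}$.  Both sides are matrix-matched and
identically diluted before analysis, so common dilution factors cancel in
the ratio.  Replicate ratios above 1 are physically impossible but occur
under noise; they are retained and flagged (truncation would bias the mean
downward), with a warning when the mean itself exceeds 1.  The assay runs
in triplicate per drug and plasma source.

**Unbound volume of distribution in brain** comes from the brain-slice
method: slices equilibrate in buffered drug solution, and

$$V_{u,brain} = \frac{A_{slice} - V_{film} C_{buffer}}{C_{buffer}},$$

with $A_{slice}$ the amount per g slice recovered from the slice
homogenate (homogenate concentration times the slice dilution fold,
default 10 for 9 added volumes) and $V_{film}$ an optional correction for
buffer film adhering to the slice surface.  $V_{film}$ defaults to 0
because the study protocol does not state a value; published variants of
the method use roughly 0.01-0.05 ml/g, and the parameter is exposed in
the configuration.  Buffer depletion over the incubation is ignored — a
single end-point buffer sample is used, matching the assay design.

Slices are subject to viability QC before contributing: end-of-incubation
pH below 7.25 or a released LDH fraction above a configurable threshold
(default 0.25; the study names the LDH criterion without a cutoff) marks
a slice non-viable, and non-viable slices are excluded from the
$V_{u,brain}$ mean entirely.

## Targeted absolute proteomics

Transporter protein levels are measured by multiplexed SRM/MRM with
stable-isotope-labeled internal standard (IS) peptides.  Each molecule is
monitored with four transition sets (Q1/Q3 pairs) in each of three
analyses.  Per transition,

$$\mathrm{amount} = \frac{A_{analyte}}{A_{IS}} \times
  \frac{IS_{fmol}}{protein_{\mu g}} \quad \text{(fmol/}\mu\text{g)},$$

standard stable-isotope-dilution arithmetic.  The decision logic around it
is what matters:

* **Positivity.**  A transition set is positive when its signal co-elutes
  with the IS peptide in every run and its mean amount reaches the
  per-transition LOQ.  A molecule is *expressed* when 3 or 4 of its 4
  transition sets are positive; otherwise it is censored as ULQ (under
  the limit of quantification).  Positivity is monotone: raising a
  transition's signal can never un-call an expressed molecule.
* **Level and SEM.**  The reported level is the mean over the pooled
  positive-transition × run amounts (up to 12 values); the SEM is
  SD/sqrt(n) over the same pool.  This SEM describes technical
  (between-transition, between-run) variability only — the capillary
  preparation is pooled tissue prepared once, so no biological replicate
  exists and between-group tests on these pools are technical-replicate
  inference, labelled as such.  Sub-LOQ transition sets are excluded from
  the mean; averaging censored near-zero values into an expressed
  molecule's level would bias it downward.
* **LOQ.**  The limit of quantification is computed per transition as
  $k \times SD$ of blank-equivalent amounts ($k = 3$ by default) and
  reported per molecule as the minimum over its transitions.  The rule is
  deliberately config-driven (multiplier, fallback value, blank source)
  so an alternative laboratory definition can be swapped in.
* **Censored fold changes.**  Ratios against a ULQ side are reported as
  bounds, never points: numerator/LOQ is a lower bound when the
  denominator is censored, LOQ/denominator an upper bound when the
  numerator is, and both-censored ratios are undefined.
* **Probe selectivity.**  Human-specific, mouse-specific and
  species-common peptide probes are modelled explicitly: in the synthetic
  generator a human-specific probe receives no signal from mouse protein
  and vice versa, while a common probe sums both.  This reproduces the
  design in which human MDR1 and mouse Mdr1a are distinguished in a
  humanized line even though they are functional homologs.

## Group statistics

Distribution metrics are compared with the unpaired two-tailed Student's
(pooled-variance) t-test at $\alpha = 0.05$, the convention of this study
design; Welch's test is available via `var_equal = FALSE` and is the
better default when group variances differ visibly, but the package
follows the named convention unless configured otherwise.  No
multiple-testing correction is applied (none is applied in the study
design the package mirrors); the run log records the number of tests
performed so readers can apply their own adjustment.  Blocker experiments
are summarized as ratios of group mean $K_p$ (with blocker / control);
being ratios of means, they carry no variability and are labelled
accordingly.  Degenerate inputs are handled explicitly: groups with fewer
than two animals are "not testable", and two exactly constant groups
yield $t = 0, p = 1$ when equal and $p = 0$ when distinct (the zero-noise
simulation limit).

## The synthetic cohort generator

The generator emulates the study's four input tables with known ground
truth (`cohort_truth()`): 4 drugs × 4 mouse lines with n = 5 animals per
group, triplicate dialysis, 6 slices per drug, and 4 transitions × 3 runs
per molecule and line.  Default truths mirror the study's reported values
(wild-type $K_p$ 0.05/0.6/0.09/4.8 for digoxin, verapamil, docetaxel,
oxycodone; $V_{u,brain}$ 44.8/48.2/789/3.75 ml/g; $f_{u,p}$
0.594/0.115/0.053/0.681; knockout-to-wild-type $K_p$ folds 20/30/4/1.6;
P-gp protein levels 22.3, 2.45 and 0.355 fmol/ug with Mdr1b absent), so
zero-noise recovery tests double as regression tests against those
values.  Typical plasma levels (50/80/500/30 ng/ml) are chosen as
realistic exposure magnitudes for the doses used; they cancel in every
ratio the pipeline computes.

The noise model is independent multiplicative lognormal error with mean 1
on *every measured quantity* (each concentration, each peak area),
parameterized by a per-assay CV (default 10%, a typical LC-MS/MS
analytical precision), plus a 25% between-animal lognormal variability on
plasma exposure (which cancels in $K_p$ under the equilibrium assumption,
and is present so the raw tables look like animal data).  Lognormal noise
was chosen over Gaussian because concentrations and areas are positive
and their group spreads are right-skewed.  A single global seed is
expanded into fixed per-table substreams, so adding a generator never
perturbs the other tables, and a fixed seed yields byte-identical CSVs.

What the generator does *not* emulate — and what passing recovery tests
therefore do not demonstrate about real data: time-course kinetics (each
animal is a single equilibrium snapshot), dose non-linearity, between-
animal variability in $K_{p,uu}$ itself, correlated (run-level or
batch-level) measurement error, retention-time drift, and
digestion-efficiency differences between peptide probes.

### Attainable precision

With the study's assay sizes the measurement-error floor can be computed
directly.  A dialysis replicate's $f_u$ is a ratio of two independent
10%-CV measurements (ratio CV ≈ 14.2%); the mean of 3 replicates has SE
≈ 8.2%, so the median absolute relative error of $f_{u,p}$ is ≈ 5.5%.
$K_{p,uu}$ combines the mean $K_p$ of 5 animals (SE ≈ 6.4%), the slice
estimate over 6 slices (SE ≈ 5.8%) and $f_{u,p}$, giving ≈ 12% SE and a
median absolute relative error around 8%.  The 500-simulation and
200-replicate studies in the test suite land on these analytical values
(bias itself is below 2% throughout — the estimators are unbiased; the
limits are pure sampling noise at the assay sizes).  Tightening recovery
below these levels requires more replicates, not a better estimator.

```{r, eval = FALSE}
rec <- simulate_recovery(n_rep = 200, cv = 0.10, seed = 1)
sapply(rec[, c("rel_err_kpuu", "rel_err_vu", "rel_err_fu")],
       function(e) median(abs(e)))
```

## Pipeline and reports

`run_pipeline()` composes the stages behind a single configuration object
(`run_config()`, YAML round-trip via `read_config()`/`write_config()`):
schema validation with itemized per-row findings, binding assays,
distribution metrics, group statistics, blocker ratios and the proteomics
table, then writes a plain-text report bundle — per-animal metrics, the
$K_{p,uu}$ reference-style table, formatted expression cells
(`"22.3 ± 2.9"`, `"U.L.Q.(< 0.112)"`), significance stars (* p < 0.05,
** p < 0.01), a machine-readable `results.json`, and a provenance log
with config and input checksums.  Reports are byte-identical across
re-runs of unchanged inputs; the only timestamp lives in the log.  A thin
command-line wrapper over these functions ships in
`inst/scripts/kpuu-pipeline.R` (subcommands `simulate`, `validate`,
`run`).

Problem sizes throughout the test suite — 200-replicate recovery studies,
500-simulation bias checks, 10,000-draw type-I and inversion sweeps — are
the package's chosen validation sizes: large enough that the Monte Carlo
error of each check is a small fraction of its tolerance, small enough to
re-run routinely.

## Known limitations

* The vascular-space correction treats ml/g volumes as fractions in its
  denominator, as conventionally printed; for realistic values
  ($V_{water} \approx 0.01$) the distinction is ~1%.
* $V_{u,brain}$ is measured in wild-type slices only and assumed equal
  across lines; genotype differences in nonspecific brain binding would
  bias between-line $K_{p,uu}$ comparisons.
* The exact slice-assay formula (surface-film term included or not) and
  the laboratory LOQ rule vary between sites; both are declared,
  configurable choices here, not claims about any specific laboratory's
  procedure.
* Proteomics group comparisons are technical-replicate inference on a
  single pooled preparation; they say nothing about between-animal
  variability.
* Cassette dosing of the slice assay (four drugs incubated together) is
  treated as four independent assays; transporter saturation or
  interaction effects in the cassette are not modelled.
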