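# kpuu

Quantifying the extent of drug transport across the blood–brain barrier
(BBB) in transporter-knockout and MDR1-humanized mouse models.

Whether a drug is kept out of (or pumped into) the brain is not visible in
the raw brain-to-plasma ratio `K_p = C_brain / C_plasma`, which confounds
transport with nonspecific brain binding and plasma protein binding.  The
quantity that isolates transport is the **unbound partition coefficient**

```
K_p,uu = K_p / (V_u,brain × f_u,p)
```

— the ratio of unbound drug in brain interstitial fluid to unbound drug in
plasma.  `K_p,uu < 1` means net efflux at the BBB (e.g. by P-glycoprotein),
`K_p,uu > 1` net active uptake.  This package implements, as tested
reusable building blocks plus an end-to-end pipeline:

* **Distribution metrics** — per-animal `K_p` with residual-blood
  correction `A_brain = (C_brain,h − V_eff·C_plasma)/(1 − V_water)`,
  `V_eff = f_u,p·V_water + (1 − f_u,p)·V_protein`, and `K_p,uu`.
* **Binding assays** — fraction unbound in plasma from equilibrium
  dialysis (replicate buffer/plasma ratios) and the unbound volume of
  distribution in brain from the brain-slice method, with slice viability
  QC (end pH < 7.25 or excess LDH release excludes a slice).
* **Targeted proteomics (QTAP)** — absolute transporter levels (fmol/µg
  protein) from SRM/MRM transition tables: stable-isotope-dilution
  amounts, the 3-of-4-transitions positivity rule, limit-of-quantification
  censoring (`U.L.Q.(< x)`), censored fold changes, and species-selective
  peptide probes (human MDR1 vs mouse Mdr1a/Mdr1b).
* **Group statistics** — unpaired Student's t-tests, group summaries,
  blocker-ratio tables.
* **A synthetic cohort generator** — all four input table kinds with known
  ground truth and seeded, byte-reproducible output, used for
  parameter-recovery validation.

For who: DMPK / neuropharmacokinetics scientists processing brain
distribution studies, and anyone needing a tested reference implementation
of the `K_p,uu` chain and SRM/MRM censoring rules.

## Worked example

Simulate a full study (4 drugs × 4 mouse lines, n = 5/group, 10%
measurement CV) and run the pipeline on it:

```r
library(kpuu)
truth <- cohort_truth(seed = 1, cv = 0.1)
paths <- simulate_study(truth, "demo_study")
cfg <- run_config(concentrations = paths[["concentrations"]],
                  dialysis = paths[["dialysis"]],
                  slices = paths[["slices"]],
                  srm = paths[["srm"]],
                  srm_blanks = paths[["srm_blanks"]],
                  out_dir = "demo_study/report", seed = 1)
res <- run_pipeline(cfg)
res$table1[res$table1$genotype %in% c("C57BL6_WT", "HMDR1"), ]
```

```
      drug  genotype n      kp v_u_brain f_u_plasma  kpuu
   digoxin C57BL6_WT 5  0.0392     42.70     0.5870 0.002
   digoxin     HMDR1 5  0.1260     42.70     0.6210 0.005
 docetaxel C57BL6_WT 5  0.0955    750.00     0.0489 0.003
 docetaxel     HMDR1 5  0.1440    750.00     0.0591 0.003
 oxycodone C57BL6_WT 5  4.9300      4.42     0.6300 1.770
 oxycodone     HMDR1 5  7.4000      4.42     0.6100 2.750
 verapamil C57BL6_WT 5  0.6010     46.40     0.1290 0.100
 verapamil     HMDR1 5 10.0000     46.40     0.1060 2.040
```

Each row is one drug × mouse-line group: `kp` is the group mean
brain-to-plasma ratio after residual-blood correction (ml/g), `v_u_brain`
and `f_u_plasma` the binding parameters estimated from the simulated slice
and dialysis assays, and `kpuu` the unbound partition coefficient at
report rounding.  Reading it: digoxin is strongly effluxed in both lines
(`K_p,uu ≈ 0.002`), oxycodone is actively taken up (`> 1`), and verapamil
flips from net efflux in wild type (0.100) to net uptake (2.04) in the
humanized line, whose P-gp complement is far weaker.  The proteomics stage
shows why:

```r
res$qtap$formatted[res$qtap$formatted$molecule %in%
                     c("Mdr1a", "hMDR1", "Mdr1b"), ]
```

```
 molecule     group             cell
    hMDR1 C57BL6_WT U.L.Q.(< 0.0616)
    hMDR1     HMDR1  0.348 ± 0.00990
    Mdr1a C57BL6_WT     22.7 ± 0.574
    Mdr1a     HMDR1    2.40 ± 0.0582
    Mdr1b C57BL6_WT U.L.Q.(< 0.0552)
    Mdr1b     HMDR1 U.L.Q.(< 0.0552)
```

Mouse Mdr1a dominates in wild type (22.7 fmol/µg), the humanized line
expresses ~9-fold less Mdr1a plus a small amount of human MDR1, human
MDR1 is censored (`U.L.Q.`) in wild type, and Mdr1b is absent in both —
the human-specific probe correctly sees nothing in wild-type capillaries.
Fold changes against a censored side are reported as bounds, never point
values (`res$qtap$fold_changes`).

The direct calculator functions work standalone:

```r
compute_kpuu(0.05, 44.8, 0.594)   # 0.001878908
round_kpuu(compute_kpuu(0.05, 44.8, 0.594))  # 0.002
```

A thin CLI over the same functions ships in
`inst/scripts/kpuu-pipeline.R` (`simulate`, `validate`, `run`
subcommands).  See `vignettes/kpuu-methods.Rmd` for the model, the assay
assumptions, the noise model and the attainable-precision analysis.

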