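# afsilico

In silico evaluation of multi-target antiarrhythmic compounds for atrial
fibrillation (AF): drugs that simultaneously block the atrial potassium
channels TASK-1 (I<sub>K2P</sub>) and Kv1.5 (I<sub>Kur</sub>) and the
cardiac sodium channel Nav1.5 (I<sub>Na</sub>). The package is aimed at
cardiac-electrophysiology modelers and medicinal chemists who want to take
a compound from docking-pose tables through functional-assay analysis to a
population-level virtual atrial drug trial.

## What it implements

**Polypharmacology pose ranking.** For each channel/site pose set, MM-GBSA
binding energies and binding-site contact counts (distinct residues with a
heavy-atom pair within 5 Å) are min-max normalized (DGBIND_NORM, INT_NORM)
and averaged (NORMT = (DGBIND_NORM + INT_NORM)/2). Poses are ordered by
contacts, then NORMT; each compound's best pose gives its per-channel RANK,
and the GLOBAL RANK is the sum of channel RANKs.

**Dose-response analysis.** Hill fits of fractional inhibition,
*b(c) = c^h / (c^h + IC50^h)*, with log-scale IC50 confidence intervals;
four-parameter logistic (4PL) fits of MTT viability; Boltzmann fits of
conductance-voltage relations *G(V) = 1/(1 + exp((V½ − V)/k))*; percent
inhibition 100·(I<sub>ctl</sub> − I<sub>drug</sub>)/I<sub>ctl</sub> and
percent hemolysis 100·(A<sub>d</sub> − A<sub>0</sub>)/(A<sub>t</sub> − A<sub>0</sub>).

**The atrial cardiomyocyte model.** The Courtemanche–Ramirez–Nattel human
atrial model extended with a TASK-1 background current
I<sub>K2P</sub> = g<sub>K2P</sub>·f<sub>GHK</sub>(V, K<sub>o</sub>, K<sub>i</sub>)·(V − E<sub>K</sub>),
integrated with Rush–Larsen/forward-Euler and voltage lookup tables
(compiled core). An AF-remodeled baseline, population generation by Latin
Hypercube sampling (±50% on 8 conductances), AP-biomarker calibration, a
zero-flux 1D monodomain cable with conduction-velocity calibration to
80 cm/s, S1–S2 effective refractory period (ERP) measurement, and a trial
runner applying per-concentration pore-block profiles
(1 µM: 0/16/58, 10 µM: 2.5/30/75, 100 µM: 50/65/85 % block of
I<sub>Kur</sub>/I<sub>Na</sub>/I<sub>K2P</sub>).

## Worked example

Fit the three channel potencies from synthetic oocyte-style dose-response
data and apply the 100 µM block profile to an AF cell:

```r
library(afsilico)

d <- gen_dose_response(ic50 = 0.31, h = 1, sigma = 0.05, n_reps = 6, seed = 11)
fit <- fit_hill(d$concentration_uM, d$response_fraction)
round(c(fit$ic50, fit$ic50_ci), 2)
#> [1] 0.33 0.30 0.38        # µM: estimate and 95% CI around the 0.31 truth

p <- apply_block(crn_params("AF"), block_profile_6f(100))
res <- pace_to_steady(p, cycle_length = 500,
                      state0 = settle_cell(crn_params("AF")))
round(res$biomarkers$apd90, 1)
#> [1] 207.4                 # APD90 (ms) at 2 Hz under 100 µM block
```

The second number is the drug-prolonged action potential duration of the
AF-remodeled baseline cell — the single-cell mechanism (TASK-1/Kv1.5 block
outweighing Na block at 2 Hz) that drives the population-level ERP
prolongation in the trial.

The full workflow lives in `analysis/` as numbered drivers
(`01_rank_compounds.R` … `05_run_trials.R`); each prints what it found and
writes its tables under `results/`.

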