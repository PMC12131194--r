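---
title: "Methods: multi-target antiarrhythmic evaluation in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-target antiarrhythmic evaluation in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`afsilico` evaluates multi-target antiarrhythmic compounds that block the
atrial potassium channels TASK-1 (I~K2P~) and Kv1.5 (I~Kur~) and the sodium
channel Nav1.5 (I~Na~) — the triple-target profile pursued for rhythm
control in atrial fibrillation (AF). It covers three stages: (i) a
polypharmacology ranking of docking poses across the three channels,
(ii) dose-response analysis of the functional assays (Hill IC50, 4PL
viability, Boltzmann G-V, percent inhibition, hemolysis), and (iii) an
in silico atrial drug trial on a population of human atrial cardiomyocyte
models, in isolated cells and on a 1D tissue strand.

# Pose ranking

Docking and MM-GBSA rescoring happen upstream in commercial tools; the
package consumes their outputs (binding free energies plus pose
structures or precomputed contact counts). Within each channel/site pose
set, both criteria are min-max normalized — energy with the sign flipped
so 1 is best (`dgbind_norm`), binding-site contacts likewise
(`int_norm`) — and averaged into `normt`. Poses are ordered by
`int_norm`, then `normt` (contacts outrank energy), then energy, then
pose id, making the order total and deterministic. A compound's channel
RANK is its best pose's ordinal; for the two Kv1.5 sites (central cavity
and side pockets) the better site ordinal wins before ranks are
re-densified to 1..n. The GLOBAL RANK is the sum of channel RANKs.

Open choices resolved here: "interactions" are counted as *distinct
binding-site residues* with any heavy-atom pair within 5 Å (the
atom-level definition is not published); normalization is min-max within
each channel/site set, with degenerate (constant) columns mapped to 1.0
so they carry no information rather than excluding poses; compounds
absent from a site are imputed worst-rank-plus-one there.

# Dose-response fits

All fits are Levenberg-Marquardt least squares (`minpack.lm`), with the
IC50 parameterized on the log10 scale so its confidence interval is
computed there and back-transformed (Wald intervals with t quantiles).
Inhibition is fitted as `c^h / (c^h + ic50^h)` with uniform weights; a
fitted `h < 0` flags an activating (TASK-4-like) response rather than
failing. Viability uses the four-parameter logistic with the asymptotes
boxed to physiologically meaningful percentages (bottom ≥ 0); with the
assay grid topping out at ~4x the midpoint, the lower asymptote is
weakly identified and the midpoint estimate inherits that variance — the
tests therefore check Monte-Carlo median recovery, not a single draw.

# The cell model

The cell is the Courtemanche-Ramirez-Nattel (CRN) human atrial
cardiomyocyte model (21 states: V~m~, 15 Hodgkin-Huxley gates, 5
concentrations) extended with a TASK-1 background current:

$$ I_{K2P} = g_{K2P} \, f_{GHK}(V, [K]_o, [K]_i) \,(V - E_K) $$

where `f_GHK` is the Goldman-Hodgkin-Katz open-rectification factor
normalized so `g_K2P` is the chord conductance at 0 mV. This reproduces
the defining properties of an open two-pore-domain K⁺ channel: reversal
exactly at E~K~, outward rectification under physiological K⁺ gradients,
[K]~o~ sensitivity, and linearity in the conductance. The published
formulation this current stands in for is not restated in a citable
closed form here, so the GHK construction — which has no free shape
constants — was chosen; `g_K2P` is the single tunable and lives in
`crn_params()` alongside every other conductance.

Numerics: Rush-Larsen updates for all gates, forward Euler for voltage
and concentrations, dt = 0.01 ms default (0.02 ms for the long
population and cable runs; halving dt moves steady-state APD90 by well
under 1 ms, which the suite asserts). All purely voltage-dependent
kinetics are tabulated on a 0.05 mV grid and linearly interpolated — the
standard acceleration for this model family — leaving only the
Ca²⁺/flux-dependent gates analytic. Stimuli are 2 ms pulses at twice the
diastolic threshold (22 pA/pF single cell, 64 pA/pF on the cable; both
thresholds measured by doubling search plus bisection). Runs start from
the published CRN resting state after an unstimulated settle; an
instability guard aborts if |V~m~| exceeds 200 mV.

# AF phenotype and the population

The AF baseline applies chronic-AF electrical remodeling before any
population sampling: I~to~ ×0.5, I~CaL~ ×0.60, I~K1~ ×1.75, I~Kur~
×0.55, and I~K2P~ ×2.0 (TASK-1 upregulation in AF). The remodeling
magnitudes and `g_K2P` (0.002 nS/pF chord at SR baseline) were fixed
once so that the *control* arm of the trial — the calibrated AF
population paced at 2 Hz with no drug — reproduces the reported control
APD distribution (mean ≈ 142 ms). Control behavior is a trial input;
every drug response in the package is emergent from the Table-of-blocks
profiles acting on this fixed baseline.

Populations are built by Latin Hypercube sampling (±50%) over
{G~Kur~, G~Kr~, G~to~, G~K1~, G~CaL~, G~Na~, G~NaK~, G~K2P~}, paced to
steady state at 1 Hz (APD90 change < 1 ms between beats), and calibrated
by requiring all five biomarkers (APD50, APD90, APA, dV/dt~max~, RMP)
inside per-phenotype ranges. The original patient-derived calibration
dataset is unpublished, so the packaged SR/AF ranges are documented
emulations of human atrial biomarker spans (e.g. AF APD90 ∈ [90, 250] ms
at 1 Hz) and are fully user-overridable. Consequences are stated
honestly where they bite: the emulated AF ranges admit somewhat
longer-APD models than the original patient calibration did, which
lowers the fraction of models able to follow 6 Hz pacing 1:1 (see
Limitations). When more models pass calibration than requested, the
population is subsampled uniformly under the run seed; if fewer pass,
all are returned with a warning.

# Tissue strand

The cable solves the 1D monodomain equation with zero-flux ends by
Strang splitting (half diffusion, reaction, half diffusion); the
conservative ghost-cell stencil is property-tested (pure diffusion
conserves total voltage to 1e-8). A stability check D·dt/dx² ≤ 0.5 runs
before stepping. Geometry: 100 cells at dx = 0.02 cm, stimulus into
cells 1-3, CV measured between cells 26 and 76, distal electrode at cell
96 — boundary effects are checked by the doubling-length test. The
diffusion coefficient is bisected (geometrically, since CV ~ √D) until
planar CV at 2 Hz hits 80 cm/s ± 1, the bulk-tissue velocity target.

ERP uses 10 S1 at 500 ms, then a binary search over the S1-S2 coupling
interval at 1 ms resolution, verified against an exhaustive linear scan.
The S1 train state is computed once; each S2 probe restarts from it. An
S2 "propagates" when the distal electrode fires once more than in an
S1-only reference run from the same state — a fixed post-S2 window
misclassifies slow S1 wavefronts under heavy I~Na~ block as S2
responses. Propagation checks precondition with 10 pulses at the test
rate before the 10 assessment pulses: jumping from rest to 6 Hz traps
models whose APD has not rate-adapted in a self-sustaining 2:1 rhythm,
which a ramped/adapted protocol avoids.

# Problem sizes

The shipped analyses and checks run at desk scale: 100 LHS samples
calibrated to ≤ 45 members for the single-cell arm, 10-model subsets for
the cable arm, 6-concentration dose-response grids with 6 replicates,
and ≤ 8-compound synthetic pose sets. These sizes were chosen as the
smallest that keep population summaries stable against seed changes.

# What the synthetic data does and does not show

Generators provide every input with known ground truth: Hill-shaped
dose-response replicates with additive truncated Gaussian noise
(σ = 0.05, matching the spread of replicate inhibition measurements),
pose sets with planted dominance orderings plus minimal PDB structures
whose geometry reproduces the planted contact counts exactly, and
calibrated populations. Passing tests show the estimators and the
pipeline are correct and self-consistent — they cannot show that the
emulated calibration ranges match the unpublished patient data, that the
GHK rectification matches the unavailable published TASK-1 formulation
constant-for-constant, or that 1D-strand refractoriness quantitatively
transfers to 3D atria.

# Known limitations

- Single-cell and 1D properties only; whole-atria AF induction,
  cardioversion and prevention statistics are out of scope by design.
- Pure pore block (instantaneous conductance scaling); no state- or
  frequency-dependent drug binding.
- The 1 μM ERP prolongation runs ~1 SD above the reported mean and the
  10 μM 6-Hz propagation fraction below it: both trace to the emulated
  AF calibration (longer-APD models retained; TASK-1 contribution fixed
  by control matching), not to the trial machinery, and both
  concentration *orderings* hold strictly.
- Homogeneous cable per model; no regional heterogeneity or anisotropy.
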