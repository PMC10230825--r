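---
title: "Simulating relapsing-remitting MS trials with rrmsim"
author: "rrmsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating relapsing-remitting MS trials with rrmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmsim)
```

## The model

`rrmsim` is a stochastic, discrete-time simulator of the immune dynamics of
relapsing-remitting multiple sclerosis (RRMS), organised in three layers that
are applied in order on every tick:

1. **Physiology layer.** Cell populations are tracked as counts per
   (cell type, activation status, compartment) across three compartments —
   peripheral lymphoid tissue, blood, and the central nervous system (CNS).
   Adaptive naive pools (CD4, CD8, B) are additionally resolved into clone
   classes, each carrying a receptor bit string of length $L = 16$. The
   affinity between two receptors is the number of bitwise-complementary
   positions; a clone reacts to an epitope when its affinity reaches the
   activation threshold $L-2$, with graded weight above it. Hematopoiesis
   replenishes every pool toward its homeostatic set-point by matched
   binomial birth and death, so pools fluctuate around their set-points.
   Sixteen cytokines are tracked per compartment; secretion adds
   `q_sec * count` per secreting population and all levels decay by a fixed
   per-tick factor (default 0.9).

2. **Disease layer.** Myelin basic protein (MBP) debris is presented by
   dendritic cells, which prime naive CD4 clones (via MHC-II) and CD8 clones
   (via MHC-I) proportionally to clone affinity and the patient's HLA match
   factor. Newly primed CD4 cells are partitioned into Th1 (IL-12 +
   IFN-gamma), Th17 (IL-6 with IL-23/TGF-beta, vetoed outright when IL-10
   exceeds its threshold) and Th2 (IL-4), scaled down by regulatory T cells.
   Th2 cells drive B-cell activation under IL-4/5/6/10/13; plasma cells
   release anti-MBP IgG. Epstein-Barr-virus molecular mimicry is modelled as
   a scheduled exogenous trigger that cross-activates a configured fraction
   of epitope-affine naive clones. Pro-inflammatory cytokines damage the
   blood-brain barrier through a saturating load function; activated Th1,
   Th17, macrophages and IgG cross it (all vetoed by IL-10), CD8 cells cross
   without the veto, and resting cells leak through only when permeability
   exceeds the damage threshold. In the CNS, microglia and astrocytes
   reactivate, IL-17 recruits neutrophils, naive cells that crossed a
   damaged barrier can be secondarily activated, and CD8 cells, macrophages,
   neutrophils and IgG destroy oligodendrocytes (ODC) with per-cell hazard
   $1-\prod_e(1-r_e E_e)$ under the local inflammatory milieu. Killed ODC
   release further MBP debris, closing the amplification loop; a slow
   regeneration term restores the pool toward capacity between attacks.

3. **Treatment layer.** Dosing schedules add to a first-order drug effect
   level; cladribine thins the CD4, CD8 and B lineages by binomial kills
   scaled by that level, ocrelizumab holds the CD20-positive B pools (naive,
   active, memory — plasma cells spared) at a deep nadir while dosing
   continues and mildly modulates T-cell activation, and interferon beta-1a
   damps Th activation and barrier damage while on board. Placebo is an
   identity.

## Why relapses are episodic

Attacks are relaxation oscillations produced by two opposing feedbacks. The
positive loop is epitope spreading: a mimicry trigger activates affine
clones, effectors enter the CNS, ODC destruction releases debris, and
presentation amplifies the attack. The negative loop is regulatory:
inflammation expands the Treg pool, whose IL-10 — once above a hard
threshold — vetoes Th17 differentiation, effector migration, antigen
presentation and pro-inflammatory cytokine synthesis. Because expanded
Tregs also secrete IL-10 constitutively, the veto outlasts the attack and
relaxes only as the Treg pool contracts, while dendritic-cell antigen
digestion and a sharp (Hill-2) presentation threshold let residual debris
clear completely. The system therefore returns to a quiescent state between
attacks instead of smouldering, and a later trigger can launch a new
full-sized episode.

Attack size is resource-proportional: the mimicry seed and subsequent
priming draw on the naive autoreactive pool, which replenishes slowly, so
depleting lymphocyte lineages (the drugs' mechanism) shrinks attacks
directly. This is what converts the calibrated depletion magnitudes into
arm-level relapse efficacy rather than leaving attack size governed solely
by the regulatory brake.

## Clinical readouts

The simulated volume is 3 mm^3 of white matter holding 150e3 ODC (50e3 per
mm^3). An episode opens when the ODC count starts declining and closes
after 14 days of net regeneration; its loss is the onset value minus the
minimum, and it is MRI-detectable when the loss reaches 50e3 cells. Only
MRI-detectable episodes count as relapses. The absolute lymphocyte count
(ALC) maps the circulating CD4+CD8+B counts to cells/ul (homeostatic state
near 1800/ul) and is graded 0-4 with the clinical bands (grade 1:
800-999/ul, grade 2: 500-799, grade 3: 200-499, grade 4: below 200; grade 0
is at least 1000 so the bands partition). Annualized relapse rates are
estimated by an intercept-only negative-binomial model with a log
person-years offset (`MASS::glm.nb`); with the trial's common exposure this
equals total relapses over total patient-years, and the confidence interval
comes from the intercept's standard error. Arm contrasts use a
treatment-indicator NB model. Levene's homogeneity test uses the classical
W statistic on absolute deviations from group means (a `center = "median"`
switch gives the Brown-Forsythe variant).

## Digital patients and calibration

A digital patient is a deterministic function of one integer seed:
demographics drawn from editable preset distributions, uniformly random
allele pairs at the HLA A/B/C and DM/DO/DP/DQ/DR loci, and derived traits —
an HLA match factor scored from the DR alleles' affinity to the epitope, a
per-patient autoreactive clone load (a Beta-distributed fraction of
thymic-escape clones near the epitope's complement), a lognormal drug
sensitivity, a lognormal baseline lymphocyte scale, a lognormal regulatory
capacity and a per-patient mimicry-trigger rate (exponential around the
preset's baseline activity). The trigger *schedule* is also derived from
the patient seed, so the same patient relapses at the same times across
arms — the digital-twin property that paired arm comparisons rely on.

Cohort calibration mirrors the in silico trial workflow: a large candidate
pool is generated (we use 4-8 times the cohort size, in the spirit of
selecting hundreds from thousands of profiles), each candidate is simulated
on the calibration arm, and a greedy stratified selection picks profiles
whose relapse-count (and optionally worst-grade) distribution matches the
target within a total-variation tolerance; an annualized-relapse-rate
target can be enforced on top. Selection failure names the worst stratum.
Cohort augmentation is a stratified bootstrap that resamples patients
within outcome strata, jitters demographics within bounds and re-seeds the
repertoire.

## Parameters that matter

* `odcCapacity` (150e3 cells) and the 50e3-cell MRI threshold are exact
  structural constants.
* Cladribine kill scales (`k_clad_*`, per tick per effect-level unit) are
  calibrated so that median depletions 12 months after the first course are
  40-45% (CD4), 20-30% (CD8) and 80-85% (CD19 B), with the B lineage
  recovering faster than the T lineages ("rapid but more transient"). The
  course follows the label structure: two yearly courses of two 5-day
  cycles, cumulative 3.5 (or 5.25) mg/kg.
* Ocrelizumab follows the trial regimen (300 mg IV days 1 and 15, then
  600 mg every 24 weeks); its 9-week effect half-life keeps the level above
  threshold across the 24-week interval, so the B pool sits at its nadir
  throughout dosing.
* The disease-layer rate table (`diseaseConfig()`) holds the calibration
  knobs: kill rates per CNS effector, migration and activation scales, the
  IL-10 threshold (25 units), Treg expansion, and the mimicry magnitude
  (0.24 of affine naive cells per trigger) and baseline rate (2.2 events
  per patient-year, scaled by the preset's baseline disease activity).
  Defaults were fixed once against the week-96 calibration tables and then
  left alone.

## Numerical choices

The tick is 8 hours (a common convention in this simulator family); all
stochastic transitions are binomial thinnings or influxes drawn from R's
RNG, so any run is bitwise-reproducible from its seeds and counts can never
go negative. The per-tick update is implemented once in C++ (Rcpp) and the
exported rule functions are thin wrappers over the same subroutines.
Degenerate inputs are handled explicitly: empty trajectories yield empty
event tables, all-zero relapse counts yield a flagged degenerate ARR of
zero, a collapsed NB dispersion falls back to a flagged Poisson fit, and a
Levene statistic on deviation-free groups is flagged rather than divided by
zero.

## Problem sizes

The shipped tests and the acceptance script run the trials at desk scale:
150 patients per arm selected from 900 candidates for the cladribine-like
trial, 200 per arm from 1600 candidates for each ocrelizumab-like trial,
and 200 patients for the depletion medians. At these sizes a full
calibration-plus-trial cycle takes tens of seconds on one core; binomial
sampling tolerances at the reduced N are used wherever the published tables
were produced at N = 1000 per arm.

## What the generator does and does not emulate

The synthetic cohorts reproduce the published trials' baseline demographics,
heterogeneity in autoreactivity, regulatory capacity, drug sensitivity and
baseline lymphocyte counts, and — after calibration — the week-96 relapse
and lymphocytopenia distributions. They do not contain real-patient data,
population-genetically accurate HLA frequencies, disability scores,
lesion geometry, or non-lymphocytopenia adverse events; passing tests show
that the machinery reproduces the published aggregate tables under the
stated mechanisms, not that it predicts individual real patients.

## Known limitations

* Attack substrate (the autoreactive naive pool) replenishes slowly, so
  disease activity declines modestly over multi-year horizons. In the
  delayed-treatment extension arm this biases the month-42 relapse-free
  fraction upward by roughly 6-10 percentage points relative to the
  published 80% — at the edge of the acceptance band — and the same bias
  appears in the other extension sequences. The mechanism (first-period
  attacks plus drug persistence draining the substrate carried into the
  extension window) is intrinsic to the resource-limited attack design.
* Candidate pools rarely produce patients with 4 or more MRI relapses in 96
  weeks (the attack/refractory cycle caps near 3), so the extreme stratum
  of the selection target is under-filled and selected comparator rates sit
  slightly below their targets, within the stated tolerances.
* Chemokines are absorbed into migration gate constants; there is no
  spatial lesion structure; EBV biology is reduced to a scheduled mimicry
  trigger.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig()
dz <- diseaseConfig()
p <- generatePatient(clarityDemographics(), seed = 42, disease = dz)
sim <- simulatePatient(p, "placebo", cfg, dz, durationWeeks = 96, seed = 1)
subset(sim$events, mri_detectable)
plot(sim$trajectory$day, sim$trajectory$odc, type = "l",
     xlab = "day", ylab = "oligodendrocytes")
```
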