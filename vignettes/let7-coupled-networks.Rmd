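---
title: "A Let-7-coupled cell-cycle and transformation network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Let-7-coupled cell-cycle and transformation network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`let7cycle` implements a deterministic kinetic model of two gene regulatory
networks coupled by the tumor-suppressor microRNA Let-7:

* a **cyclin/Cdk cell-cycle network** (15 variables): the mRNAs of cyclins
  D, E, A and B (`Md`, `Me`, `Ma`, `Mb`), their Let-7-bound inactive
  complexes (`CLd` ... `CLb`), the cyclin/Cdk complexes (`Cd`, `Ce`, `Ca`,
  `Cb`; Cdk subunits are assumed in excess, so complexes form directly on
  translation), active and total E2F, and active APC;
* a **malignant-transformation network** (14 variables): free Let-7,
  NF-kB, Lin28 (mRNA + protein), IL6 (mRNA, Let-7 complex, protein),
  STAT3, miR-21, PTEN (mRNA + protein) and Ras (mRNA, Let-7 complex,
  active protein).

Time is measured in hours and concentrations in arbitrary units, matching
the scales on which the dynamics were calibrated (cell-cycle period of a
few tens of hours). The full 29-equation right-hand side is
`grn_rhs()` (reference R implementation) and `src/grn_model.c` (the
compiled copy used by `integrate_model()`; the two are tested to agree to
machine precision).

Kinetic forms are deliberately simple: linear mass-action synthesis and
degradation; Michaelis-Menten transcriptional activation by GF, E2F and
NF-kB; reversible second-order Let-7/mRNA binding into translationally
inactive complexes; Michaelis-Menten (zero-order-switch) activation and
inactivation of the conserved E2F, APC, NF-kB and STAT3 pools.

### The cell-cycle oscillator

Growth factor (GF) drives cyclin D mRNA; cyclin D/Cdk4-6 and cyclin
E/Cdk2 activate E2F; E2F drives cyclins E and A; cyclin A/Cdk2
inactivates E2F (the delayed negative feedback that paces the cycle);
cyclin B/Cdk1 requires cyclin A/Cdk2 for its activation (as in the
skeleton Cdk model this block extends) and activates APC, which degrades
cyclins A and B and resets the oscillator. Two structural choices were
needed for the stated behaviors and deserve mention:

* E2F carries a **basal, cyclin-A-independent inactivation** (`V_I0E2F`).
  Without it the quiescent state is not an attractor: any trace of cyclin
  D would slowly push E2F up. The ratio of activation slope to `V_I0E2F`
  defines a sharp ignition threshold on `Cd + Ce`, which is what makes
  quiescence a genuine state rather than a slow transient.
* E2F activation **saturates** in `Cd + Ce` (constant `K_AE2FC`). Without
  saturation, strong cyclin overexpression makes the activation outgrow
  the cyclin-A-driven inactivation and the oscillator locks at a stable
  high-E2F fixed point instead of cycling.

### The ceRNA sponge

Let-7 binds six target mRNAs (the four cyclins, IL6 and Ras). A bound
mRNA cannot be translated; complex decay removes **both** partners. This
stoichiometry is essential: because every sponged transcript consumes one
Let-7, repression capacity is bounded by the Let-7 synthesis flux
(`V_SLET7`, a.u./h). Three consequences shape the whole phenotype map:

* at `V_SLET7 = 0.5` the basal (GF-independent) cyclin mRNA flux
  (~0.2 a.u./h) is comfortably repressed, so the cell stays quiescent at
  `GF = 0`, while at high GF the cyclin D flux alone overwhelms the
  sponge and cycling resumes;
* at the basal coupled setting (`V_SLET7 = 10`, `V_SMCYC = 1.5`) the
  E2F-driven cyclin E/A demand (~8.5 a.u./h once cycling) sits just
  *below* the Let-7 supply, so the quiescent state is stable but not far
  from collapse - which is exactly what makes it fragile to parameter
  noise, as required by the population analysis;
* raising `V_SMCYC` to 2.5 pushes that demand *past* the supply: free
  Let-7 collapses, IL6 and Ras are de-repressed, and the transformation
  switch flips. This is the competing-endogenous-RNA (ceRNA) route from
  cyclin overexpression to malignant transformation. The collapse is slow
  near the threshold (half-fall of Let-7 in tens of hours at 2.5) and
  fast far above it (hours at 12).

### The bistable transformation switch

NF-kB is activated by three branches: the inflammatory input Src
(`k_AA1NFKB`), the IL6/STAT3 branch (`k_AA2NFKB`, with Hill coefficient
`n_STAT3 = 6` - the steepness that makes the switch bistable and
irreversible), and active Ras (`k_AA3NFKB`). PTEN promotes NF-kB
inactivation; miR-21 (driven by STAT3) blocks PTEN translation, giving
the on-state its second lock. NF-kB drives Lin28, which promotes Let-7
degradation - the master feedback that couples the two networks: once
Lin28 is up, free Let-7 stays near zero, all six targets are
de-repressed, and both the transformed state and proliferation persist
after the trigger is gone.

NF-kB-driven Lin28 synthesis is gated with Hill coefficient 2
(`n_LIN28`). This is a stability requirement, not decoration: with a
linear activation, the product of a trace NF-kB level and a large free
Let-7 pool creates a parasitic degradation flux that slowly erodes the
quiescent state at intermediate `V_SLET7`. The quadratic gate makes the
off-state leak negligible while leaving the on-state unchanged.

Division of labor between the branches: the Ras branch *ignites* the
switch when free Let-7 first collapses (Ras mRNA is weakly sponged, so
active Ras rises early), while the IL6/STAT3 branch *maintains* it (IL6
is strongly sponged, `kA_MIL6 = 20`, so its de-repression requires a deep
and lasting Let-7 collapse). This separation is what allows a large
Let-7 increase (`V_SLET7 = 50`) to revert transformed cells - it
re-sponges IL6 and starves the Hill branch - while moderate PTEN or Ras
changes cannot, reproducing the stated asymmetry of interventions.

## Protocols, thresholds, defaults

* **Integration**: stiff-capable adaptive `lsoda` with `rtol = 1e-8`,
  `atol = 1e-10`; perturbation schedules are integrated segment-wise with
  restarts at every event boundary, so parameter steps are sharp. Halving
  the tolerances changes reported quantities by well under 0.1%.
* **Regime classification** (`classify_regime()`): the final 40% of a
  600 h horizon is analyzed (the horizon is many times the ~20-35 h cycle
  period); a species oscillates if its peak-to-trough amplitude exceeds
  `delta_abs = 0.01` a.u. and 5% of its peak (`delta_rel = 0.05`). Both
  cyclin E/Cdk2 and cyclin B/Cdk1 oscillating means proliferative
  oscillations; cyclin E/Cdk2 alone means endocycle-like dynamics
  (DNA replication without mitosis); otherwise the state is steady.
  Periods are mean inter-peak intervals (minimum prominence `delta_abs`,
  at least 3 peaks). The thresholds are exposed because amplitude is
  interpreted semi-quantitatively; near a Hopf boundary small-amplitude
  oscillations are genuinely ambiguous.
* **Fixtures** (`make_fixtures()`): the quiescent non-transformed state
  is the 1000 h converged state under basal parameters; the transformed
  proliferative state is reached after a 5 h Src pulse (0.5 a.u.,
  100-105 h; the pulse height is a package choice - any value giving
  `k_AA1NFKB * Src` well above the NF-kB activation threshold behaves the
  same). Both fixtures are verified against the index thresholds at
  construction.
* **Indexes**: CPI sums the window *maxima* of the four free cyclin
  mRNAs (threshold 1 for proliferation); NTSI is the ratio of window
  *means*, (PTEN + Let7) / (IL6 + NFKB + STAT3 + miR21 + Lin28 + Ras)
  (threshold 10 for the non-transformed state). Maxima are reserved for
  CPI as defined; means are used for NTSI because the definition applies
  to expression levels without a printed time statistic. Classification
  uses strict inequalities ("above which"), so boundary pairs fall on the
  quiescent / transformed side. For expression cohorts the indexes are
  computed per sample and then averaged (computing them on group-mean
  expression is the alternative; per-sample is implemented because it
  also yields the per-sample classification).
* **Populations** (`run_population()`): each cell's parameters are drawn
  independently and uniformly from `p0 * (1 +/- f)`; external inputs GF
  and Src are exempt by default (they are protocol-controlled, and the
  heterogeneity is meant to be cell-intrinsic); the exemption list is
  configurable. Cells run for 1000 h (long enough for switches to
  manifest, given the tens-of-hours switch latencies) with indexes over
  the final 40%. All draws come from one seeded matrix laid out cell by
  cell, so results do not depend on execution order or population size.
  A cell "switches" when its transformed/non-transformed status (NTSI
  threshold) differs from the zero-jitter reference cell. Failed
  integrations are excluded (never imputed); more than 5% failures is an
  error.
* **Regime maps** (`scan_2d()`): each grid cell is an independent run
  from the quiescent fixture. The shipped analysis uses a 20 x 20 grid
  over `V_SMCYC` in [0.1, 3] and `GF` in [0, 10]; the oscillatory area is
  the fraction of proliferative cells (endocycle-like cells reported
  separately). The grid ranges are package choices; the endocycle-like
  band sits at low `V_SMCYC`, where cyclin B/Cdk1 amplitude falls below
  `delta_abs` while cyclin E/Cdk2 still cycles.
* **Sensitivity** (`oat_sensitivity()`): one-at-a-time multiplicative
  fold-changes (default 0.25, 0.5, 2, 4 - parameters span scales, so
  folds rather than additive steps); parameters with zero basal value are
  probed at small absolute values instead.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of bulk tumor /
non-tumor expression cohorts: each sample is one heterogeneous model cell
(uniform parameter jitter, default 50%), started from the quiescent
attractor for non-tumor samples and from the transformed attractor for
tumor samples, except for a configurable fraction of "non-activated"
tumors started from the quiescent attractor (the simplest mechanism for
tumors that cluster with normals). Per-gene expression is the per-cell
model summary (window maxima for cyclin mRNAs, window means otherwise -
the same statistics that enter the indexes) mapped through an editable
gene-symbol table and multiplied by lognormal measurement noise
(multiplicative, because expression data are positive and right-skewed;
default CV 0.2).

What the generator does *not* emulate: sequencing-depth normalization,
batch effects, intermediate (partially transformed) cell states,
tumor-microenvironment admixture, or the absolute expression scales of
any real cohort. Tests passing on synthetic cohorts therefore show that
the index pipeline recovers *planted* structure of this specific kind;
they do not validate the model against real tumors.

## Numerical choices and degenerate inputs

Conserved pools (E2F, APC, NF-kB, STAT3) use Michaelis constants of
0.001-0.05 on pool fractions, giving zero-order ultrasensitivity; the
inactive-pool arguments are clamped at zero so the positive orthant is
forward-invariant (tested on randomized boundary states). A zero NTSI
denominator is guarded by a pseudocount (1e-9, with a warning). Ties in
classification are broken by the strict-inequality rule above. Grids must
be ascending and non-empty; schedules reject overlapping events for the
same parameter.

## Calibration and its limits

The kinetic constants are a calibrated set, not fitted to measurements:
they were chosen so that the qualitative regime structure holds - the
four Let-7 x GF regime corners, the shrinking oscillatory domain with
rising Let-7, endocycle-like dynamics, transformation by a transient Src
pulse or by cyclin overexpression (slower near threshold), durable rescue
by transient Lin28 / NF-kB inhibition or PTEN overexpression,
irreversibility of the cyclin-overexpression switch, the greater noise
fragility of the quiescent state, its protection by Let-7 / PTEN / Ras
changes, and reversion of transformed cells only by a large Let-7
increase. Quantities not constrained by that list (absolute
concentrations, exact periods and amplitudes) should be read as
order-of-magnitude only. The jittered-population and cohort analyses in
the tests use 100-500 cells and horizons of 1000 h; these sizes give
binomial errors of a few percent on switch fractions, which is the
resolution at which the qualitative claims are asserted.

## A minimal session

```{r, eval = FALSE}
library(let7cycle)
fx <- make_fixtures()

## transient inflammation transforms a quiescent cell
sch <- perturbation_schedule(default_parameters(), list(
  list(t_start = 100, t_end = 105, overrides = c(Src = 0.5))))
tr <- integrate_model(sch, initial = fx$NT, t_end = 800)
classify_regime(tr)
cpi_from_trajectory(tr); ntsi_from_trajectory(tr)

## heterogeneous population, 25% jitter
res <- run_population(population_spec(n_cells = 100, jitter_fraction = 0.25,
                                      start = "NT", seed = 1),
                      fixtures = fx)
res$summary
```
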