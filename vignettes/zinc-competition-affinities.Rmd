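---
title: "Competition equilibria and differentiated zinc affinities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition equilibria and differentiated zinc affinities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincomp)
```

## The problem

Metallothionein-2 (MT2) is a small, cysteine-rich protein that binds up to
seven Zn(II) ions in two thiolate clusters.  Whether those seven ions share
one undistinguished (low-picomolar) affinity or span a nanomolar-to-picomolar
gradient decides what the protein *is* physiologically: a storage depot or a
wide-range zinc buffer.  The experimental route to this question is
competition: a chelator, fluorescent probe, zinc-finger peptide or
zinc-inhibited enzyme of known affinity is equilibrated with the loaded
protein, and the amount of transferred metal reports on the protein's site
constants.  This package implements the quantitative machinery around such
experiments: an equilibrium speciation solver, the competing inference
models applied to transfer observations, readout conversions for the common
assay types, simulators that expose the bias of the single-affinity analysis,
and a seeded synthetic-data generator standing in for the wet-lab inputs.

## The equilibrium model

One divalent metal M distributes among (i) a free-ion pool, (ii) independent
receptor sites with fixed conditional step constants
$K_{d,1} \ge K_{d,2} \ge \dots \ge K_{d,n}$ (index 1 = weakest site, the
$\mathrm{Zn_7 \to Zn_6}$ step), and (iii) competitor ligands with 1:1 or 1:2
metal:ligand stoichiometry.  All constants are conditional (apparent) values
at the stated pH (7.4 unless noted); protonation microstates are absorbed
into the constants and never modelled explicitly.  With free metal $Z_f$:

* site occupancy is the Langmuir term $Z_f/(Z_f + K_{d,i})$;
* a 1:1 ligand obeys $L_f = L_{tot}/(1 + Z_f/K_d)$;
* a 1:2 ligand (e.g. PAR, overall constant $K_{d12}$ in M$^2$, two ligands
  consumed per bound metal) obeys the quadratic
  $(2 Z_f/K_{d12}) L_f^2 + L_f - L_{tot} = 0$, solved in its numerically
  stable form.  The 1:1 PAR complex is excluded at pH 7.4, where the 1:2
  complex dominates.

Total bound metal is strictly increasing in $Z_f$, so the metal mass balance
has a unique root.  `solve_speciation()` finds it on $\log_{10} Z_f$ with a
bracket of $[-25, \log_{10} M_{tot} + 2]$ via Brent's method (a hybrid of
bisection and interpolation, unconditionally convergent on a bracket), to a
relative mass-balance tolerance of 1e-9 by default.  The log scale matters:
free Zn(II) in these systems spans at least 1e-13 to 1e-7 M.  Degenerate
inputs (zero total metal or ligand) return exact zeros rather than errors.

The test suite checks the solver against an *independent* oracle written
only for the tests: plain bisection on log free metal with nested bisection
on each ligand's free concentration, sharing no code with the solver.

### Pairwise exchange without a free-metal pool

Transfer between one donor site and one acceptor protein is often written
without an explicit free-metal species: with $x$ the exchanged amount,

$$\frac{x^2}{(D - x)(A - x)} = K_{ex} = \frac{K_d^{donor}}{K_d^{acceptor}}.$$

`pairwise_exchange()` solves this quadratic and returns the root in
$(0, \min(D, A))$.  The formalism is exact when free metal is negligible
against the totals, and the suite verifies agreement with the full solver in
that regime.  We deliberately kept this free-metal-free form (rather than
adding a free pool) because it reproduces the enzyme-inhibition anchor
exactly: an equimolar 0.1 uM mixture of a donor site with
$-\log K_d = 8.2$ and the zinc-inhibited phosphatase PTP1B
($K_d = 1.6\times 10^{-8}$ M) leaves 61% activity:

```{r}
ex <- pairwise_exchange(10^-8.2, 1e-7, 1.6e-8, 1e-7)
round(100 * (1 - ex$acceptor_saturation))
```

One caveat is documented rather than reconciled: the same simple exchange
transfers 0.39 mol eq to the enzyme, whereas the source experiment reports
about 0.6 mol eq transferred; the two readings (exchange bookkeeping vs a
free-pool speciation) give slightly different donor constants (8.2 vs about
8.0) and we follow the exchange form, which matches the printed pairing.

## The three inference models

Given an observed transfer $t$ from receptor total $R$ to a competitor with
free ligand $L_f$ (depletion-corrected: total minus stoichiometry times
$t$ — the corrections are small at up to 235-fold ligand excess but nonzero):

* **Step-wise** (`kd1_stepwise()`): the transfer is attributed to the
  weakest site only. $K_{ex} = t^2 / ((R - t) L_f^{s})$ and
  $K_{d1} = K_d^{comp} \cdot K_{ex}$. Valid in the single-event regime
  $0 < t < R$; outside it the function raises classed errors.
* **Cooperative** (`kdav_cooperative()`): the simplified model in which all
  $n$ sites share one constant and release is all-or-nothing.  The apo
  receptor is $t/n$, the cooperative exchange constant
  $K_{ex}^{coop} = t^n (t/n) / ((R - t/n) L_f^{sn})$, and the aggregate
  constant $(K_d^{comp})^n K_{ex}^{coop}$ (units M$^n$).  The per-ion
  average is the $n$-th root of the aggregate; the literal
  "divide the aggregate by $n$" reduction is exposed as
  `reduction = "divide"` but is not the default, because only the root form
  maps the aggregate range ($10^{-54}$ to $10^{-78}$ M$^7$ across realistic
  PAR competitions) onto the reported per-ion $-\log K_d^{av}$ range of
  roughly 7.6–11.  Internally the computation runs in logarithms: $t^7$ at
  micromolar concentrations underflows double precision.
* **CI-based** (`kd1_from_ci()`): ligands with mixed stoichiometries and
  protonation states (ATP, GSH, His) are collapsed into a hypothetical 1:1
  ligand Z whose apparent complex constant is $10^{-CI}$ at the stated
  totals; the step constant then follows from the same 1:1 arithmetic.  CI
  values are *inputs* (computed externally from literature protonation
  constants); this package does not re-derive them.  Where a printed CI
  range maps to two ligand concentrations, we assume the higher
  concentration carries the higher CI.

Every estimate carries a mandatory model tag, and the tags are never
merged: a cooperative and a step-wise number from the same observation
answer different questions, and the bias simulations below show how far
apart they can be.

Two more estimators complete the set.  `fit_transfer_isotherm()` fits a
bounded logistic $y = p / (1 + 10^{\,n_h (m - x)})$ in $x = -\log_{10} Z_f$
by Levenberg–Marquardt least squares (start: midpoint at the median $x$,
Hill slope 1, plateau at the maximum observed; Hill slope bounded to
[0.3, 5]); the midpoint estimates $-\log K_{d1}$ and a Hill slope above 1
flags overlapping transfer from a second site.  `match_hypothetical_site()`
scans a $-\log K_d$ grid (default step 0.1, mirroring the resolution such
overlays support) for the family member minimising squared residuals
against observed points, breaking ties toward the weaker affinity and
flagging best fits at the grid edge — a competitor can only resolve donor
affinities within its own window, which is why very tight fingers report
"too weak to determine" rather than a number.

### Probe readout

For a calibrated 1:1 fluorescent probe, fluorescence rises on metal
binding, so $F - F_{min}$ tracks the complex and $F_{max} - F$ the free
probe, giving

$$[\mathrm{Zn}]_{free} = K_d^{probe}\,\frac{F - F_{min}}{F_{max} - F}.$$

`free_metal_from_fluorescence()` implements this form: readings at or below
$F_{min}$ return 0 with an underflow flag, readings at or above $F_{max}$
raise a saturation error (free metal is then not determinable).  Note the
ratio direction: writing it inverted would map a saturated probe to zero
free zinc.

`kd1_from_probe_titration()` chains the pieces: per-point free metal from
the calibration, transferred equivalents from the bound-probe fraction,
restriction to the single-event window (at most 0.9 mol eq transferred, so
the second dissociation event does not drag the midpoint), and the logistic
fit.  On data forward-simulated from the seven-site reference model the
pipeline returns the generating weakest-site constant to within 0.01 log
units; the 0.9-eq window is the one analysis choice that matters, and it is
exposed as an argument.

## Simulators: why the "average" constant is an artifact

`simulate_bias_surface()` runs the full differentiated-site speciation for a
grid of hypothetical 1:1 competitors ($K_d$ 1e-14 to 1e-6 M at several
concentrations), then applies the cooperative estimator to each simulated
transfer.  Although the generating receptor never changes, the naive
$-\log K_d^{av}$ sweeps more than three log units across the grid, is
monotone along both axes, and approaches the weakest-site constant in the
weak-competitor limit: the estimator, not the protein, varies.  The
weak-limit check is made at $K_d = 10^{-7}$ M and low competitor
concentrations; for still weaker competitors the transferred amounts fall
below anything an assay could quantify, and the cooperative arithmetic on
such vanishing transfers is not meaningful.  Reported average constants for
the same protein therefore legitimately range from nanomolar to picomolar
depending only on the probe and its concentration; cells of this surface
are compared qualitatively (order of magnitude, monotonicity), since the
competitor concentrations behind any specific published average are
usually unstated.

`buffering_isotherm()` makes the complementary point: plotting the released
metal fraction against the solver's own equilibrium free metal collapses
all competitors — any affinity, any stoichiometry, any concentration — onto
the single curve
$f(Z_f) = \tfrac1n \sum_i K_{d,i}/(K_{d,i} + Z_f)$
(`transfer_fraction_vs_free_metal()`).  Free zinc, not the competitor, is
the buffering set-point.

`simulate_transfer_scenarios()` and `simulate_loading_titration()` generate
the overlay families used to read donor affinities off single observations
(zinc-finger saturation and enzyme-inhibition curves; two-receptor loading
titrations with switchable constant sets, e.g. the solution-derived vs the
ESI-MS-derived MT2 models in `mt_constants()`).

## The synthetic-data generator

No deposited dataset exists for these experiments, so `ground_truth()` plus
the `gen_*()` functions generate every input the estimators and assay
conversions need, from the seven-site reference model (`mt2_ref32`: four
sites at 1.6e-12 M, one at 3.6e-11 M, one at 1.1e-10 M, one at 2e-8 M).
Defaults reproduce the study conditions: 1.7 uM protein with 5–400 uM PAR
(kinetic absorbance at 492 nm, $\varepsilon = 71500$ M$^{-1}$cm$^{-1}$);
0.5 uM protein with 0.05–2.0 uM ZnAF-2F ($K_d = 5.5\times10^{-9}$ M) with
per-point $F/F_{min}/F_{max}$ calibration; equimolar 0.1 uM enzyme
inhibition; 5 uM zinc-finger CD titrations at donor ratios 0.1–2 read at
3–60 min; and 38 uM protein vs 20–40 mM weak ligands separated by SEC.

The noise model is multiplicative Gaussian with $\sigma = 2\%$ on every
measured signal plus an additive floor of 0.1% of the *per-measurement*
full scale (each titration point carries its own calibration maximum; each
kinetic trace its own equilibrium absorbance).  Kinetic traces approach
equilibrium exponentially with a 300 s time constant (the experimental
plateau arrives "after 30 minutes", so $\tau \ll 1800$ s); traces without a
reducing agent gain a linear drift term emulating oxidative metal release
and never plateau — `detect_plateau()` classifies them accordingly, using a
slope tolerance tied to the trace's own noise (median absolute successive
difference x 3, with a small resolution floor).  The CD generator lets the
first (weakest-site) transfer equilibrate fast and later sites slowly,
reproducing the time-dependent saturation seen between 3 and 60 minutes.
All generators are pure functions of (truth, parameters, seed); the
caller's RNG state is saved and restored.

What the generator does *not* emulate: ternary probe–metal–protein
complexes, non-specific probe–protein association at large probe excess,
inner-filter effects, baseline drifts beyond linear, mechanistic oxidation
chemistry, and gas-phase (ESI-MS) speciation effects.  Passing round-trip
tests therefore demonstrate that the estimators invert the stated
equilibrium model faithfully — not that every real-data complication is
handled.

One scenario choice deserves a note: the SEC round-trip test uses an
ATP-like setting (CI 5.1 at 20 mM) rather than the strongest LMW scenario
(CI 7.2 at 40 mM), because under the reference model the latter mobilises
more than one equivalent (the second dissociation event engages) and the
1:1 inversion then correctly refuses with an out-of-regime error — itself a
tested behaviour.  Relatedly, forward simulation of the reference model
predicts somewhat larger transfers for the strongest LMW scenarios than the
published measurements show; we keep the model as specified and surface the
tension here rather than tuning constants.

## Problem sizes and numerical choices

The shipped tests fit in well under a minute: the solver-oracle comparison
uses 1000 random systems (up to 8 sites, up to 3 mixed-stoichiometry
ligands) at a 1e-6 relative agreement bound; mass-balance conservation runs
on 200 further systems at 1e-9; Monte-Carlo recovery uses 25 seeds per
assay.  Root finding tolerances: solver mass balance 1e-9 relative
(speciation), machine-precision bracketing on the log scale; isotherm fits
run up to 200 LM iterations.  Ties in grid matching break toward weaker
affinity; degenerate inputs (zero concentrations) yield exact zeros; all
failure modes raise classed conditions (`zincomp_no_transfer`,
`zincomp_out_of_regime`, `zincomp_saturation`, `zincomp_solver_failure`,
`zincomp_no_transition`, `zincomp_config`) so pipelines can branch on them.

## Limitations

Single-metal systems only (no Cd/Cu competition); no kinetics of exchange
beyond the generator's phenomenological time constants; no global
multi-dataset fit of all seven constants; uncertainty reporting is limited
to replicate spread and fit covariance; CI values are consumed, not
derived.  Constants are conditional at the stated pH — nothing here models
protonation explicitly.
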