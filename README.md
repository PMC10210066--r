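# zincomp

Competition equilibria and differentiated zinc affinities of multi-site
metalloproteins.

## What this is for

Metallothionein-2 (MT2) binds seven Zn(II) ions, and the central question
about it — storage protein or dynamic zinc buffer? — comes down to whether
those ions share one undistinguished picomolar affinity or span a
nanomolar-to-picomolar gradient.  Experimentally this is probed by
competition: chelators (PAR), fluorescent probes (ZnAF-2F), zinc-finger
peptides, zinc-inhibited enzymes (PTP1B) or weak cellular ligands
(ATP/GSH/His) are equilibrated with the loaded protein, and the transferred
metal reports on the site constants.  `zincomp` is for researchers running
or interpreting such experiments.  It provides:

* a **speciation solver** (`solve_speciation()`) for one divalent metal
  among independent receptor sites (step constants
  `K_d1 >= K_d2 >= ... >= K_dn`, index 1 = weakest), 1:1/1:2 competitor
  ligands and a free-ion pool, by mass-balance root finding on log free
  metal;
* the **inference models** applied to transfer observations: step-wise
  (`kd1_stepwise()`, `Kd1 = Kd_comp * t^2 / ((R - t) Lf^s)`), cooperative
  single-affinity (`kdav_cooperative()`), competitivity-index based
  (`kd1_from_ci()`), logistic isotherm fitting (`fit_transfer_isotherm()`)
  and grid matching against exchange families
  (`match_hypothetical_site()`);
* **assay readout models** (Beer–Lambert, plateau detection, enzyme
  activity, CD saturation, Zn-per-protein stoichiometry, probe calibration
  `Zn_free = Kd (F - Fmin)/(Fmax - F)`);
* **bias simulators** showing that the popular "average" constant tracks
  the competitor, not the protein (`simulate_bias_surface()`), and that
  the buffering isotherm is competitor-independent
  (`buffering_isotherm()`);
* a seeded **synthetic-data generator** (`ground_truth()`, `gen_*()`)
  reproducing the assay designs from a seven-site ground truth, so the
  whole pipeline is testable without wet-lab files.

Packaged constant sets: `mt_constants("mt2_ref32")` (solution model: four
sites at 1.6e-12 M, 3.6e-11 M, 1.1e-10 M, 2e-8 M), `"mt1_esi"` and
`"mt2_esi"` (gas-phase models), plus the competitor table
`zn_competitors()` and reported results `mt2_kd1_results()`.

## Worked example

Compete 1.7 uM fully loaded MT2 against 10 uM PAR, then estimate the
weakest-site constant two ways:

```r
library(zincomp)
mt2 <- multisite_receptor(mt_constants("mt2_ref32"), 1.7e-6, "MT2")
par10 <- competitor_ligand(7.1e-13, 1e-5, stoich = 2, label = "PAR")
st <- solve_speciation(zn_system(mt2, par10, total_metal = 7 * 1.7e-6))
st
#> <speciation_state> free metal 1.22e-08 M (residual 6.3e-15)
#>   complexes: PAR 1.065e-06 M
#>   receptor 1 occupancy: 0.379 0.991 0.997 1.000 1.000 1.000 1.000

obs <- competition_observation(1.7e-6, par10,
                               transferred = st$complex_conc[["PAR"]])
kd1_stepwise(obs)
#> <affinity_estimate> -logKd = 7.69  [model: stepwise]
kdav_cooperative(obs)
#> <affinity_estimate> -logKd = 8.06  [model: cooperative]
```

The step-wise estimate recovers the generating weakest site (-log10 of
2e-8 is 7.70).  The cooperative ("all seven sites equal") estimate does
not — and it moves with the competitor concentration: repeating the same
calculation at 200 uM PAR gives

```r
#> <affinity_estimate> -logKd = 10.23  [model: cooperative]
```

Same protein, same model constants, 2 log units apart: the average
constant is a property of the experiment, not the protein.  The
full-pipeline version of the same point, from a noiseless synthetic probe
titration through the calibrated readout to the isotherm fit:

```r
tab <- gen_probe_titration(ground_truth(sigma = 0, floor_frac = 0))
kd1_from_probe_titration(tab, probe_kd = 5.5e-9, receptor_total = 0.5e-6)
#> <transfer_isotherm> midpoint -logKd = 7.699, Hill n = 1.51,
#>                     plateau = 0.918 eq (7 points)
```

The midpoint lands on the weakest site; the Hill slope above 1 is the
fingerprint of partial overlap with the second dissociation event.
Recovery under the 2% noise model is exercised in the test suite (25-seed
Monte Carlo, median within 0.1 log units).

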