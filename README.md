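# formateswitch

Kinetic modelling and omics statistics for the formate-dependent metabolic
switch in nucleotide and energy metabolism.

Mammalian cells oxidise serine to formate faster than biosynthesis needs,
and release the excess (formate overflow). Because de novo purine synthesis
consumes two formyl groups per ring, formate availability couples to the
adenine nucleotide pools (AMP, ADP, ATP) and, through them, to glycolysis,
oxidative phosphorylation and proliferation. `formateswitch` is for
systems-biology and metabolism researchers who want to reproduce, probe or
extend that coupling: it implements the steady-state kinetic model of the
switch, the emergent Michaelis–Menten description of the energy pathways,
the ATP-threshold flux-balance model of orotate/argininosuccinate
accumulation, and the permutation statistics used to score proteomics and
metabolomics tables against an ordinal one-carbon availability index —
plus synthetic-data generators that emulate the study designs so the whole
analysis runs with no external data.

## The model in brief

At steady state, with intracellular formate `F`, one-carbon pool `C` and
total adenine pool `A = AMP + ADP + ATP`:

```
formate:     v_ser + k_tr (F_ext − F)  =  v_fix,   v_fix = V_fts F/(K_F+F) − k_rev C
one-carbon:  v_fix + q_cyto            =  n_1C · v_pur,  v_pur = V_pur C/(K_C+C)
purines:     v_pur                     =  μ · A          (μ coupled to ATP, ADP, or constant)
energy:      V_gly ADP/(K_gly+ADP) + V_ox ADP/(K_ox+ADP) = V_use ATP/(K_use+ATP)
adenylates:  ADP² = K_AK · ATP · AMP   (adenylate kinase equilibrium)
```

Raising `v_ser` drives a low-to-high transition in all three adenine
pools; formate release starts when production reaches the threshold set by
the purine synthesis rate (`n_1C·V_pur − q_cyto`). Exogenous formate or
cytosolic one-carbon production shift the transition to lower production
rates. The satellite model explains the steep orotate rise: production by
the ATP-dependent synthetase (Hill, `h = 1` for CAD, `h = 2` for
argininosuccinate synthetase) against saturable turnover diverges as ATP
approaches `ATP* = Kp (Vt/(Vp−Vt))^(1/h)`.

See the methods vignette (`vignettes/formate-switch-model.Rmd`) for the
assumptions, default parameters and numerical choices.

## Worked example

```r
library(formateswitch)
p <- kinetic_params()                      # defaults, mM and mM/h

steady_state(p, v_ser = 0.1, F_ext = 0.02)[c("F","ATP","ADP","AMP","v_pur","v_tr","mu")]
#>         F  ATP   ADP   AMP v_pur    v_tr     mu
#> 1 0.00792 0.72 0.288 0.116 0.056 -0.0121 0.0499
```

At a production rate of 0.1 mM/h the cell is below the overflow point:
formate stays at ~8 µM, `v_tr < 0` means net uptake of the 20 µM
extracellular formate, and the pools sit mid-transition (ATP 0.72 mM).
The overflow threshold and its analytic bound:

```r
overflow_threshold(p, F_ext = 0.02, eps = 0.05)
#>   v_ser_star analytic_bound   eps found
#> 1      0.211            0.3  0.05 TRUE
```

Release exceeds 5% of production from 0.211 mM/h onward — below the
demand bound 0.3 because passive transport leaks earlier. The emergent
Michaelis–Menten law of the glycolysis chain over 500 random cofactor
states:

```r
cf <- sample_cofactors(500, seed = 1)
fit_michaelis_menten(tibble::tibble(
  substrate = cf$ADP,
  rate = glycolysis_rate(cf$ADP, cf$ATP, cf$NAD_ox, cf$NAD_red)))
#> <mm_fit>  Vmax = 3.911, Km = 0.0979998 mM, R^2 = 0.9752 (n = 500)
```

A five-step chain collapses onto a single hyperbola in ADP (R² 0.98).
Association testing on synthetic proteomics (six conditions, index
0/1/1/2/2/2, exhaustive enumeration of all 720 orderings):

```r
design <- gen_condition_design()
sim <- gen_proteomics(n_features = 100, frac_responsive = 0.2, seed = 1)
assoc <- oc_associations(sim$table, design, n_perm = 2000, seed = 1)
table(detected = assoc$p_value < 0.05, responsive = sim$truth$responsive)
#>         responsive
#> detected FALSE TRUE
#>    FALSE    76    0
#>    TRUE      4   20
```

All 20 planted features are recovered at the exact permutation p < 0.05.
`run_pipeline(pipeline_config(seed = 1), out_dir)` chains every stage —
sweeps, MM fits, titration, orotate fit, associations, enrichment — and
writes a manifest of invariant checks.

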