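---
title: "The formate-dependent metabolic switch: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The formate-dependent metabolic switch: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formateswitch)
```

## The model

Mammalian cells oxidise the third carbon of serine to formate, mostly in
mitochondria, at rates that can exceed the biosynthetic demand for
one-carbon (1C) units; the excess is released from the cell (formate
overflow). The largest 1C sink is de novo purine synthesis, which consumes
two formyl groups per purine ring and thereby couples formate availability
to the adenine nucleotide pools, and through them to glycolysis, oxidative
phosphorylation and proliferation. `formateswitch` implements a steady-state
kinetic model of that coupling, together with the statistical machinery
used to score omics readouts against a one-carbon availability index.

The cell state is intracellular formate $F$, a usable 1C pool $C$
(10-formyl-THF equivalent) and the total free adenine pool
$A = \mathrm{AMP} + \mathrm{ADP} + \mathrm{ATP}$ (all mM). Four balances
define a steady state:

* **Formate.** Production $v_{ser}$, passive transport
  $k_{tr}(F_{ext} - F)$ and net fixation balance:
  $v_{ser} + k_{tr}(F_{ext} - F) = v_{fix}$, with
  $v_{fix} = V_{fts}\,F/(K_F + F) - k_{rev} C$.
* **One-carbon pool.** $v_{fix} + q_{cyto} = n_{1C}\, v_{pur}$, with
  Michaelis--Menten purine synthesis $v_{pur} = V_{pur} C/(K_C + C)$,
  $n_{1C} = 2$ (the GAR- and AICAR-transformylase steps) and a constant
  cytosolic 1C production $q_{cyto}$.
* **Purine pool growth.** At balanced growth the purine pool is diluted by
  proliferation: $v_{pur} = \mu A$. The coupling of $\mu$ to the energy
  state is configurable: Michaelis--Menten in ATP (default), in ADP, or
  constant.
* **Energy.** ADP phosphorylation by glycolysis and oxidative
  phosphorylation balances ATP consumption,
  $V_{gly}\frac{\mathrm{ADP}}{K_{gly}+\mathrm{ADP}} +
   V_{ox}\frac{\mathrm{ADP}}{K_{ox}+\mathrm{ADP}} =
   V_{use}\frac{\mathrm{ATP}}{K_{use}+\mathrm{ATP}}$,
  with the split of $A$ into AMP/ADP/ATP pinned by the fast adenylate
  kinase equilibrium $\mathrm{ADP}^2 = K_{AK}\,\mathrm{ATP}\cdot\mathrm{AMP}$.

### The reverse fixation flux

The term $-k_{rev} C$ makes net fixation reversible (10-formyl-THF
synthetase catalyses both directions). It is structurally necessary: with
irreversible fixation the 1C pool has no finite steady state once supply
exceeds the maximal purine demand $n_{1C} V_{pur} - q_{cyto}$, and the
overflow threshold would be set by the fixation capacity $V_{fts}$ rather
than by the purine synthesis rate. With the relief valve, excess 1C units
return to formate, intracellular formate rises and the surplus is
exported -- overflow begins where purine demand saturates, which is the
behaviour the model exists to capture. The analytic demand bound
$n_{1C} V_{pur} - q_{cyto}$ is reported by `overflow_threshold()` next to
the operational $\varepsilon$-crossing.

### Solving

`steady_state()` uses nested deterministic scalar root finding rather than
stiff ODE integration: $F$ first (the 1C pool then has a closed-form
quadratic solution given $F$), then the total adenine pool from the
purine-growth balance, with the energy ratio solved by bracketed root
refinement in $\log r$ (relative tolerance $10^{-13}$). Reported fluxes
are reconstructed through the conservation identities, so the mass
balances hold to machine precision and the root tolerance only limits
rate-law consistency. `relax_steady_state()` (deSolve) integrates the
dynamic counterpart as an independent cross-check; the test suite verifies
agreement to $10^{-6}$.

Degenerate inputs return the zero-flux fixed point rather than erroring;
the reported ATP/ADP ratio at zero pool size is the analytic limit of the
energy balance. In a closed system ($k_{tr}=0$) with excess 1C supply no
steady state exists and a `saturated` row with `F = Inf` is returned.

## Default parameters

Units are mM and mM/h throughout; proliferation is 1/h. The study the
model describes does not print its parameter values, so the defaults were
chosen once to place the model in the physiological regime in which all of
its qualitative claims hold, and then frozen:

* `V_fts = 0.5`, `K_F = 0.02`: fixation saturates in the tens-of-µM
  formate range, so formate stays low below the overflow point.
* `V_pur = 0.15`, `K_C = 0.05`, `n_1C = 2`: maximal purine demand
  ($2 V_{pur} = 0.3$) sits below the fixation capacity, making purine
  demand the overflow bottleneck. The implied high-state pool,
  $A \approx v_{pur}/\mu \approx 2.5$ mM, is a typical cellular total
  adenine concentration.
* `k_tr = 1`, `k_rev = 1`: transport and reverse fixation on the h$^{-1}$
  scale, slow against the enzymatic steps.
* `V_gly = 2`, `V_ox = 4`, `K_gly = K_ox = 0.25`, `V_use = 5`,
  `K_use = 0.4`: supply capacity just above demand and an ATP
  half-saturation of consumption in the sub-mM/mM range (the regime
  motivated by synthetases such as carbamoyl-phosphate synthetase, whose
  ATP half-saturation is on the mM scale). In this regime ATP rises
  superlinearly with the total pool while AMP and ADP still rise with it
  -- which is what makes all three pools increase along the production
  axis, as observed, and what makes the constant-proliferation variant's
  transition at least as steep as the ATP-coupled one.
* `mu_max = 0.05` (a ~14 h doubling time), `K_mu = 0.002`: most
  ATP-utilising enzymes have µM-range Michaelis constants, so the
  proliferation coupling saturates early; the mM-range exception is on
  the consumption side (`K_use`), per the synthetase argument above.
* `K_AK = 1`: near-equilibrium adenylate kinase.

The sweeps use a 50-point grid over $v_{ser} \in [0, 0.6]$ mM/h, which
brackets the overflow threshold (about 0.21 mM/h operationally at
$\varepsilon = 0.05$).

```{r sweep, fig.width = 7, fig.height = 5}
p <- kinetic_params()
grid <- seq(0, 0.6, length.out = 50)
sw <- dplyr::bind_rows(
  sweep_production(p, grid, "baseline_0.02mM"),
  sweep_production(p, grid, "formate_1mM"),
  sweep_production(p, grid, "cytosolic")
)
plot_sweep(sw)
```

## Emergent Michaelis--Menten kinetics of the energy pathways

The effective single-substrate laws used in the core model are justified
by detailed chain models. The glycolysis chain has five saturable steps
(ATP-consuming upper lump, NAD$^+$-dependent oxidation, two
ADP-phosphorylating kinase lumps, NADH-consuming terminal lump); oxidative
phosphorylation is a respiration stage in series with an ATP-synthase
stage inhibited by the ATP/ADP ratio. The chain flux is composed as the
series ("harmonic") limit of the sequential steps,
$J = (\sum_i 1/v_i)^{-1}$: the slowest step dominates, every step blocks
the chain at zero, and the composition is smooth. For the two
ADP-dependent steps this composition is *exactly* Michaelis--Menten in ADP
with cofactor-dependent apparent constants, which is why a single MM curve
fits a cloud of random cofactor states well -- the package asserts
$R^2 \ge 0.9$ over 500 log-uniform cofactor draws for both pathways rather
than any particular constant. The oxphos model's ratio inhibition makes it
deviate more (its $R^2 \approx 0.96$ against $\approx 0.98$ for
glycolysis in the shipped configuration), mirroring the poorer MM fit of
oxidative rates seen in data.

`fit_michaelis_menten()` minimises unweighted least squares on the rate
scale. $V_{max}$ enters linearly for fixed $K_m$ and is profiled out,
leaving a one-dimensional search over $\log K_m$ (a Hanes linearisation
`s/v ~ s` centres the window). Because `optimize()` cannot resolve a
minimum below $\sqrt{\epsilon}$, the minimiser is polished by bisection on
the sign of the profile gradient, which is deterministic to machine
precision and makes the fit exactly scale-equivariant (scaling all rates
by $c$ scales $\hat V_{max}$ by $c$ and leaves $\hat K_m$ unchanged).

## The ATP-threshold model of orotate and argininosuccinate

Orotate production is gated by the ATP-dependent carbamoyl-phosphate
synthetase step, modelled as a Hill law
$v = V_p\,\mathrm{ATP}^h/(K_p^h + \mathrm{ATP}^h)$ with $h = 1$;
argininosuccinate synthetase shows ATP cooperativity with $h = 2$.
Turnover is saturable, $V_t O/(K_t + O)$. When $V_p > V_t$ the steady
level $O = K_t v/(V_t - v)$ diverges at
$\mathrm{ATP}^* = K_p (V_t/(V_p - V_t))^{1/h}$ -- the threshold-like rise
of orotate as ATP approaches a limiting value.

The level curve determines only two parameter combinations (an amplitude
$K_t V_p / K_p^h$ and the critical point $(V_p - V_t)/K_p^h$), so the fit
fixes both $V_t = 1$ (making $V_p$ the capacity ratio $V_p/V_t$) and the
turnover half-saturation $K_t$ (default 1; peak areas carry an arbitrary
scale). Leaving $K_t$ free would put the optimum on a one-dimensional
ridge. Starting values come from inverting the turnover law --
$O/(O + K_t)$ is MM in $\mathrm{ATP}^h$ and is fitted with the profiled MM
fitter -- followed by Nelder--Mead on the log-parameters with a fallback
start grid; predictions in the unbounded region are capped at a multiple
of the largest observed level to keep the objective finite.

## Association statistics

Conditions are scored by an ordinal one-carbon availability index: 0 for
the MFT-SHMT1 double knockout, 1 for the MFT and SHMT2 single knockouts,
2 for the formate-supplemented knockouts and the parental line. The
per-feature statistic is the OLS slope of log2 intensity on the index
(or the Spearman rank correlation); raw tables are log2-transformed with
zeros masked (dropped for that measurement) rather than pseudocounted,
because LFQ zeros are missingness, not abundance. A pseudocount would bias
slopes for features missing in one arm; masking only reduces their sample
size.

Significance comes from permuting values across conditions. Replicates
are averaged within condition before permuting -- the exchangeable unit
under the null is the cell line/condition, not the technical replicate --
with a replicate-level block mode available. When the number of orderings
is within the permutation budget (720 for six conditions) the
distribution is enumerated exhaustively and $p = b/N$ is exact with the
identity included; otherwise the Monte-Carlo estimator
$p = (b+1)/(N+1)$ is used, whose floor $1/(N+1)$ avoids zero p-values.
Raw permutation p-values are always reported; Benjamini--Hochberg
adjustment is an opt-in extra column, never applied silently.

Gene-set enrichment uses the weighted running-sum score (hits weighted by
$|{\rm slope}|$, misses by $1/(N - n_{hit})$), feature-label permutations
for the null, and a stable sort on feature ID as the tie-break so results
are reproducible; the test suite cross-checks the score against the
`fgsea` implementation. Two-group comparisons use Welch's t test with
Satterthwaite degrees of freedom, and pathway protein mass is the raw-scale
sum over member features with replicates averaged first.

## What the generators emulate -- and what they do not

`gen_proteomics()` reproduces the statistical skeleton the association
machinery assumes: log-normal LFQ intensities (normal log2 baselines,
SD 2 around 25), a responsive subset with a linear log2 trend per index
step, and independent normal replicate noise (SD 0.2 log2 units) over the
six-condition, three-replicate design. `gen_titration_metabolomics()`
drives the kinetic model over the nine twofold dilutions of supplemented
formate (1 mM down to 0.0039 mM) with $v_{ser} = 0$, emitting adenine
pools, an orotate readout through the threshold model, a lactate proxy
proportional to $v_{gly}$, and multiplicative log-normal noise (CV 0.1),
the standard error structure of LC-MS peak areas. AICAR is a
*phenomenological* proxy, $\propto v_{pur} K_I/(K_I + \mathrm{ATP})$: it
rises with purine flux at low ATP and is suppressed at high ATP,
reproducing the rise-then-fall across the titration qualitatively; the
core model does not carry purine intermediates mechanistically.

The generators deliberately omit missing-value structure, batch effects,
peptide-to-protein inference and intensity-dependent variance. Passing
tests therefore demonstrate correctness of the statistics under the
model's own assumptions, not robustness to everything real LFQ data can
do.

All generators are pure functions of their arguments and seed
(bit-identical regeneration, caller's RNG stream untouched), and tables
round-trip through the TSV writer at 12 significant digits.

## Problem sizes and runtime choices

The shipped checks use 50-point sweeps over three scenarios, 500 cofactor
draws for the emergence claim, 100 Monte-Carlo repeats for the two noisy
fit-recovery properties, 500 null features at a 2000-permutation budget
(exhaustive enumeration engages at 720) for calibration, and 200 features
for the power property -- sizes at which every stochastic assertion is
stable across seeds while the whole suite runs in about a minute. The
pipeline (`run_pipeline()`) wires the stages together, writes per-stage
TSV/JSON plus a manifest of all invariant checks, records the
configuration hash and seed in the manifest, and is bit-identical under a
fixed configuration.

## Known limitations

* No NAD redox state in the core model (it appears only in the detailed
  pathway chains), no dTMP/thymidine branch, no compartmentalised folate
  speciation.
* The energy module is phenomenological: no proton-motive force or
  thermodynamic oxphos model, and no alternative law for the oxphos
  deviation from MM.
* The proliferation couplings are quasi-static; transient dynamics are
  only used as a numerical cross-check.
* The orotate model stops at the flux balance for a single metabolite; no
  downstream pyrimidine pools, and the urea cycle enters only through the
  argininosuccinate synthetase step ($h = 2$).
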