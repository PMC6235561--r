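---
title: "Two-compartment kinetic modelling of the Calvin-Benson cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment kinetic modelling of the Calvin-Benson cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrenoidCBC)
```

# The problem

In *Chlamydomonas reinhardtii* most Rubisco sits inside the pyrenoid, a
liquid-like microcompartment of the chloroplast, while the remaining
Calvin-Benson-cycle (CBC) enzymes stay in the stroma. Under low CO2 the
carbon concentrating mechanism (CCM) pushes the Rubisco partition from
roughly a fifth to roughly two thirds pyrenoidal. Metabolite
concentrations, however, can only be measured as chloroplast totals:
separating the compartments destroys the pools. This package infers what
cannot be measured — the compartment-resolved fluxes, free and
enzyme-bound pools, and the exchange fluxes across the pyrenoid boundary
— by combining an elementary-reaction mass-action model with constrained
flux sampling and log-linear parameter estimation.

# Model structure

Every enzymatic reaction is decomposed into irreversible elementary
steps with explicit enzyme-substrate complexes: an irreversible reaction
`A -> B` catalysed by `E` becomes `A + E -> AE`, `AE -> A + E`,
`AE -> B + E` (3 steps, one complex); a reversible reaction gets the
mirror-image triplet for the reverse direction (6 steps, two complexes).
Co-substrates bind in a single step, so each direction has exactly one
complex. Reversible stroma/pyrenoid diffusion becomes two irreversible
directions; cytosol exchange, CO2 uptake and the ATPase/FNR
pseudo-reactions (the lumped light reactions) stay single irreversible
columns. All fluxes are nonnegative by construction, and every enzyme
moiety (free enzyme plus its complexes) is conserved by every column of
the stoichiometric matrix — `moiety_check()` verifies this together with
carbon/phosphate balance against the packaged moiety table.

## The packaged catalogue and the census

The original study states totals of 226 irreversible reactions and 128
components, but also itemises its census as 2 x 65 elementary reactions
+ 40 diffusion + 8 triose-phosphate exchanges + 2 pseudo-reactions =
180; the two figures cannot both describe the same enumeration, and the
full reaction list is in supplementary material that is not
redistributed here. The packaged catalogue is therefore a
reconstruction, chosen once, that reproduces the printed totals exactly
with defensible chemistry:

* 16 enzymatic reactions per compartment: the 13 canonical CBC steps
  (4 irreversible: Rubisco, FBPase, SBPase, PRK; 9 reversible), plus the
  second chloroplast GAPDH isoform (both isoforms appear in the
  localisation data), plus phosphoglucose isomerase (F6P <-> G6P, the
  measured hexose-phosphate node) and the NADP-malate dehydrogenase
  redox valve. That is 84 elementary steps and 28 complexes per
  compartment.
* 20 stroma/pyrenoid diffusion pairs — 40 irreversible diffusion
  reactions, matching the itemised figure.
* 8 triose-phosphate/Pi cytosol exchanges plus 8 further envelope
  exchanges (CO2 uptake and release, ATP import/ADP export, OAA/malate
  exchange), and the two pseudo-reactions.

Totals: 2 x 84 + 40 + 16 + 2 = 226 reactions and
2 x (22 metabolites + 14 enzymes + 28 complexes) = 128 species.
`census()` always reports both this census and the itemised reference
figures with their deltas (84 vs 65 elementary steps per copy; the extra
envelope exchanges), so the reconstruction is visible, not silent.

A scenario (`scenario()`, `standard_scenarios()`) restricts which
enzymes are catalytically active in the pyrenoid; stroma/pyrenoid
exchange is then derived, never configured: exactly the metabolites
participating in reactions of pyrenoid-active enzymes, plus CO2 (the CCM
requires CO2 diffusion into the pyrenoid in every scenario).

# The constrained flux cone

`build_constraints()` imposes on `N v = 0, 0 <= v <= vmax`:

* **Fixed boundary fluxes** (µM/s, chloroplast-volume basis): CO2 uptake
  398, FNR 796 (two NADPH per O2), ATPase 1194 (1.5 ATP per NADPH).
  These three are mutually consistent with CBC stoichiometry — 2 NADPH
  and 3 ATP per CO2 — which is also why the ATPase figure must be read
  as 1194 rather than 1.194: with 1.194 the adenylate pool cannot
  balance and the cone is empty. Because the ATP synthase pseudo-reaction
  lumps a whole membrane activity, pseudo-reactions are exempt from the
  per-enzyme cap `vmax` = 1000 µM/s.
* **Auxiliary envelope exchanges pinned to zero** by default: gas
  exchange measures net CO2 uptake; the nucleotide translocator is
  dark-active; the malate valve is closed when the NADPH budget balances
  exactly. All configurable.
* **Partition-ratio constraints** `v_pyr = q (v_str + v_pyr)` on the
  catalytic steps of every pyrenoid enzyme with measured partition data
  (activity measures turnover, so the constraint binds catalysis, not
  binding). `q` is redrawn per sample, uniformly on mean ± 1 SE clipped
  to [0, 1]; enzymes measured below 5% pyrenoidal are treated as
  stroma-only (`q = 0`). An inequality mode (`ratio_mode = "bound"`) is
  available.

`sample_fluxes()` runs hit-and-run with isotropic directions in the
null space of the equality system and uniform steps on the feasible
chord, with defaults of 1000 warm-up and 100 thinning steps per sample.
Two numerical points matter. First, the tableau LP solver used for
feasibility cannot digest redundant equality rows (the stoichiometric
matrix carries one conservation relation per enzyme moiety), so the LP
layer row-reduces the equality block by QR and re-verifies the dropped
rows on every solution. Second, a hit-and-run chain started at an LP
vertex never moves (almost every direction leaves the polytope), so the
chain starts from a cone centre obtained by averaging ~25 vertices that
optimise random objectives — the classic warm-up of
artificial-centering samplers. Each sample's freshly drawn `q` rotates
the affine subspace slightly; the centre is retuned to the new ratio
exactly by moving catalytic flux along a steady-state-preserving
transport cycle, so no additional LP is needed per sample.

# Log-linear parameter estimation

For a sampled `v*`, mass action gives
`log v*_j = log k_j + sum_i n-_ij log c_i` for every active reaction.
Eliminating `log k` by substitution leaves the log concentrations and
the elastic variables as the LP unknowns: minimise
`sum(eps+ + eps-) + sum |log k - log k_lit|` subject to the pairing
equalities `log k_pyr - log k_str = eps+ - eps-` for every elementary
step present in both compartments, box constraints on `log k`, and
concentration bounds. Choices, with reasons:

* **Concentration bounds** (`build_bounds()`): every free pool is capped
  at 100% of the measured total; ordinary metabolites get a lower bound
  of 90% (default) or 99% (sensitivity preset) of the total; 3PGA gets
  50%; RuBP and BPGA only the generic floor (0.01 µM in spirit; 1e-3 µM
  numerically). The special cases are not arbitrary: RuBP, BPGA and 3PGA
  are exactly the pools that are either mostly enzyme-bound or split
  across both compartments in the Rubisco-only scenario, where a 90%
  floor applied per compartment would force the modelled total towards
  twice the measurement. Unmeasured metabolites (gases, cofactors) get
  generic bounds of 1e-3 to 1e4 µM, enzymes and complexes 1e-6 to 200 µM
  (protein pools do not exceed a couple of hundred µM).
* **Kinetic bounds**: literature turnover numbers (packaged
  reconstruction of standard plant values) bound the forward catalytic
  constants of six enzymes and act as soft targets with unit weight —
  the method's statement that the optimiser "attempts to reduce the
  difference" from published values is implemented as L1 elastics.
  All other *enzymatic* steps get the generic prior
  `log10 k in [-3, 8]`. Transport, exchange and pseudo-reactions carry
  no kinetic prior: their rate coefficients are boundary or diffusion
  parameters, and a floor on them would silently impose a flux floor
  (a 0.06 µM/s export from a 300 µM pool is a perfectly admissible
  sample but implies k ~ 2e-4 s^-1).
* **Zero-flux reactions**: fluxes below 1e-4 µM/s — an order below the
  steady-state tolerance of the sampler (1e-6 x vmax = 1e-3 µM/s) — are
  numerical zeros; their log-equations are dropped and their rate
  constant is reported at the geometric mean of its box.
* **Infeasible instances** are rediagnosed by elastic relaxation and
  reported as kinetic- or concentration-bound conflicts.

`total_concentration()` compares to data as free stroma + free pyrenoid
+ all bound forms, summed as concentrations without volume weighting,
the same totalling convention the measurements use.

# Scenario selection

`chi_square()` uses the Pearson-style form
`sum((modelled - measured)^2 / measured)` with the measured total as
expectation (the variance-weighted form is available via
`form = "variance"`); the default panel is the 11 CBC intermediates
measured in both conditions. A fit is "significant" (not rejected) below
the 0.95 chi-square quantile at panel-size degrees of freedom. Mean
statistics are reported over all samples, selection keeps the
1000 best with deterministic tie-breaking (`rank_and_select()`), and
`compare_scenarios()` additionally flags the circular-transport
artifact: a scenario scoring well while an allegedly pyrenoid-active
enzyme carries no catalytic flux there, its metabolites merely cycling
in and out of the compartment.

# Thermodynamics and net fluxes

`delta_g()` evaluates `-RT (ln Keq - ln Q)` exactly, with Q built from
free metabolite pools converted to mol/L against the 1 M standard state
(enzymes and complexes never enter Q). Defaults: T = 297.15 K (the 24 °C
culture temperature; the study does not state the temperature used) and
a packaged equilibrium-constant table with typical apparent values at
pH ~7.5 — the original table is not redistributed, and the shipped one
documents its own assumptions, including the molecularity change
`delta_n` that fixes the concentration basis. Net fluxes follow the
elementary-step conventions (`v_f - v_b` for transports; `v_cat` for
irreversible and `v_cat_f - v_cat_b` for reversible enzymatic
reactions, binding fluxes never counting as activity), with positive
transport meaning stroma to pyrenoid. Direction classes over a selected
ensemble call a reversible reaction bidirectional when both catalytic
directions carry at least 1% of the larger one in at least 5% of the
sets (thresholds configurable; none are stated in the original work).
`diffusion_proxy()` divides net transport flux by the stroma-pyrenoid
free-concentration difference and refuses to evaluate 0/0: a zero
gradient with nonzero flux is reported as the distinct "no-gradient
transport" case (diffusional equilibrium, as for 3PGA).

# The synthetic-data generator

The generator defines the package's testable world. It allocates each
enzyme between the compartments at the measured partition mean (the 5%
detection rule applies), samples one flux distribution from exactly the
same constrained cone the inference uses, draws free concentrations
log-uniformly on the measured scales (20-300 µM for metabolites, 5-50 µM
for proteins, 0.02-0.5 µM for the trace free pools of RuBP and BPGA),
sizes the complexes of literature-constrained enzymes as
`v_cat / k_lit`, and derives every rate constant from mass action,
`k = v / prod(c^n-)`. The result is an *exact* steady state — the
certificate `max|N v| <= 1e-8 max(v)` is algebraic, not a time-stepping
heuristic. This construction was chosen deliberately: free-running
mass-action CBC kinetics with a pinned CO2 influx has no finite stable
steady state for generic rate constants (RuBP integrates its production
surplus without any feedback, which long stiff integrations confirm),
so "integrate until stationary" is not a reliable generator. A stiff
integrator is still exported (`relax_to_steady_state()`) for studying
dynamics near a constructed state and is exercised on a closed
symmetric cycle in the tests.

By default the truth has exactly equal pyrenoid/stroma rate constants:
the sampled flux is retuned (within the cone) so each paired elementary
step runs at the enzyme's partition ratio, and pyrenoid concentrations
mirror the stroma ones scaled by that ratio. This is the regulation-free
reference case in which the elastic objective can reach zero.

`emit_measurements()` perturbs the chloroplast totals of the measured
carbon metabolites with multiplicative lognormal noise (default CV 0.15,
typical of HPLC-MS/MS replicates; 4 replicates as in the data) and emits
partitions as the true flux shares plus a small jitter — in exactly the
file schemas of the real-data readers, so the pipeline cannot tell
provenance. The packaged `measurements_synthetic.tsv` is one such
dataset (Rubisco-only truths, seeds 101/202), regenerable with
`scripts/make_reference_dataset.R`.

What passing tests on this world do and do not show: they demonstrate
that the pipeline recovers the generating compartmentation hypothesis,
reproduces measured totals (Pearson r > 0.99), and drives the
compartment elastics towards zero when the truth warrants it. They do
not validate the biology of the real measurements — the synthetic world
has no redox regulation, no measurement-correlated errors, and its
literature rate constants sit exactly at the published point values.
Conversely, ensemble chi-square levels depend strongly on the bound
preset (the 99% preset gives X-bar^2 ~ 1, the 90% preset ~ 10) and on
the measured values themselves, so absolute chi-square magnitudes are
not comparable across datasets — only scenario orderings are.

# Problem sizes and runtime

The study sampled 5000 flux distributions per scenario and condition
and kept the best 1000. The packaged tests and examples run the same
pipeline at 500 samples (selection 100) with a 400-step warm-up, which
reproduces ensemble means to within a few percent while keeping the
whole suite in the minutes range on one core; all sizes are arguments.

# Known limitations

* Chi-square magnitudes on the packaged data are not those of the
  original study: the study's raw metabolite table is not
  redistributable, and the statistic is a function of it.
* Individual rate constants are poorly identified from a single flux
  sample (the LP returns one vertex of an optimal face); only quantities
  constrained by bounds, pairing or literature priors are meaningful.
  Rate constants without any prior (e.g. transketolase) can sit at a box
  edge.
* No redox regulation (GAPDH/SBPase activation states), no
  thylakoid-lumen bicarbonate chemistry, no photorespiration, no starch
  synthesis flux — matching the scope of the original model.
* The equilibrium-constant and turnover tables are reconstructions with
  stated assumptions, not the original supplementary tables.
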