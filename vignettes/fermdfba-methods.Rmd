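---
title: "Multiphase multiobjective dynamic FBA for batch wine fermentation"
author: "fermdfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase multiobjective dynamic FBA for batch wine fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermdfba)
```

## The model

`fermdfba` implements a dynamic genome-scale model of batch wine
fermentation by *Saccharomyces* yeasts. The intracellular network is treated
as being at quasi-steady state: at every instant the flux vector `v`
(mmol/(gDW h)) satisfies `S v = 0` and the flux bounds, and is selected by a
phase-specific linear objective solved as a linear program. The
extracellular medium evolves by ordinary differential equations driven by
the exchange fluxes:

    dC_m/dt = v_m(C) * DW,      dDW/dt = mu(C) * DW,

where `DW` is the biomass dry weight (g/L) and `mu` the biomass flux at the
LP optimum. This is the direct-coupling formulation of dynamic flux balance
analysis (dFBA): the LP is embedded in the ODE right-hand side and solved at
every integration step, with the parsimonious FBA (pFBA) refinement — fix
the optimal objective value, then minimize the total absolute flux — making
the reported flux vector unique and reproducible.

### Five phases, five objectives

Batch fermentations pass through lag, exponential growth, growth under
nitrogen limitation, stationary phase and decay; the boundaries
`T_L < T_E < T_S < T_D` are model parameters (estimated from data, like any
kinetic constant). Each phase has its own cellular objective:

| phase        | objective                                          |
|--------------|----------------------------------------------------|
| lag          | maximize ATPase expenditure (maintenance ATP)      |
| exponential  | maximize growth rate (biomass pseudoreaction)      |
| N-limited    | maximize growth with carbohydrate accumulation     |
| stationary   | maximize ATP *and* protein production              |
| decay        | maximize ATP *and* protein production              |

The two-term stationary/decay objective is scalarized as a weighted sum in
which each term is weighted by the reciprocal of its standalone optimum
under the current bounds, so neither term dominates by units. The weighting
is recomputed at every step by default (`normalize_each_step = TRUE`); the
estimation configuration computes it once per phase, which halves the LP
count of the long stationary phase and changes trajectories negligibly
(the standalone optima vary slowly within a phase). The integrator restarts
at every phase boundary because objectives and constraints switch
discontinuously; the state is continuous across boundaries, fluxes need not
be.

### Kinetic exchange constraints

Extracellular concentrations (all mM) constrain the exchange fluxes:

* hexoses (equalities): `v = -vmax C/(C + k) / (1 + E/K_Ei)` — saturating
  transport under noncompetitive ethanol inhibition, for glucose and
  fructose separately;
* ammonium (lower bound): Michaelis–Menten;
* amino acids (lower bounds): first order (mass action), one constant per
  amino acid;
* arginine (lower bound): first order during lag through nitrogen-limited
  growth, and exactly zero from the stationary phase onward — the species
  modelled cannot consume arginine to completion, and its consumption stops
  when growth stops;
* oxygen (equality): first order in dissolved O2, so oxygen matters only at
  the start of fermentation;
* products (equalities): `v_Pj = -X_A k_Pj (v_Glx + v_F)` — ethanol, higher
  alcohols, carboxylic acids and esters are formed in proportion to total
  hexose transport. `k_P` may be overridden per phase; a negative
  stationary-phase acetate coefficient models the acetate re-consumption
  observed at standard temperature. An uptake-direction product constraint
  is zeroed once its extracellular pool is exhausted, so the LP never
  imports mass that is not there. The activity coefficient `X_A` (in
  [0, 1], default 1) mirrors the multiplicative role this factor has in the
  constraint; it is phase-resolvable and estimable in the stationary and
  decay phases.

The distinction between equalities (hexoses, oxygen, products) and one-sided
lower bounds (nitrogen sources) is deliberate: nitrogen uptake is an offer
the cell may decline, product formation is a stoichiometric commitment.

### Dynamic biomass composition and the GAM decomposition

The biomass pseudoreaction details the millimoles of monomer precursors
needed to form 1 g of cells. Its protein content depends on yeast
assimilable nitrogen (YAN, mg N/L, counting ammonium and free amino-acid
nitrogen with arginine's four nitrogens):

    p(YAN) = p_min + (p_max - p_min) * YAN / (YAN + k_p).

The data constrain only the endpoints of this relationship (the
initial-must protein contents of 0.66 at 12 degrees C and 0.41 at
25 degrees C), not its shape; a two-parameter saturating curve with a floor
is the package's calibration choice — smooth, monotone, and exact at both
endpoints once `p_max` is solved from the initial YAN. mRNA is proportional
to protein (`rho = 0.05` g/g by default), DNA and lipid fractions are fixed
constants, and carbohydrates absorb all remaining mass, so the fractions
always close to 1. Under nitrogen limitation a second, carbohydrate-enriched
biomass pseudoreaction is used (carbohydrate raised by 20 mass points,
protein reduced correspondingly — the accumulation is qualitative in the
source data, so the magnitude is a package default).

Growth-associated maintenance decomposes as

    GAM = GAM_F + GAM_prot + GAM_RNA + GAM_carb + GAM_DNA,

where the polymerization terms are `fraction x unit cost` with shipped
literature unit costs (37.7, 10, 12.8, 10 mmol ATP per g of protein, RNA,
carbohydrate, DNA; overridable), and `GAM_F` is the fitted
non-polymerization component (turnover, leakage repair). GAM is implemented
as the ATP-hydrolysis stoichiometry inside the biomass pseudoreaction, the
consensus-model convention, in mmol ATP per gDW formed (the literature
habitually prints the unit as mmol ATP/(gDW h); the quantity multiplies a
per-hour biomass flux, which restores the printed dimension). The preset
`GAM_F` values (108.5 and 77.5 mmol ATP/gDW) are back-computed so the totals
reproduce the reported ~137 and ~99.8 at the respective protein contents.

## The bundled toy network

A hand-curated three-compartment network (~100 reactions) realizes the
pathways the analysis cares about at desk scale: lumped glycolysis, both
PPP branches plus the erythritol branch (`ery1`, `ery2`,
`EX_erythritol_e` — fixed ids so flux-ratio reports are reproducible),
fermentation to ethanol, acetate formation (NAD- and NADP-dependent
acetaldehyde dehydrogenases) and its AMP-producing activation to acetyl-CoA
serviced by adenylate kinase, the mevalonate route, oxidative TCA to
2-oxoglutarate, the cytosolic reductive branch to succinate, the
malate/2-oxoglutarate antiporter and oxaloacetate carrier, the GABA shunt,
Ehrlich routes with parallel NADH/NADPH reductions, the
ethanol–acetaldehyde mitochondrial shuttle, the glycerol branch, and
respiration while dissolved oxygen lasts.

Simplifications to know about:

* Elemental bookkeeping covers carbon and nitrogen only; water, protons and
  inorganic phosphate are free pools (adenylates are still conserved, so
  ATP costs are real).
* The amino-acid pool is collapsed to three generic species plus arginine;
  the 19-amino-acid interface is config-driven.
* Acetoin and malate export act as redox-neutral and NADH-consuming
  overflow valves. They matter: with ethanol and glycerol yields pinned to
  hexose uptake, glycolytic redox closes almost exactly, and the valves
  absorb the residual surplus or deficit that biomass synthesis creates.
  Real yeasts solve the same problem with the same excretions.
* Cofactor carriers are carbon-free; acyl groups carry only transferable
  carbons.

Every internal reaction is C/N-balanced (checked strictly at construction),
and the stoichiometric worked examples hold exactly: one mevalonate costs
three acetyl-CoA (hence three acetate) and two NADPH; the GABA shunt
produces one NADPH per succinate. The yield queries close all exchanges,
inject 1 mmol of substrate, let the caller declare which inorganic/cofactor
pools may be balanced externally, and read the tracked cofactor off a
regeneration pseudo-flux at the pFBA optimum — NAD(P)H is deliberately not
among the default sinks, because redox closure is what these questions
probe.

## Scenario presets: the study conditions

`scenario_preset()` fixes the two study conditions. Both share the initial
must (555 + 555 mM glucose/fructose, about 235 mg N/L YAN, 0.02 gDW/L
inoculum, 0.25 mM dissolved O2). The contrasts follow the temperature sign
pattern the model family is used to study: the cold preset has longer
phases (T_S at 260 vs 70 h, end of run 650 vs 300 h), roughly halved uptake
kinetics, higher `GAM_F` (108.5 vs 77.5), higher initial protein content
(0.66 vs 0.41), higher erythritol yield, lower succinate yield, and near-zero
stationary acetate uptake; the standard preset re-consumes acetate strongly
in the stationary phase. Product-yield coefficients are calibrated so the
stationary-phase ratios land on the reported per-hexose scale (succinate
0.94 vs 0.19, acetate uptake ~4.1 vs ~0.1, erythritol 0.25 vs 0.69 mmol per
100 mmol hexose), ethanol yields (1.80/1.78 per hexose) give a finished
wine of ~12% vol, and arginine constants leave the reported unconsumed
residual (~100 and 80 mg per 470-mL vessel). These calibrations are inputs
taken from printed observations, not quantities the package claims to
predict.

What the generator emulates: phased dynamics, saturating and inhibited
hexose uptake, first-order nitrogen depletion, the arginine gate,
hexose-proportional product formation, and multiplicative lognormal
measurement noise (mean-one multiplier with
`sigma = sqrt(log(1 + CV^2))` — concentrations stay positive and errors
scale with signal, as for chromatographic quantification). What it does not
emulate: temperature laws connecting the two presets (each temperature is a
separate parameterization, as in the underlying framework), replicate
bioreactor variability, measurement dropout, and the quantitative titres of
any particular experimental campaign. Passing tests therefore demonstrate
internal consistency and recoverability under the stated noise model, not
agreement with any wet-lab dataset.

## Numerics

**Linear programming.** The FBA core is a dense bounded-variable two-phase
primal simplex written for this package (no LP library is required at run
time). Pivot rules are deterministic — Dantzig pricing with smallest-index
tie-breaks and a Bland's-rule fallback after a stall threshold — so
identical inputs give bit-identical solutions; repeated pFBA solves agree
exactly, which the integrator and the flux-ratio tables rely on. Fixed
(pinned) columns and retired artificial columns are skipped during pricing
and updates, which matters because a third of the columns in a
kinetically-pinned fermentation LP are equalities. Optimality and
feasibility tolerances are 1e-9; steady-state conservation `max |S v|` is
checked at every accepted sample and stays below 1e-8.

**pFBA.** Stage two fixes the stage-one objective to a relative 1e-9 and
minimizes total absolute flux with directionally split variables. Ties in
stage one are thereby resolved to the route with fewer active reactions
(the classic two-route degeneracy case selects the shorter route exactly).

**Integration.** The default integrator is the variable-step,
variable-order Adams predictor–corrector (`deSolve::ode(method = "adams")`)
at `rtol = 1e-6`, `atol = 1e-9`, restarted at phase boundaries, sampling
25 points per phase plus the boundaries. Any state component crossing zero
is clamped at zero and its uptake shut off (event-free clamping). For
parameter estimation, where thousands of simulations are needed, a
fixed-step Heun (second-order Runge–Kutta) configuration with 10–12 steps
per phase and no in-step pFBA is used (`fit_sim_options()`); the exchange
fluxes that drive the dynamics are pinned by the kinetic equalities or
selected by the phase objective, so the cheap path tracks the adaptive one
closely. Halving the adaptive tolerances changes final states by well under
0.1% on the compressed self-convergence scenario.

**Estimation.** The objective is the mean-normalized least squares

    J(theta) = sum_j sum_i ((y_ji(theta) - y_ji^m) / q_j)^2,

with `q_j` the mean of variable j's observed readout (read as a
per-variable scalar; a full weighting matrix is not specified by the
framework). Predictions are matched to sampling times by monotone cubic
interpolation of the trajectory. Simulation failures return a large finite
penalty so the global search continues. The optimizer is a
scatter-search-style global method: Latin-hypercube diversification, a
reference set evolved by convex/reflective pair recombination, a coordinate
sweep of the incumbent across each parameter's box (this is what rescues
weakly-coupled parameters such as phase times from one-dimensional local
basins), and Nelder–Mead polish. It is seed-deterministic, never returns a
point worse than its best initial sample, and respects the box everywhere.
Phase-time ordering is enforced by rejection (a misordered trial point gets
the penalty value), which in practice confines proposals to the valid
simplex; a strict increment reparameterization was considered and rejected
as it complicates per-parameter bounds.

**Recovery experiments.** The parameter-recovery checks generate data and
fit with the same forward configuration (fixed-step, 12 steps per phase).
This is intentional: the experiment isolates the estimator. When data are
generated with the adaptive integrator instead, the integration mismatch
adds a systematic floor to J of the same order as the signal of
weakly-identified parameters; that configuration measures the combined
integrator-plus-estimator error, which is a different (and harsher)
question than the estimator contract. With the cold preset, 5%
multiplicative noise and a 600-evaluation budget, the glucose Vmax, the
ethanol yield coefficient and the stationary onset T_S are each recovered
within 15% of truth — T_S owes its identifiability largely to the arginine
gate, whose kink at T_S is visible in a measured variable.

## Flux-ratio analysis

For a phase window `[a, b]` (growth `[T_L, T_S]` — the lag is excluded;
stationary `[T_S, T_D]`; decay `[T_D, t_end]`), the accumulated flux ratio
of reaction i is

    S_i = 100 * Int_a^b v_i DW dt / Int_a^b (v_Glx + v_F) DW dt,

by trapezoidal quadrature on the accepted samples — millimoles of compound
per 100 millimoles of hexose consumed. The printed definition of the decay
ratio integrates the whole fermentation while its label says decay; the
package treats that as a typesetting slip and uses `[T_D, t_end]`, with
`whole_run = TRUE` reproducing the literal formula. Two denominator
orientations are provided because the conventions in circulation disagree:
`"production"` (default, consumption magnitude as denominator — produced
compounds positive, uptakes negative, matching how production ratios are
reported) and `"consumption"` (the signed hexose integral as printed — the
hexose exchanges then sum to exactly +100). Fold comparisons between
conditions use `log2` of the magnitudes; pairs whose ratios have opposite
signs are flagged as direction reversals and excluded from fold rankings.
Differential selection uses the magnitude cut (max of the two ratios above
0.1, applied to absolute values) and the fold cut (|log2| above 1).

## Problem sizes and defaults used by the shipped checks

The test-suite and acceptance computations run the two presets with the
fixed-step configuration (10 steps per phase, full pFBA flux pass at every
sample), the compressed scenario for adaptive self-convergence, and a
600-evaluation recovery fit — sizes chosen so the whole battery is a
desk-scale computation. The full Yeast8 reconstruction can be plugged in
through the SBML reader (Level 3 with the fbc package; reactions lacking
fbc bounds are reported by id, malformed files are reported by element),
but no genome-scale inputs ship with the package and no genome-scale
numbers are asserted anywhere.

## Known limitations

* The toy network's succinate can be made through the reductive TCA branch
  when NADH disposal is tight; the GABA-shunt dominance seen in
  genome-scale reconstructions is guaranteed here only in the closed yield
  queries, not along every simulated trajectory.
* Esters and several minor products of real fermentations are absent from
  the toy product list; the product interface is config-driven.
* Fitting each temperature is independent; no Arrhenius-type coupling.
* Identifiability is not analysed; the recovery checks cover three
  deliberately chosen parameters with distinct dynamical signatures.
* The LP solver is dense and intended for curated/toy networks (up to a
  few hundred reactions); a genome-scale model will solve, but slowly.
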