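---
title: "Stress-coupled metabolism-and-expression modeling with mestress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-coupled metabolism-and-expression modeling with mestress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mestress)
```

## The model

Classical flux balance analysis treats enzymes as free. A
metabolism-and-expression (ME) model does not: every catalyzed flux `v`
demands synthesis of its catalyst at rate

    v_synthesis = (mu / keff) * v

where `mu` is the specific growth rate (1/h) and `keff` the enzyme's
effective turnover rate, stored in 1/s as conventionally printed and
converted to 1/h internally. The demand is enforced as a lower bound on
synthesis: each protein species has a free excess sink, so the cell may
overexpress but never undersupply. Because enzyme needs grow like
`mu * v` while flux itself scales with `mu`, protein demand grows roughly
quadratically in `mu` against a proteome budget that grows linearly — that
tension, not a substrate bound alone, is what caps growth.

Two constraints close the system. First, the usual steady-state mass
balance over every metabolite, including all macromolecule species. Second,
a proteome budget: total modeled protein synthesis mass equals
`(1 - unmodeled_protein_fraction) * mu * total_proteome_mass`, with an
unmodeled-protein sink carrying exactly the remaining fraction. The default
unmodeled fraction is 0.10, so the modeled proteome carries 90% of total
proteome mass by construction — `proteome_mass_fractions()` reports this as
`modeled_protein_fraction`, and its sitting at 0.90 is the structural
identity the test suite asserts. The budget is an equality rather than an
upper bound; together with the excess sinks this reproduces the
alternative-optima behavior of genome-scale ME models, where the proteome
is always exactly filled but its allocation may be degenerate.

Since `mu` multiplies constraint coefficients, the problem is nonlinear in
`mu` but linear once `mu` is fixed. `maximize_growth()` therefore bisects on
`mu`: assemble the LP at a trial growth rate, test feasibility, and narrow
the bracket. Feasibility is monotone in `mu` on these models (asserted by a
grid-scan oracle in the tests), which is what makes bisection exact up to
its tolerance.

## Stress mechanisms

**Thermal.** Protein stability follows a Gibbs-Helmholtz
parameterization: `delta_g_unfold()` is zero at the melting temperature
`tm_k` and controlled by the melting enthalpy `dHm_kj_mol` and heat
capacity change `cp_kj_mol_k`; `unfolding_keq()` converts it to the
Native = Unfolded equilibrium constant. Proteins routed through the folding
network are translated as unfolded chains, and a partition row caps
productive folding at the equilibrium folded share `1/(1+Keq)` of
translation — destabilized proteins must be overtranslated. Three routes
compete for the folding flux: spontaneous folding, whose cost is the
unfolded pool `mu/kf(T)` it must hold (the pool requirement is charged
against the folded share, so slow folders cannot free-ride on the doomed
unfolded surplus); DnaK-assisted folding; and GroEL/ES-mediated folding,
each coupled to chaperone synthesis with an ATP cost per folding event.
Pathway rates are effective clients-per-chaperone-hour couplings, not
single-molecule turnover numbers: spontaneous folding slows with
temperature (negative activation slope) and aggregation propensity, while
the chaperone routes gain agg-weighted boosts, DnaK linear and GroEL
quadratic, so highly aggregation-prone clients migrate to GroEL. Misfolded
protein can also be degraded by the ATP-dependent Lon protease with full
amino-acid recycling. Metabolic keffs themselves carry a mild Arrhenius
temperature dependence (default activation energy 25 kJ/mol), which
penalizes cold temperatures; the folding burden penalizes hot ones, and the
growth-temperature curve is unimodal in between.

**Acid.** Acid stress acts through exactly three channels. Periplasmic
protein unfolding free energy drops by `slope_kj_per_ph` (default 6
kJ/mol per pH unit below 7); the periplasmic chaperone HdeB offers an
alternative folding route gated below `hdeb_gate_ph` (default 6.0, a
declared choice — the mechanism is qualitative and no sharper number is
established); membrane lipid synthesis interpolates between a neutral and
an acidic fatty-acid composition with fixed total mass; and membrane-located
enzymes have their keffs scaled by a tabulated activity factor that is 1 at
pH 7 and falls with acidity. Proton balance and cytoplasmic pH homeostasis
are deliberately out of scope. Because HdeB is periplasmic and the
cytoplasmic chaperones never serve periplasmic clients, the acid response
competes with the rest of the proteome only through the shared global
budget.

**Oxidative.** The ROS environment is a basal state (superoxide 0.02 nM,
hydrogen peroxide 50 nM) scaled by a common multiplier; the superoxide
basal value follows the validation range of the single-stress literature,
and the peroxide basal with its influx conversion (1e-4 mmol/gDW/h per nM)
is a fixture choice. Damage is first-order in ROS and in enzyme amount,
folded into the LP as a forced consumption of native catalyst per unit
flux, which keeps the problem linear at fixed `mu`. Fe-S clusters oxidize
to a damaged species releasing Fe(II) (two irons out per event, one back on
repair — clusters degrade); YtfE re-inserts iron at an ATP cost through a
deliberately scarce capacity coupling, so heavy damage forces a choice
between repair, resynthesis, or rerouting. Fe(II) enzymes can also be
demetallated, re-metallated (again through YtfE), or replaced outright by a
mismetallated variant with a keff penalty that is immune to further damage.
Free Fe(II) reacts with peroxide (Fenton) into a lumped DNA-damage cost;
AhpC reduces peroxide at an NADH cost, and Dps sequesters surplus iron
through an ordinary capacity coupling.

## The kinetome layer

Keff vectors are named per-reaction tables in 1/s. The packaged toy ships
two: `wild_type` and `heat_evolved`, differing at the essential
terpenoid-precursor bottleneck (0.01 vs 88.72 1/s — an 8872-fold demand
ratio per unit flux), at a redundant recycling step (0.01 vs 28.8), at a
permanently blocked reaction, and by small jitter on four central enzymes.
`sensitivity_screen()` swaps one differing keff at a time, re-maximizes
growth, restores, and ranks by |delta| (ties broken by reaction id);
`consolidate()` builds a relabeled vector from overrides with provenance;
`redundancy_probe()` sweeps one keff and reports growth against the
catalyst's mass fraction, separating growth-critical bottlenecks (growth
tracks keff) from redundant steps (growth flat, catalyst cost swinging
orders of magnitude because a forced byproduct flux must pass through
regardless).

## What the toy model emulates — and what it does not

`build_toy_model()` emits a ~60-metabolite, ~120-reaction, 22-protein
network: periplasmic glucose uptake, lumped glycolysis/TCA, a high-yield
Fe-S NADH dehydrogenase against a lower-yield Fe-S-free alternative, an
acetate overflow branch whose kinase step has two interchangeable
catalysts, four supplementable amino-acid pools, the
terpenoid/homocysteine bottlenecks above, pH-dependent lipid synthesis, the
full folding network, and the ROS cycle. Glucose uptake is capped at 6
mmol/gDW/h so that carbon and proteome bind together at the optimum,
producing a mixed respiro-fermentative vertex — acetate overflow with
simultaneous respiration — rather than an all-or-nothing route choice.
Melting temperatures of the folding clients sit between 312 and 322 K so
the thermal window of interest (26-46 °C) spans from negligible to
overwhelming folding burden; the least stable protein is the terpenoid
bottleneck enzyme, which is why the kinetome difference shifts the whole
temperature optimum.

The generator is deterministic in its seed, and randomness touches only
non-critical parameters (the heat-evolved jitter, optional extra enzymes).
It does not emulate: transcription or ribosome machinery (translation is
one lumped reaction per protein), complex assembly stoichiometry, chaperone
folding of the chaperones themselves, regulator logic (OxyR/SoxRS appear
only as registry entries), proton bioenergetics, or any numeric phenotype
of a genome-scale reconstruction. Passing tests therefore demonstrate the
mechanisms and their interactions qualitatively — monotonicities,
unimodality, route switches, conservation identities — not quantitative
agreement with measured growth curves.

## Numerical choices

The LP core (`solve_lp`) is a dense two-phase revised simplex with explicit
variable bounds, written for the small, highly degenerate LPs this package
produces. Choices that matter:

* geometric-mean equilibration of the matrix, since coefficients span
  `mu/keff` terms (~1e-5) to per-protein residue counts (~5e3);
* a Harris-style two-pass ratio test (relaxation 1e-10, with a looser
  1e-7 tier for noise-level movements) so tiny pivots neither enter the
  basis nor silently block progress;
* periodic refactorization with self-repair — a numerically singular basis
  is rebuilt from its independent columns plus artificial columns;
* phase 2 keeps artificial variables under a big-M cost instead of pinning
  them to zero, so a borderline-feasible LP parks its residual there
  instead of pushing structural variables out of bounds;
* Dantzig pricing with an automatic switch to Bland's rule, plus a
  verify-and-retry pass: if the returned point violates bounds beyond
  1e-6, the whole solve is repeated under Bland pivoting.

Bisection uses a bracket of [0, 3]/h and a default tolerance of 1e-6/h.
The reported flux vector is the final feasible LP re-solved with a
waste-minimizing objective (sink fluxes), which selects a need-based
proteome among the degenerate optima; at the growth optimum the budget is
tight, so the choice of reporting objective has vanishing influence there.
FVA fixes growth `10*tol` below the requested fraction of the optimum
because the optimum itself is only known to the bisection tolerance;
unfolding equilibrium constants are capped at 1e6 to keep partition rows
well scaled; and `mu = 0` is handled by pinning the biomass flux to zero,
so the all-zero flux vector decides feasibility. Tests that only assert
qualitative shapes run the bisection at 1e-4/h to keep the default suite
fast; identities and oracle comparisons run at 1e-5 to 1e-6. Problem sizes
follow the same logic: the oracle models have at most 8 reactions so that
exhaustive vertex enumeration and grid scans stay exact, and the
property grids use 2 °C temperature steps over 26-46 °C.

## Design choices where the design was open

* The enzyme-coupling is enforced as "synthesis at least `mu*v/keff`"
  (species balance plus excess sink) rather than strict equality; combined
  with the exact proteome budget this is what lets interchangeable
  catalysts produce clean alternative optima.
* The folding partition is a hard equilibrium split (folded share
  `1/(1+Keq)`) rather than reversible mass action, keeping the LP linear
  at fixed `mu` and temperature.
* Chaperone/client pathway competition is resolved by the LP through
  per-pathway effective rates, not by kinetic ODEs.
* No tie-breaking is imposed among alternative catalysts; the solver's
  deterministic vertex is accepted and tests assert phenotype invariance,
  not catalyst identity.
* Acid destabilization is a single linear free-energy shift per pH unit;
  per-protein pH curves are out of scope.
* Chaperone stoichiometry and ATP costs per folding event (5 for DnaK, 14
  for GroEL) are fixture placeholders exposed in the folding parameter
  block.

## Worked example

```{r example, eval = FALSE}
model <- build_toy_model(seed = 7)
baseline <- maximize_growth(model, stress_condition(37, 7, 1))
baseline
report <- proteome_mass_fractions(model, baseline)
report$modeled_protein_fraction

## which keff difference separates the strains?
screen <- sensitivity_screen(model, model$keff_vectors$wild_type,
                             model$keff_vectors$heat_evolved,
                             stress_condition(), tol = 1e-5)
head(screen, 3)

## alternative optima at 95-100% of maximal growth
fva(model, stress_condition(), targets = c("EX_ac", "EX_glc"),
    solution = baseline)

## a stress grid with CSV reports
condition_grid(model, temps_c = c(37, 42), phs = c(7, 5), ros_mults = 1,
               out_dir = "grid_out")
```

## Known limitations

The simplex is dense and intended for desk-scale models (hundreds of rows);
genome-scale ME matrices need sparse factorizations and extended precision.
The proteome-budget equality makes sub-optimal allocations non-unique, so
per-protein mass fractions away from the growth optimum should be read as
one optimal allocation among several. Temperature, pH and ROS enter only
through the mechanisms listed above; there is no regulation, no kinetics,
and no explicit maintenance energy beyond the growth-associated ATP cost.
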