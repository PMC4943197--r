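---
title: "Models of selection on protein expression levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of selection on protein expression levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprsel)
```

`exprsel` asks a narrow quantitative question: if a mutation moves one
protein's expression away from its fitness optimum, how large is the
selection coefficient `s`? The package answers it in four model families
of increasing realism, which agree on a simple scaling: 2-fold changes
cost on the order of the protein's proteome fraction (`s ≳ 0.2·P`), while
small changes cost quadratically less (`s ~ ε²·P`). This vignette
explains each model, its assumptions, the tunable parameters, the
numerical machinery, and what the package's tests do and do not
establish.

## Conventions

`P` is the focal protein's share of total protein mass (dimensionless, in
`[0, 1)`). Total protein is treated as fixed: when `P` changes, every
other protein is rescaled by a common factor `(1 − P_new)/(1 − P_old)`,
ribosomes included. This proportional-compensation convention is what
makes `P` the natural variable — it also means the models say nothing
about proteins in tightly bound heteromeric complexes, where the
co-expressed partners do *not* co-vary and the linear cost
`|s| ≈ |ΔP|` of `reference_costs()` is the better model. `s ≥ 0` always
denotes a fitness reduction; the perturbation is parameterized either by
the multiplicative factor `x = P/P_opt` (so gene loss is `x = 0`) or by
the relative change `ε = x − 1`.

## The cost-benefit form

`net_benefit(P, f, K)` is `f·P/(K+P) − P`: a Michaelis–Menten-like
benefit saturating at `f`, minus a linear cost equal to the expression
level itself. Its pedigree matters: for a linear pathway of reversible,
unsaturated enzymes with proportional compensation, the exact steady-state
flux is `metabolic_flux(P, K) = P/(K + P/(1−P))`, and expanding in small
`K` shows the two coincide at `f = 1` — `compare_forms()` exposes the
fractional differences of the optima in closed form (`K` exactly for
`P_opt`, `2K − K²` for `s_opt`, both relative to the metabolic values, so
~1–2% at `K = 0.01`). The linear cost is the empirically supported
choice: gratuitous overexpression experiments in fast-growing microbes
find growth-rate reductions of roughly 1–2 times the useless protein's
proteome share.

Parameters and their ranges:

* `f` (maximum benefit, dimensionless fitness fraction): 1 for an
  essential protein, down to ~10⁻⁵ for the subtlest benefit a large
  population can maintain against mutational degradation.
* `K` (expression at half-max benefit): bounded below by one protein copy
  per cell, ~2·10⁻⁷ for a bacterium; `K < f` is required for the protein
  to be worth expressing at all.

The closed-form optimum (`cb_optimum()`) is `P_opt = √(Kf) − K` with full
loss `s_opt = (√f − √K)²`; `selection_exact()` evaluates the exact loss
at any factor and `selection_quadratic()` the small-change approximation
`ε²·P_opt/(1+ε)`. The approximation tracks the exact loss to within
2-fold for 2-fold-and-smaller changes whenever `f > 10·K`; it
deliberately is *not* trusted as `ε → −1`, where its `1/(1+ε)` divergence
outruns the exact loss (which saturates at `s_opt`) — the property tests
encode exactly that envelope.

`fk_grid()` generates the log-spaced parameter grids used for sweeps,
filtered to optima in `[5·10⁻⁶, 0.03]` — the realistic expression range
of fitness-relevant microbial proteins. The grid density (10 points per
decade by default) is the package's own choice; correlation summaries
from `sweep_correlations()` depend mildly on it, which is why the tests
assert the *comparison* (selection correlates more strongly with `P_opt`
than with the net benefit) across several densities rather than a
particular correlation value.

## The two-step Michaelis–Menten pathway

The cost-benefit derivation assumes enzymes are far from saturation.
`mm_params()` / `mm_optimize()` drop that assumption: a pathway
S ↔ I ↔ E with reversible saturable kinetics

```
v = (S − I/Keq) · (V/Kf) / (1 + S/Kf + I/Kr)
```

with `S = 2` mM, `E = 1` mM, `Keq = 10` per step, all Michaelis constants
equal to `Km`, focal enzyme activity `V1 = 100·P` (100-fold more active
per unit mass than the second enzyme, keeping its optimal share moderate)
and `V2 = 1 − P` carrying the compensation. The steady-state intermediate
solves `flux₁(I) = flux₂(I)`; the imbalance is strictly decreasing in `I`
on the thermodynamically admissible bracket `(E/Keq₂, S·Keq₁)`, so the
root is unique and found by safeguarded bracketing (`stats::uniroot`,
absolute tolerance 10⁻¹² mM).

Expression is optimized on the fixed grid 5·10⁻⁴ to 0.5 in steps of
5·10⁻⁴ and reported at grid resolution (one decimal as a percent), which
is how the headline optima 9.4% (no intermediate cost) and 8.8% (with it)
arise. For *small* perturbations the grid is too coarse — the step is
~0.3% of the optimum, the same order as a 1% perturbation — so
`mm_optimize(refine = TRUE)` adds a Brent refinement between the grid
neighbours and `mm_perturb()` then measures costs from the refined
optimum. Two-fold costs are insensitive to this choice; 1% costs are
meaningless without it.

Expensive intermediates are modelled as dilution: flux is divided by
`1 + I·c`. The coefficient `c = 1/(mw_ratio · 4 mM)` follows from an
intermediate `mw_ratio` times lighter than an enzyme in a cytoplasm with
4 mM protein monomers (`mm_dilution_cost()`); `mw_ratio = 100` is a
typical metabolite, 10 an extreme one. Because the dilution divides both
step fluxes equally, it leaves the steady-state `I` unchanged and only
rescales the objective — the optimizer, not the solver, feels it.

A `focal = "second"` variant puts the focal protein on the second step;
it needs a grid extending close to 1 because the slow enzyme optimally
takes most of the proteome. It is provided for completeness and tested
for sanity (non-negative costs), not tied to any quantitative target.

## The growth model

The pathway models treat growth as flux through a chain. The growth model
adds the two features a chain lacks: branches (20 amino acids demanded in
fixed proportions `f_i`) and proteins making proteins (a "ribosome" `R`
that is itself part of the proteome). Growth rate equals protein
synthesis rate,

```
g = R / Σᵢ fᵢ/Aᵢ ,
```

the ribosome concentration times the `f`-weighted harmonic mean of the
amino-acid pools `Aᵢ` (incorporation is first-order, so translation time
adds inverse concentrations). Each amino acid is made by one enzyme with
unsaturated reversible kinetics, precursor concentration 1 and
equilibrium constant 10, so at steady state
`g·fᵢ = Eᵢ·rᵢ·(1 − Aᵢ/10)` and every `Aᵢ` lies in `(0, 10)`.

**Steady-state solver.** Substituting `Aᵢ(g) = 10·(1 − g·fᵢ/(Eᵢrᵢ))`
reduces the 20 balance equations to one scalar fixed-point equation in
`g` with a strictly decreasing left-hand side, solved by bracketing on
`(0, g_max)` where `g_max = minᵢ Eᵢrᵢ/fᵢ` is the capacity bound of the
slowest enzyme. This replaces a 20-dimensional least-squares minimization
with an unconditionally convergent scalar search for the identical fixed
point; residuals in both model equations are below 10⁻¹⁰ relative.

**Allocation optimizer.** `growth_optimize()` maximizes `g` over the
ribosome share and the focal enzyme's share, with the 19 identical
non-focal enzymes constrained equal (the optimum inherits their
symmetry). The three-way proteome split is parameterized by an
unconstrained softmax, so every candidate is strictly feasible, and
searched by Nelder–Mead from four starts (relative tolerance 10⁻¹⁴, plus
a restart at the winner to rebuild the simplex at a finer scale). On the
fully symmetric instance (`fᵢ = 0.05`, `rᵢ = 5`) the optimizer reproduces
the closed form `R_opt = √2 − 1`, `g_opt = 10·R(1−R)/(1+R) ≈ 1.7157` to
better than 10⁻⁶.

**Random settings.** `sample_growth_params()` draws the focal usage
fraction as `f₁ = 2^{N₁}/Σ2^{Nᵢ}` over 20 standard normals and the focal
rate from the same distribution with an independent normal vector,
rescaled so the 20 rates average exactly 5 (enzymes typically 5-fold
faster per unit mass than the ribosome). The two draws are independent —
"the same distribution" is read as an independent replicate, not a
transform of the same normals. Across draws `f₁` has median ≈ 0.04 and
range ≈ 0.01–0.4. Determinism comes from R's Mersenne-Twister via an
explicit integer seed.

**Results and a caveat.** Over 100 settings the focal enzyme's optimal
share has median ≈ 0.026–0.03, halving it costs a median ≈ 21% of the
growth rate, and the half-max expression level `K_half`
(`growth_half_max()`, root-search on the downward branch) sits about
3-fold below `P_opt` — far steeper than the cost-benefit form's
`P_opt ≈ K`, and steeper than real haploinsufficiency data, so the model
brackets reality from the pessimistic side for downward changes. Doubling
costs fall between `P_opt/2` and `P_opt` in the large majority of
settings; a few settings with unusually large focal optima
(`E₁ ≈ 0.15–0.2`) overshoot the upper endpoint by a few percent, which is
expected — `P_opt` itself is the leading-order (log-linear) cost scale,
and its accuracy degrades as `P_opt` stops being small. Small changes
cost between 1× and ~5× the quadratic lower bound `ε²·P_opt` (typically
~3×), always far below the linear `|ε|·P_opt` curve.

## Metabolic control analysis

To argue the conclusions are not artifacts of the particular kinetic
models, `mca_flux()` takes the local log-linear view
`F ∝ Πᵢ Pᵢ^{Cᵢ}` with control coefficients `Cᵢ`. For a purely metabolic
network the summation theorem forces `ΣCᵢ = 1` (doubling every enzyme at
fixed metabolite levels doubles every flux — a linearity the tests check
directly on the pathway's rate law), the optimal allocation puts
`Pᵢ ∝ Cᵢ`, and perturbing one protein with proportional compensation
gives

```
s(ε) ≈ |−ε + ln(1+ε)| · P_opt
```

(`mca_selection()`; natural log, fixed by the small-`ε` limit
`s → ε²/2·P_opt`). The coefficients — 0.31·P_opt for doubling, 0.19·P_opt
for halving, 5·10⁻⁵·P_opt for 1% — are about half the cost-benefit
values and never exceed them. `useless_protein_cost()` is the `C_tot`
generalisation `1 − (1−f_U)^{C_tot}`: the cost of useless protein equals
its proteome share exactly when `C_tot = 1`. For `C_tot > 1` (proteins
acting on proteins) the cost of *upward* deviations scales with
`C_tot`; the analogous statement for downward deviations is not part of
the approximation, so `mca_selection()` applies the scaling to `ε > 0`
only and documents the caveat.

## Population-genetic interpretation

The bound matters because of arithmetic, not magnitude. `ne_s()` forms
`Ne·|s|`; with fitness-relevant proteins expressed above
`P ≈ 5·10⁻⁶` and the 2-fold cost `≥ 0.2–0.5·P`, any `Ne ≳ 10⁶` puts
2-fold changes — gene duplications included — under effective selection.
`gene_mutational_target()` bounds the mutational-robustness benefit of a
duplicate (≈ 2·10⁻⁷ per generation for a 1 kb gene), an order of
magnitude below the predicted cost. `maintenance_threshold()` raises the
drift threshold `1/Ne` by `ln(ratio)` ≈ 7 for the ~1000-fold asymmetry
between inactivating and restoring mutations, and
`deleterious_frequency()` is the `μ/s` mutation–selection balance.
`popgen_report()` assembles the worked arithmetic into one table. These
are deliberately back-of-envelope: no diffusion theory, no fixation
probabilities.

## Problem sizes and reproducibility

The package's own test suite and the acceptance script use: 10⁶-point
grids for brute-force verification of closed-form optima; the full
5·10⁻⁴-step grid (1000 points) for every pathway optimization; 100
random growth-model settings for the sweep medians (matching the study
design; the medians then carry sampling spread of roughly ±20–30%, which
is the tolerance applied to them) and 4–5 settings for per-setting
property checks; 1000 draws for distributional checks on `f₁`. All
stochastic results are reproducible from a single integer seed, and
every sweep function returns plain tibbles so the tables written by
`write_sweep_csv()` are byte-stable given seed and parameters.

## Known limitations

* Heteromeric complexes, toxic intermediates, and regulatory/signalling
  proteins fall outside the models' assumptions; for those the linear
  (or steeper) cost curves in `reference_costs()` are the relevant
  comparison.
* Redundant paralogs and parallel pathways relax selection (a 2-fold
  change in one of two equal paralogs is a 25% change in the pool,
  costing ~0.05·P_total); the package provides the quadratic machinery
  to do this arithmetic but no dedicated redundancy model.
* The growth model's optimal expression is unrealistically fragile
  downward (`P_opt ≈ 3·K_half`); real metabolism, with multi-step
  pathways per amino acid, should land between it and the cost-benefit
  form.
* Condition-dependence of `f`, expression noise, and mRNA-level costs
  are not modelled.
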