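---
title: "Ensemble epistasis: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble epistasis: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiensemble)
```

## The model

A macromolecule is treated as a discrete conformational ensemble. Each
conformation `c` has a free energy `G_c` (kcal/mol) and a Boltzmann weight
`exp(-G_c / RT)`. Conformations are partitioned into an *active* and an
*inactive* sub-ensemble, and the observable is

$$\Delta G_{obs} = \langle G_{active}\rangle - \langle G_{inactive}\rangle,
\qquad
\langle G \rangle = -RT \ln \sum_c e^{-G_c/RT}.$$

A mutation is a vector of per-conformation energetic effects
$\delta G_c$; a genotype's conformation energies are the baseline plus the
sum of its mutations' effects (plus optional within-conformation pair
couplings $\delta\delta G_c$). This *within-conformation additivity* is the
central modelling assumption: any nonadditivity of the observable that
remains with zero couplings is generated by the ensemble average alone.
Pairwise epistasis is the mutant-cycle double difference

$$\varepsilon = (\Delta G_{obs}^{AB} - \Delta G_{obs}^{aB})
             - (\Delta G_{obs}^{Ab} - \Delta G_{obs}^{ab}),$$

reported in kcal/mol with exactly this sign convention (no negation).
Because active-sub-ensemble terms are genotype-additive, they cancel from
the double difference, leaving the equivalent *reduced form*
$\varepsilon = -[(\langle G_Y^{AB}\rangle - \langle G_Y^{aB}\rangle) -
(\langle G_Y^{Ab}\rangle - \langle G_Y^{ab}\rangle)]$ over the inactive
sub-ensemble $Y$ only. `mutant_cycle()` computes both and verifies their
agreement at every call (tolerance `1e-8`, relative to the epsilon scale)
whenever no coupling touches an active conformation; with active-side
couplings the two legitimately differ and the full-cycle value is the one
reported.

Two consequences of the algebra are enforced as properties rather than
assumed: $\varepsilon = 0$ whenever the inactive sub-ensemble has a single
conformation, and whenever each mutation's effects are uniform across the
inactive conformations. Both hold to machine precision in the test-suite
over randomized ensembles of up to six conformations with effects drawn
uniformly from [-5, +5] kcal/mol.

Ligand linkage enters through stoichiometries: a conformation binding
$n_l$ copies of ligand $l$ at chemical potential $\mu_l$ (kcal/mol,
relative to a reference concentration) has
$G_c(\mu) = G_c^0 - \sum_l n_{c,l}\,\mu_l$. Converting $\mu$ to molar
concentrations would require reference-state binding constants and is out
of scope.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `gas_constant` | 1.9872e-3 | kcal/(mol K) | energies are kept in kcal/mol throughout; overridable for kJ conventions |
| `temperature` | 298 | K | room-temperature reference; RT = 0.592 kcal/mol |
| `cutoff` | 0.6 | kcal/mol | the scale of thermal fluctuations (~RT); below it a pair is called non-epistatic. It is an analysis choice, so every summary sweeps it (default 0 to 3 by 0.1, which includes 0.6 and 2.0) |
| `sign_tol` | 1e-6 | kcal/mol | minimum effect magnitude for a sign comparison; suppresses floating-point sign flips around zero |
| `G_apo`, `G_ca` | 0, 10 | kcal/mol | S100A4 model at zero potential: the closed apo form dominates until calcium is raised |
| `G_capep` | 30 | kcal/mol | only sets where the active state crosses over; it cancels from epsilon exactly, so the value is a free display choice |
| Ca2+ stoichiometry | 4 | — | four calcium ions bound by the `ca` and `capep` conformations; peptide stoichiometry 1 on `capep` |
| `mu_grid` | 0 to 5 by 0.1 | kcal/mol | spans the apo-to-capep switch of the default energies, covering the interesting operating points between ~2 and ~4 |

The temperature and gas constant ride along on the ensemble object, so a
single definition fixes the thermodynamic context of every downstream
computation.

## Classification

Supra-cutoff pairs are classified from the background dependence of each
mutation's effect *on the observable*: a mutation shows a sign change when
its effect is positive in one background and negative in the other (each
side exceeding `sign_tol`). Both changing sign is reciprocal-sign, exactly
one is sign, neither is magnitude epistasis; the classes are mutually
exclusive and exhaustive. Two genuinely open choices are surfaced as
arguments rather than hard-wired:

- *Which observable do effects refer to?* Effects are measured on the full
  $\Delta G_{obs}$ (including active-conformation contributions of the
  mutations), which is the scale an experimentalist's mutant cycle would
  measure. Since active terms are additive, they shift both backgrounds
  of a mutation equally and cannot *create* epistasis, but they can move
  effects across zero and hence the class boundary. This is the package's
  convention everywhere (cycles, titrations, scans, the DMS engine).
- *Must a sign-changing effect also be large?* By default a sign change
  only needs to exceed `sign_tol`. Setting `require_effect_cutoff = TRUE`
  additionally requires both background effects to exceed the epistasis
  cutoff — a stricter convention some analyses prefer. Both behaviours are
  tested.

Third-order epistasis is the change in the pairwise epsilon of (a, b) upon
introducing c — the standard three-way mutant-cycle double difference
(four times the third-order Walsh coefficient, up to sign convention). It
vanishes identically on additive and purely pairwise observable surfaces,
and for single-inactive-conformation ensembles.

## Titrations, scans, and the DMS engine

`titrate_epistasis()` rebuilds the full mutant cycle at every grid point;
`peak_epistasis()` maximises $|\varepsilon|$ (both signs are biologically
meaningful) and reports the signed value, breaking ties towards the lowest
potential. Type switches are counted between *consecutive supra-cutoff*
points: sub-cutoff stretches are skipped entirely, so an excursion below
the cutoff with the same class on both sides counts as zero switches.

The scans parameterise the analytic three-conformation model. The
identical-mutation scan fixes the j-side values (`G_j = 0`,
`dG_j = -0.96` kcal/mol, a mildly stabilising probe) and varies the
baseline gap `Gj - Gk` and differential effect `dGj - dGk`; the pair scan
starts from an equal-energy inactive baseline and splits each mutation's
differential symmetrically (`dGj = +x/2`, `dGk = -x/2`). With an
equal-energy baseline, epsilon depends only on the differentials, so the
symmetric split is a canonical representative; the worked scenarios at
differentials of ±0.7 kcal/mol correspond to per-conformation effects of
±0.35. Default grid extents are ±2 kcal/mol at 0.05 resolution —
comfortably past where epsilon saturates at this temperature.

`run_dms()` enumerates all unordered cross-site mutation pairs (same-site
double mutants are chemically impossible) in a deterministic order (site,
then mutant residue) and titrates every pair over the potential grid. The
engine is vectorised over pairs and works chunk-wise (default 200,000
pairs per block), so memory is bounded and chunked and whole-run execution
are bit-identical. Epsilon is computed on the reduced inactive-sub-ensemble
form; classification effects use the full observable. Coupling rows on
active conformations are dropped as inert — they provably cannot enter the
reduced epsilon — while inactive-side couplings add within-conformation
epistasis on top of the ensemble part. Per-pair curves are not retained
unless `keep_curves = TRUE`; the default records only peak, class at peak,
and switch count.

## The synthetic generator

`simulate_ddg_table()` emulates the statistical shape of per-conformation
stability predictions from structure-based calculations: a destabilising
skew (most mutations destabilise; a heavy destabilising tail; a minority
stabilise) and partial correlation of a mutation's effects across
conformations. Effects follow a one-factor model
`dG_c = location + scale * (sqrt(rho) * u + sqrt(1 - rho) * e_c)` with
standardised gamma deviates (shape 2 by default) for `u` and `e_c`, so the
marginal is identical for every conformation and the cross-conformation
correlation equals `rho` exactly. `rho = 1` gives identical effects on all
conformations and hence provably zero ensemble epistasis; lowering `rho`
monotonically dials in differential effects, which the tests verify
downstream of the full pipeline. Defaults (`location = +1.0`,
`scale = 1.5` kcal/mol, `rho = 0.5`) are deliberate but arbitrary: the
true effect distributions of any particular protein must come from data,
and every parameter is exposed.

What the generator does *not* emulate: structural correlations between
sites, residue-type-specific effect distributions, correlations between a
mutation's effect and its site's burial or secondary structure, or any
relationship between couplings and structural contacts
(`simulate_couplings()` draws couplings independently, Normal(9.3, 9.8)
kcal/mol by default, matching coupling statistics reported for S100A4
mutant pairs). Passing tests on synthetic tables therefore demonstrates
correctness of the *computation*, not that any real protein has a
particular epistasis fraction.

All generators take explicit integer seeds, restore the caller's RNG
state, and are bit-reproducible.

## Numerics

- All Boltzmann averages use a max-shifted log-sum-exp, finite for
  energies of arbitrary magnitude (tested at |G| = 1e4, where the naive
  form overflows) and agreeing with naive summation to 1e-10 on
  well-scaled inputs.
- At very low temperature the shifted form returns the minimum energy
  exactly once competing weights underflow, so the zero-temperature limit
  of epsilon is exact rather than approximate whenever one conformation is
  the global minimum across all four genotypes.
- Equality comparisons on epsilon use absolute tolerances (1e-9 for
  route-equivalence checks, 1e-12 for exact-zero conditions); peak-grid
  ties resolve to the first (lowest-potential) grid point.
- The classification boundary at `|epsilon| = cutoff` is closed
  (`>= cutoff` is epistatic), so sweep fractions at cutoff 0 are exactly 1.

## Problem sizes

The test-suite exercises the property checks at 10^4 randomized ensembles
each and the full pipeline at 1007 mutations (53 sites x 19 substitutions,
~497,000 cross-site pairs) over a 51-point potential grid, which completes
in well under a minute; the acceptance script runs the same full-scale
scan plus a coupled/uncoupled comparison on a 6-site subset. These sizes
were chosen to match the scale of a realistic single-protein scan while
keeping a complete run interactive.

## Limitations

- Free energies are temperature-independent inputs; no
  enthalpy/entropy decomposition, so temperature scans vary only RT.
- Chemical potentials are relative; mapping to concentrations needs
  binding constants the model does not carry.
- The engine assumes the supplied per-conformation effects are exact;
  uncertainty propagation from upstream structure-based calculations is
  not modelled.
- Within-conformation couplings are accepted as supplied; the package
  neither predicts them nor enforces consistency with any structure.
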