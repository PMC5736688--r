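---
title: "Structure-based modeling of VEGFR-adapter signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based modeling of VEGFR-adapter signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfrsim)
```

## The scientific problem

VEGF receptor 1 binds VEGF with very high affinity but phosphorylates
weakly, which earned it a reputation as a decoy that merely sequesters
ligand. Whether VEGFR1 nevertheless transduces a meaningful intracellular
signal — and through which adapter proteins — is a question that can be
attacked mechanistically: the two structural steps that couple receptor to
phenotype are (1) phosphorylation of specific carboxy-terminal tyrosines
and (2) SH2-domain adapter binding at those phospho-tyrosines, followed by
adapter phosphorylation. `vegfrsim` implements both a conventional model
in which this site structure is erased (one generic binding site per
receptor) and a structure-resolved model, so that the consequences of the
site architecture itself can be isolated by comparing the two.

## Reaction scheme and assumptions

Every network is generated from one scheme per receptor R and adapter A:
ligand binding lumped with activation (`VEGF + R <-> pR`), reversible
adapter binding to the phospho-receptor, irreversible adapter
phosphorylation at a shared rate `kp`, reversible engagement of a
generalized phosphatase PTPN by the phospho-adapter, and catalytic release
(`[pR:pA:PTPN] -> pR + [A:PTPN]`). The model assumes:

- *Lumped activation.* VEGF binding yields a phospho-receptor directly;
  dimerization is not an explicit reaction. All sites of a phospho-receptor
  are simultaneously competent.
- *Shared kinetics.* An adapter has one kon/koff pair used for both
  receptors and all of its sites, so phosphorylation differences between
  adapters arise from concentrations and site architecture, not bespoke
  per-site rates. `kp = 0.01/s` for every adapter for the same reason.
- *Phosphatase reservoir.* PTPN is held at constant concentration (an
  inexhaustible reservoir) and all adapters share its kinetics. Adapters do
  not auto-dephosphorylate.
- *Adapter recycling.* The scheme as written leaves `[A:PTPN]` terminal;
  adapter moiety conservation requires a return path, so the complex
  dissociates to free adapter and phosphatase at `koff_PTPN`. This is a
  package design choice.
- *Boundary ligand.* A bath dose (default 50 ng/mL VEGF-A164) vastly
  exceeds receptor numbers, so the ligand is constant by default; a
  depletion flag makes it consumable.
- *Units.* Everything runs in molecules/cell, converted from molar via a
  1 pL cell volume. The VEGF dose is converted with the ~38.2 kDa homodimer
  mass — VEGF engages its receptors as a dimer — stored as an overridable
  field.

## Steric co-occupancy

In the specific variant, multiple adapters may bind one receptor when
their combined size fits into the space between tyrosine sites. Adapters
bind in one dimension along the chain; an adapter's centre engages the
phospho-tyrosine, so its one-sided footprint is half its total
crystal-structure y-extent. The inter-site distance is the residue
separation times an average spacing of 0.171 Å per amino acid for VEGFR1
(e.g. Tyr1242–Tyr1333: 91 × 0.171 ≈ 15.6 Å). Feasibility is evaluated
*pairwise* — every pair of occupied sites must satisfy
`footprint_i + footprint_j < distance_ij` strictly, with ties infeasible
and at most one adapter per site. Pairwise checking is the weakest reading
of "combined size smaller than available space" that still reproduces a
two-adapter maximum on VEGFR1; a global packing model along the chain
would be strictly stronger and is not what the rule states. Enumeration
walks sites in residue order with exact pruning (pairwise feasibility is
monotone under adapter removal) and is verified in the tests against a
brute-force filter of all site-to-adapter assignments.

The specific network's species are phospho-receptor states: a feasible
occupancy plus, per bound adapter, one of three flags (bound,
phosphorylated, phosphorylated with PTPN engaged). Transitions exist only
between feasible states; an adapter cannot translocate between sites
without fully unbinding. Collapsing all sites to one shared exclusive site
makes the specific builder reproduce the nonspecific model exactly, which
serves as a cross-validation between the two independent builders.

## Numerical choices

Integration uses `deSolve::lsoda` with relative/absolute tolerances
1e-8/1e-10. The default horizon is 3600 s with 601 output points — the
order of magnitude of a phospho-ELISA observation window; both are
arguments, and halving the grid spacing moves integrated responses and
amplitudes by far less than 0.1%. Small negative excursions (all observed
below 1e-9 molecules) are zeroed after integration. Every simulation
verifies adapter and receptor moiety conservation over the whole grid to
relative error 1e-6 and aborts with an integrity error otherwise; in
practice drift is at machine precision. Phosphorylated-adapter counts
include PTPN-bound intermediates, which remain chemically phosphorylated
until the catalytic step fires; the post-catalysis `[A:PTPN]` complex does
not count.

## Responses, inhibitors, and validation metrics

Migration and proliferation are weighted sums of adapter phosphorylation
with calibrated nonnegative weights; degradation *is* the c-Cbl phospho
trace. Summaries are the trapezoid area under the response–time curve and
the peak amplitude; relative integrated responses are shares of the
three-response total, so the specific-vs-nonspecific migration gain is
quoted relative to proliferation and degradation.

Inhibitors block the target adapter's phosphorylation step while binding
is retained: Wortmannin, U73122 and Imatinib are activity inhibitors, and
keeping the silenced adapter on the receptor preserves site competition —
which is why inhibitor reductions for different adapters can sum beyond
100%. Depleting the adapter instead is available behind a flag. A treated
response is called model-significant when it falls strictly outside the
±10% band around the untreated integrated response (bounds inclusive).

Goodness of fit against measured phospho/total (p/t) time courses uses
`chi2 = sum(((obs - scale * pred)/sem)^2)` with `dof = n - 1` and a 0.05
significance level; measurement SEM is the natural scale because p/t data
are reported as mean ± SEM, and a Pearson variant (sqrt of expected in the
denominator) is available behind a flag. The molecules/cell-to-p/t scale
factor is not a published constant and is exposed as a parameter.
Background subtraction of inhibitor-matched p/t signal is upstream of the
package.

## Sensitivity analyses

Concentration sweeps run one simulation per point of a log-spaced grid on
10²–10⁵ molecules/cell, the physiological range for these adapters. Monte
Carlo uncertainty propagation perturbs each adapter's kon and koff by
independent log-uniform factors spanning one decade either way
(`10^U(-1, 1)`), a scheme chosen because binding kinetics are the least
certain inputs (often borrowed from homologous receptor systems); the
perturbation target (kinetics vs concentrations) and width are fully
configurable, and all outputs carry the spec used. Draws are seeded,
bitwise reproducible, and leave the caller's RNG state untouched. Routine
tests use 200 draws; the published analysis style uses 4000, which is the
package default only for the standalone `montecarlo` CLI runs where the
user sets `--draws`.

## The synthetic parameter sets and what they do (not) show

The original calibration tables (adapter complement, concentrations,
kinetics, weights, VEGFR2 spacing) live in supplementary material that is
not redistributable, so `reference_parameters()` ships a synthetic
stand-in, flagged `provenance = "synthetic"`. It encodes the published
structural facts exactly: the five VEGFR1 tyrosine sites and their
0.171 Å/aa spacing; kp and the cell volume; PLCγ and PI3K as the only
Tyr794 binders; adapter sizes chosen so that half-size sums fall between
the widest C-terminal gap (28.0 Å) and the Tyr794 gap (64.1 Å), making
"two adapters, one at Tyr794" the exact steric ceiling. Receptor surface
densities use quantitative flow cytometry scales (endothelial: low VEGFR1,
higher VEGFR2; macrophage: the reverse), adapter concentrations sit inside
the 10²–10⁵ molecules/cell sweep range, and SH2-domain kinetics use
micromolar-and-below dissociation constants. VEGFR2's Å/aa spacing is not
published in the main text and is treated as a required input (the
synthetic set reuses 0.171).

Because these quantities are plausible rather than calibrated, simulations
on the synthetic set demonstrate the machinery and the structural
mechanism, not the published magnitudes: with only the five main-text
adapters and uniform-scale kinetics, doubling VEGFR1's binding capacity in
the specific model lifts *every* adapter's phosphorylation, so the
published pattern in which only PLCγ and PI3K gain — and the specific
numeric predictions (16%/23% migration gains, 72%/64% inhibition
reductions, 2.4/2.6 receptor folds) — are not reproduced and are not
claimed. The corresponding checks in the test suite assert the published
values anyway and are expected to fail until externally calibrated tables
are supplied via `load_parameters()`. Everything independent of the
calibration (steric geometry, occupancy ceiling, conservation laws,
variant reduction equivalence, equilibrium isotherms, inhibitor algebra,
Monte Carlo reproducibility) is fully verified.

The randomized fixture generator (`generate_fixture_parameters()`) serves
the same role for tests: log-uniform adapter concentrations on 10²–10⁵
molecules/cell, dissociation constants on 1–1000 nM, and sizes adjusted so
at least one co-occupancy constraint is active. It emulates scale and
structure, not any particular cell line, and deliberately omits features
of real data such as correlated parameter uncertainties, receptor
trafficking, and adapter–adapter cooperativity.

## Problem sizes

The synthetic reference specific network has 187 species and 603
reactions (24 feasible VEGFR1 configurations, 7 for VEGFR2) and simulates
in a few seconds; test fixtures use one receptor, two sites and two
adapters (17 species) so that property checks, 200-draw Monte Carlo runs
and CLI round-trips complete in seconds. The acceptance script's fixture
blocks derive their seed from `--seed`.

## Known limitations

- No receptor trafficking or internalization; degradation is a readout
  (c-Cbl phosphorylation), not receptor removal.
- No adapter–adapter interactions and no phosphatase specificity; one
  generalized PTPN serves all adapters.
- Deterministic ODE dynamics only; stochasticity enters solely through
  Monte Carlo over parameters.
- The steric rule is pairwise and one-dimensional; no 3-D docking or PDB
  geometry is computed — adapter sizes are inputs.
- Weight calibration against wound-healing/MTT data is consumed as input,
  not fitted by the package.
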