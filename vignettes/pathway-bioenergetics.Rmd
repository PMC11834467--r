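---
title: "Bioenergetic trade-offs in CO2-fixation pathways: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioenergetic trade-offs in CO2-fixation pathways: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmdf)
```

## The model

A carbon-fixation pathway is a set of elementary reactions over metabolites
whose concentrations the cell can adjust. Writing $C_i$ for the molar
concentration of species $i$ and $K_j$ for the equilibrium constant of
reaction $j$ (with the ATP formed or consumed by substrate-level
phosphorylation already folded in, so ATP/ADP/Pi never appear as species),
thermodynamic feasibility of every step is the linear system

$$ S^\top \ln C + \frac{\mathrm{pmf}}{RT}\, n_p + F \le \ln K,
   \qquad n_{p,j} \in \mathbb{Z}, $$

where $n_{p,j}$ is the number of protons translocated across the membrane at
step $j$ (allowed only at steps catalyzed by membrane-bound machinery, in
either direction up to a cap), and $F_j = -\Delta G_j / RT \ge 0$ is the
step's dimensionless driving force. Clamped species — dissolved CO₂ and H₂ —
and fixed-activity species (water, protons at pH 7) are folded into the
constant term. Two conflicting objectives are optimized in sequence
(ε-constraint method):

1. maximize the chemiosmotic proton yield $\sum_j n_{p,j}$ subject to
   feasibility (all $F_j$ at a floor, zero by default, or a positive imposed
   driving force);
2. fix $\sum_j n_{p,j} = n_{p,\mathrm{opt}} - \varepsilon$ and maximize $B$,
   the smallest driving force of any step — the max–min driving force (MDF),
   reported as $B \cdot RT$ in kJ/mol.

$\varepsilon$ counts proton translocations traded away for driving force;
sweeping it maps the yield-versus-rate trade-off front. Rate enters through
the flux-force efficacy $\mathrm{FFE} = \tanh(\Delta G_\mathrm{diss}/2RT)$,
the fraction of enzyme capacity realized as net forward flux; the package
evaluates it in this `tanh` form, which is algebraically identical to the
exponential ratio $(e^{x}-1)/(e^{x}+1)$ and numerically stable far into
saturation.

A *variant* of a pathway fixes one electron carrier per redox step, adds the
carrier couple to the step's stoichiometry, and closes the balance with one
regeneration reaction per distinct carrier against the terminal donor
(EC$_\mathrm{ox}$ + H₂ → EC$_\mathrm{red}$). Carrier red/ox concentrations
are ordinary decision variables constrained to a ratio window; because the
regeneration reverses exactly what the redox steps consume, the net
transformation and the summed standard Gibbs energy of a variant never
depend on the carrier choice.

In the carrier-potential mode the named carriers are dropped: each redox
step exchanges electrons at a continuous dimensionless potential
$\Phi_j = -F E_j / RT$, which enters the constraint like a log-concentration
with coefficient equal to the electrons transferred, and a generic donor
half-reaction (H₂ → 2H⁺ + 2e⁻, reversed for oxidations) closes each electron
balance. After the two-stage optimum is found, the integer solution pool is
enumerated, $n_p$ and the MDF are fixed, and each $\Phi_j$ is maximized and
minimized as a plain LP; the union over the pool is the optimal potential
interval, convertible to volts and comparable with the Nernst windows of
known carriers.

## Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| temperature | 298.15 | K | the printed pairing 5.45 kJ/mol ↔ 80 % FFE solves $\tanh(\Delta G/2RT)=0.8$ only near 298 K |
| `dG_ATP` | 50 | kJ/mol | physiological ATP hydrolysis energy |
| `r_H_per_ATP` | 10/3 | H⁺/ATP | common ATP-synthase stoichiometry; sets pmf = 15 kJ/mol and the per-step CPT cap `floor(r)` = 3 |
| `conc_bounds` | 10⁻⁶–10⁻² | mol/L | osmotic/kinetic range for internal metabolites; clamped CO₂/H₂ are exempt |
| carrier ratio | 10⁻²–10² | — | admissible [EC_red]/[EC_ox] window |
| potential window | −0.6 to +0.4 | V | brackets all biological carriers |

All are arguments of `env_conditions()`; every reported ATP cost is
`(SLP consumed − Σn_p / r_H_per_ATP) / CO₂ fixed`.

## Encoded pathways

Twelve pathways ship as JSON fixtures: six natural (reverse TCA,
dicarboxylate/4-hydroxybutyrate, 3-hydroxypropionate/4-hydroxybutyrate,
3-hydroxypropionate bicycle, methanogenic and acetogenic Wood–Ljungdahl) and
six postulated glyoxylate-producing designs (via-pyruvate, via-citrate,
via-malonyl-CoA and CETCH cores, each closed by either the tartronate-
semialdehyde route to glycerate or the glyoxylate-shunt route to pyruvate).
Each fixture reproduces the published per-pathway aggregates exactly: number
of carrier variants, elementary reaction count, SLP ATP cost, the overall
equation (2 CO₂ + 4 H₂ + CoA → acetyl-CoA + 3 H₂O at −142.3 kJ/mol for the
acetyl-CoA pathways; 3 CO₂ + 5 H₂ → pyruvate + 4 H₂O + H⁺ at −113.6 kJ/mol
for the bicycle and the pyruvate-producing postulated routes) and the 75 %
carbon atom economy of the postulated designs.

Per-step standard Gibbs energies are not individually published, so the
fixtures carry standard-source estimates (pH 7, ionic strength 0.1 M)
reconciled in two stages: the flux-weighted sum is forced onto the printed
overall value exactly, and the residual of that reconciliation is spread
over designated redox steps chosen so that the fixtures also reproduce the
reported sweep behavior (the aerobic pathways reaching peak max–min driving
forces above 4 and 3 kJ/mol at zero traded translocations). These per-step
splits, and the siting of CPT-capable steps beyond the documented rTCA
sites, are transcription choices of this package, not published data —
conclusions that depend on an individual step's energy rather than on
pathway aggregates should not be read off the fixtures.

Three modeling conventions matter when interpreting them:

* all redox steps are two-electron, and ferredoxin is treated as a
  two-electron couple at −0.400 V; with hydrogen as the only electron donor
  this yields the characteristic [H₂] threshold below which Fd-obligate
  pathways (both Wood–Ljungdahl routes, the via-pyruvate/citrate cores) are
  infeasible — real organisms escape it with electron bifurcation, which is
  outside the model;
* for the same reason, steps that net-oxidize a substrate must hand their
  electrons to a low-potential carrier (NAD/NADP): a reduced quinone pool
  cannot be re-oxidized against H₂ in a model with no O₂ sink;
* pathways whose product requires two turns of a glyoxylate-producing core
  carry an integer per-reaction `flux` (2 for the core, 1 for assimilation);
  aggregates are flux-weighted while each reaction still contributes one
  unit driving-force constraint, and the stage-1 objective and ε-constraint
  act on the flux-weighted translocation total.

## Numerical implementation

The integer programs are solved exactly in-package: a dense two-phase
primal simplex (compiled, Dantzig pricing with a Bland's-rule fallback
against cycling; pivot tolerance 10⁻¹⁰, feasibility tolerance 10⁻⁹) under a
depth-first branch-and-bound on the translocation variables (integrality
tolerance 10⁻⁶, deterministic down-branch-first order). Equally optimal
integer solutions can be canonicalized (`canonical = TRUE`) by sequentially
minimizing the $n_p$ vector in reaction order at the fixed optimum; scans
skip this because the reported objective values are tie-invariant, and the
search order itself is deterministic, so repeated runs are bit-identical
either way. Near-zero MDF optima at translocation thresholds are reported
as-is, with no hidden floor; unreachable ε targets and thermodynamically
impossible conditions return status `"infeasible"` rather than an error.

The solution pool of the potential analysis is enumerated exhaustively over
the (small, bounded) integer lattice rather than by solver no-good cuts —
with at most a handful of CPT sites capped at ±3 this is exact and cheap.

Two independent verification routes back the optimizer: every LP is
cross-checked in the tests against `boot::simplex`, and a brute-force
oracle re-solves small instances (≤ 6 reactions, ≤ 4 variable metabolites,
≤ 2 CPT sites) by enumerating all integer assignments and minimizing the
convex worst-violation function over the concentration box by multiscale
grid refinement to about 10⁻³ in log-space, agreeing with the
branch-and-bound to 0.05 kJ/mol on 50 seeded instances.

## The synthetic generator

`synthetic_spec()`/`generate_pathway()` build chains (or simple cycles) of
carbon-neutral conversions with clamped endpoints, a prescribed total
standard dissipation (split equally or by a seeded symmetric Dirichlet),
and optional CPT sites, two-electron redox steps with configurable carrier
sets, and SLP steps. For equal-split chains with slack bounds the MDF has
the closed form

$$ \mathrm{MDF} = \frac{-\Delta G^0_\mathrm{tot}
   + RT\,(\ln C_\mathrm{sub} - \ln C_\mathrm{prod} + n_{H_2} \ln [H_2])
   - \mathrm{pmf}\,\Sigma n_p + \Delta G_\mathrm{ATP}\,
     n_\mathrm{ATP,consumed}}{n_\mathrm{reactions}} $$

(`analytic_mdf()`), which anchors the optimizer end to end. The
"slack bounds" proviso is strict: a carrier-bearing redox step adds a
regeneration constraint and ratio bounds that always bind, and a large
`dG_ATP` can shift an SLP step's equilibrium beyond the four-decade
concentration box; in those regimes the grid-refinement oracle, not the
closed form, is the reference. The generator emulates the *structure* real
pathways stress the optimizer with — thresholds, bottlenecks, carrier
coupling — but not branched topologies, shared cofactor pools across a
metabolome, enzyme kinetics or measurement noise; a green synthetic suite
therefore validates the optimization machinery, not the biological accuracy
of any fixture.

## Problem sizes used by the tests

The test and acceptance suites sweep log₁₀[H₂] over [−6, −1] at steps of
0.2–0.25 with CO₂ at 10 mM, enumerate all variants per point (up to 216 for
the dicarboxylate/4-hydroxybutyrate cycle), run 50 seeded oracle
comparisons and 30 seeded closed-form chains; these sizes were chosen to
exercise every threshold visible at the default parameters while keeping a
full run in the order of a minute on one CPU.

## Known limitations

* No activity-coefficient corrections and no temperature dependence of
  ΔG°′ (van 't Hoff); CO₂ speciation is reduced to dissolved CO₂ plus an
  explicit carbonic-anhydrase step where a pathway consumes bicarbonate.
* The H₂-donor convention makes high-potential carriers useless for
  net oxidations (no O₂ terminal sink is modeled).
* Per-step fixture energies are reconciled estimates (see above).
* The flux-force efficacy treats each step as a single saturable enzyme;
  no enzyme-cost weighting is attempted.
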