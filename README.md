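# pathmdf

Bioenergetic trade-off analysis of microbial CO₂-fixation pathways.

Autotrophic prokaryotes fix CO₂ through a handful of pathways (reverse TCA
cycle, the two Wood–Ljungdahl routes, the dicarboxylate/4-hydroxybutyrate
and hydroxypropionate cycles, plus several postulated synthetic designs).
Each pathway can run in many *variants* — one concrete electron-carrier
choice per redox step, closed by carrier regeneration against the terminal
donor (dissolved H₂) — and each variant faces the same trade-off: conserving
more energy as ATP leaves less Gibbs energy to drive the reactions, which
throttles the attainable rate. `pathmdf` quantifies that trade-off for
metabolic engineers and environmental microbiologists who want to know which
pathway configuration is optimal under given CO₂ and H₂ concentrations.

## The model

For a pathway variant with stoichiometric matrix **S** over metabolite
log-concentrations ln *C* (bounded to 10⁻⁶–10⁻² M), every reaction *j* must
satisfy the energy constraint

```
S'_j · ln C  +  (pmf/RT) · n_p,j  +  F_j  ≤  ln K_j ,      n_p,j ∈ ℤ
```

where *K_j* is the equilibrium constant with any substrate-level
phosphorylation (SLP) folded in, *n_p,j* is the number of protons a
membrane-bound (CPT-capable) step translocates (each worth the proton motive
force, pmf ≈ 15 kJ/mol), and *F_j* = −ΔG_j/RT ≥ 0 is the driving force. Two
objectives are solved in sequence (the ε-constraint method):

1. **maximize Σ n_p,j** — the chemiosmotic ATP yield (driving forces at a
   floor, zero by default);
2. with **Σ n_p,j = n_opt − ε** (ε translocations traded away), **maximize
   B = min_j F_j** — the max–min driving force (MDF).

The MDF maps to a flux-force efficacy FFE = tanh(ΔG/2RT), the fraction of
enzyme capacity realized as net forward flux; 5.45 kJ/mol ≙ 80 %. The net
ATP cost per CO₂ fixed is `(SLP consumed − Σn_p / r_H+/ATP) / CO₂ fixed`.

A second mode drops the named carriers entirely: each redox step exchanges
its electrons at a continuous dimensionless potential Φ = −FE/RT, and after
optimizing yield and MDF the admissible interval [E_min, E_max] of each
step's potential is extracted and compared with the Nernst windows of known
carriers (NAD, NADP, FAD, ferredoxin, quinone, F420).

The mixed-integer linear programs are solved exactly by an in-package
branch-and-bound over a dense two-phase simplex (compiled); an independent
exhaustive-enumeration oracle verifies the optimizer on small instances.

## Worked example

Optimize the reverse TCA cycle at 10 mM CO₂ and 10 mM H₂, picking the best
of its 54 carrier variants:

```r
library(pathmdf)
env <- env_conditions(conc_CO2 = 1e-2, conc_H2 = 1e-2)
best <- best_variant(pathway_fixture("rtca"), env)
best$result
#> <pmdf_result> status: optimal
#>   total CPT 9, MDF 2.8954 kJ/mol, ATP cost -0.3500 /CO2 (-0.7000 /product)
```

Nine protons are pumped per acetyl-CoA (the three CPT sites — the OAA,
fumarate and oxalosuccinate reductions — each saturate at the cap of 3), so
after paying its 2 SLP ATP the pathway *nets* 0.35 ATP per CO₂ fixed, while
every step still dissipates at least 2.90 kJ/mol. Trading one translocation
(`epsilon = 1`) raises the MDF to 3.02 kJ/mol at a cost of −0.20 ATP/CO₂.

The carrier-free potential analysis for the fumarate reduction at the same
conditions:

```r
sys  <- build_potential_system(pathway_fixture("rtca"), env)
pool <- enumerate_optimal_pool(sys)
rng  <- phi_range(sys, pool, "fum_red")
#> E in [-0.340, -0.325] V
match_known_carriers(rng, pathway_fixture("rtca")$carriers)
#> NAD  compatible at [NADH]/[NAD] 1.46–4.68; NADP at 0.014–0.044;
#> FAD, quinone, Fd incompatible
```

Sweeps (`tradeoff_sweep()`), cost grids (`atp_cost_grid()`) and the scan of
optimal carrier potentials against the donor concentration
(`carrier_range_scan()`) build the full trade-off pictures; all twelve
encoded pathways are listed by `list_pathway_fixtures()`. A thin CLI wrapper
is included at `inst/scripts/pathmdf-cli.R`.

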