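# kinstab

Quantitative analysis and design of **protein kinetic stability** — the
height of the free-energy barrier that separates a folded protein from its
unfolding transition state, which sets how long the native state lives.

The package is aimed at protein engineers and folding biophysicists who
want to (i) score a structure's topological complexity, (ii) predict how
fast it will unfold at the denaturation midpoint, (iii) simulate its
unfolding barrier with a coarse-grained structure-based model, and (iv)
fit the equilibrium and kinetic denaturation experiments that validate a
design. The workflow it implements is the one used to engineer
kinetically stabilized β-trefoil variants by swapping conserved
hydrophobic core residues between a weakly stable natural protein and a
hyper-stable designed homolog.

## What it computes

**Contact maps.** Heavy-atom contacts below a strict 6 Å cutoff (residue
pairs with |i−j| > 1), projected to residue pairs, either as a plain
cutoff map or as a *shadow map* in which a candidate contact is discarded
when a third atom (occlusion radius 1 Å) blocks the line of sight between
the two atoms.

**Topology metrics.** Absolute contact order and long-range order,

```
ACO = (1/Nc) Σ |i − j|          (atom contacts, |i − j| > 1)
LRO = (1/L) Σ n(i, j),  n = 1 when |i − j| ≥ 12
```

**Rate prediction.** Empirical log-linear correlations for two-state
β-sheet proteins at the transition midpoint:

```
log10(ku / s⁻¹) = −1.70·LRO + 6.6
log10(ku / s⁻¹) = −0.52·ACO + 5.9
```

with fold-change and half-life (ln 2 / ku) helpers.

**Cα structure-based (Gō-type) folding model.** One bead per residue,
harmonic bonds/angles, 1+3 cosine dihedrals, 10–12 Lennard-Jones native
contacts of depth ε, r⁻¹² excluded volume; BAOAB Langevin dynamics
(compiled, bitwise reproducible per seed); folding-temperature search by
bisection on the two-state populations; F(Q) = −ln P(Q) free-energy
profiles with single-histogram Boltzmann reweighting to equal basin
depths; unfolding barrier heights in k_B·T_f; average contact maps near
the transition-state ensemble (Q ≈ 0.4).

**Denaturation fits.** Single-exponential kinetic traces (optional linear
drift), two-state chevron fits
`ln k_obs = ln[kf·e^(mf·x/RT) + ku·e^(mu·x/RT)]`, the two-state linear
extrapolation model for equilibrium curves, and the derived quantities
m_eq = mu − mf, β_T = |mf|/m_eq, ΔG = −RT·ln(ku/kf), C_mid = ΔG/m_eq,
ku(C_mid), and the midpoint unfolding half-life (T = 300.15 K,
R = 1.987×10⁻³ kcal K⁻¹ mol⁻¹).

**Core-swap design.** Per-residue long-range contact accounting (a
contact between two core residues counts 0.5 per residue), contact
deficits between homologs at structurally aligned positions, core-swap
sequence proposals, and model screening by LRO/ACO interquartile-range
outlier removal.

All of this is testable offline: deterministic generators build toy bead
folds, homolog pairs with a controlled long-range contact surplus,
synthetic kinetic traces and chevrons, and two-state Q/energy series with
a known generating barrier.

## Worked example

Predicted unfolding at the midpoint from published topology scores, and
the derived stability of wild-type hisactophilin from its chevron
parameters:

```r
library(kinstab)

predict_rates(lro = 4.1, aco = 12.2)
#>   source_metric metric_value   ku_cmid half_life_min
#> 1           LRO          4.1 0.4265795    0.02708159
#> 2           ACO         12.2 0.3597493    0.03211251

wt <- derive_stability(chevron_parameters(
  kf_h2o = 26.0, ku_h2o = 4.0e-4, mf = -5.46, mu = 1.29))
wt
#> derived_stability (T = 300.15 K):
#>   m_eq 6.750 kcal/mol/M   beta_T 0.809
#>   dG 6.609 kcal/mol   C_mid 0.979 M
#>   ku(C_mid) 3.326e-03 s^-1   half-life 3.47 min
```

The LRO prediction (0.43 s⁻¹) and ACO prediction (0.36 s⁻¹) are the
midpoint unfolding rate constants implied by this protein's long-range
order and absolute contact order; the derived block turns the measured
folding/unfolding rate constants and their denaturant dependences into
the equilibrium stability (6.61 kcal/mol), the transition midpoint
(0.98 M GuHCl), the β-Tanford value (0.81: a native-like transition
state), and a ~3.5-minute unfolding half-life at the midpoint.

A desk-scale folding simulation on the built-in toy fold:

```r
s    <- toy_fold(20, seed = 3)
m    <- cutoff_residue_map(atom_contacts(s, cutoff = 7.0, min_sep = 4),
                           s$length)
topo <- build_sbm(s, m)
tf   <- find_tf(topo, t_bracket = c(0.9, 1.4), n_steps = 2e6, seed = 41)
traj <- run_dynamics(topo, sbm_params(tf$tf, n_steps = 5e6,
                                      save_every = 500, seed = 101))
prof <- reweight_equal_basins(traj, bins = "levels")
barrier_height(prof)   # unfolding barrier in kB*Tf units
```

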