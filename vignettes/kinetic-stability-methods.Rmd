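---
title: "Models and methods for kinetic stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for kinetic stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinstab)
```

Kinetic stability — the free-energy barrier between a protein's native
state and its unfolding transition state — controls how long a folded
protein survives, independently of its equilibrium stability. This
vignette documents the models this package implements, the parameters
that matter, and the numerical choices behind them, at the level of
detail a user needs to judge what the results do and do not mean.

## Contact maps

Two residues are in contact when any pair of their heavy atoms lies
strictly within a cutoff (default 6 Å). Atom-level contacts additionally
require a sequence separation |i − j| ≥ 2, the floor used by the absolute
contact order. Distances are compared with a strict `<` at the cutoff.

The *shadow* variant prunes the cutoff map: a candidate atom pair is
discarded when a third heavy atom occludes it, i.e. when a sphere of the
occlusion radius (default 1 Å) centred on the third atom intersects the
open line segment between the two atom centres, with the perpendicular
foot strictly between the endpoints. With radius 0 the shadow map equals
the cutoff map; for any radius it is a subset. The occlusion predicate is
a geometric idealization of published shadowing algorithms, which differ
in small details (e.g. how bonded neighbours are discounted); for the
residue-level maps used here those details move individual borderline
contacts, not the topology metrics computed from them.

Hydrogens, waters, and heteroatoms are removed on reading; alternate
locations resolve to the highest-occupancy conformer; only one model of a
multi-model file is used. Residues are indexed 0-based internally with
author numbering preserved for reporting. Energy minimization prior to
mapping is deliberately *not* performed: the package consumes coordinates
as given, so metrics computed from deposited (unminimized) structures can
differ in the first decimal from values derived from minimized
coordinates. Both cutoff and shadow maps are exposed so users can compare.

## Topology metrics and rate prediction

ACO is the mean sequence separation over qualifying atom contacts; LRO is
the number of residue contact pairs with separation ≥ 12, divided by the
chain length. The threshold boundary is inclusive (separation 12 counts,
11 does not). Both metrics are dimensionless.

The midpoint unfolding-rate predictors are empirical correlations
calibrated on two-state β-sheet proteins at the denaturation midpoint:

$$\log_{10} k_u = -1.70\,\mathrm{LRO} + 6.6, \qquad
  \log_{10} k_u = -0.52\,\mathrm{ACO} + 5.9,$$

with $k_u$ in s⁻¹. The correlations are printed in the source literature
without the logarithm, but only the log-linear reading reproduces the
published worked values (LRO 4.1 → 0.43 s⁻¹), so that reading is
implemented. The predictions are meaningful only at the transition
midpoint and only for proteins inside the calibration class; they should
be treated as order-of-magnitude estimates elsewhere.

For core-swap accounting, a long-range contact between two residues that
are both members of the subset under study (e.g. the conserved
hydrophobic core) contributes 0.5 to each member, so the pair contributes
1.0 to the subset total; a contact with a single endpoint in the subset
contributes 1.0 to that endpoint. Design-model screening flags a model as
an outlier when its LRO or ACO falls outside
[Q1 − 1.5·IQR, Q3 + 1.5·IQR] over the model set, with quartiles by linear
interpolation (type 7); the 1.5 multiplier is the conventional Tukey
fence, chosen here because the screening literature names only "the
interquartile range method".

## The Cα structure-based model

The folding simulator is a standard Cα Gō-type model: one bead per
residue at the native Cα position, with

* harmonic bonds, $k_b = 100\ \varepsilon/\text{Å}^2$;
* harmonic angles, $k_a = 20\ \varepsilon/\text{rad}^2$;
* cosine dihedrals with periodicities 1 and 3,
  $k_d [\,(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)\,]$,
  $k_d = 1\ \varepsilon$;
* a 10–12 Lennard-Jones well of depth $\varepsilon = 1$ at the native
  distance for every contact-map pair with separation ≥ 4;
* $r^{-12}$ excluded volume (radius 4 Å) for every other pair with
  separation ≥ 4.

Separations 1–3 are governed solely by the bonded terms, the convention
of the model lineage this potential follows. All quantities are in
reduced units ($\varepsilon = k_B = m = 1$); simulation temperatures are
model-internal and do not correspond to Kelvin.

Dynamics use a BAOAB-split Langevin integrator (timestep 0.0005 reduced
time, friction 1.0). One integer seed drives both the Maxwell initial
velocities and the thermostat noise stream through a dedicated
xorshift/Box–Muller generator, so a run is bitwise reproducible
independent of R's global RNG state. Degenerate dihedrals — quadruplets
whose native geometry is collinear — have no defined native angle and are
dropped at build time with a warning. At the native geometry the bonded
terms vanish identically and every contact sits at its −ε minimum; the
only residual is the small excluded-volume tail from just-outside-cutoff
pairs, so the native structure is a force stationary point to within that
tail.

A contact is *formed* when its bead distance is below 1.2× the native
distance; Q is the formed fraction. The folding temperature is located by
bisection: at each candidate temperature two runs are started (native and
unfolded geometry) and pooled, a chain is classified folded once Q rises
above 0.65 and unfolded once it falls below 0.35 (hysteresis suppresses
barrier-top recrossings and avoids committing to a fixed basin position),
and T_f is accepted when the folded population lies in 40–60% and at
least 3 folding/unfolding transitions were seen. Unfolded starting
structures come from short high-temperature runs that are retried with
doubled length (derived seeds) until the final frame has Q < 0.2.

Default run lengths are fixture-scale: 10⁷ steps for production-style
runs, 2×10⁶ per T_f probe. The cluster-scale protocol used for full-size
proteins (2×10¹⁰ steps) is available as
`sbm_params(preset = "production")`; nothing else in the code changes.

## Free-energy profiles, reweighting, barriers

F(Q) = −ln P(Q) from the binned Q histogram, in units of k_B·T at the
sampling temperature. The barrier bin is the global maximum of F over the
interior spanned by the outermost local minima; the unfolded and folded
basins are the deepest local minima on either side of it, with ties
resolved toward extremal Q. Two numerical choices matter:

* **Occupancy floor.** Bins visited by fewer than 5 frames are excluded
  from basin/barrier *identification* (their F is still reported):
  −ln P estimated from one or two visits produces spurious interior
  maxima several k_B·T above the true barrier.
* **Level binning.** Q from an n-contact simulation takes the discrete
  values k/n. A fixed bin count that is not commensurate with n aliases —
  alternate bins catch one or two Q levels and the profile acquires a
  spurious sawtooth. `bins = "levels"` places one bin per Q level and is
  the recommended setting for simulation output; the 50-bin default is
  appropriate for continuous or pooled data.

To compare barriers between proteins, each trajectory is reweighted so
the folded and unfolded minima are equal (then set to zero):
single-histogram temperature reweighting assigns each frame the weight
$e^{-(\beta' - \beta) E}$ and root-finds $\beta'$ (searched as
$\beta'/\beta \in [0.5, 2]$) so the basin minima match. Energies enter
only through differences, making the result invariant to a uniform
energy offset; the implementation subtracts the mean energy before
exponentiating to avoid overflow. The reweighting is a *temperature*
perturbation — the cited reweighting lineage also admits contact-energy
perturbations, which are not implemented.

Average contact maps pool all frames with |Q − q_target| ≤ tol (default
q_target 0.4, near the transition-state ensemble) and report per-contact
formation probabilities.

## Denaturation fitting

Kinetic traces fit $Y = A e^{-t/t_1} + Y_0 (+ d\,t)$ by
Levenberg–Marquardt least squares; $k = 1/t_1$. A fit whose amplitude is
statistically indistinguishable from zero (|A| < 2·SE, or negligible
against the signal scale) is flagged degenerate rather than rejected.

Chevron data fit
$\ln k_{obs} = \ln[k_f^{H_2O} e^{m_f x / RT} + k_u^{H_2O} e^{m_u x/RT}]$
on the log scale (uniform relative error, the chevron convention; plain-k
fitting is available via a flag). Starting values come from straight-line
fits to the two limbs; data covering a single limb are rejected as
unidentifiable (the rate minimum must be interior to the concentration
range). Note the chevron *minimum* does not sit at the midpoint: it lies
at $C_{mid} + RT\ln(|m_f|/m_u)/m_{eq}$, about 0.13 M above it for typical
parameters here.

Equilibrium curves fit the two-state linear extrapolation model with
linear baselines,
$Y = [(Y_N + S_N x) + (Y_U + S_U x)K]/(1+K)$,
$K = e^{-( \Delta G - m x)/RT}$. Published typesettings of this equation
are frequently garbled; this algebraic form, the one the standard fitting
lineage uses, is the only reading consistent with two baselines.

Derived quantities use T = 300.15 K (27 °C) and
R = 1.987×10⁻³ kcal K⁻¹ mol⁻¹: $m_{eq} = m_u - m_f$;
$\beta_T = |m_f|/m_{eq}$ (the absolute value reconciles the sign
convention in which $m_f$ is negative with the positive β-Tanford values
reported for cooperative folders); $\Delta G = -RT \ln(k_u/k_f)$;
$C_{mid} = \Delta G/m_{eq}$; $k_u(C_{mid}) = k_u e^{m_u C_{mid}/RT}$;
half-life $= \ln 2 / k_u(C_{mid})$. Parameter uncertainties are
asymptotic covariance standard errors from the least-squares fit; they
will not numerically match errors from other fitting programs.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of their arguments (seed included) and
restore R's global RNG state.

* `toy_fold()` places 20 (8–64) beads on a serpentine cubic-lattice path
  (spacing 4.2 Å) with a small seeded jitter (σ 0.15 Å), redrawn until no
  two beads are closer than 3.8 Å. The jitter breaks the lattice's
  collinear degeneracies so all dihedrals are defined. The fold is
  compact with ≥ 3 long-range contacts — enough for every contact-map,
  metric, and SBM operation to be exercised. For folding runs the
  recommended map uses a 7.0 Å bead–bead cutoff: single-bead residues
  have no side-chain atoms, so the 6 Å heavy-atom criterion is too tight
  at bead resolution (Cα-model conventions run 7–8 Å), and on this
  lattice geometry 7.0 Å gives the cleanest two-state behaviour —
  narrower maps melt without a barrier, wider ones bury the transition
  under contacts too weak to be cooperative.
* `homolog_pair()` returns two structures of identical geometry whose
  maps differ by a stated number of extra long-range pairs, all inside a
  designated "core" subset, drawn from real inter-bead distances just
  outside the map cutoff. The deficit is therefore exact by
  construction, and the native structure remains the energy minimum of
  both SBM topologies.
* `synthetic_trace()` / `synthetic_chevron()` generate exponential traces
  and two-limb chevrons from stated truths (chevron truth defaults to
  the wild-type hisactophilin parameter set) with additive or
  multiplicative Gaussian noise.
* `two_state_q_series()` samples Q from a double-well density (two
  truncated Gaussian basins whose common width is set from the requested
  barrier) with E linearly coupled to Q. It returns the *exact* bin
  masses of the generating density and the barrier they imply, so
  recovery tests compare against the construction, not an approximation.

Passing tests on these fixtures demonstrates the correctness of the
algorithms — contact geometry against brute-force oracles, fit recovery
at stated noise, barrier recovery against a known generating density, and
the directional response of the simulated barrier to added long-range
contacts. They do not demonstrate that a 20-bead lattice fold behaves
like a 100+-residue β-trefoil: the toy's folded basin sits near Q ≈ 0.7
rather than ≈ 0.95, its barrier is of order 1 k_B·T_f rather than 4–17,
and its transition is weakly cooperative. Conclusions about real
proteins require real structures and production-length runs.

## Simulation scale

The shipped tests and examples run at desk scale: 20-bead folds, 2×10⁶
steps per T_f probe, 5×10⁶-step production runs, 50-level histograms —
a few minutes end to end. At this scale two-seed barrier estimates agree
to within ~0.5 k_B·T_f; resolving the ~1.5 k_B·T_f barrier differences
that separate engineered variants of real proteins requires the
production preset (2×10¹⁰ steps) and structures with hundreds of
contacts, for which sub-0.1 k_B·T_f barrier precision has been reported
in the literature this model follows.

## Known limitations

* The shadow-map predicate is a single-sphere line-of-sight test; it does
  not reproduce every bonded-atom special case of published
  implementations.
* Temperature reweighting assumes the sampled ensemble overlaps the
  target ensemble; it cannot fix a run that never crossed the barrier.
* The rate correlations are calibrated for two-state β-sheet proteins at
  the midpoint; applying them to other folds or conditions extrapolates.
* Comparative modelling, stereochemical model screening (Ramachandran),
  and cavity-volume calculations are out of scope; an external keep/drop
  vector can carry such screens into `evaluate_designs()`.
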