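---
title: "Multistate design of hinge-motion conformational landscapes"
author: "confdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate design of hinge-motion conformational landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdesign)
```

## The problem

Hinge-bending enzymes such as aspartate aminotransferase (AAT)
interconvert between an open and a closed conformation by rotating a
small moving domain relative to a larger fixed one. When only the
closed form is catalytically competent, the open/closed equilibrium
caps the catalytic efficiency: a substrate that binds but closes the
enzyme poorly is turned over slowly. `confdesign` implements a
multistate design strategy for shifting that equilibrium: instead of
optimizing a sequence on a single structure, every candidate sequence
is scored on structural ensembles of *both* states, and the difference
of its Boltzmann-weighted state energies,
$\Delta E = E_\mathrm{closed} - E_\mathrm{open}$, predicts which
conformation it favors. Negative $\Delta E$ predicts preference for
the closed state.

This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic fixtures do and do not
demonstrate.

## Hinge geometry

`domain_rotation()` takes a user-supplied partition of residues into
fixed domain, moving domain and hinge. The fixed domains of the two
conformations are superposed on their C$\alpha$ atoms (least-squares,
proper rotation only); the residual rigid transform of the moving
domain is then decomposed into screw form. The angle comes from
$\cos\theta = (\operatorname{tr} R - 1)/2$ with the argument clamped
to $[-1, 1]$ for numeric safety; the axis from the skew part of $R$
(eigenvector fallback near 180°); the translation along the axis is
the axis-parallel component of the translation vector. Below an angle
floor (default $10^{-4}$ degrees) the motion is reported as null
rather than returning a meaningless axis.

Automatic domain decomposition is deliberately *not* reimplemented:
partitions come from the user or a YAML config. The quantitative
outputs (angle, axis, per-residue C$\alpha$ displacements after a
fixed-domain fit) are what downstream logic needs. On constructed
fixtures with a known screw motion the angle and axis are recovered to
$10^{-6}$ degrees; applying this machinery to real structure pairs
requires the user to supply the (method-dependent) domain partition,
and the recovered angle will be sensitive to it.

## Ensembles by perturbation/minimization

`generate_ensemble()` emulates backbone flexibility around one state:
each member is created by displacing every heavy atom by exactly
$\pm m$ along each Cartesian axis with independent random signs
(default $m$ = 0.001 Å, so each atom moves $m\sqrt 3$) and relaxing
the copy with a bounded minimization (default 100 iterations).
Member $i$ uses seed $s + i$, making ensembles bit-reproducible. The
"±" in the perturbation is read as a fixed magnitude with a random
sign (Rademacher); uniform sampling in $[-m, m]$ is available via
`scheme = "uniform"`.

The bundled potential is an elastic network: harmonic restraints on
all interatomic distances within 5 Å of each other in the input
geometry. This reproduces the *mechanism* — perturb, then relax into
a nearby minimum — with an analytic gradient and no parameter fitting,
and the potential is pluggable for users who want a force field. Two
consequences are worth being explicit about. First, the elastic
network has the input geometry as its global minimum, so relaxed
members land very close to the seed structure and the ensemble
diversity is tiny (~$10^{-9}$ Å backbone RMSD) rather than the
~0.3 Å obtained with a molecular-mechanics force field; absolute
diversities are therefore out of numeric scope here, while all the
bookkeeping (determinism, shared topology, diversity statistics) is
exercised for real. Second, the minimizer is a contract, not a brand:
any deterministic, monotone, iteration-bounded second-order descent
qualifies. The bundled implementation is truncated Newton with a
conjugate-gradient inner loop (capped at 25 inner iterations,
forward-difference Hessian-vector products), Armijo backtracking line
search, and a steepest-descent fallback whenever the Newton direction
is not a finite descent direction. The energy trace is monotone
non-increasing by construction.

## The design energy function

Sequences are scored by pairwise nonbonded energies only — rotamer vs
template and rotamer vs rotamer — with no bonded terms, no entropy and
no unfolded-state reference. Five terms:

* **Lennard-Jones 12-6**, per-atom radii scaled by 0.9 before
  combination (arithmetic-mean combined radius, geometric-mean well
  depth). The scaling softens the hard-sphere surface so that discrete
  rotamers are not over-penalized for small clashes.
* **Hydrogen bond**: hybrid 12-10 distance dependence with well depth
  8.0 kcal/mol at a donor–acceptor distance of 2.8 Å, times an
  angular factor $\cos^4\theta_\mathrm{DHA}$, zero below 90°. The
  $\cos^4$ form is a package choice (the angular form is otherwise
  unconstrained); inside matrix assembly the angular factor is
  evaluated at ideal proxy-hydrogen geometry (factor 1) for
  donor/acceptor-typed heavy-atom pairs within 3.5 Å.
* **Coulomb** with a distance-dependent dielectric
  $\varepsilon(r) = 10r$ (constant $\varepsilon = 10$ available by
  configuration), prefactor 332.0637 kcal·Å/(mol·e²).
* **Occlusion solvation**: a per-atom penalty coefficient times the
  neighbor volume occluding it, with a Gaussian kernel
  $\exp(-(r/3.5\,\text{Å})^2)$ — pairwise-decomposable so it folds
  into the singles/pairs matrices.
* **Secondary-structure propensity**: a residue-type × class (helix /
  strand / other, assigned from template $\phi/\psi$) table, additive
  over positions, entering singles only.

Nonbonded cutoff 8 Å with no switching function; contacts below 0.5 Å
and any per-contact energy above +100 kcal/mol are capped at +100,
keeping all matrix entries finite and the optimization well-posed.
The parameter tables (radii, depths, charges by atom class,
donor/acceptor typing, solvation constants, propensities) ship as
versioned plain-text files (`ff_params_v1.csv`,
`ss_propensity_v1.csv`). They are self-consistent stand-ins: the
published design-suite tables behind the reference study are not
public, so absolute energies here do not, and are not meant to,
reproduce published energy tables. All validation of the energy
machinery is structural and relative (decomposability, rigid-motion
invariance, term-by-term closed forms).

Within a design residue, the rotamer's interactions with its own
backbone and the adjacent peptide units are excluded from the singles
(they are bonded-geometry artifacts that would add a near-constant
clash term to every choice).

## Rotamers and solvers

Rotamers come from a Dunbrack-style backbone-dependent text library;
the bundled mini-library covers all 18 designable side-chain-bearing
types (proline is excluded from the design alphabet, glycine is
handled rotamer-free) with field-plausible $\chi$ means and spreads —
it is explicitly synthetic, adequate for exercising every code path
but not a statistical rotamer set. Each rotamer is expanded
$\pm 1\sigma$ around $\chi_1$ and $\chi_2$ (9 variants for two or more
$\chi$ angles, 3 for one; $\chi_3/\chi_4$ unexpanded). Side chains are
built by sequential torsion (NeRF) construction from ideal internal
coordinates; re-measuring $\chi$ from built coordinates returns the
inputs to $10^{-6}$ degrees.

Three solvers operate on the same matrices:

* `brute_force_gmec()` — exact enumeration (the oracle), refusing
  search spaces above a bound (default $10^6$);
* `dee_prune()` — Goldstein dead-end elimination iterated to a
  fixpoint, provably GMEC-preserving;
* `faster_optimize()` — iterative batch relaxation from the
  per-position singles minima, followed by single-perturbation/
  relaxation sweeps accepted on strict improvement. Pair-perturbation
  moves are not implemented. Ties break lexicographically everywhere
  (position order, then choice order), making every solver
  deterministic.

On 100 seeded toy problems (up to 5 positions × 6 choices) FASTER
matches the brute-force optimum in ≥95% of instances (100% in the
shipped runs) and, by construction, never reports an energy below it.

## Multistate scoring and library design

For each sequence and each state, rotamers are optimized independently
on every ensemble member and the member energies are combined as a
Boltzmann-weighted average at 300 K
($R = 1.9872 \times 10^{-3}$ kcal/(mol·K), log-sum-exp stabilized), so
$\min_b E_b \le \bar E \le \mathrm{mean}_b\, E_b$. Sequences whose
$E_\mathrm{closed}$ *or* $E_\mathrm{open}$ lies above the 75th
percentile of the respective column are discarded before ranking —
"outside the percentile" is read as *above* (worse), since a sequence
that destabilizes one state can otherwise show a spuriously favorable
$\Delta E$. Survivors are ranked by $\Delta E$, ascending for a
closed-stabilizing objective.

Library design follows the scored-size-configuration idea: a
combinatorial library is a choice of an amino-acid set per position;
all size configurations whose product lies within the target window
(default 20 ± 4) are enumerated, each position takes its top-$n_i$
amino acids by probability, and the configuration with the largest
summed probability mass wins (ties: smaller library, then
lexicographic sets). The per-position probabilities are normalized
Boltzmann weights over $\Delta E$ with a selection temperature
(default 1 kcal/mol on the $\Delta E$ scale) — the published
procedure's internal probability model is not public, so this
weighting is a documented stand-in; the configuration search itself is
exhaustive and exact.

## Two-state thermodynamics

Variable-temperature 1-D spectra in slow exchange are deconvoluted
into two Lorentzians plus a constant baseline by Levenberg-Marquardt
least squares; widths and amplitudes are parameterized on the log
scale, so negative values are impossible. Peak areas
($\pi \cdot \text{amplitude} \cdot \text{hwhm}$) give populations;
their ratio gives $K_\mathrm{eq}$, with the closed state assigned to
the more upfield peak by default (a configuration choice, never
inferred silently). A genuinely single-peak spectrum drives the second
amplitude to zero and is flagged degenerate rather than erroring.

The van't Hoff relation with temperature-dependent enthalpy and
entropy,
$$\ln K_\mathrm{eq} = -\frac{\Delta H^\circ_\mathrm{ref}}{R}\frac{1}{T}
  + \frac{\Delta S^\circ_\mathrm{ref}}{R}
  - \frac{\Delta C_p}{R}\left[\frac{T - T_\mathrm{ref}}{T}
  + \ln\frac{T_\mathrm{ref}}{T}\right],$$
is *linear* in $(\Delta H^\circ_\mathrm{ref}, \Delta S^\circ_\mathrm{ref},
\Delta C_p)$ once written in $\ln K_\mathrm{eq}$ space, so
`fit_vant_hoff()` solves it by exact linear least squares (`lm` on the
basis functions) rather than an iterative optimizer — same contract,
exact recovery on noiseless data, covariance-based uncertainties.
Reported uncertainties are 95% confidence half-widths
($t_{0.975,\,\mathrm{df}} \times \mathrm{SE}$). The linear van't Hoff
model simply drops the $\Delta C_p$ basis function. Gibbs energies of
closing follow either from
$\Delta G = \Delta H_\mathrm{ref} + \Delta C_p(T - T_\mathrm{ref}) -
T[\Delta S_\mathrm{ref} + \Delta C_p \ln(T/T_\mathrm{ref})]$ or from
$-RT\ln K_\mathrm{eq}$; the two are algebraically identical and the
package asserts that identity to $10^{-9}$.

Under 1% multiplicative noise on $K_\mathrm{eq}$ at seven temperatures
(5–35 °C in 5° steps, the variable-temperature schedule of the
reference experiments), all three parameters fall inside their joint
95% intervals in ≈91% of 500 seeded replicates.

## Steady-state kinetics

`initial_rate()` finds the linear phase of an absorbance trace by an
expanding window from $t = 0$, keeping the longest window with linear
$R^2 \ge 0.995$ (configurable; "linear phase" has no canonical
definition). Because $R^2$ is a weak curvature detector, the slope is
evaluated on the early half of the detected window — otherwise the
bent tail of the window biases the rate several percent low. The slope
converts to a molar rate via $\varepsilon_{340}$ = 6220 M⁻¹cm⁻¹ and
the well path length.

Michaelis–Menten and substrate-inhibition
($v_0 = v_\mathrm{max}[S]/(K_M + [S] + [S]^2/K_i)$) models are fitted
by Levenberg–Marquardt with positivity bounds; the substrate-
inhibition model nests Michaelis–Menten as $K_i \to \infty$, and its
fitted curve peaks at $[S] = \sqrt{K_M K_i}$ (both asserted in tests).
$k_\mathrm{cat}/K_M$ uncertainty uses first-order propagation from the
fit covariance. `efficiency_linear_regime()` estimates
$k_\mathrm{cat}/K_M$ directly from the origin-constrained slope of
$v_0$ vs $[S]$ at $[S] \ll K_M$. Selectivity is the ratio of
efficiencies across substrates, and the fold switch is the ratio of
selectivities against a reference enzyme. At 2% multiplicative rate
noise the median relative parameter error stays below 5% over 200
seeded replicates per model.

## Synthetic fixtures: what they show and what they don't

All tests run on generator output: ideal-geometry polyalanine
scaffolds (fixed $\phi/\psi$, no Ramachandran realism), toy design
problems with independently enumerated optima, equilibrium series and
spectra generated from known thermodynamic parameters, and rate data
from known kinetic parameters. Passing tests therefore demonstrate
*correctness of the computations* — geometry recovery, solver
optimality, round-trip parameter identification, determinism — not
predictive accuracy on real proteins, which additionally depends on
force-field quality, rotamer statistics and ensemble realism that the
bundled stand-ins deliberately do not claim.

Problem sizes in the shipped tests and acceptance script (8-residue
scaffolds, 2–6 ensemble members, 2 design positions, 3–6 letter
alphabets, 100 solver instances, 200–500 statistical replicates) were
chosen to exercise every code path with comfortably interactive run
times; every generator accepts larger sizes.

## Known limitations

* The homodimer question (design on one chain vs both) is left to the
  user: selections and partitions are chain-explicit, and the pipeline
  default operates on whatever chains the input structure provides.
* Hydrogens are implicit except as ideal proxies in hydrogen-bond
  geometry; no protonation-state logic.
* No mmCIF input, symmetry expansion or anisotropic B-factors.
* The FASTER implementation omits pair-perturbation moves; on larger
  problems than the shipped fixtures this can cost optimality more
  often than the measured ≥95% match rate.
* Exchange lineshape modeling (beyond two static Lorentzians) and
  bi-substrate mechanism fitting are out of scope.
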