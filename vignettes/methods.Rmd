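---
title: "Models, assumptions and design notes"
author: "combonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combonet)
```

This vignette documents the models implemented in `combonet`, the tunable
parameters that matter, the numerical choices behind the solvers, what the
synthetic-data generator does and does not emulate, and the design decisions
made where the design was genuinely open. It states no empirical result that
the test suite or the acceptance script does not itself compute.

## 1. The MRA data model and its sign convention

Modular Response Analysis treats the steady-state log2 fold change
`R[i, k]` of node `i` under perturbation `k` as the propagated consequence of
a direct effect `s[i, k]` through a network of local response coefficients
`r[i, j]` (percent change of `i` per 1% change of `j`, diagonal normalized to
−1). Two algebraic facts drive everything:

* residual form: `ε = r·R + s`, zero for exact steady-state data;
* forward solve: `R = −r⁻¹·s`, the unique response to a direct effect
  vector when `r` is invertible.

The source literature is typographically ambiguous about the sign of `s` in
the forward solve (the constraint and simulation equations are printed with
inconsistent signs). We use the pair above because it is internally
consistent and physically sensible: an inhibitor (`s < 0`) lowers its own
target's activity in the absence of feedback. Data prepared under the
opposite convention would flip fitted signs; the package never silently
reinterprets user input.

The model is quasi-steady-state: it describes a single short-term
measurement (the 2 h scale of phospho-protein responses), not kinetics.

## 2. Comparative Network Reconstruction as an exact MIQP

`build_cnr_problem()`/`solve_cnr()` fit both cell lines jointly by
minimizing squared residuals plus `η`·(number of edges) plus `θ`·(number of
between-line differences), with binary indicators enforcing sparsity
(`I_edge = 0 ⇒ r_ij = 0` in every line), shared edges (`I_diff = 0 ⇒ r_ij`
equal across lines) and shared perturbations (one `I_sdiff` per
drug–target pair covering both dose levels). Structural constraints encode
the experimental design: every fitted `s` is an inhibitor effect, strictly
negative, and stronger at IC90 than at IC50. Strictness is realized as
`≤ −δ` with `δ = 1e-6` (configurable); `δ` only matters when a drug has no
detectable effect, where it pins the estimate at the margin rather than
leaving the sign free.

**Why a hand-built solver.** The environment provides no mixed-integer
programming backend, and the objective and all constraints of this program
separate exactly by target node: row `i` of `r` and `s` appears in no other
row's residuals, penalties or constraints. Each row is therefore a small
MIQP (≤ ~20 binaries for the 9-node panel) solved exactly by depth-first
branch-and-bound:

* the relaxation at a search node is the convex least-squares problem under
  the constraints implied by indicators *fixed to 0* plus the penalties of
  indicators *fixed to 1* (a valid lower bound, since unfixed indicators
  contribute neither);
* equality and zero constraints are eliminated structurally (columns merged
  or dropped), inequalities are handled by `quadprog::solve.QP` on a
  ridge-stabilized normal system (ridge `1e-9`·max diag, far below every
  tolerance the package promises);
* incumbents come from rounding the relaxed solution (an indicator is set to
  1 when its constraint is violated beyond `1e-7`) and re-solving;
* pruning at `1e-9` certifies exactness, which the test suite confirms
  against brute-force enumeration over all indicator assignments on 3-node
  instances.

Two encodings are exposed: `"indicator"` (exact elimination, default) and
`"bigM"` (adds box constraints `|r|, |s| ≤ B`, default `B = 10`; log2
effects beyond ±10 are unphysical). They agree whenever the solution is
interior to the box — a tested invariant.

**Hyperparameters.** `η` (default 0.1) prices an edge; `θ` (default 2.0)
prices a between-line difference and may be `Inf` to forbid differences
entirely (the regime used by all null ensembles, so that only the randomized
ingredient varies). `cnr_loocv()` selects both on a grid by leave-one-out
over *two-drug conditions only* — single-drug conditions anchor the per-dose
`s` parameters and can never be held out. The held-out column is predicted
from single-drug estimates as `−r̂⁻¹(ŝ_A + ŝ_B)` and scored by per-entry
mean squared error; ties break toward smaller `η`, then larger `θ`
(sparser, more shared models). The scoring rule is our choice — the source
describes which conditions were held out but not the error metric.

## 3. Null ensembles and the empirical p value

Three randomization schemes calibrate the fitted model's residual RMS
(`sqrt(mean(ε²))` over all entries and both lines — the square root is ours;
the printed formula appears to have lost its radical in rendering):

* `random_topology`: random edge sets of the true size, differences
  forbidden;
* `node_permutation`: node labels of the data permuted, true topology kept
  (this stands in for degree-preserving rewiring, which is not separately
  implemented);
* `random_differences`: true topology with a fixed number of randomly chosen
  difference indicators forced active.

The reference RMS is always the actual model re-fit under the same
`θ = Inf` regime. The empirical p value is `(k+1)/(n+1)` with ties counted
as beating the reference — conservative, and never exactly zero.

## 4. Signaling → viability models

Six forms are implemented (`fit_viability_model()`): a full linear model on
all node responses, a bivariate linear model on pAKT/pERK, and four
nonlinear forms in which viability collapses when either pAKT or pERK is
fully inhibited. The selected Michaelis–Menten-like form
`v = 1/(1 − R_AKT/K_AKT − R_ERK/K_ERK)` has two interpretable parameters per
cell line: `K_M` is the log2 fold change producing 50% viability inhibition
(25% and 33% for the two exponential forms at the same evaluation point —
identities the acceptance suite checks).

Numerical choices: replicates are averaged per condition before fitting
(configurable); linear forms are fit on inhibition `1 − v` without an
intercept (so vehicle maps to `v = 1` exactly); nonlinear forms are fit by
multi-start quasi-Newton minimization of the residual sum in a log-K
parameterization, which enforces `K > 0` by construction (the spec's
"non-positive K flagged" case is thereby unreachable), with starts on the
grid {0.5, 1, 2, 4}² plus, for the selected form, a start from the exact
linear solve of `1/v − 1` in the inverse parameters. The cross-validated
comparison metric is the mean squared held-out residual per condition
(leave-one-condition-out per cell line, summed over lines); the magnitudes
in the source's comparison table are on this scale (σ² ≈ reported L2),
which fixed our reading of an otherwise ambiguous label. Bootstrap CIs are
nonparametric (conditions resampled within cell line, percentile 95%),
replacing an external resampling package that is not available here.

The form-4c model is only defined while `1 − R_AKT/K − R_ERK/K > 0`;
evaluation outside raises an error rather than returning a negative
pseudo-viability.

## 5. Dose interpolation

`s(c) = Imax·c/(KI + c)` on concentrations normalized to the highest applied
dose (IC90 = 1) is pinned exactly by the two CNR anchors; the closed form is
`KI = c50(1 − ρ)/(ρ − c50)` with `ρ = s50/s90`. When `ρ ≤ c50` no positive
`KI` exists and a least-squares compromise through both anchors is used and
flagged. Only interpolation is allowed (`0 ≤ c ≤ 1`); IC10 lies inside this
range. Single-dose drugs (the RAFi pattern, IC90 only) borrow the median
`KI` of the same line's two-dose drugs and solve `Imax` from their single
anchor — the source is silent here, and the choice is flagged per row.

## 6. Combination simulation and optimization

A triple A+B+C at concentrations `c` is simulated per line as
`R = −r⁻¹(s_A(c_A)+s_B(c_B)+s_C(c_C))` and mapped to viability with that
line's `K_M`. Selectivity is `v_parental − v_mutant` (first minus second
cell line); anti-selectivity its negation. The dosing optimization
minimizes `v_x` subject to `v_y ≥ v_min` (default 0.8, deliberately
conservative) and per-drug caps at IC10, treated per-drug (not as a shared
cap). The optimizer is multi-start projected L-BFGS-B with a ramped
quadratic penalty for the floor and a final polish that scales the
concentration vector toward zero until the floor holds within `1e-6`
(always feasible because `v(0) = 1`). Every returned optimum is validated in
the tests against a vectorized 21³ dense-grid oracle at `1e-4`. Control
dosings minimize `(v_x−0.8)² + (v_y−0.8)²` on the same box.

The power analysis adds i.i.d. Gaussian noise (default sd 0.25, the scale of
viability-prediction residuals) to each combination's predicted selectivity
and applies a two-sided rank-sum test at α = 0.05; the source names no test,
and its "Wilcoxon signed-rank" for two *unpaired, unequal-size* groups in
the validation analysis cannot be a paired test — `validation_stats()`
therefore uses the unpaired rank-sum for the group comparison and documents
rather than imitates the label.

## 7. The synthetic world

The generator emulates the study's shape: 9 nodes, 9 inhibitors (two doses
each except one IC90-only drug), 17 single-drug + 17 two-drug conditions
(IC50+IC50) = 34 perturbations × 9 nodes × 2 lines = 612 measurements. The
identity of the 17 pairs is not published; they are drawn deterministically
from the seed, among drugs that also have a single IC50 condition so every
combination dose is anchored by a monotherapy. Defaults chosen once and
documented here:

* dose levels IC10 = 1/81, IC50 = 1/9 of IC90 (a unit Hill slope);
* edge weights: magnitude U(0.3, 1.2), negative with probability 0.2;
* direct effects: `s(IC90) = −U(0.5, 2)`, `s(IC50) = s(IC90)·U(0.3, 0.8)`
  (dose ordering holds by construction);
* planted differences: the second line's coefficient multiplied or divided
  (equal probability) by U(1.5, 3); perturbation differences scale both dose
  levels, preserving ordering;
* `K_M`: parental (1.5, 2.0), mutant (1.8, 2.4) — "differ slightly";
* noise: additive Gaussian sd 0.1 on log2FC (log-normal on ratios);
  viability noise sd 0.05, truncated at 0, 3 replicates.

Sampled truths are accepted only if both interaction matrices are
well-conditioned and the noiseless responses stay inside the viability
model's domain (denominator ≥ 0.05, |log2FC| ≤ 8) — real training data
satisfy both by construction, so this is part of the stated world rather
than tuning.

What the generator does *not* emulate: raw bead intensities, blank
subtraction and protein-normalization artifacts, off-target drug effects,
kinetic transients, or batch structure. A green test therefore establishes
algorithmic correctness (recovery, calibration, optimality) under the
model's own assumptions, not robustness to the full messiness of Luminex
data.

**A structural identifiability note.** The default prior topology is a
12-edge canonical MAPK/PI3K network. An earlier draft included the
`p70S6K → AKT1` feedback; combined with an mTOR inhibitor that directly
perturbs both AKT1 and p70S6K, that makes the AKT1 row of the design matrix
*exactly* rank-deficient — a one-dimensional family of (r, s) fits noiseless
data perfectly, so no solver can recover the generative parameters. The
shipped prior uses the equally canonical `AKT1 → CREB1` edge instead. Users
supplying their own prior + drug map can hit the same degeneracy; the
symptom is a fitted row far from expectation at near-zero residuals.

## 8. Known limitations

* The viability model approaches zero only asymptotically; predictions below
  ~0.3 are outside its comfortable range (by design, the low-dose regime
  lives near 0.8–1.0).
* Two anchors cannot identify the shape of the dose–inhibition curve beyond
  the assumed hyperbola; no Hill coefficient is fitted.
* More than two cell lines are supported by the equations (means over lines)
  but not tuned or tested beyond pairs.
* 4-drug optimization is combinatorially available but untuned.
* The branch-and-bound is exact but exponential in the worst case; with the
  full 72-edge candidate set and small `η` it remains interactive (seconds),
  but pathological penalty settings can slow it.
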