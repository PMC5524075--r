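---
title: "From expression states to condition-specific fluxes: methods and design"
author: "fluxcond"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression states to condition-specific fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcond)
```

# The model and its assumptions

A metabolic network with $m$ metabolites and $n$ reactions is an
$m \times n$ stoichiometric matrix $S$; a flux vector $v$ is feasible
when it is mass balanced and within capacity,

$$ S v = 0, \qquad v_{\min} \le v \le v_{\max}. $$

Three modeling conventions are fixed package-wide:

* **Exchange reactions** are single-sided columns
  ($\emptyset \rightarrow$ metabolite); uptake vs secretion is encoded
  entirely by the sign of the bounds. This keeps the boundary explicit
  instead of introducing boundary metabolites.
* **Reversibility** is a negative lower bound, never a split reaction
  pair, at the model layer. (The MILP introduces separate forward and
  reverse *indicators*, not variables, where needed.)
* **Thermodynamics** means directionality bounds only. No loopless
  constraints are imposed; on the small networks the package targets,
  futile cycles can only arise through reversible spans, and the
  agreement-constrained FVA bounds expose them when they exist.

Infinite bounds are replaced by `default_bound` (1000 flux units),
three orders of magnitude above the activity threshold, so "unbounded"
and "active" remain well separated.

# Expression to reaction states

Within each sample, genes are ranked and the top
$\lfloor 0.25\,G \rfloor$ are HIGH, the bottom $\lfloor 0.25\,G \rfloor$
LOW, the rest MODERATE. Two choices deserve justification:

* **Ties resolve toward MODERATE.** A gene enters HIGH only when its
  value strictly exceeds the first excluded rank's value. This is the
  conservative reading of "top quartile": a gene that cannot be
  distinguished from the cut never drives a flux constraint, and an
  all-equal sample is entirely MODERATE.
* **Quantiles are computed per sample across genes**, not per gene
  across samples. Discretization is described per sample, and only the
  per-sample reading makes the two-thirds aggregation meaningful.
  The alternative (per-gene quantiles across samples) would make every
  gene HIGH in some sample by construction; it is noted here as the
  rejected reading, and the discretizer is deliberately a small,
  replaceable function should a sensitivity analysis want it.

Per-condition aggregation requires agreement in at least
$\lceil \tfrac{2}{3} n \rceil$ samples — "at least two-thirds", so 2 of
3 but 3 of 4. With `fraction > 1/2` the HIGH and LOW thresholds cannot
both be met.

GPR rules map gene states to reaction states under
LOW < MODERATE < HIGH with AND $\to$ min (a complex is limited by its
scarcest subunit) and OR $\to$ max (any isozyme suffices). Reactions
without a rule, and genes missing from the matrix, are MODERATE: the
moderate state attaches no indicator to the MILP, i.e. "no information"
imposes no preference. This makes `reaction_states()` monotone: raising
a gene's state can never lower a reaction's state.

# The iMAT program

For HIGH reaction $r$, binaries $y^+_r$ (and $y^-_r$ when reversible)
enforce $v_r \ge \varepsilon$ (resp. $v_r \le -\varepsilon$) through
big-M rows built from the reaction's own bounds, with
$y^+_r + y^-_r \le 1$. For LOW reactions, $y^0_r = 1$ forces
$v_r = 0$. The objective maximizes $\sum y$; its optimum $A^*$ is the
agreement level. MODERATE reactions carry no term — the objective is the
pure count of expression-consistent reactions, with no penalty weights.

Parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `epsilon` | 1.0 | flux | activity threshold; standard iMAT practice, 1000-fold below `default_bound` |
| `default_bound` | 1000 | flux | stand-in for infinite capacity |
| `mip_gap` | 1e-9 | — | branch-and-bound prunes at `best - 1e-9`; objectives are integral, so this is exact |
| `feas_tol` | 1e-9 | flux | accepted steady-state residual |

Alternative optima are real: the reported flux vector is whichever
optimum the search returns first. Nothing downstream depends on it —
direction calls and enrichment depend only on $A^*$ and the FVA bounds,
which are optimum-invariant.

**Solver.** No LP/MILP library is available in the supported
environment, so the package implements a dense two-phase simplex
(bounded variables via shift-plus-slack rows, Dantzig pricing with a
Bland fallback for anti-cycling) in C++ and a depth-first
branch-and-bound over the binaries in R. This is adequate — and
exhaustively tested — at the tens-of-variables scale the package
targets; it is *not* a genome-scale solver (see Limitations).

# Flux space at maximal agreement

FVA re-solves the MILP $2n$ times (min and max of each $v_r$) under the
added constraint $\sum y = A^*$. Feasibility is guaranteed because
$A^*$ itself was attained.

Sampling then draws from the polytope
$\{S v = 0,\ \text{FVA-min} \le v \le \text{FVA-max}\}$. The binaries
are dropped deliberately: the FVA box already encodes their reachable
envelope, and retaining $S v = 0$ is what makes each sample a flux
distribution rather than a box point. (A `box_only` flag exists for
sensitivity checks of exactly this reading.)

The sampler is hit-and-run in the affine hull: directions are isotropic
in the null space of $S$ (augmented with unit rows for
degenerate-width coordinates, so fixed reactions never move), chord
endpoints come from the box, and the start point maximizes the minimum
slack (an analytic-center surrogate computable by one LP). Burn-in is
1000 steps and thinning 10 — generous for the $\le$ 5-dimensional
polytopes of the toy networks, and recorded in the output metadata so
larger uses can judge. All randomness flows through the `seed`
argument; given a seed, runs are byte-identical.

# Differential calls and pathway enrichment

A reaction is UP when
$\text{med}_B - \text{med}_A > \text{tol} \cdot \max(1, |\text{med}_A|)$
(DOWN symmetrically). The 5% relative tolerance with an absolute floor
of one flux unit (= $\varepsilon$) exists because medians of two
independent 2000-sample chains differ by Monte-Carlo noise; a zero
tolerance would call that noise.

Enrichment uses the exact hypergeometric survival function
(summed `dhyper` terms, no normal approximation): $x$ directional calls
inside a pathway of size $K$, out of $N$ directional calls in a universe
of $M$. The universe contains only pathway-labeled reactions —
exchanges and other unlabeled plumbing would otherwise dilute $M$ with
reactions that can never contribute to any pathway's $x$. UP and DOWN
are tested separately and corrected as one joint BH family, matching a
single FDR threshold over both directions.

# GSEA with a gene-set-randomization null

Genes are ranked by signal-to-noise
$(\mu_A - \mu_B) / (\sigma'_A + \sigma'_B)$ with each
$\sigma' = \max(\sigma, 0.2\,|\mu|, 0.2)$ — the Broad floors, which keep
low-variance genes from dominating the ranking at n = 3–4. Sets are
restricted to measured genes first, then filtered to sizes 15–500.

The running sum rises by $|s|^w$ (normalized) at members and falls by
$1/(G-K)$ elsewhere; the ES is the signed extreme (positive wins an
exact tie). The null recomputes ES on the *fixed* ranking for random
same-size gene sets. This is the correct null when samples are too few
to permute: with 7 arrays, phenotype permutation has at most 35
distinguishable relabelings, far too few for FDR estimation, whereas
gene-set randomization asks the sharper question "is this *particular*
set more coherent than a random one of its size". The cost is a changed
null hypothesis: correlated member genes inflate significance relative
to phenotype permutation, which is why the vignette's power claims are
made only for the synthetic generator's independent-gene world.

P-values are same-sign one-tailed with add-one correction;
NES = ES / mean(|same-sign nulls|); FDR compares NES against the pooled
sign-normalized null with a step-up monotonicity pass
(`fdr_method = "bh"` swaps in plain BH on permutation p-values as a
cross-check).

# The synthetic world

`make_toy_network()` builds parallel linear pathways (uptake → chain →
shared hub → secretion), each internal reaction carrying a pathway label
and a private 1–2 gene GPR; optionally one dead-end branch that
`validate_model()` must report blocked. `plant_condition_fluxes()`
assigns each pathway ON (`base_flux` = 5, safely above
$\varepsilon = 1$ and below capacity 10), OFF (0), or a scale factor,
and balances the hub exactly in integer arithmetic, so planted modes
satisfy $S v = 0$ with zero residual.

`simulate_expression()` encodes activity in three strata on a
log2-like scale — low ≈ 2, mid ≈ 5, high ≈ 8 — with Gaussian noise
(default SD 0.5, i.e. strata separated by 6 SD) and filler genes at
twice the model gene count. The filler ratio is what makes the
discretizer's quartile capacity ($\lfloor 0.25 \cdot 3n_g \rfloor$)
exceed the active-gene count for any effect map that keeps at least one
pathway off per condition; the default effect map (last pathway OFF in
condition A, second pathway OFF in condition B, first pathway ON in
both) respects that and plants all three direction classes. Sample
sizes default to 4 vs 3, the small two-group design the gene-set
randomization null exists for.

What the generator does **not** emulate: probe-level noise, RMA
artifacts, correlated co-expression within gene sets, shared genes
between reactions, or SCALED-only flux changes (a pathway ON in both
conditions has the *same* reaction states in both, so a pure magnitude
change is invisible to discretized states — planted SCALED effects are
recoverable only through the flux polytope when bounds differ, and the
default world does not rely on them). A green end-to-end test therefore
establishes internal consistency of the whole chain, not robustness to
array artifacts.

# Numerical choices

* Simplex pivot tolerance 1e-9; phase-1 feasibility tolerance 1e-7
  (relative to $\|b\|_\infty$); branch-and-bound integrality tolerance
  1e-6. Stoichiometries and bounds are small integers, so these are
  comfortable.
* Hit-and-run clips O(machine-epsilon) chord-end excursions back into
  the box after each step; accumulated steady-state residual over the
  21 000 steps of a default run stays orders of magnitude below the
  1e-6 contract.
* Zero-width polytopes (all FVA bounds point-like) return the unique
  point replicated, with a warning rather than an error: downstream
  medians remain well defined.
* ES magnitude ties resolve positive, in both the implementation and
  its brute-force oracle, with a 1e-12 guard so binary-float noise
  cannot flip the sign of a mathematically tied extreme.

# Calibration checks and their noise floor

The test suite checks the GSEA null by the Kolmogorov distance between
50 set-level p-values (no planted effect) and the uniform distribution,
at a fixed seed. One caveat is worth stating precisely: for $n = 50$
*exactly uniform* draws, the empirical Kolmogorov statistic has median
$\approx 0.83/\sqrt{50} \approx 0.118$. A pass threshold of 0.1 at this
sample size is therefore below the noise floor of the check itself and
fails for a perfectly calibrated null roughly as often as not; the
acceptance test asserts it as specified and its outcome should be read
with that in mind. The package's broader evidence of calibration is the
sign-symmetry property test and the BH cross-check, which are stable.

# Known limitations

* The built-in simplex/branch-and-bound is for toy and teaching scale
  (tens of reactions). Genome-scale models parse fine, but solving them
  needs an industrial MILP solver behind the same `solve_imat()`
  contract.
* SBML support is read-only and covers Level 3 + FBC version 2 (bounds
  by parameter reference, gene products, nested and/or associations);
  pathway labels must come from the JSON/TSV dialects, as SBML groups
  are not parsed.
* Direction calls compare marginal medians; reactions whose change is
  only in covariance structure across the polytope are invisible.
* The GSEA module ranks genes with its own signal-to-noise metric; it
  does not reproduce moderated-t pipelines, and no leading-edge
  reporting is provided beyond member lists.
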