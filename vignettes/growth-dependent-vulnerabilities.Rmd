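---
title: "Growth-dependent vulnerability detection: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-dependent vulnerability detection: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemvuln)
```

## The model and its assumptions

A constraint-based metabolic model is the tuple {R, M, S, L, U}. We
assume throughout: (i) mass balance at steady state, `S·v = 0`; (ii)
box constraints `L ≤ v ≤ U` with `L[r] ≤ U[r]`; (iii) a designated
growth reaction `r_g` with `L[r_g] ≥ 0` — a negative growth lower
bound is biologically meaningless here and is clamped to zero with a
warning on load. The sign convention is the usual one: `S[m, r] < 0`
means m is consumed by r running forward.

Flux balance analysis (FBA) gives the growth optimum `μ_max = max
v[r_g]` over that polytope. Flux variability analysis (FVA) with a
growth floor solves, per reaction, the LP pair `min/max v[r]` under the
same constraints plus `γ·μ_max ≤ v[r_g]`, `γ ∈ [0, 1]`. The resulting
intervals `[lbγ, ubγ]` replace L, U to form the growth-constrained
model on which all growth-dependent sets are computed.

Reactant/product roles are direction-aware via star-sets: m is a
*star-reactant* of r if `S[m,r] < 0` and `U[r] > 0` (forward run
possible) or `S[m,r] > 0` and `L[r] < 0` (backward run possible);
star-products mirror this. Chokepoints are unique star-consumers or
star-producers of some metabolite; dead-end metabolites have an empty
star side; a reaction is dead when both bounds are zero. A reaction is
γ-essential when pinning `v[r] = 0` caps the knockout optimum strictly
below `γ·μ_max` (or makes the LP infeasible). Because growth is never
negative, the γ = 0 essential set is empty for any feasible model —
the fact the acceptance target checks.

## Parameters that matter

* `epsilon` (default `1e-6`, flux units): the zero tolerance. Used to
  snap FVA bounds to exact zero *before* classification, for all
  strict sign tests in star-sets and the dead/reversible tests, and as
  the "growth is zero" threshold. The method description is silent on
  tolerances; `1e-6` sits well above HiGHS/simplex feasibility noise
  (~1e-9) and well below the smallest meaningful flux in these models
  (~1e-3). Snapping **before** classification is a documented choice:
  a borderline reversible with `lbγ = -1e-9` becomes non-reversible
  rather than reversible.
* `gamma`: the growth fraction. The floor is implemented exactly as
  the linear constraint `γ·μ_max ≤ v[r_g]` (folded into the lower
  bound of `r_g`, which is equivalent for a single-reaction
  objective), not as an equality at γ = 1, so alternate optima remain
  admissible.
* `epsilon_rel` (default `1e-6`): relative tolerance on the strict
  `< γ·μ_max` essentiality comparison; a knockout that preserves
  exactly the floor is *not* essential.
* `solver`: `"simplex"` (package-authored dense two-phase simplex,
  Bland's rule, deterministic, no RNG) or `"scipy"` (HiGHS through a
  batched python subprocess). The built-in solver clamps infinite
  bounds to ±1e6 and reports an optimum pinned to that clamp on an
  objective variable as unbounded growth. Both backends must agree on
  set membership — this is a tested invariant, not an aspiration.
* `include_boundary` (default `FALSE`): metabolites flagged
  `boundaryCondition="true"` have no enforced mass balance, so
  producer/consumer uniqueness over them is meaningless; they are
  excluded from chokepoint/DEM computation unless this flag is set.
  Reported chokepoint counts for curated models may follow either
  convention, which is why it is a flag and not a constant.
* `gammas` for `run_sweep()`: default `{0, 0.1, …, 0.9, 0.95, 0.99,
  1}` — dense enough to show the dead-set plateau on [0, 1) and the
  jumps at both ends; there is no canonical grid for such sweeps, so
  this one is merely a default and fully configurable.

## Design choices where the design was open

* **FVA is computed once** against the original L, U (as the defining
  LP pair states), never iterated on the updated model. Re-analysis of
  the bound-updated model at the same γ provably reproduces the same
  γ-level sets (the feasible polytope is unchanged); this idempotence
  is an acceptance test. The *blocked* set is the exception: it is
  defined against raw bounds, and the updated model's raw bounds embed
  the γ floor, so its blocked set legitimately grows.
* **Knockout encoding**: `v[r] = 0` is imposed by temporarily setting
  `L[r] = U[r] = 0`; when `0 ∉ [L[r], U[r]]` the knockout LP is
  infeasible by inspection and is reported as such (and infeasibility
  counts as essential at every γ, per the definition).
* **Chokepoint uniqueness counts reaction identities**: a reversible
  reaction that is simultaneously the sole star-producer and the sole
  star-consumer of a metabolite is one chokepoint, not two.
* **Metabolites touched only by dead reactions** have both star sides
  empty and are classified as dead-end metabolites (the definition's
  disjunction is satisfied); the corner is not discussed in the method
  description, so it is pinned by a test here.
* **Dead-end removal cascades**: any reaction touching a dead-end
  metabolite can carry no steady-state flux, so removing the
  metabolite also empties that reaction's stoichiometry (the reaction
  is retained and flagged `orphaned`, keeping R stable for set
  comparisons). This is what makes removal iterate: a metabolite whose
  only consumer was such a reaction becomes a dead end on the next
  pass, until a fixpoint.
* **Multiple nonzero fbc objective coefficients** are refused with an
  instruction to pass `objective` explicitly; silently summing fluxes
  would change the meaning of μ_max.
* **Spreadsheet format is TSV** (plus self-contained HTML). No xlsx
  writer is available in the dependency budget, and TSV diffs cleanly
  in version control; the schema (a `summary` table and a long-format
  `memberships` table) is this package's own.

## What the synthetic generator emulates — and what it does not

`make_fixture()` builds exchange → internal pathway(s) → biomass
networks: `n_parallel_paths` redundant routes with per-path exchange
capacities (the redundancy knob controlling the size of
R − ERγ − DRγ), a `reversible_fraction` of internal links opened to
negative flux, an optional planted produced-never-consumed metabolite
(whose producer is then necessarily blocked — the classic dead-end
pattern), and an optional bound-dead reaction. Backbone stoichiometry
is unit-weight so exchange capacities translate directly into μ_max
(two paths with capacities 3 and 4 give μ_max = 7); redundant padding
edges may carry weight 2. Feasibility holds by construction — paths
are laid down first, so rejection sampling is never needed — and
generation is deterministic given `seed` without disturbing the global
RNG stream.

These fixtures exercise every definition, lemma-style property and
corner the test suite needs, but they are *not* realistic GEMs: no
cofactor coupling, no compartments, no thermodynamic consistency, and
sizes of tens rather than thousands of reactions. A green test
establishes that the definitions are computed correctly and the
theory's set relations hold; it does not validate predictions on any
real organism. The *P. falciparum* case study (twelve reference set
sizes for the published model iAM-Pf480) is wired into the acceptance suite but requires supplying the
iAM-Pf480 SBML file, which cannot be redistributed here; that test is
red in its absence by design.

A second, deliberately naive implementation (`brute_force_sets()`)
recomputes every set by literal evaluation — double loops over
(metabolite, reaction) pairs, one LP per definition, a different LP
backend — and equality with the main path on every fixture is the
oracle acceptance criterion.

## Numerical notes and known limitations

* The built-in simplex is dense and O(iterations × rows × columns) per
  LP: fine for ≤ ~50 reactions, wrong tool for genome scale. Use
  `solver = "scipy"` there; FVA/knockout batches are shipped to one
  subprocess per batch, so the python startup cost is paid once per
  operation, not per LP.
* Degenerate ties in the simplex are broken by Bland's rule (lowest
  index), so results are deterministic and cycling-free.
* `μ_max < epsilon` is treated as exactly zero growth; the γ floor is
  then vacuous and a sweep collapses to γ = 0 with a warning.
* A fixture knockout example worth recording: with parallel paths of
  capacity 3 and 4 (μ_max = 7), at γ = 4/7 the capacity-4 path *is*
  γ-essential (its knockout leaves growth 3 < 4) while the capacity-3
  path is not; neither is essential at γ = 3/7. Intuition about
  "redundant paths are never essential" fails once γ exceeds the
  complement's capacity share.
* Gene–protein–reaction rules, double knockouts, parsimonious FBA,
  loopless FVA and Petri-net rendering are out of scope.
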