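---
title: "Relatedness-controlled multi-trait selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness-controlled multi-trait selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The selection problem

A breeding program has `n` candidate genotypes, each with best linear
unbiased estimates (BLUEs) for `p0` traits, and must advance exactly `s`
of them. Truncation on an index of genetic merit alone tends to pick
close relatives — the best candidates in a panel are often sibs — which
erodes genetic diversity, raises inbreeding, and undermines future
selection response. `mtselect` treats the choice as a constrained binary
optimization that prices relatedness explicitly.

Write `y_ji` for the standardized, direction-adjusted score of candidate
`i` on trait `j`, `G` for the genomic relationship matrix, and
`x ∈ {0,1}^n` for the selection indicator. The quadratic index (QPMSI)
maximizes

    Z = Σ_j Σ_i y_ji x_i  −  k · xᵀ G x

subject to

    Σ_i x_i = s                      (exactly s selected)
    Σ_i y_ji x_i ≥ l_j  for each j   (per-trait minimum gains)

with `l_j = R_j · s / 100`. The first term is the group's summed
standardized merit; the second grows when related candidates are
co-selected (both `x_i` and `x_j` set with `G_ij` large), so maximizing
`Z` trades gain against co-ancestry. The linear baseline (LPMSI) drops
the quadratic term and maximizes merit under the same constraints.

Two modelling points deserve emphasis:

* **The zero-gain base case still constrains.** `R_j = 0` gives
  `l_j = 0`, which requires each trait's summed standardized score over
  the selected group to be *nonnegative* — it does not remove the
  constraint. Because standardized scores are centred, a merit-best
  subset can fail this floor on a neglected trait, and the solvers
  honour that.
* **Both objective and constraints consume the standardized,
  direction-adjusted scores.** Standardization (step 1) makes traits
  commensurable; negating lower-is-better traits (step 2) makes "higher
  is more favourable" uniform. The preprocessing order is part of the
  method: raw BLUEs never enter the optimization.

## Preprocessing conventions

`standardize_traits()` uses the sample standard deviation (denominator
`n − 1`) by default, matching the convention of the common statistical
stacks that produce BLUE tables; a `sd_type = "population"` switch is
provided. Non-finite BLUEs are a hard error by default — silently
dropping or imputing a genotype would change every `l_j` comparison —
with an explicit opt-in to drop offending genotypes with a warning.
Trait polarity is configuration, never inferred from data: only the
breeder knows whether plant height is a target or a defect.

## The genomic relationship matrix

`compute_grm()` defaults to `G = W Wᵀ / p` where `W` has column-wise
z-scored dosages and `p` is the marker count — the literal reading of a
"scaled marker matrix" cross-product. Under this scaling `G` has zero
row sums and trace `n − 1`, both of which the tests pin. The classic
VanRaden method-1 allele-frequency form (centring by `2p̂_j`, dividing
by `2 Σ p̂_j(1 − p̂_j)`) is available as `scaling = "vanraden_freq"` for
compatibility with pipelines that expect it; the two differ by a
marker-weighting and an overall scale, and the choice propagates into
the size of `k`'s effect. Monomorphic markers error by default (dropping
them silently would change `p` and rescale `G`). Any numeric dosage
coding works, since centring removes the offset.

Externally supplied `G` matrices go through `validate_grm()`:
asymmetry up to `1e−6` is averaged away, worse asymmetry errors;
minimum eigenvalues in `[−1e−4, −1e−8)` warn (numerical PSD slack),
worse errors; rows/columns are reordered to the trait table's id order.

# The exact solver

The quadratic program is a cardinality-constrained binary quadratic
maximization — NP-hard in general, but small-to-moderate breeding panels
are well within reach of exact search. `solve_qpmsi(method = "exact")`
runs a purpose-built branch-and-bound:

* Candidates are ordered by decreasing adjusted linear coefficient
  `d_i = c_i − k G_ii` (the diagonal enters linearly because
  `x_i² = x_i`), and the search branches include-first, so its first
  leaf is the unconstrained top-`s` set — immediately a strong
  incumbent.
* At each node the remaining budget `r` is bounded by assigning every
  free candidate its best case: its adjusted merit minus half the sum of
  its `r − 1` smallest remaining pairwise penalties `2k G_ij`. Summing
  the `r` largest such scores never underestimates the subtree optimum,
  so pruning on it is admissible and the returned solution is provably
  optimal.
* A second prune discards nodes whose `r` best remaining per-trait
  scores cannot reach a gain threshold — infeasibility is detected, not
  guessed.
* Ties within `1e−9` resolve to the lexicographically smallest index
  set, making results deterministic and making the exact solver and the
  enumeration oracle comparable set-by-set, not just value-by-value.

The solver is verified against `brute_force_select()`, a deliberately
independent pure-R path that enumerates all `C(n, s)` subsets
(`utils::combn`) and shares no code with the C++ search; the test suite
and the acceptance script both require objective *and selected-set*
agreement on hundreds of random instances. A seeded greedy-plus-swaps
`method = "local_search"` is provided for panels too large for exact
search; it labels its results `status = "heuristic"` and never claims
optimality.

Numerical conventions: constraint feasibility `1e−6`, objective
comparisons and tie detection `1e−9`, no optimality gap (the search is
exact). Infeasibility is a first-class result (`status = "infeasible"`
plus a diagnostic naming any single trait whose threshold even the
top-`s` genotypes on that trait cannot meet), not an exception — a
too-demanding `(s, k, R)` is a legitimate outcome, and the recommended
fallback is the linear index.

## What the theory guarantees (and the tests assert)

For exact solutions over the same feasible set with `k > 0`:
`merit(QPMSI) ≤ merit(LPMSI)` and `xᵀGx(QPMSI) ≤ xᵀGx(LPMSI)` — the
linear optimum is QPMSI-feasible, so the quadratic optimum can only
trade merit *down* in exchange for penalty. Consequently `M` and `V`
orderings between the two indices are theorems, not empirical patterns,
and the suite asserts them on every random instance. At `k = 0` the
objectives coincide and only merit equality is guaranteed (tie-breaking
may pick any penalty). Along an increasing `k` grid, both the optimal
penalty and the optimal merit are non-increasing.

# Evaluation metrics

For a selected set of size `s`: `M = Σ y_ji x_i / (s·p0)` (mean gain on
the standardized scale), `V = xᵀGx / s²` (variance of the group mean —
all `s²` submatrix entries, diagonal included, matching the penalty term
up to `1/s²`), `MV = M / √V` (gain per unit relatedness; undefined when
`V ≤ 0`), and `MR` = mean of the strictly-upper-triangle entries of the
selected `G` submatrix (pairwise relatedness only; undefined at
`s = 1`). Undefined values are flagged, never silently zeroed.

Relative efficiency compares methods on one metric: the best method is
the maximum for `M` and `MV` and the minimum for `V` and `MR`, and
`RE = (best/q − 1)·100` or `(q/best − 1)·100` respectively. The ratio
form is ill-behaved when values straddle zero — `MR` is legitimately
negative for well-spread selections under zero-row-sum scaling — so such
entries are computed verbatim but flagged `unreliable_sign_change`
rather than redefined. Reports print three decimals; full precision is
kept internally.

# The simulator

No public fixture reproduces the relevant structure at test scale, so
`simulate_dataset()` generates it: full-sib families (two
Binomial-sampled parents per family, offspring by per-locus Mendelian
transmission) create block-structured relatedness, and marker effects
drawn with a target inter-trait correlation create genetically
correlated traits. `h2` mixes the unit-variance genetic value with
independent noise, playing the role of BLUE estimation accuracy.

Defaults — 5 families × 10 sibs, 500 markers with founder frequencies in
(0.1, 0.9), four traits at pairwise genetic correlation 0.3, `h2 = 0.7`
— describe a small breeding panel with moderately correlated traits:
trait correlations in the public panels this emulates span roughly 0 to
0.96, and 0.3 sits in the moderate regime most of them occupy; `h2 =
0.7` reflects BLUEs from replicated trials, informative but not
noise-free. Markers that come out monomorphic are redrawn so every
generated dataset standardizes cleanly.

What the simulator does *not* emulate: linkage disequilibrium,
multi-generation pedigrees, selection history, genotype-by-environment
structure, or trait architectures with major genes. Tests passing on
simulated sib families therefore demonstrate correctness of the
optimization and calibration of the generator — not that any particular
real panel will show a specific effect size.

Calibration checks (asserted in the suite and recomputed by the
acceptance script): sample genetic-value correlations recover the 0.8
target within ±0.1 at `n = 500`; mean within-family off-diagonal
relatedness exceeds between-family in ≥95/100 replicates at the default
setting; at `h2 → 0` a permutation association test between traits and
kinship is non-significant at the nominal rate. End-to-end, on 100
seeded replicates at `n = 50, s = 10, k = 1`, the quadratic index's
`MR` is at or below the linear index's in well over 90 — the
relatedness control the method exists to provide.

# Problem sizes and reproducibility

The test suite exercises exact/oracle equivalence at `n ≤ 15` (where
enumeration is cheap) and end-to-end behaviour at `n = 50, s = 10`,
where a branch-and-bound solve takes a few hundredths of a second;
panels in the few-hundreds of candidates remain practical, and the
heuristic path covers larger ones. All simulation draws derive from a
single seed (per-stage sub-seeds are derived deterministically), exact
solver paths ignore seeds entirely, and report files are byte-identical
across reruns of the same configuration.

# Known limitations

* The branch-and-bound bound weakens when `k` is very large and `G`
  dense with near-equal entries; pathological instances can approach
  enumeration cost. A node-limit parameter exists and returns
  `status = "time_limit"` rather than a silent wrong answer.
* Relative efficiency on metrics that straddle zero (often `MR`) is
  reported with flags; cross-study comparisons of such percentages are
  not meaningful.
* Optimal contribution selection — continuous contributions rather than
  a fixed `s` — is out of scope; the indices here select sets.
* BLUE estimation, imputation, and LD pruning belong upstream.
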