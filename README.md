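# mtselect

Multi-trait genomic selection indices with explicit control of genomic
relatedness.

## The problem

Breeding programs advance a fixed number `s` of candidates per cycle,
judged on several traits at once. Ranking on genetic merit alone tends
to advance close relatives — the top of a panel is usually dominated by
a few good families — which erodes genetic diversity and compounds
inbreeding across cycles. `mtselect` poses the choice as a constrained
binary optimization over the selection indicator `x ∈ {0,1}ⁿ`:

**QPMSI** (quadratic-programming multi-trait selection index)

    maximize   Z = Σⱼ Σᵢ y_ji xᵢ − k · xᵀ G x
    subject to Σᵢ xᵢ = s,   Σᵢ y_ji xᵢ ≥ l_j  for every trait j

where `y_ji` are standardized, direction-adjusted trait scores, `G` is
the genomic relationship matrix built from marker dosages
(`G = WWᵀ/p` with column-scaled `W`, or VanRaden allele-frequency
scaling), `k ≥ 0` prices relatedness against gain (`k = 1` weighs them
equally), and `l_j = R_j·s/100` encodes a per-trait minimum desired
gain `R_j` in percent. **LPMSI**, the linear baseline, maximizes the
merit term alone under the same constraints.

The exact solver is a purpose-built branch-and-bound (Rcpp) with
admissible bounds and deterministic tie-breaking, verified against an
independent exhaustive-enumeration oracle; a seeded local-search
heuristic covers panels too large for exact search. Selections are
scored by four metrics — mean gain `M`, variance of the group mean
`V = xᵀGx/s²`, gain-to-relatedness ratio `MV = M/√V`, and mean pairwise
relatedness `MR` — with relative-efficiency comparisons across methods.
A sib-family simulator generates marker and correlated multi-trait BLUE
data with known structure for testing and calibration.

## Worked example

Simulate a panel of 5 full-sib families × 10 sibs with four correlated
traits, build `G`, and compare the quadratic index over a `k` grid
against the linear baseline, selecting `s = 10`:

```r
library(mtselect)

cfg <- simulation_config(n_families = 5, family_size = 10,
                         p_markers = 500, seed = 42)
ds  <- simulate_dataset(cfg)
y   <- adjust_direction(standardize_traits(ds$traits))
G   <- compute_grm(ds$markers)
pr  <- selection_problem(y, G, selection_spec(s = 10, k = 1, R = 0))

compare_methods(pr, k_grid = c(0.5, 1, 1.5))
#>       method   k  status     M     V    MV     MR
#> 1      LPMSI 0.0 optimal 1.230 0.323 2.164  0.243
#> 2 QPMSI_k0.5 0.5 optimal 1.136 0.169 2.765  0.074
#> 3   QPMSI_k1 1.0 optimal 0.982 0.076 3.562 -0.028
#> 4 QPMSI_k1.5 1.5 optimal 0.982 0.076 3.562 -0.028
```

Reading the table: the linear index extracts the most raw gain
(`M = 1.230`) but takes 8 of its 10 picks from a single family
(`MR = 0.243`). At `k = 1` the quadratic index gives up about 20% of
the mean gain, spreads its picks over all five families, and drives
mean pairwise relatedness *negative* (`MR = −0.028`, i.e. the selected
pairs are less related than the panel average) — so per unit of
accumulated relatedness it is 64.6% more efficient:

```r
compare_methods(pr, k_grid = c(0.5, 1, 1.5))$efficiency$MV
#> relative efficiency on MV (best: QPMSI_k1)
#>   LPMSI              64.59%
#>   QPMSI_k0.5         28.81%
#>   QPMSI_k1            0.00%
#>   QPMSI_k1.5          0.00%
```

A single run returns the selected ids and the objective decomposition:

```r
solve_qpmsi(pr)
#> selection_result [qpmsi_exact, k = 1]: status optimal
#>   s = 10, Z = 31.6854 (merit 39.2897, penalty 7.60427)
#>   selected: F01_003, F02_004, F02_009, F03_001, F04_006, ...
```

An over-demanding configuration (large `k` with tight per-trait gains)
returns `status = "infeasible"` with a diagnostic instead of an error;
the linear index is the recommended fallback in that case.

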