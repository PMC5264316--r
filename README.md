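# poets

Multiobjective simulated annealing for estimating *ensembles* of model
parameters on or near the optimal trade-off surface between conflicting
training objectives.

Biochemical models are rarely identifiable from a single data set, and
real training data — different cell lines, labs, reagent lots — are often
mutually inconsistent. Fitting one "best" parameter set to pooled data
hides those conflicts. `poets` instead treats each data set (or any other
error criterion) as its own objective and searches for the family of
parameter sets that optimally trades the objectives off against each
other, giving robust predictions with uncertainty bands plus individual
members that excel on each single objective.

## The algorithm

Given a decision vector `p` with box bounds `L ≤ p ≤ U`, optional
inequality constraints `g_i(p) ≥ 0`, and a user objective returning a
K-vector of errors `O(p) = (O_1, …, O_K)`, the package solves

```
min_p (O_1(p), …, O_K(p))
```

with a simulated-annealing loop whose "energy" is the **Fonseca–Fleming
Pareto rank**: the number of archived solutions that dominate the
candidate (rank 0 = nondominated). A candidate at iteration `i+1` is
accepted with probability

```
P(p_{i+1}) = exp( − rank(O(p_{i+1}) | O_i) / T )
```

so nondominated candidates are always accepted while higher-rank moves
survive early, high-temperature exploration. Accepted candidates with
rank below a cutoff (default 5, i.e. rank ≤ 4) enter a column-aligned
archive `(S, O, R)` of decision vectors, objective vectors and ranks,
which is re-ranked and filtered after every insertion. The temperature
cools geometrically (`α = 0.9` by default) until it passes
`temperature_min`. Constraints enter through a penalty term
`λ · Σ_j max(0, −g_j)` added to every objective (`λ = 100` by default).
An optional *hybrid mode* periodically collapses the problem to the
scalar objective sum and polishes the best archive member with a bounded
local search. Multistart runs partition the search domain, anneal from
one draw per partition, and re-rank the pooled archives jointly.

The package also ships a proof-of-concept application: a hybrid
cybernetic model (HCM) of a small metabolic network — 6 metabolites,
7 reactions, elementary-mode decomposition, pseudo-enzyme dynamics with
cybernetic controls `u` (synthesis allocation, Σu = 1) and `v` (activity,
max v = 1) — plus a generator of conflicting synthetic training data and
ensemble trajectory summaries.

## Worked example

Enumerate the elementary modes of the canonical demo network:

```r
library(poets)
enumerate_elementary_modes(canonical_network())
#> elementary mode set: 6 modes over 7 reactions
#>   em1: {r1,r2,r3,r6}  substrate = A_e  growth flux = 0
#>   em2: {r1,r2,r3,r7}  substrate = A_e  growth flux = 1
#>   em3: {r1,r2,r4}  substrate = A_e  growth flux = 0
#>   em4: {r3,r5,r6}  substrate = B_e  growth flux = 0
#>   em5: {r3,r5,r7}  substrate = B_e  growth flux = 1
#>   em6: {r4,r5}  substrate = -  growth flux = 0
```

Six support-minimal balanced pathways: three growing on or converting
substrate A_e, two on the secreted intermediate B_e, and one futile
exchange cycle that the cybernetic controls silence.

Recover the trade-off front of a classic bi-objective benchmark
(`O_1 = x²`, `O_2 = (x−2)²`, optimal set `x ∈ [0, 2]`):

```r
arch <- run_multistart(test_problem("schaffer"), n_partitions = 10,
                       config = sa_config(steps_per_temperature = 10,
                                          rng_seed = 42))
arch
#> ensemble archive: 2421 members, D = 1, K = 2
#> rank counts: 0:2416 1:2 2:2 3:1
#> objective minima: 9.0956e-08 7.0096e-07
range(arch$S[1, arch$R == 0])
#> [1] 3e-04 2.0008
```

Every archived member has rank ≤ 4; the nondominated members span the
analytic Pareto set almost exactly.

The end-to-end biochemical demo generates four conflicting data sets
(same network, per-data-set kinetic constants), identifies the
13 kinetic parameters against all four objectives at once, and
summarizes the ensemble:

```r
res <- poets_demo(seed = 1)
res$archive
#> ensemble archive: 169 members, D = 13, K = 4
#> rank counts: 0:80 1:33 2:22 3:19 4:15
#> objective minima: 14.125 5.7226 6.1596 9.2574
head(res$band, 3)
#>   time species      mean     lower     upper
#> 1  0.0     A_e 10.000000 10.000000 10.000000
#> 2  0.8     A_e  9.872382  9.818589  9.918824
#> 3  1.6     A_e  9.694239  9.595996  9.800963
```

No single member minimizes two conflicting objectives at once, yet the
ensemble's 95% trajectory band brackets the across-data-set measurement
means, and `select_top_fraction(res$archive)` pulls out the members that
describe each data set individually.

A thin command-line wrapper (`inst/cli/poets.R`) exposes the same
workflows as `run`, `demo`, `rank` and `summarize` subcommands writing
aligned CSV archives (`S.csv`, `O.csv`, `R.csv`) plus a JSON metadata
echo.

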