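---
title: "Pareto-ensemble estimation by rank-based simulated annealing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-ensemble estimation by rank-based simulated annealing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poets)
```

This vignette is the package's own account of the science it implements:
the multiobjective annealing algorithm, the penalty handling of
constraints, the benchmark problems, the hybrid cybernetic model behind
the biochemical demo, the synthetic-data generator, and the numerical
and design choices that shape all of them.

## The estimation problem

Deterministic models of biochemical systems are chronically
under-determined: many parameter sets fit a given data set about equally
well, and data sets collected under different conditions usually
conflict. Rather than a single best fit, we estimate an *ensemble* — a
family of parameter sets on or near the optimal trade-off surface
between $K$ training objectives:

$$\min_{\mathbf p}\;\bigl(O_1(\mathbf p),\dots,O_K(\mathbf p)\bigr),
\qquad \mathcal L \le \mathbf p \le \mathcal U,\qquad
g_i(\mathbf p)\ge 0,\; i = 1,\dots,C,$$

where each $O_j$ is typically the sum of squared residuals against one
data set and the objective function is free to solve whatever model
equations it needs internally (here, an ODE system).

## Rank-based annealing

A candidate's quality is its **Pareto rank**: the number of archived
objective vectors that dominate it, where domination means no worse in
every component and strictly better in at least one (the
Fonseca–Fleming counting scheme). Rank replaces the scalar energy of
classical simulated annealing; the acceptance probability is

$$\mathcal P(\mathbf p_{i+1}) = \exp\{-\mathrm{rank}(\mathbf
p_{i+1})/T\},$$

evaluated against the archive *before* the candidate is inserted. A
fresh uniform draw decides acceptance (`accept iff u ≤ P`), so rank-0
candidates are always accepted and high-rank candidates survive only
while the temperature is high. Acceptance (which moves the working
point) is deliberately separate from archiving: only candidates with
rank strictly below `rank_cutoff` are stored, after which the archive is
re-ranked and filtered so its largest rank never exceeds
`rank_cutoff - 1`. With the default cutoff 5 this yields the "rank ≤ 4"
archive rule; we read the admission test as a strict inequality because
that is the only reading consistent with both the default cutoff value
and the stated rank bound. Duplicate objective vectors do not dominate
each other, so duplicates share a rank and are retained — the archive's
density carries information.

Two related subtleties are worth stating. Ranks are compared with exact
floating-point comparisons, no epsilon: near-ties are resolved by the
stochasticity of the search, not by a tolerance. And ranks computed
within one run are meaningless for a pooled collection, so
`rerank_combined()` concatenates archives, recomputes all ranks jointly
and re-applies the filter; `run_multistart()` does this automatically.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `initial_temperature` | 1.0 | starting temperature; with rank-valued energies, $e^{-\text{rank}}$ makes the early search permissive |
| `cooling_alpha` | 0.9 | geometric cooling factor per temperature level |
| `temperature_min` | 0.001 | stop once $T$ falls below this |
| `steps_per_temperature` | 20 | proposals evaluated at each level |
| `rank_cutoff` | 5 | archive admits rank < cutoff |
| `penalty_lambda` | 100 | weight of the constraint-violation penalty |
| `neighbor_scale` | 0.1 | Gaussian step s.d. as a fraction of each bound interval |

The initial temperature and neighbour scale are not dictated by the
method; 1.0 and 10% of the box width are our defaults, chosen for a
permissive early search and a proposal step that balances exploration
against acceptance. Both are plain configuration values.

The default neighbour adds an independent Gaussian step per coordinate
(s.d. `neighbor_scale` times the interval width) and clips to the box,
so bound constraints are structural. Nonlinear constraints use a penalty
transform that adds $\lambda\sum_j\max(0, -g_j)$ — the total violation
magnitude under the $g \ge 0$ convention — to *every* objective
component. A violation must make a point worse, so the violation
magnitude is added; the same additive term is applied to all $K$
objectives. Feasible points are untouched, and any evaluation that
fails or returns non-finite values is mapped to $+\infty$ in all
components so an ODE solver failure can never poison the archive.

### Hybrid refinement

Hybrid mode periodically collapses the search to the scalar sum
$\sum_j O_j$ and polishes the archive member currently minimizing that
sum with a bounded local search, re-injecting the result as the working
point. We refine once per temperature drop — a bounded extra cost that
matches the "temporarily switches to a single objective" idea. The
refiner is Nelder–Mead on a closure that clips proposals into the box
before evaluation (`stats::optimize` on the interval for 1-D problems),
with a non-degrading guard: if the polished point is not at least as
good, the start point is returned. Refinement budget (`maxit`, default
200) is the knob that trades polish depth against objective-evaluation
cost; the parameter-recovery workflow below uses 1000.

### Multistart

The first coordinate's bound interval is split into `n_partitions`
equal segments; one initial guess is drawn uniformly per segment
(remaining coordinates uniform over their full ranges), each start runs
with a seed derived as `rng_seed + start_index`, and the per-start
archives are pooled and re-ranked jointly. Partitioning a single
designated coordinate reproduces the 1-D protocol exactly and
generalizes predictably to higher dimension; all stochasticity flows
from the one master seed, so repeated runs are bit-identical.

## Benchmark suite

Three classic bi-objective problems with known fronts anchor the tests:

* **Schaffer** (D = 1 on $[-10,10]$): $O_1 = x^2$, $O_2 = (x-2)^2$;
  Pareto set exactly $x\in[0,2]$, front $O_2 = (\sqrt{O_1}-2)^2$.
* **Binh–Korn** (D = 2 on $[0,5]\times[0,3]$): quadratic objectives with
  two disc constraints, handled by the penalty method. We use the
  standard constraint orientation — stay inside the disc of radius 5
  around $(5,0)$ and outside the disc of radius $\sqrt{7.7}$ around
  $(8,-3)$: written with both inequalities pointing the same way the
  second disc would exclude the entire domain (its nearest domain point,
  $(5,0)$, is at squared distance 18 > 7.7), leaving an empty feasible
  set, so the outside orientation is the only solvable reading and the
  one whose front matches the published trade-off curves. The second
  domain line is read as a bound on $y$.
* **Fonseca–Fleming** (D = 3 on $[-4,4]^3$):
  $O_{1,2} = 1-\exp(-\sum_i (x_i \mp 1/\sqrt3)^2)$; Pareto set is the
  diagonal segment $x_1=x_2=x_3=t$, $t\in[-1/\sqrt3,1/\sqrt3]$.

`front_distance()` supplies the oracle used in testing: the closed-form
front residual for Schaffer, the objective-space distance to a dense
parameterization of the diagonal curve for Fonseca–Fleming, and the
distance to a cached polyline obtained by nondominated filtering of a
dense feasible grid for Binh–Korn, which has no convenient closed form.

## The hybrid cybernetic demo model

The biochemical demo reconstructs a prototypical network of six
metabolites and seven irreversible reactions: uptake $A_e\to A$, chain
$A\to B\to C$, reversible $B/B_e$ exchange modelled as two irreversible
reactions, secretion $C\to C_e$, and growth $C\to$ cellmass.
Intracellular $A,B,C$ are balanced; $A_e,B_e,C_e$ are dynamic. This
reconstruction is a design decision anchored to the printed facts (six
metabolites, seven reactions, balanced $A,B,C$, six elementary modes);
the exact published reaction diagram is figure-only, so every
mode-dependent test is anchored to this canonical network.

**Elementary modes.** The network is decomposed into support-minimal,
chemically balanced steady-state flux vectors. For small networks
($R \le 15$) exhaustive support testing *is* the algorithm: every
reaction subset is tested for a one-dimensional steady-state null space
(via SVD, tolerance $10^{-10}$) whose vector has full support, a
consistent sign on irreversible reactions, and no qualifying proper
sub-support. The canonical network yields exactly six modes, including
one uptake-free futile cycle ({r4, r5}). Columns are normalized so each
mode's *net* substrate uptake equals one ($z_{s,l}=1$); the futile
cycle, with zero net uptake, is scaled to unit maximum entry and
assigned $z_{s,l}=0$, which silences it in the control laws below.
Using net rather than gross uptake is what makes the futile cycle
"uptake-free" even though one of its reactions consumes $B_e$.

**Dynamics.** Each mode $l$ is catalyzed by a pseudo-enzyme $e_l$ with
regulated rate

$$\bar q_l = k_l\, e_l\, \frac{s_l}{K_{sat,l}+s_l},\qquad
q_l = v_l\,\bar q_l,$$

where $s_l$ is the mode's uptake substrate concentration (saturation
kinetics is stated for the original model; the Monod form in the mode's
own substrate is our concrete choice). With weights
$w_l = z_{s,l}\bar q_l$, the cybernetic controls are
$u_l = w_l/\sum w$ (enzyme-synthesis allocation, $\sum u = 1$) and
$v_l = w_l/\max w$ (activity, $\max v = 1$), with $u=v=0$ when every
weight vanishes. The balances are

$$\frac{dx_i}{dt} = \sum_{j}\sum_{l}\sigma_{ij}z_{jl}q_l\,c,\qquad
\frac{de_l}{dt} = \alpha_l + r_{E,l}u_l - (\beta_l + r_G)e_l,\qquad
\frac{dc}{dt} = r_G\,c,$$

with growth rate $r_G=\sum_l z_{\mu l}q_l$ and regulated enzyme
synthesis $r_{E,l}=k_E\,s_l/(K_{sat,l}+s_l)$ (the synthesis saturation
constant is shared with the uptake kinetics — one fewer free parameter
per mode, and the paper's "13 model parameters" count admits no
extras). Initial conditions: $x_0=(10,0,0)$, $c_0=0.05$, $e_l=0.5$
(only the enzyme level is printed in the source description; the others
are our defaults in arbitrary concentration units).

**Decision vector.** Identification exposes
$\mathbf p = (k_1..k_6,\,K_{sat,1}..K_{sat,6},\,k_E)$ — 13 continuous
variables, the smallest natural parameterization reproducing the stated
count — with $\alpha_l=0.001$, $\beta_l=0.05$ fixed, and default bounds
$[0.01, 5]$ on every coordinate.

**Integration.** `deSolve::lsoda` with relative tolerance $10^{-6}$ and
absolute $10^{-8}$; states are clamped at zero inside the rate
evaluation so solver undershoot cannot produce negative concentrations
or rates. The derivatives are implemented twice — in C for speed (the
default) and in R — and the two are cross-checked against each other in
the tests; networks too large for the compiled parameter buffer fall
back to the R path automatically.

## Synthetic training data

`generate_synthetic_datasets()` emulates the study design of measuring
the same species on several cell types that share topology but differ
in performance: per data set, every mode rate constant is multiplied by
an independent lognormal factor with coefficient of variation
`kinetic_cv` (default 0.25), the model is simulated, and multiplicative
lognormal measurement noise with CV `noise_cv` (default 0.05) is
applied. Lognormal factors keep rates positive and make the noise
relative, which matches how concentration measurements err; both CVs
are our choices since the source describes only "randomly varying" the
kinetics. The measurement grid `seq(0, 16, 0.8)` (21 points) was fixed
from the true-parameter trajectory alone so that both substrate phases
($A_e$ consumption, then the secreted $B_e$) and the final growth
plateau fall inside the window. Mean-one corrections
($\text{meanlog} = -\sigma^2/2$) keep the perturbations unbiased.

What this generator does *not* emulate: structural model error (the
fitted model class always contains each generating model), correlated
noise, missing observations, and non-stationary measurement error. A
passing recovery test therefore demonstrates the estimator's behaviour
under conflict and noise, not robustness to model misspecification.

Each data set contributes one objective,
$O_j=\sum_i\sum_\tau (x_i(\tau)-y_i(\tau))^2$ over the four observables
(three extracellular species and cellmass), all sharing a single model
simulation per candidate.

## Ensemble summaries

`ensemble_band()` simulates every archive member and reports, per time
point and observable, the ensemble mean and a 95% band. The default
band spans the ensemble 2.5/97.5 percentiles. We deliberately do *not*
default to the standard error of the mean: with $A$ archive members the
SE band shrinks like $1/\sqrt A$ toward zero width, while the
ensemble-mean-to-data-mean distance is bounded below by the compromise
the conflicting objectives force, so the SE band stops covering the
data at exactly the archive sizes where the ensemble is most
informative — at reference ensemble sizes in the thousands it would be
two orders of magnitude thinner than the ensemble spread. The spread
band is the quantity that brackets the training data; `"stderr"` and
`"sd"` (mean ± one ensemble s.d., for best-member overlays) remain
available.

`select_top_fraction()` implements the subsampling used to ask whether
the ensemble contains members that describe each data set individually:
keep members with rank ≤ 1 that fall in the best 25% of at least one
objective, and tag the single best member per objective.

## Numerical choices, degenerate inputs, limitations

* **Ties and duplicates** never dominate; archives may contain exact
  duplicates by design.
* **Degenerate bound intervals** (upper = lower) freeze that coordinate
  in the neighbour proposal.
* **Empty archives** rank to an empty vector; a candidate against an
  empty archive has rank 0.
* **Zero-temperature-step configurations**
  (`temperature_min ≥ initial_temperature`) return an archive holding
  only the evaluated initial point.
* **All-zero cybernetic weights** (no substrate or no enzyme anywhere)
  return $u=v=0$ rather than dividing by zero.
* **Problem scale.** The bundled workflows are sized for a laptop CPU:
  benchmark front recovery uses 10 partitions × 10 steps per
  temperature; the demo identification uses 4 partitions × 20 steps to
  `temperature_min = 0.01`; the single-objective recovery run uses
  hybrid mode with a 1000-iteration refiner. These produce archives of
  order $10^2$–$10^3$ members rather than the $10^4$ of a full study,
  which widens percentile bands slightly and leaves the front sparser;
  all qualitative behaviour is unchanged.
* **Exhaustive mode enumeration** is exponential in reaction count and
  guarded at 15 reactions; large-network enumeration (double
  description at scale) is out of scope.
* **Identifiability** is not addressed: the ensemble is constrained by
  model performance, not by confidence that true parameter values lie
  within it. The futile-cycle parameters $(k_6, K_{sat,6})$ are exactly
  non-identifiable in the canonical model — the silenced mode carries no
  flux — and simply remain at whatever values the search visits.
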