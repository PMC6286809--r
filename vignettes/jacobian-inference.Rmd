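---
title: "Inferring directed metabolic networks from steady-state covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed metabolic networks from steady-state covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Replicate measurements of a metabolome at steady state are never identical:
intrinsic molecular noise makes concentrations fluctuate around their
steady-state values, and the covariance of those fluctuations carries the
imprint of the interaction network. Writing the mole balances as
$dC/dt = f(C)$ and linearizing around the steady state $C_s$ with
$X = C - C_s$ gives $dX/dt \approx JX$, where
$J_{ij} = \partial (dC_i/dt) / \partial C_j$ is the Jacobian: a nonzero
$J_{ij}$ is a directed influence of metabolite $j$ on metabolite $i$, its
sign distinguishing activation from inhibition. Adding white-noise forcing
of intensity $\sqrt{2 D_i}$ per metabolite turns this into a Langevin
system whose stationary covariance $C$ obeys the Lyapunov equation

$$ J C + C J^\top = -2 D . $$

`lyapnet` solves the inverse problem: given the sample covariance of
replicate data and a diagonal fluctuation matrix $D$, recover the sparse
sign structure of $J$. The equation is underdetermined in this direction
($C$ has $n(n+1)/2$ independent entries, $J$ has $n^2$), so additional
structure must be imposed. Vectorizing (column-major throughout this
package) gives a linear system

$$ A\,j + 2 d = 0, $$

with $A$ an $n^2 \times n^2$ matrix assembled from $C$, $j =
\mathrm{vec}(J)$ and $d = \mathrm{vec}(D)$. Fixing a candidate support (a
bitstring over the $n^2$ positions) removes the zero entries of $j$ and
the matching columns of $A$; the surviving coefficients are then an
ordinary least-squares fit, and its Euclidean residual measures how well
that structure explains the data.

## The search

Metabolic networks are sparse — the small networks we examined all have
Jacobian sparsity above 0.55 — so the search maximizes a dual objective
over structures:

$$ f = (\text{number of zeros}) \times \lambda - \log_{10} \lVert A_r j_r + 2d \rVert, $$

rewarding sparsity and penalizing the residual. A genetic algorithm over
bitstrings does the maximization, with the minimum-sparsity constraint
(default 0.5) and any prior-knowledge mask built into creation, crossover
and mutation — repair operators keep every individual admissible, so no
time is spent generating and rejecting invalid structures.

The scaling factor $\lambda$ balances the two objectives and its useful
range is problem-dependent: it must be large enough that pruning a
spurious edge pays, yet small enough that the residual gradient toward
covering the true support is not drowned out. Rather than estimating one
value, the pipeline scans a grid (default 0.01–0.10 in steps of 0.005)
with 10 repeated GA runs per value — about 200 best-found candidates per
inference. For a given data scale the informative interval can sit
elsewhere; the 13-metabolite glycolysis fixture in this package, whose
covariance entries are large because of a slow dynamic mode, is best
served by $\lambda$ around 0.002–0.01, and the benchmark drivers use such
a grid. The scan makes this a configuration choice rather than a tuning
burden: uninformative $\lambda$ runs simply contribute weak candidates
that the selection step ignores.

From all best-found candidates, an *elite* is chosen (most zeros among
candidates with at-or-below-median log residual, ties broken by smaller
residual and then run order). Averaging the binarized structures of the
*community* — candidates within ±5% of the elite's zero count whose
residual is no less than 95% of the elite's — gives a fractional support
per position, thresholded at 0.5 (ties count as edges) to yield the final
consensus network. A looser threshold of 0.4 raises both the true- and
false-positive rates; `combine_structures` warns when the consensus drops
below the minimum sparsity. The lower residual boundary deliberately
excludes candidates fitting *better* than the elite band: with
noise-free covariances those are typically overfitted dense supports.
The geometric reading of that boundary is genuinely ambiguous (one could
instead cap residuals from above at 105%); the rule is isolated in
`community_bounds` so the alternative is a one-line change.

## Numerical choices

* **Least squares.** `solve_reduced` uses the SVD with a relative rank
  tolerance of $10^{-10}$ and returns the minimum-norm solution on
  rank-deficient supports, because the GA explores arbitrary structures.
  Inside the GA a pivoted-QR path (`.lm.fit`) computes the same residual
  faster; aliased coefficients are zeroed.
* **Residual floor.** Fitness uses $\log_{10}$ of the residual clamped
  below at $100\,\varepsilon\,\lVert 2d\rVert$ (and absolutely at
  1e-300). Residuals below that floor are roundoff, not signal; without
  the clamp, meaningless differences between exactly-fitting supports
  (common with noise-free covariances) would swamp the sparsity term and
  the selection rules. Elite and community comparisons use the same
  floored residuals.
* **Conditioning.** The vectorized operator $A$ is frequently extremely
  ill-conditioned (condition numbers beyond $10^{30}$ occur in the
  fixtures). The least-squares solvers are rank-revealing and the search
  compares residuals, not coefficients, so no conditioning safeguard is
  applied; the condition number is reported in the result diagnostics so
  users can see it.
* **Symmetry.** Input covariances must satisfy
  $\max|C - C^\top| \le 10^{-8} \max|C|$ and are then symmetrized by
  averaging.
* **Fluctuation matrix.** $D$ is diagonal by assumption. From replicate
  data, $D_i$ is estimated as the sample standard deviation of metabolite
  $i$ (unbiased, $m-1$ denominator) — a simple, observable proxy for the
  unobservable noise intensities. Solutions are highly sensitive to $D$;
  this estimate is an approximation, and computing $D$ back from true
  Jacobians shows genuine off-diagonal structure that the method ignores.

## GA defaults

The protocol-level defaults are 800 generations, 5% per-bit mutation,
minimum sparsity 0.5, and the 19-point $\lambda$ grid with 10 repeats.
Population size, selection and elitism are not part of that protocol and
are this package's choices: population 200, tournament selection (size
2), 5% elitism, and a crossover/mutation split in which 80% of non-elite
children come from uniform crossover alone and 20% from mutation alone.
The split matters: mutating every crossover child (about $0.05 n^2$ bit
flips each) destroys recombination exactly when the search needs to
exploit shared structure between good parents, so the two operators act
on disjoint children, as is conventional for generational GAs. Runs
are deterministic given a seed; scan-level seeds are derived as
`rng_seed + 1000 * lambda_index + repeat_index`, so serial and concurrent
execution give identical results.

## The synthetic-data generator

`make_toy_network` draws sparse, diagonally dominant (hence
Hurwitz-stable) linear kinetic models with known Jacobians, rejecting
draws with sparsity below 0.55. `glycolysis_synthetic_model` is a
hand-built 13-metabolite mass-action model of a glycolysis-like pathway
(hexose phosphates, triose phosphates, pyruvate/ethanol, ATP and NAD
coupling) — a synthetic stand-in constructed for benchmarking at
realistic size, not a published model; its rate constants put the steady
state at unit concentrations, and its Jacobian there is stable with
sparsity 0.78.

`simulate_replicates` integrates the Langevin system with Euler–Maruyama;
each replicate is by default the endpoint of an independent trajectory
started at the steady state (replicates in an experiment are independent
samples, not a thinned time series; thinning is available for
comparison). The default step keeps `dt * max|eigenvalue| = 0.05` and the
default horizon is ten relaxation times of the slowest mode.
Concentrations are floored at zero and floor events counted. Default
study conditions are fluctuation magnitude $D_i = 0.005$ for every
metabolite and 1000 replicates.

Two noise protocols mimic imperfect data: `noisy_covariance` multiplies
each covariance entry (symmetrically) by an independent $N(1, 0.005)$
factor, and `add_measurement_noise` adds per-metabolite Gaussian noise
whose standard deviation is, literally, 10% of that metabolite's sample
*variance*. That mixes units; the package implements the literal rule as
the default and exposes `mode = "sd"` (10% of the standard deviation)
without endorsing either reading.

What the generator does *not* emulate: real metabolomics features such as
correlated (off-diagonal) noise sources, measurement batch effects,
missing values, or non-stationary drift. Passing the synthetic benchmarks
therefore demonstrates correctness of the machinery and behavior under
the stated noise models, not performance on real measured metabolomes.

## Problem sizes used in the shipped checks

The packaged tests exercise the full pipeline at sizes chosen for quick
iteration: exact-covariance recovery on 5-node toys (20 pipeline runs,
compact GA settings: population 50, 150 generations, five $\lambda$
values × 3 repeats), two noisy-covariance draws on the 13-metabolite
fixture with a reduced scan, and Monte-Carlo property checks at a few
thousand samples. The full-scale protocol (population 200, 800
generations, 19 × 10 scan, 10 noisy draws, 1000 SDE replicates) is
available through the same functions and the `benchmark` command; a
single full-scale GA run on the 13-metabolite fixture takes on the order
of a minute, and a complete scan a few hours.

## Known limitations

* Cost grows steeply with network size ($A$ is $n^2 \times n^2$ and the
  search space doubles per position); the method is intended for small
  networks (< 20 metabolites), and below ~100 replicates the covariance
  estimate itself becomes the bottleneck.
* The diagonal-$D$ assumption is wrong in detail for nonlinear systems;
  it is retained because $D$ is otherwise unobservable.
* The GGM baseline infers undirected edges only and is evaluated
  off-diagonal against the symmetrized truth; comparisons with the
  directed method are therefore indicative, not position-by-position.
* Consensus support values are not calibrated probabilities.
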