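---
title: "Uncertainty-adjusted optimal calibration designs"
author: "optcalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-adjusted optimal calibration designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optcalib)
```

## The design problem

A testing organization must calibrate $n$ new items by assigning each
examinee exactly one of them, after the examinee has answered $m$
operational items of known parameters. Under the 2PL model the probability
of a correct answer is $p_i(\theta) = 1/(1+e^{-a_i(\theta-b_i)})$, and the
contribution of one examinee at ability $\theta$ to the Fisher information
about $\zeta_i = (a_i, b_i)$ is the rank-one matrix
$p_i(1-p_i)\,\nabla\eta_i\,\nabla\eta_i^\top$ with
$\nabla\eta_i = (\theta-b_i,\,-a_i)$. Aggregating over an allocation rule
$h_i(\theta)$ (the sub-density of examinees routed to item $i$, summing to
the standard normal population density) gives the standardized block
information matrix $M(h)$, and D-optimality maximizes
$\det M(h) = \prod_i \det M_i(h_i)$. When no two items share a parameter
vector the D-optimum assigns each ability level wholly to one item, so the
optimal design is a partition of the ability axis into intervals.

Abilities, however, are estimated. The package's central objects therefore
average the response function over an uncertainty model
$g(\theta\,|\,\hat\theta)$ before forming information:
$\tilde p_i(\hat\theta) = \int p_i(\theta)\, g(\theta|\hat\theta)\,
d\theta$, and the elemental information at $\hat\theta$ becomes
$\Psi\Psi^\top / (\tilde p_i(1-\tilde p_i))$ with
$\Psi(\hat\theta) = \int (\partial p_i/\partial\zeta_i)(\theta)\,
g(\theta|\hat\theta)\, d\theta$. Two models of $g$ are supported:

* **normal** — the asymptotic posterior
  $N(\hat\theta,\, 1/I(\hat\theta))$, where
  $I(\theta) = \sum_{k=1}^m a_k^2 p_k(1-p_k)$ is the operational test
  information. Because it depends only on the operational item parameters,
  the design can be computed *before* anyone is tested, which is what an
  integrated calibration set-up requires.
* **draws** — per-examinee Metropolis–Hastings samples from the posterior
  under a N(0,1) ability prior. No distributional approximation is made,
  but the design can only be computed after the operational responses have
  been collected and analysed, which suits a separated set-up.

The known-ability case is the degenerate member of the family (a point mass
at $\hat\theta$), and everything downstream — optimization, efficiencies,
simulation — treats it uniformly through the same interface.

For 3PL items the $\Psi$ integrand is the parameter gradient
$\partial p/\partial\zeta = \big((\theta-b)\tfrac{(p-c)(1-p)}{1-c},\,
-a\tfrac{(p-c)(1-p)}{1-c},\, \tfrac{1-p}{1-c}\big)$, which reduces to the
2PL integrand $p(1-p)(\theta-b,-a)$ at $c=0$ and reproduces the standard
3PL item information; the package asserts both reductions in its tests.

## Numerical choices

**Inner integral.** $\tilde p$ and $\Psi$ are smooth logistic-by-Gaussian
integrals and are computed by Gauss–Hermite quadrature recentred at the
prior's mean and scale, 61 nodes by default. At the variances arising from
operational tests of 6–120 items, 61 nodes agree with adaptive quadrature
to better than $10^{-10}$; draw-based priors replace the quadrature by the
Monte-Carlo average over the draw set.

**Outer integral.** The ability axis is truncated to $[-6, 6]$ (standard
normal mass outside $< 2\times10^{-9}$) and discretized into cells of width
0.01 by default; information matrices are assembled by the midpoint
(Riemann) rule. The default step is comfortable for interactive work; the
experiments reported by `scripts/acceptance.R` use 0.001, at which the
efficiency values below are grid-converged (they change by $<10^{-3}$
between steps 0.001 and 0.0005, and the two-item known-ability design's
interval boundaries agree with a continuous-boundary oracle to the cell
width). The discretization matters more than one might expect: a design
boundary can only sit on a grid line, and a 0.005 boundary shift moves
c-efficiencies in the second decimal.

**Exchange optimizer.** `optimize_design()` starts from a round-robin
assignment of cells to items and sweeps the cells, moving a cell to the
item whose *exact* criterion change (closed-form update of the block
determinants, or of the traces for the L-criterion) is largest, until a
full sweep makes no move. This makes the criterion path non-decreasing by
construction, which is asserted on every run in the test suite. Two
refinements matter in practice:

* cells in the far tails carry population mass below machine precision
  relative to the criterion, so their exact gain is numerically zero; such
  indifferent cells are settled by the sensitivity direction
  $\mathrm{tr}(M_i^{-1} E_{ij})$ (the directional derivative of the
  criterion), which keeps the reported intervals a clean partition of the
  axis. A relative margin on the comparison keeps exactly tied items (e.g.
  duplicated items) from oscillating.
* very coarse grids raise singularity barriers — moving any single cell
  would leave a donor item with a rank-deficient block — which can trap
  single-cell exchanges. On grids of at most a few hundred cells the
  optimizer therefore also tries exact two-cell swaps and a small set of
  deterministic restarts; on such grids it provably attains the exhaustive
  0/1 optimum in the test suite. Fine grids (the intended regime) do not
  exhibit the barrier, and grid-refinement stability is checked instead.

Determinants below $10^{-10}$ times the product of a block's diagonal are
treated as rank-deficiency noise (a one-cell 2PL block is an exact rank-one
outer product; its floating-point determinant is meaningless cancellation
residue rather than information).

**Tie-breaks and conventions.** Interval boundaries are half-open with
boundary estimates falling rightward; item indices are 1-based in all
reports; ability estimation (MLE by safeguarded Fisher scoring, EAP by
241-node quadrature) works on the same $[-6,6]$ domain, with perfect and
zero scores clamped to the boundary for the MLE.

## Design comparisons

`relative_efficiency()` reports, for D-optimality,
$\mathrm{RE}_D = (\det M(h^{(1)})/\det M(h^{(2)}))^{1/p}$ with $p$ the
total parameter count, per-item versions using each block alone, and for
the c/L-criterion the variance-approximation ratio
$c^\top M_i^{-1} c$ between designs ($c=(1,0)$ targets discrimination,
$c=(0,1)$ difficulty; general L-matrices are supported). An efficiency of
1.2 means the comparison design needs 20% more examinees for the same
precision. `efficiency_experiment()` wires the standard comparisons:
uncertainty-adjusted optimal, known-ability optimal, and random designs,
always *evaluated under the same uncertainty model* — comparing a design
derived under assumed-known abilities against the uncertainty-adjusted one
only makes sense on the uncertainty-adjusted information scale.

Three reference behaviours, all recomputed by the acceptance script: the
efficiency of the optimal over the random design grows with the operational
test length $m$ (there is more ability information to exploit) and is
largest for blocks containing extreme items; ignoring the uncertainty
costs little for well-matched blocks (two-item block: never below 0.98)
but up to 12% for a block with a steep, difficult item at $m=6$; and
acknowledging uncertainty widens the middle intervals of the design —
a robustness property, since misclassifying an examinee near a boundary
then matters less.

## The synthetic-data generator

`make_operational_test()` builds the stylized operational test used across
the experiments: $m$ 2PL items, common discrimination $a_{op}=1$,
difficulties equidistant on $[-1.5, 1.5]$. This isolates the effect of test
length on ability information (which scales as $m\,a_{op}^2$) from item
heterogeneity; real tests have spread discriminations and skewed difficulty
distributions, so passing tests here demonstrates the method's behaviour
under its stated conditions, not calibration quality on any particular
operational instrument. Abilities are drawn from N(0,1) and responses are
independent Bernoulli draws from the model — no position effects, no
random responders, no misfit, all of which exist in real pretesting and are
outside the generator's scope.

`run_sim_study()` (N = 500 examinees, m = 30, 2–4 calibration items per
block by default) draws true abilities, simulates operational responses,
estimates abilities, assigns calibration items per design, generates
calibration responses *from the true abilities*, and refits each item by
logistic regression on the *estimated* abilities — the mismatch being
exactly the phenomenon under study. The ability estimator used for
assignment is EAP by default (the MLE's boundary behaviour at perfect
scores otherwise contaminates extreme intervals); an MLE option is
provided. Replications in which an item's fit is degenerate (single
response class, separation, vanishing slope) are flagged non-estimable and
excluded from that item's aggregate with counts reported. Difficulty-MSE
aggregates are heavy-tailed — a handful of replications can carry half of
the mean squared error of an extreme item under random allocation — so
these quantities carry large Monte-Carlo error even at 1000 replications,
and comparisons against them are made in Monte-Carlo standard errors.

All simulation randomness flows from the single `seed` in `sim_config()`
through R's sequential stream; a fixed seed reproduces a study bit-exactly.

## Problem sizes

The test suite optimizes on 0.01–0.001 grids (1200–12 000 cells, seconds
per design on one CPU), enumerates exhaustively only on coarse grids
(≤ 6561 assignments), and runs the recovery simulation at 300
replications; the acceptance script uses 0.001 grids and 1000
replications. These sizes were chosen so the full suite completes in a few
minutes while every reported quantity is at its converged value.

## Limitations

* Only dichotomous 2PL/3PL models; no polytomous or multidimensional items.
* One calibration item per examinee per block; larger item sets are handled
  by blocking, outside the package's scope.
* The draws-based uncertainty model requires analysed operational
  responses; the package enforces this rather than approximating.
* Local optimality in the item parameters: designs are computed at assumed
  ("best guess") calibration parameters, and severe misspecification
  degrades them — the robustness analyses here vary the ability
  information, not the guessed parameters.
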