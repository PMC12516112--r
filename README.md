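# optcalib

Optimal calibration designs for test items when examinee abilities are
estimated, not known.

## The problem

Before a test item can be used operationally, its item response theory (IRT)
parameters — discrimination *a* and difficulty *b* under the two-parameter
logistic (2PL) model, plus a guessing parameter *c* under the 3PL model —
must be estimated by giving the item to examinees (*calibration* or
*pretesting*). Precision is maximized by matching items to examinees:
allocating an item mostly to examinees whose ability θ is informative about
that item's parameters. Methods from optimal experimental design turn this
into the maximization of a design criterion over allocation rules
*h<sub>i</sub>(θ)*, the sub-density of examinees sent to item *i*, with
Σ<sub>i</sub> h<sub>i</sub> = h<sub>tot</sub>, the N(0,1) population density.
The D-optimal rule maximizes det *M(h)*, where

  *M(h)* = diag(*M*₁(*h*₁), …, *M*<sub>n</sub>(*h*<sub>n</sub>)),  
  *M*<sub>i</sub>(*h*<sub>i</sub>) = ∫ p<sub>i</sub>(θ)(1−p<sub>i</sub>(θ))
  (∂η/∂ζ<sub>i</sub>)(∂η/∂ζ<sub>i</sub>)ᵀ *h*<sub>i</sub>(θ) dθ

is the standardized information matrix of item *i*, and the optimum is an
interval partition of the ability axis.

In practice θ is never known: it is estimated from *m* operational items, and
the estimation error changes which allocation is optimal. `optcalib`
implements uncertainty-adjusted information matrices in which the response
probability is averaged over an uncertainty model g(θ|θ̂) — the asymptotic
normal posterior N(θ̂, 1/I(θ̂)) with I the operational test information, or an
empirical set of Metropolis–Hastings posterior draws — so that

  p̃<sub>i</sub>(θ̂) = ∫ p<sub>i</sub>(θ) g(θ|θ̂) dθ,  
  *M*<sub>i</sub>(*h*<sub>i</sub>) = ∫ Ψ(θ̂)Ψ(θ̂)ᵀ /
  (p̃<sub>i</sub>(1−p̃<sub>i</sub>)) · *h*<sub>i</sub>(θ̂) dθ̂,
  with Ψ(θ̂) = ∫ (∂p<sub>i</sub>/∂ζ<sub>i</sub>)(θ) g(θ|θ̂) dθ,

and derives D- (or L/c-) optimal interval designs by an exchange algorithm on
a discretized ability axis. It also quantifies how much a design gains over
random allocation (relative efficiencies, interpretable as sample-size
ratios) and validates the asymptotics with a bias/MSE parameter-recovery
simulation.

## Worked example

Two calibration items (a = 1.6, b = ∓1), abilities estimated from a 6-item
operational test:

```r
library(optcalib)

calib <- item_bank(list(irt_item(1.6, -1), irt_item(1.6, 1)))
op    <- make_operational_test(m = 6, a_op = 1)
um    <- uncertainty_model("normal", op)

design <- optimize_design(calib, build_grid(step = 0.01), um)
extract_intervals(design)
#>   lower upper item
#> 1  -6.0  -0.9    1
#> 2  -0.9   0.0    2
#> 3   0.0   0.9    1
#> 4   0.9   6.0    2

efficiency_experiment(calib, m = 6)
#> <D-efficiency> uncertainty vs random
#>   item1   item2 overall
#>    1.14    1.14    1.14
```

Reading: an examinee with estimated ability in (−0.9, 0] or above 0.9
calibrates the harder item 2, the rest calibrate item 1; relative to handing
items out at random, this allocation is worth 14% more examinees. Under
known abilities the same design problem gives narrower middle intervals
(boundaries at ±0.74) and a D-efficiency of 1.23 versus random — the wider
intervals are the price (and the robustness gain) of acknowledging the
ability uncertainty.

The recovery simulation closes the loop at finite samples:

```r
cfg <- sim_config(calib, N = 500, m = 30, reps = 200, seed = 1)
run_sim_study(cfg, list(optimal = design, rd = "random"))
```

returns per-item bias and MSE of the logistic-regression estimates of
(a, b), with calibration responses generated from true abilities and fitted
against estimated ones.

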