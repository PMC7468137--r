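---
title: "Methods: the chaotic HHO / cuckoo search hybrid and its wrapper fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chaotic HHO / cuckoo search hybrid and its wrapper fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hawkfs)
```

This vignette documents the model behind `hawkfs`, the choices made where
the method's published description is ambiguous, and what the synthetic
benchmark does and does not demonstrate.

## The baseline optimizer

Harris hawks optimization maintains `N` position vectors in a box
`[LB, UB]^D` and the best-so-far solution `X_rabbit`. Each iteration draws
an initial escape energy `E0 ∈ (-1, 1)` and decays it linearly,
`E = 2·E0·(1 - t/T)`. The magnitude of `E` dispatches every hawk to exactly
one of four operators (plus exploration):

* `|E| ≥ 1` — exploration: with probability `q ≥ 0.5` perch relative to a
  random hawk, `X_rand - r1·|X_rand - 2·r2·X|`; otherwise relative to the
  prey and the population mean, `(X_rabbit - X_m) - r3·(LB + r4·(UB-LB))`.
* `|E| ∈ [0.5, 1)`, `r ≥ 0.5` — soft besiege:
  `ΔX - E·|J·X_rabbit - X|`, with `ΔX = X_rabbit - X` and jump strength
  `J = 2(1 - r5)`.
* `|E| < 0.5`, `r ≥ 0.5` — hard besiege: `X_rabbit - E·|ΔX|`.
* `r < 0.5` — progressive rapid dives: a besiege point
  `Y = X_rabbit - E·|J·X_rabbit - X|` (soft regime) or
  `Y = X_rabbit - E·|J·X_rabbit - X_m|` (hard regime) and a Lévy point
  `Z = Y + S ⊙ LF(D)`; the hawk moves to `Y` if it strictly improves its
  own fitness, else to `Z` if that improves, else stays. The published
  update rule for this step composes a Lévy function with scalar fitness
  values and cannot be evaluated as written; we use the standard greedy
  three-way comparison, which the surrounding description supports. The
  soft and hard dive modes share this acceptance rule and differ only in
  `Y`.

The Lévy step is Mantegna's: `LF = 0.01·u·σ/|v|^{1/β}` with `u, v` standard
normal, `β = 1.5` and the closed-form scale `σ(β)`.

Decisions where the method description is silent, fixed once here:

* `r` is a fresh `U(0,1)` draw per hawk per iteration, distinct from
  `r1`–`r5`.
* `E0` is drawn once per iteration and shared across hawks. This matches
  the single energy schedule and is what makes the chaotic override
  (below) well-defined with one chaotic draw per iteration.
* `X_rand` is resampled uniformly from the current population on every
  exploration call; a hawk may draw itself.
* Positions are hard-clipped to the box after every update, before
  evaluation.
* The prey update is elitist with strict `<`; ties keep the incumbent, so
  two runs with the same seed are bit-identical and the best-so-far trace
  is monotone non-increasing.
* The core minimizes. The feature-selection layer hands it the negated
  (maximized) wrapper fitness and re-negates for reporting.

## Chaotic maps

Ten classical one-dimensional recurrences (tent, logistic, sinusoidal,
singer, sine, Chebyshev, circle, iterative, Gauss/mouse, piecewise) serve
as deterministic, highly mixing substitutes for uniform draws. Where only
parameter ranges are conventional, we fix canonical values: logistic
`a = 4`, sinusoidal `a = 2.3`, singer `μ = 1.07`, sine `a = 3.99`
(respecting the strict upper bound of 4), iterative `a = 0.7`, circle
`a = 0.5, b = 0.2`, piecewise `P = 0.4`, tent branch point `0.7`. The
Chebyshev recurrence `cos(k·acos(x))` uses the step index as its
multiplier.

Normalization into `[0, 1]`: Chebyshev and iterative have range `[-1, 1]`
and are folded affinely via `(v+1)/2`; sinusoidal and sine are clamped;
the remaining maps already live in the unit interval. Two degeneracies need
a guard: several maps have absorbing points (logistic collapses to 0
forever from `x = 0.5`; Gauss/mouse from 0), and boundary values 0/1 would
freeze the affine energy map. If an iterate lands exactly on 0, 1, or its
own predecessor, the state is reseeded to `(x + 10^-6) mod 1`. The guard
changes nothing on typical trajectories (exact hits have measure zero) but
makes the driver total.

When no initial value is configured, `x0` is drawn uniformly from the
run's seeded RNG stream, so chaotic runs remain reproducible end to end.

## The hybrid

Three independent strategies, each individually switchable, augment the
baseline:

1. **Chaotic initialization** — population coordinates come from the map
   sequence instead of uniform draws.
2. **Chaotic energy** — `E0 = 2c - 1` with `c` the next normalized chaotic
   iterate (one draw per iteration). The exact published formulation of
   this override is not printed in the method's description; the affine map
   composed with the standard envelope is the minimal formulation that (a)
   keeps `E0 ∈ (-1,1)`, (b) preserves `|E| ≤ 2(1 - t/T)` and `E(T) = 0`
   exactly, and (c) produces the depicted non-linear decay.
3. **Cuckoo-search refinement** — once per iteration, one CS generation
   runs on the hawk population: per nest, a Lévy proposal
   `x + α·L⊙(x - x_best)` (`α = 0.01`, `β = 1.5`) is dumped into a random
   host nest and survives only on strict improvement; then the worst
   `⌊p_a·n⌋` nests (`p_a = 0.25`), never the best, are rebuilt uniformly at
   random. Improved nests re-enter the population from which exploration
   draws `X_rand`, and the prey is replaced only if the refined best
   strictly improves it — the "update only if better" contract. Refinement
   runs every iteration rather than once at the end of the run, since a
   one-shot refinement could not steer the guiding vectors during the
   search. The step length enters the proposal once: `L` is the raw
   Mantegna deviate, `α = 0.01` the published step length (wiring the
   0.01-scaled dive flight into the proposal would square it).

With all three switches off, `chho_cs_run()` is bit-identical to
`hho_run()` for any seed — the reduction contract is asserted in the test
suite on multiple seeds and objectives. The plain HHO–CS variant is the
hybrid with the two chaotic switches off.

Abandonment is realized deterministically as the worst `⌊p_a·n⌋` nests
rather than per-nest Bernoulli draws: it matches the "fraction of n nests"
reading, makes the replaced count exactly testable, and combined with the
elitism guard guarantees the best nest survives.

## The wrapper fitness

A candidate position in `[0,1]^C` becomes a descriptor subset by strict
thresholding at `τ = 0.5`; an all-below-threshold position keeps its single
largest coordinate so the subset is never empty. The subset score is

`fitness = α·accuracy + β·(1 - |selected|/C)`, `α = 0.99`, `β = 0.01`.

The published printed form of this objective is internally inconsistent
(it adds a constant performance weight, rewards the error term, and
subtracts a data column); the form above is the canonical wrapper
objective consistent with the stated weights, the stated maximization, and
the reported accuracy-versus-subset-size trade-off. The acceptance
threshold sometimes attached to it (fitness must exceed a floor `T`) is
subsumed by elitist selection and is exposed only as an optional flag-style
check, disabled by default.

**Classifier.** The accuracy comes from an RBF-kernel SVM (`e1071::svm`)
with cost 1 and `gamma = 1/|selected|`, features standardized on each
training fold only. The method names the classifier but no kernel or
hyperparameters; these are the library defaults a practitioner would
start from, and they are exposed (`kernel`, `cost`, `gamma`).

**Evaluation protocol.** The default is stratified 5-fold cross-validation
with the per-fold confusion matrices summed; a single stratified hold-out
(`folds = 1`, `split_ratio = 0.8`) is available. The hold-out was the
initial design, but a single small test fold saturates: on a 200-sample
task many distinct small subsets reach accuracy 1.0 on 40 held-out
samples, the fitness then degenerates to pure sparsity pressure, and the
search strips genuinely informative descriptors. Summed 5-fold confusions
keep the accuracy estimate on 200 evaluation samples, which restores the
gradient between "enough informative descriptors" and "too few". This is
the standard protocol for wrapper selection at these sample sizes.

The fold assignment is a deterministic function of the run seed and is
fixed for the whole run, so a mask's fitness is a constant; mask-level
memoization then removes most classifier fits (the optimizer revisits
masks heavily late in a run). Classifier failures score as accuracy 0 —
the worst fitness — rather than aborting the search. Metrics follow the
usual confusion-matrix formulas, macro-averaged one-vs-rest for more than
two classes, with zero-denominator rates defined as 0.

## The synthetic benchmark

`synth_descriptors()` plants `n_informative` descriptors whose
class-conditional means differ by `effect_size` within-class standard
deviations (unit variance, Gaussian) among `n_noise` standard-normal
noise columns. Defaults — 200 samples, 5 informative at effect size 2, 15
noise, balanced classes — form the reference recovery task: hard enough
that dropping an informative column measurably costs accuracy, small
enough that a wrapper run takes seconds.

What it emulates: the low-sample, moderate-dimension regime of descriptor
tables with a sparse informative subset. What it does not emulate:
correlated descriptor blocks (real descriptor sets are strongly
collinear), heavy-tailed or discrete descriptor distributions, label
noise, and class imbalance beyond the `class_balance` knob. Passing the
recovery test therefore shows the search machinery works — it does not
certify performance on any particular chemical dataset.

Two reference checks used throughout the tests:

* **Recovery** — on the default task, the hybrid wrapper (N = 20, T = 50)
  should recover most planted descriptors while keeping the subset small.
* **Enumeration optimality** — with one strongly separating descriptor
  (effect size 8) among nine noise columns (`C = 10`), the exhaustive
  `2^10`-mask optimum is the separator alone, and the wrapper should find
  exactly that optimum. A composition with five moderately informative
  columns is deliberately *not* used here: near the accuracy ceiling
  cross-validation ties make the exact argmax among ~1000 masks
  essentially random, and no budgeted search can be expected to hit it.

## Numerical and engineering choices

* Problem sizes in the tests: operator oracles run 100–1000 random
  instances at tolerance 1e-12; continuous convergence uses the
  10-dimensional sphere with 30 agents and 500 iterations; wrapper checks
  use 10 seeds at the reference task sizes. These sizes make the whole
  suite run in minutes on one core while keeping every check at full
  method fidelity.
* All stochastic APIs take an explicit `seed`; internal classifier splits
  isolate their RNG use (`withr::with_seed`), so an objective evaluation
  never perturbs the optimizer's stream.
* Box bounds for feature selection are `[0,1]` per coordinate; continuous
  benchmarks use symmetric boxes. Bounds handling is hard clipping.
* `agents` defaults: 30 for the continuous optimizers, 20 for the wrapper
  (the published setup quotes both 30 and 50 agents in different places;
  both are plain arguments).
* Campaign reporting re-negates the internal objective so summary tables
  read "higher is better", with metrics as percentages; convergence
  exports keep the internal minimized scale, so files are monotone
  non-increasing per column.

## Known limitations

* The comparison baselines (PSO, MFO, GWO, SSA, SCA) are reserved names
  that error cleanly; only HHO, CS and the hybrids ship.
* The wrapper optimizes cross-validated accuracy on the full table; there
  is no outer evaluation loop, so reported accuracies are model-selection
  accuracies, not unbiased generalization estimates.
* Only a margin-classifier fitness ships; the fitness interface accepts
  alternative kernels/hyperparameters but not other model families.
* Chaotic maps are used as drivers, not analyzed: no bifurcation or
  Lyapunov diagnostics.
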