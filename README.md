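# hawkfs

Wrapper feature selection for descriptor tables with a chaotic Harris hawks /
cuckoo search hybrid metaheuristic (CHHO–CS).

## The problem

QSAR and related cheminformatics models start from large tables of computed
molecular descriptors — often hundreds or thousands of columns for a few
dozen to a few thousand compounds. Most descriptors are redundant or
irrelevant, and classifiers trained on the full table overfit and obscure
which structural properties drive activity. *Wrapper* feature selection
searches the space of descriptor subsets directly, scoring each candidate
subset by the held-out performance of a trained classifier. With `C`
descriptors the search space has `2^C` subsets, so the search needs a strong
global optimizer.

`hawkfs` is for modellers who have such a table (one row per compound,
numeric descriptor columns, one class label) and want a small, accurate
descriptor subset plus an honest benchmark harness for comparing search
strategies.

## The method

The search engine is Harris hawks optimization (HHO): a population of
candidate solutions ("hawks") pursues the best solution found so far (the
"rabbit" `X_rabbit`). An escape energy

    E = 2 E0 (1 - t/T),   E0 ∈ (-1, 1)

schedules the transition from exploration (`|E| ≥ 1`: random perching moves)
to exploitation (soft besiege `ΔX - E|J·X_rabbit - X|`, hard besiege
`X_rabbit - E|ΔX|`, and Lévy-flight "rapid dive" variants accepted
greedily). The hybrid augments baseline HHO with:

1. **Chaotic maps** (ten classical one-dimensional recurrences — tent,
   logistic, piecewise, Gauss/mouse, Chebyshev, ...) driving both population
   initialization and the energy schedule: `E0 = 2c - 1` with `c` the
   normalized chaotic iterate, giving a non-linear, diversity-preserving
   decay.
2. **Cuckoo search refinement**: each iteration, one cuckoo-search
   generation (Lévy-flight proposals `x + 0.01·L⊙(x - x_best)`, greedy
   host-nest replacement, abandonment of the worst `⌊p_a·n⌋` nests) runs on
   the hawk population and may replace `X_rabbit` and the pool from which
   `X_rand` is drawn — but only when it strictly improves the fitness.

For feature selection each hawk lives in `[0,1]^C`; coordinates above
`τ = 0.5` select the corresponding descriptor. A subset is scored by

    fitness = α · accuracy + β · (1 - |selected| / C),   α = 0.99, β = 0.01

where accuracy is stratified 5-fold cross-validated accuracy of an RBF-SVM
(cost 1, `gamma = 1/|selected|`, per-fold standardization) trained on the
selected columns. The optimizer maximizes this fitness (internally it
minimizes its negation).

## Worked example

```r
library(hawkfs)

# 200 synthetic compounds: 5 informative descriptors (class means two
# within-class SDs apart) plus 15 pure-noise descriptors
d <- synth_descriptors(n_samples = 200, n_informative = 5, n_noise = 15,
                       effect_size = 2, seed = 42)

fit <- select_features(d, "class", optimizer = "chho-cs",
                       n_agents = 20, n_iter = 50, seed = 42)
fit
#> <hawk_fs> chho-cs-piecewise: 13/20 features selected
#>   fitness:   0.9836
#>   accuracy:  0.99
#>   selected:  f01, f02, f03, f04, f05, f07, f08, f09, f11, f13, f16, f17, f18

fit$report
#> <hawk_report>
#>           predicted
#> truth      active inactive
#>   active       99        1
#>   inactive      1       99
#>
#>    accuracy sensitivity specificity      recall   precision   f_measure
#>        0.99        0.99        0.99        0.99        0.99        0.99
```

All five planted informative descriptors (`f01`–`f05`) are recovered; the
fitness 0.9836 decomposes as `0.99 × 0.99` (accuracy term) plus
`0.01 × (1 − 13/20)` (sparsity term). The 0.99 accuracy is the summed
confusion over the five cross-validation folds (198/200 correct).

`tidy(fit)` gives the per-feature positions and selection flags,
`glance(fit)` a one-row metric summary, and `autoplot(fit)` the convergence
curve. Multi-run benchmarks with the mean/std/best/worst statistics come
from `run_campaign()` + `export_summary()` / `export_convergence()`, also
available from the shell via `inst/scripts/hawkfs run --config cfg.yaml`.
The continuous optimizers are usable on their own objective functions via
`hho_run()`, `cs_run()` and `chho_cs_run()`.

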