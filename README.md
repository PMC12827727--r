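# causalemergence

Quantifying which scales of a discrete Markov system irreducibly contribute to
its causal workings.

Complex systems admit many coarse-grained descriptions, and most of them are
poor accounts of how the system actually causes its own future. This package
implements a multiscale analysis that scores every scale of a finite Markov
chain by its *causal primitives* — sufficiency (certainty of an effect given a
cause) and necessity (certainty of a cause given an effect) — and their
information-theoretic generalizations, the determinism and degeneracy
coefficients. It then searches the lattice of state-space partitions for
coarse grains that *gain* causal strength over the microscale, apportions
those gains along a micro → macro path, and summarizes how widely the gains
are spread as an entropy: the emergent complexity.

It is aimed at researchers in systems biology, network science and
neuroscience who work with discrete-state causal models (logic-gate networks,
coarse-grained regulatory or neural dynamics) and want a principled,
reproducible answer to "which scales of this system matter causally?".

## The quantities computed

For an $n$-state chain with transition probability matrix $P$ and an
intervention distribution $P(C)$ over causes (uniform by default):

- sufficiency $\mathrm{suff}(e,c) = P(e \mid c)$; necessity
  $\mathrm{nec}(e,c) = 1 - P(e \mid C, \lnot c)$; system-wide values are
  expectations weighted by $P(C)\,P(e \mid c)$.
- determinism $= \sum_c P(c)\,\bigl(1 - H(E \mid c)/\log_2 n\bigr)$ and
  degeneracy $= 1 - H(E)/\log_2 n$, with specificity $= 1 -$ degeneracy.
- the combined causal-primitive score of a scale,
  $\mathrm{CP} = \mathrm{determinism} + \mathrm{specificity} - 1$
  (equivalently sufficiency $+$ necessity $-1$ on the primitive scale), and
  the effective information
  $\mathrm{EI} = (\mathrm{determinism} - \mathrm{degeneracy}) \cdot \log_2 n$.
- macroscales: partitions of the state space, each with an aggregated TPM,
  kept only when they are *dynamically consistent* (a lumpability-style
  random-walker check).
- causal emergence $\mathrm{CE} = \mathrm{CP}(\pi^{(k)}) -
  \mathrm{CP}(\text{micro})$, the telescoped sum of per-step gains
  $\Delta\mathrm{CP}_i$ along a path
  $\pi^{(1)} \to \pi^{(2)} \to \cdots \to \pi^{(k)}$ of consistent coarse
  grains; $1 - \mathrm{CP}(\text{micro})$ bounds it from above.
- emergent complexity
  $\mathrm{EC} = -\sum_i p_i \log_2 p_i$ with
  $p_i = \Delta\mathrm{CP}_i / \sum_j \Delta\mathrm{CP}_j$, normalized by
  $\log_2 L$ for a path of $L$ steps.

## Worked example

The 8-state walkthrough system has a deterministic 4-cycle over states 0–3
and an equivalency class over states 4–7, each of which transitions uniformly
within the block:

```r
library(causalemergence)

sys <- make_cycle_plus_block(4, 4)
fit <- causal_emergence(sys)   # exhaustive endpoint search, uniform P(C)
summary(fit)
#> Multiscale causal-emergence analysis
#>   8 microstates; measure = cp_info; P(C) = uniform; endpoint search = exhaustive
#>   CP(micro) = 0.6667   CE bound (1 - CP(micro)) = 0.3333
#>   endpoint: (0),(1),(2),(3),(4,5,6,7)  (CP = 1)
#>   total causal emergence = 0.3333 over 3 path steps
#>   emergent complexity = 1.571 bits (normalized 0.9911)
#>   contribution profile: top_heavy
#>
#> Per-scale causal apportioning:
#>                            scale n_states     cp delta_cp contribution
#>  (0),(1),(2),(3),(4),(5),(6),(7)        8 0.6667       NA      0.66667
#>    (0),(1),(2),(3),(4,5),(6),(7)        7 0.7580  0.09137      0.09137
#>      (0),(1),(2),(3),(4,5,6),(7)        6 0.8710  0.11301      0.11301
#>        (0),(1),(2),(3),(4,5,6,7)        5 1.0000  0.12895      0.12895
#>
#> Microscale primitives: suff 0.625  nec 0.9464  det 0.6667  deg 0  EI 2 bits
#> EI comparison: micro 2 bits, endpoint 2.322 bits (gain 0.3219)
```

Reading this: the microscale alone carries CP = 0.667 — the noisy uniform
block keeps it below 1. Exhaustive search over all 4,140 partitions of the 8
states finds that merging the equivalency class `(4,5,6,7)` into one
macrostate (which then has a self-loop of p = 1) lifts CP to its maximum of
1, so the system exhibits causal emergence CE = 0.33, apportioned across the
three merge steps. `coef(fit)` returns the per-scale CP values, `plot(fit)`
draws the path and contribution profile, and `write_ce_report(fit, "report.json")`
emits the full analysis as JSON.

Other entry points: `cp_scores()` for one scale's primitives,
`consistency_check()` for the lumpability filter, `find_endpoint_greedy()`
for the diminishing-returns search on larger systems,
`redistribution_sweep()` and `noise_sweep()` for the sensitivity
experiments, `svd_reversibility()` for the singular-value screening
heuristic, and `make_block_model()` / `make_mesoscale_variant()` /
`make_nested_blocks()` / `make_permutation()` for reference systems. A thin
command-line front end lives at `inst/cli/causal-emergence.R` with
`analyze`, `fixtures`, `sweep` and `enumerate` subcommands.

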