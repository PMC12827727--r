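---
title: "Multiscale causal apportioning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale causal apportioning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalemergence)
```

## The model

The package analyzes finite, time-homogeneous Markov chains given as a
row-stochastic transition probability matrix (TPM) $P$, where
$P_{ce} = P(e \mid c)$ is the probability that state $c$ at time $t$ is
followed by state $e$ at $t+1$. The analysis is interventionist: causal
strength is always assessed against an intervention distribution $P(C)$ over
causes, not against the data distribution a trajectory would happen to
visit. Two assumptions are therefore baked in: the dynamics are Markovian
and discrete, and interventions can set the system into any state of the
scale under study.

Every quantity reduces to two primitives. The sufficiency of a cause for an
effect is $P(e \mid c)$; the necessity is $1 - P(e \mid C, \lnot c)$, the
probability that the effect would *not* have arisen from the remaining
causes, drawn from $P(C)$ restricted away from $c$ and renormalized.
System-wide versions average over transitions with weight
$P(c)\,P(e \mid c)$ — the unique reading under which the weights form a
probability measure over realized transitions.

Their information-theoretic generalizations are the determinism coefficient
$\sum_c P(c) (1 - H(E \mid c)/\log_2 n)$ and the degeneracy coefficient
$1 - H(E)/\log_2 n$, where $H(E)$ is the entropy of the effect mixture
$P(e \mid C) = \sum_c P(c) P(e \mid c)$; specificity is one minus
degeneracy. All entropies are base 2: every score is either a probability or
a quantity in bits, and the effective information decomposes exactly as
$\mathrm{EI} = (\mathrm{determinism} - \mathrm{degeneracy}) \log_2 n$,
which the tests verify against mutual information computed directly from the
joint distribution.

A *scale* is a partition of the microstates; its TPM aggregates member rows
by uniform averaging (matching uniform interventions), with
stationary-weighted averaging available for the observed-distribution
variant. The combined score of a scale,
$\mathrm{CP} = \mathrm{determinism} + \mathrm{specificity} - 1$, is the
default measure (`cp_info`); the primitive-scale version
sufficiency $+$ necessity $- 1$ (`cp_primitive`) is a configuration switch.
Causal emergence is the total CP gain along a refinement path from the
discrete partition to an endpoint macroscale; by telescoping it equals
$\mathrm{CP}(\text{endpoint}) - \mathrm{CP}(\text{micro})$, and
$1 - \mathrm{CP}(\text{micro})$ bounds it before any search.

## Dynamical consistency

Not every partition is a faithful description of the microscale. A
macroscale is kept only if it passes a lumpability-style random-walker
check: for each macrostate, the uniform distribution over its members is
evolved $t = 1, \dots, h$ steps under the micro TPM and lumped, and compared
(total-variation distance) with the same start evolved under the macro TPM.
Defaults are a tolerance of $10^{-9}$ and horizon $h = 3$; both are
arguments everywhere they matter. The criterion is exact for partitions over
equivalency classes (identical rows), reduces to weak lumpability at the
uniform prior, and accepts every macroscale the reference systems treat as
valid while rejecting merges whose block-level outflows differ. A stricter
or weaker notion (e.g. per-initial-condition strong lumpability) would
change which borderline macroscales survive; the chosen operationalization
is deliberately the permissive one that still catches first-step and
short-horizon divergences.

## Endpoint selection and path construction

The endpoint is the consistent partition with maximal CP; among ties the
one with the *most* macrostates wins (the point past which coarse-graining
stops paying), then the lexicographically smallest canonical label — a pure
reproducibility tie-break. Exhaustive search enumerates all set partitions
(restricted growth strings; guarded at $n = 10$, Bell$(10) = 115{,}975$,
overridable). The greedy alternative applies the best consistent pairwise
merge per step and stops after `window = 3` consecutive gains below
`epsilon = 1e-6`, returning the highest-dimensional scale attaining the
maximum CP seen; on all shipped system families it reproduces the
exhaustive endpoint, which the tests assert as a fixture-level property, not
a theorem.

The path itself is the longest chain of consistent single merges from the
discrete partition to the endpoint. Where several merges are available the
one with the largest CP gain is taken (ties again lexicographic); a merge
with negative gain is never chosen while a nonnegative alternative exists.
If the chain jams before the endpoint, the path jumps there directly and is
flagged `non_maximal_chain` rather than silently shortened. One consequence
of the largest-gain rule is worth stating: for two-block equivalency-class
systems the *final* merge carries the largest gain, because intermediate
scales of a block-diagonal system retain degeneracy (their effect mixture
stays concentrated) that only the last merge clears. Systems whose dominant
contribution genuinely sits at an interior scale need nested structure —
see `make_nested_blocks()` below.

## Emergent complexity

Per-step gains, microscale excluded, are normalized to
$p_i = \Delta\mathrm{CP}_i / \sum_j \Delta\mathrm{CP}_j$ and summarized as
$\mathrm{EC} = -\sum p_i \log_2 p_i$, optionally normalized by $\log_2 L$.
Three conventions needed deciding:

- zero-gain steps contribute zero entropy and stay in $L$ by default
  (`zero_steps = "include"`); excluding them is a switch, since either
  reading of the normalization is defensible and the difference only shows
  on paths with idle steps.
- negative gains are clamped to zero *with a flag* listing the clamped
  steps; $p$ must be a distribution, but hiding a negative contribution
  would hide a model violation.
- when no step gains at all, EC is `NA` with flag `no_positive_gain` rather
  than 0: "no emergence" and "all emergence at one scale" (a true EC of 0)
  are different findings.

The contribution profile label is a documented constant rule: a step
dominates when its gain is strictly largest ($> 10^{-9}$ margin);
`top_heavy` if that step is the final one, `mesoscale` if interior,
`bottom_heavy` when nothing dominates and the microscale's own CP exceeds
the total gain (including the degenerate no-gain path), `flat` otherwise.

## Reference systems and what they do (and do not) show

All generators are deterministic given their parameters.

- `make_block_model(c(4, 4))`: two equivalency classes of four states,
  uniform within the block. Microscale determinism $1/3$, degeneracy 0,
  EI 1 bit; the block partition lumps it to the $2 \times 2$ identity.
- `make_cycle_plus_block(4, 4)`: the walkthrough system — deterministic
  4-cycle plus a uniform 4-block. Microscale CP $2/3$; merging the block
  lifts CP to 1, so CE $= 1/3$ with the gain spread over three merges.
- `make_mesoscale_variant(c(4, 4), c(0.7, 0.1, 0.1, 0.1))`: one member per
  block deviates from its equivalency class while keeping all mass inside
  the block, so the endpoint stays consistent. Its gains are spread more
  widely than the pure block model's (EC 1.92 vs 1.73 bits) — the
  spread-versus-concentration contrast — though its single largest gain
  still sits at the endpoint merge, for the degeneracy reason above.
- `make_nested_blocks(0.95)`: four equivalency pairs inside two
  superblocks, with 95% within-pair retention. Chosen as the exemplar of
  genuine mesoscale structure: the pair scale is nearly deterministic at
  four states, the final superblock merge resolves only the residual 5%
  leak, and the dominant gain lands at an interior step (profile
  `mesoscale`). The retention default was picked as the weakest coupling
  for which the interior step dominates cleanly; it is a structural
  illustration, not an empirical calibration.
- `make_permutation(n)`: the zero-emergence limit; CP is already 1.
- `make_random_tpm(n)`: Dirichlet rows for property-style tests.

These systems emulate the *structure* of the published demonstration
systems (equivalency classes, deterministic residues, distinguishable
members); the exact demonstration matrices exist only as archived artifacts
and are not replicated pixel-for-pixel, so tests built on these fixtures
establish structural behaviors, not bit-level agreement with any external
figure. Real empirical systems differ in ways the fixtures do not probe:
estimated TPMs carry sampling noise (no consistency margin is modeled for
that), state spaces are larger than the enumeration guard, and real
dynamics may be non-Markovian — inference of a TPM from time series is out
of scope altogether.

The two sweep experiments are likewise structural. The redistribution sweep
moves each state's within-block mass onto its self-loop in `1/steps`
increments (steps $0$ through `steps`, ending exactly at the identity
permutation): CP-based emergence at the fixed block macroscale starts at
$2/3$ and decays strictly to 0, while the EI criterion — which declares
emergence only when macroscale EI exceeds microscale EI — detects nothing at
any step (the raw EI difference is 0 initially and negative thereafter,
since the size term $\log_2 n$ rewards the microscale). The noise sweep
blends any TPM toward uniform and demonstrates the monotone response of
determinism and sufficiency.

## Numerical choices

- Probabilities are doubles; rows within $10^{-9}$ of stochastic are
  accepted and renormalized, but only when they drift by more than
  $10^{-13}$ — rows already normalized to a few ulps are left untouched so
  that read → write → read round-trips are bit-identical (CSV at `%.17g`,
  JSON at 17 significant digits).
- Stationary distributions are the Cesàro (time-averaged) limit from a
  uniform start, computed in closed form: recurrent classes by boolean
  reachability, per-class laws by linear solve, class weights by absorption
  probabilities. This is well defined for every stochastic matrix —
  reducible and periodic included — and equals the unique stationary law
  when one exists, verified to $\pi P = \pi$ within $10^{-8}$.
- Single-state scales have no causal distinctions; all combined scores and
  EI are defined as 0 there. Necessity with all intervention mass on the
  cause is refused rather than guessed.
- Combined CP scores are reported unclamped and flagged when negative;
  empirically sufficiency $+$ necessity $\ge 1$ held on every tested
  stochastic matrix, but it is not enforced.
- CP ties during search use a $10^{-9}$ comparison margin; path-step ties
  $10^{-12}$.

## Problem sizes

Everything ships desk-scale: 8-state systems (Bell$(8) = 4140$ partitions
per exhaustive search), 200 random matrices for the decomposition oracle,
50-step sweeps. The full test suite runs in well under two minutes on one
CPU, and the reproduction script in seconds; these sizes were chosen to
keep exhaustive search — the reference the greedy heuristic is judged
against — routine to re-run.

## Known limitations

Single-path apportioning only: integrating over the full non-commensurate
set of paths (Möbius- or Shapley-style schemes) is not attempted. Only
state-space coarse grains are searched — no temporal black-boxing, no
higher-order recombinations of states. The singular-value reversibility
screen (`svd_reversibility()`, $\sum_i \sigma_i^\alpha$ with
$\alpha = 1$ by default) is exactly that, a screen: it orders systems by
reversibility and tracks the sweeps monotonically, but is never a CP
computation and is labeled heuristic in reports. And the exact consistency
statistic is a package choice among defensible lumpability
operationalizations; conclusions about borderline macroscales inherit it.
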