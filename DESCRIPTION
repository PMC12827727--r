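Package: causalemergence
Title: Multiscale Causal Emergence and Emergent Complexity for Discrete Markov Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how much each scale (coarse-graining) of a discrete
    Markov system contributes to its causal workings. Computes the causal
    primitives (sufficiency and necessity) and their information-theoretic
    generalizations (determinism, degeneracy, specificity) for a transition
    probability matrix under a chosen intervention distribution; constructs
    macroscale transition matrices from state-space partitions and filters
    them by dynamical consistency (a lumpability-style check); searches for
    the macroscale endpoint that maximizes the combined causal-primitive
    score; apportions the per-step gains along a micro-to-macro path; and
    summarizes the distribution of those gains as an emergent-complexity
    entropy in bits. Includes deterministic generators for block-model,
    cycle-plus-block, mesoscale and permutation test systems, probability
    redistribution and noise sweeps, a singular-value reversibility
    heuristic, effective-information comparisons, and JSON/TSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
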