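#' Block-model transition matrix
#'
#' A block-diagonal TPM in which every state transitions only within its
#' own block and all rows within a block are identical — the blocks are
#' exact equivalency classes, so coarse-graining each block into one
#' macrostate loses no dynamical information (the macroscale TPM is the
#' identity).
#'
#' @param block_sizes integer vector of block sizes (each >= 1).
#' @param within_block `"uniform"` (each row spreads evenly over its own
#'   block) or a list of row vectors, one per block, giving the common
#'   within-block row.
#' @return a [tpm].
#' @export
make_block_model <- function(block_sizes, within_block = "uniform") {
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1)) ce_stop("block sizes must be at least 1")
  n <- sum(block_sizes)
  P <- matrix(0, n, n)
  offset <- 0L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    idx <- offset + seq_len(sz)
    row <- if (identical(within_block, "uniform")) rep(1 / sz, sz)
           else as.numeric(within_block[[b]])
    if (length(row) != sz || abs(sum(row) - 1) > 1e-9) {
      ce_stop(sprintf("within-block row for block %d must be a length-%d probability vector",
                      b, sz))
    }
    P[idx, idx] <- matrix(row, sz, sz, byrow = TRUE)
    offset <- offset + sz
  }
  tpm(P)
}

#' Cycle-plus-block transition matrix
#'
#' States `0..cycle_len-1` form a deterministic cycle (one-hot rows);
#' the remaining `block_len` states form an equivalency class, each
#' transitioning uniformly over the block. The block coarse-grains into a
#' single macrostate with a self-loop of p = 1, while the cycle states
#' are already maximally deterministic and non-degenerate, making the
#' partition that merges only the block the natural endpoint.
#'
#' @param cycle_len length of the deterministic cycle (>= 1).
#' @param block_len size of the uniform block (>= 2).
#' @return a [tpm] over `cycle_len + block_len` states.
#' @export
make_cycle_plus_block <- function(cycle_len = 4, block_len = 4) {
  cycle_len <- as.integer(cycle_len); block_len <- as.integer(block_len)
  if (cycle_len < 1) ce_stop("cycle length must be at least 1")
  if (block_len < 2) ce_stop("block length must be at least 2")
  n <- cycle_len + block_len
  P <- matrix(0, n, n)
  for (i in seq_len(cycle_len)) {
    P[i, if (i == cycle_len) 1L else i + 1L] <- 1
  }
  blk <- cycle_len + seq_len(block_len)
  P[blk, blk] <- 1 / block_len
  tpm(P)
}

#' Block model with one distinguishable member per block
#'
#' A block-diagonal system in which the first member of each block
#' deviates from the block's equivalency class (its row is
#' `distinct_member_row`, supported on its own block) while the remaining
#' members stay identical (uniform over the block). Because all rows
#' still keep their mass inside their own block, the block-level outflows
#' are preserved and the endpoint macroscale over the blocks remains
#' dynamically consistent — but the deviating members create gains at
#' interior path steps, i.e. mesoscale structure.
#'
#' @param block_sizes integer vector of block sizes.
#' @param distinct_member_row probability vector of length
#'   `block_sizes[b]` used (relative to each block) as the deviating
#'   member's row; the same shape is applied in every block that can hold
#'   it. Uniform reduces to [make_block_model()].
#' @return a [tpm].
#' @export
make_mesoscale_variant <- function(block_sizes = c(4, 4),
                                   distinct_member_row = c(0.7, 0.1, 0.1, 0.1)) {
  base <- make_block_model(block_sizes)
  P <- unclass(base)
  r <- as.numeric(distinct_member_row)
  if (abs(sum(r) - 1) > 1e-9) ce_stop("distinct member row must sum to 1")
  offset <- 0L
  for (sz in as.integer(block_sizes)) {
    if (length(r) == sz) {
      P[offset + 1L, ] <- 0
      P[offset + 1L, offset + seq_len(sz)] <- r
    }
    offset <- offset + sz
  }
  tpm(P)
}

#' Two-level nested block hierarchy
#'
#' Eight states organized as four equivalency pairs nested inside two
#' superblocks: each state spreads mass `retention` uniformly over its
#' own pair and `1 - retention` over the sibling pair of the same
#' superblock. With high retention the pair scale is almost deterministic
#' at the four-state level while the final superblock merge resolves only
#' the residual cross-pair leak, so the dominant CP gain sits at an
#' interior step of the path — a system with genuine mesoscale structure
#' (contribution profile `"mesoscale"` at the default retention).
#'
#' @param retention within-pair transition mass, in `(0.5, 1)`.
#' @return an 8-state [tpm].
#' @export
make_nested_blocks <- function(retention = 0.95) {
  if (retention <= 0.5 || retention >= 1) {
    ce_stop("retention must lie in (0.5, 1)")
  }
  P <- matrix(0, 8, 8)
  pairs <- list(1:2, 3:4, 5:6, 7:8)
  sibling <- c(2L, 1L, 4L, 3L)
  for (p in 1:4) {
    for (i in pairs[[p]]) {
      P[i, pairs[[p]]] <- retention / 2
      P[i, pairs[[sibling[p]]]] <- (1 - retention) / 2
    }
  }
  tpm(P)
}

#' Permutation transition matrix
#'
#' Fully deterministic, non-degenerate dynamics: every state transitions
#' with p = 1 to a unique next state. The zero-causal-emergence limit —
#' CP is already 1 at the microscale.
#'
#' @param n number of states.
#' @param mapping permutation of `0..n-1` (0-based images); default the
#'   identity (all self-loops).
#' @return a [tpm].
#' @export
make_permutation <- function(n, mapping = 0:(n - 1)) {
  mapping <- as.integer(mapping)
  if (!setequal(mapping, 0:(n - 1)) || length(mapping) != n) {
    ce_stop("mapping must be a permutation of 0..n-1")
  }
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), mapping + 1L)] <- 1
  tpm(P)
}

#' Probability-redistribution sweep (block model toward a permutation)
#'
#' Starting from a block-diagonal model, incrementally moves each state's
#' within-block non-self transition mass onto its self-loop in
#' `steps` equal increments, ending at the identity permutation. At every
#' step (0 = the initial block model, `steps` = the permutation) the
#' causal-primitive gain (CP at the fixed macroscale minus CP at the
#' microscale) and the effective-information gain are recorded. Because
#' the block-level outflows never change, the macroscale TPM — and its EI
#' — stays fixed while the microscale grows more deterministic, so the
#' CP gain decays to exactly 0 at the final step. The raw EI gain
#' `ei_macro - ei_micro` never exceeds 0 here; `ce1_emergence` records
#' the emergence the EI criterion actually declares, `max(0, ei_gain)`.
#'
#' @param tm a block-diagonal [tpm] (e.g. [make_block_model()]).
#' @param macro the block [partition] (or partition string) used as the
#'   fixed macroscale.
#' @param steps number of redistribution increments (>= 1).
#' @param pc_mode intervention mode used at both scales.
#' @param measure CP measure, as in [build_path()].
#' @return a data frame with one row per step: `step`, `tm_checksum`,
#'   `micro_cp`, `macro_cp`, `ce2_gain`, `ei_micro`, `ei_macro`,
#'   `ei_gain`, `ce1_emergence`.
#' @export
redistribution_sweep <- function(tm, macro, steps = 50, pc_mode = "uniform",
                                 measure = c("cp_info", "cp_primitive")) {
  measure <- match.arg(measure)
  n <- n_states(tm)
  if (is.character(macro)) macro <- parse_partition(macro, n)
  if (steps < 1) ce_stop("steps must be at least 1")
  P0 <- unclass(tm)
  memb <- block_membership(macro)
  for (i in seq_len(n)) {
    if (any(P0[i, memb != memb[i]] > 0)) {
      ce_stop("TPM must be block-diagonal with respect to the macro partition")
    }
  }
  self0 <- diag(P0)
  movable <- 1 - self0                    # within-block non-self mass
  records <- vector("list", steps + 1L)
  for (s in 0:steps) {
    f <- s / steps
    P <- P0
    off <- P0; diag(off) <- 0
    scale <- ifelse(movable > 0, 1 - f, 1)
    P <- off * scale
    diag(P) <- self0 + f * movable
    tm_s <- tpm(P, labels = state_labels(tm))
    macro_tm <- coarse_grain_tpm(tm_s, macro)
    micro_pc <- pc_for_scale(tm_s, discrete_partition(n), pc_mode)
    macro_pc <- pc_for_scale(macro_tm, macro, pc_mode)
    micro_cp <- cp_value(tm_s, micro_pc, measure)
    macro_cp <- cp_value(macro_tm, macro_pc, measure)
    ei_mi <- effective_information(tm_s, micro_pc)
    ei_ma <- effective_information(macro_tm, macro_pc)
    records[[s + 1L]] <- data.frame(
      step = s,
      tm_checksum = sum(P * outer(seq_len(n), seq_len(n),
                                  function(i, j) i + n * j)) / n^2,
      micro_cp = micro_cp, macro_cp = macro_cp,
      ce2_gain = macro_cp - micro_cp,
      ei_micro = ei_mi, ei_macro = ei_ma,
      ei_gain = ei_ma - ei_mi,
      ce1_emergence = max(0, ei_ma - ei_mi)
    )
  }
  do.call(rbind, records)
}

#' Noise sweep: blending a system toward the uniform TPM
#'
#' Evaluates all causal scores on `(1 - lambda) * tm + lambda * uniform`
#' for each `lambda`, tracing how the primitives respond as transition
#' probability is redistributed toward full randomness. Determinism and
#' system sufficiency are non-increasing in `lambda`.
#'
#' @param tm a [tpm].
#' @param lambdas blend weights in `[0, 1]`.
#' @param pc_mode intervention mode.
#' @return a data frame with one row per `lambda` and the [cp_scores()]
#'   fields as columns.
#' @export
noise_sweep <- function(tm, lambdas = seq(0, 1, by = 0.1), pc_mode = "uniform") {
  if (any(lambdas < 0 | lambdas > 1)) ce_stop("lambdas must lie in [0, 1]")
  n <- n_states(tm)
  U <- matrix(1 / n, n, n)
  rows <- lapply(lambdas, function(l) {
    tm_l <- tpm((1 - l) * unclass(tm) + l * U, labels = state_labels(tm))
    s <- cp_scores(tm_l, pc_mode)
    data.frame(lambda = l, suff_sys = s$suff_sys, nec_sys = s$nec_sys,
               determinism = s$determinism, degeneracy = s$degeneracy,
               specificity = s$specificity, cp_primitive = s$cp_primitive,
               cp_info = s$cp_info, ei = s$ei)
  })
  do.call(rbind, rows)
}

#' Singular-value reversibility heuristic
#'
#' Screens a TPM for dynamical reversibility without any search across
#' macroscales: returns `sum(sigma_i^alpha)` over the singular values of
#' the matrix, and the same normalized by `n`. Permutation matrices (all
#' singular values 1) attain the maximum `n` (normalized 1); the uniform
#' TPM, of rank one, scores 1 (normalized `1/n`). Higher values indicate
#' more deterministic, less degenerate — more reversible — dynamics. A
#' screening heuristic correlated with the causal-primitive analysis, not
#' a CP computation.
#'
#' @param tm a [tpm].
#' @param alpha exponent in `(0, 2]`; default 1.
#' @return list with `value` (`sum sigma^alpha`), `normalized`
#'   (`value / n`) and `alpha`.
#' @export
svd_reversibility <- function(tm, alpha = 1) {
  if (alpha <= 0 || alpha > 2) ce_stop("alpha must lie in (0, 2]")
  sv <- svd(unclass(tm), nu = 0, nv = 0)$d
  val <- sum(sv^alpha)
  list(value = val, normalized = val / n_states(tm), alpha = alpha)
}

#' Random row-stochastic transition matrix
#'
#' Draws each row independently from a symmetric Dirichlet distribution —
#' a reproducible source of arbitrary stochastic matrices for
#' property-style checks.
#'
#' @param n number of states.
#' @param concentration Dirichlet concentration per entry (1 = flat).
#' @return a [tpm].
#' @export
make_random_tpm <- function(n, concentration = 1) {
  g <- matrix(stats::rgamma(n * n, shape = concentration), n, n)
  tpm(g / rowSums(g))
}
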