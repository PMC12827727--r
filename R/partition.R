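#' State-space partitions (coarse grains)
#'
#' A `partition` groups the 0-based microstate indices `0..n-1` into
#' disjoint, exhaustive blocks; each partition defines one coarse grain
#' (scale) of the system. The canonical string notation lists indices
#' sorted within blocks and blocks sorted by smallest member, e.g.
#' `"(0,1,2),(3)"`.
#'
#' @param blocks list of integer vectors of 0-based state indices.
#' @param n_micro number of microstates covered.
#' @return an object of class `partition`.
#' @export
partition <- function(blocks, n_micro) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  if (n_micro == 0) {
    if (length(blocks) > 0) ce_stop("a 0-state system admits only the empty partition")
    return(structure(list(blocks = list(), n_micro = 0L), class = "partition"))
  }
  if (any(lengths(blocks) == 0)) ce_stop("partition blocks must be nonempty")
  idx <- unlist(blocks)
  if (anyDuplicated(idx)) {
    ce_stop(sprintf("duplicate state index %d in partition",
                    idx[duplicated(idx)][1]))
  }
  if (length(idx) != n_micro || !setequal(idx, 0:(n_micro - 1))) {
    missing <- setdiff(0:(n_micro - 1), idx)
    extra <- setdiff(idx, 0:(n_micro - 1))
    if (length(extra)) ce_stop(sprintf("state index %d out of range 0..%d",
                                       extra[1], n_micro - 1))
    ce_stop(sprintf("partition does not cover state(s): %s",
                    paste(missing, collapse = ", ")))
  }
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  structure(list(blocks = blocks, n_micro = as.integer(n_micro)),
            class = "partition")
}

#' @export
format.partition <- function(x, ...) {
  paste(vapply(x$blocks, function(b) sprintf("(%s)", paste(b, collapse = ",")),
               character(1)), collapse = ",")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition of %d states into %d blocks: %s\n",
              x$n_micro, length(x$blocks), format(x)))
  invisible(x)
}

#' @export
as.character.partition <- function(x, ...) format(x)

n_blocks <- function(part) length(part$blocks)

#' Parse a partition string
#'
#' Parses the `"(0,1,2),(3)"` notation into a [partition]. Every index in
#' `0..n-1` must appear exactly once; `parse -> format` round-trips to the
#' canonical form.
#'
#' @param text partition string.
#' @param n number of microstates.
#' @return a [partition].
#' @export
parse_partition <- function(text, n) {
  text <- gsub("\\s", "", text)
  if (!grepl("^\\((\\d+,)*\\d+\\)(,\\((\\d+,)*\\d+\\))*$", text)) {
    ce_stop(sprintf("malformed partition string: %s", text))
  }
  groups <- regmatches(text, gregexpr("\\(([^)]*)\\)", text))[[1]]
  blocks <- lapply(groups, function(g) {
    as.integer(strsplit(gsub("[()]", "", g), ",", fixed = TRUE)[[1]])
  })
  partition(blocks, n)
}

#' The discrete (microscale) partition
#'
#' All-singleton partition `(0),(1),...,(n-1)`: the microscale itself.
#'
#' @param n number of microstates.
#' @return a [partition].
#' @export
discrete_partition <- function(n) {
  partition(as.list(0:(n - 1)), n)
}

block_membership <- function(part) {
  # 1-based vector: membership[i+1] = block index of microstate i
  m <- integer(part$n_micro)
  for (j in seq_along(part$blocks)) m[part$blocks[[j]] + 1L] <- j
  m
}

block_label <- function(block, labels) {
  if (length(block) == 1) labels[block + 1L]
  else sprintf("(%s)", paste(labels[block + 1L], collapse = ","))
}

#' Coarse-grain a transition matrix by a partition
#'
#' Builds the macroscale TPM with one macrostate per block. With uniform
#' aggregation (the default, matching uniform interventions) the macro
#' transition probability is the average outflow of the block's member
#' rows: `P(B | A) = (1/|A|) sum_{i in A} sum_{j in B} P(j | i)`. With
#' `weights` supplied (e.g. a stationary law), member rows are averaged
#' with the given weights restricted to the block and renormalized.
#'
#' @param tm a [tpm].
#' @param part a [partition] of `tm`'s states.
#' @param weights optional microstate weights for the row aggregation;
#'   `NULL` means uniform within each block.
#' @return a [tpm] over the macrostates; rows are stochastic by
#'   construction.
#' @export
coarse_grain_tpm <- function(tm, part, weights = NULL) {
  n <- n_states(tm)
  if (part$n_micro != n) {
    ce_stop(sprintf("partition covers %d states but TPM has %d", part$n_micro, n))
  }
  k <- n_blocks(part)
  P <- unclass(tm)
  if (is.null(weights)) weights <- rep(1, n) else weights <- as.numeric(weights)
  M <- matrix(0, k, k)
  for (a in seq_len(k)) {
    rows <- part$blocks[[a]] + 1L
    w <- weights[rows]
    if (sum(w) <= 0) w <- rep(1, length(rows))
    w <- w / sum(w)
    row_avg <- drop(w %*% P[rows, , drop = FALSE])
    for (b in seq_len(k)) {
      M[a, b] <- sum(row_avg[part$blocks[[b]] + 1L])
    }
  }
  labs <- vapply(part$blocks, block_label, character(1),
                 labels = state_labels(tm))
  tpm(M, labels = labs, tol = 1e-6)
}

#' Refinement order on partitions
#'
#' `finer` refines `coarser` when every block of `finer` lies inside some
#' block of `coarser`; i.e. `coarser` is a further coarse grain of
#' `finer`, so `finer -> coarser` is a legal step on a micro-to-macro
#' path.
#'
#' @param finer,coarser [partition]s over the same number of microstates.
#' @return `TRUE` or `FALSE`.
#' @export
is_refinement <- function(finer, coarser) {
  if (finer$n_micro != coarser$n_micro) {
    ce_stop("partitions cover different numbers of microstates")
  }
  mc <- block_membership(coarser)
  all(vapply(finer$blocks, function(b) length(unique(mc[b + 1L])) == 1, logical(1)))
}

#' Enumerate all set partitions of n states
#'
#' Yields every set partition of `0..n-1` exactly once, in canonical
#' (restricted-growth-string) order; the count is the Bell number
#' `B(n)`. Guarded at `n = 10` (`B(10) = 115975`) against accidental
#' combinatorial blow-ups.
#'
#' @param n number of microstates.
#' @param limit guard on `n`; pass a larger value to override.
#' @return list of [partition]s.
#' @export
enumerate_partitions <- function(n, limit = 10) {
  if (n > limit) {
    ce_stop(sprintf("n = %d exceeds the enumeration guard (%d); raise `limit` to override",
                    n, limit))
  }
  if (n == 0) return(list(partition(list(), 0)))
  # restricted growth strings: a[1] = 0, a[i] <= max(a[1..i-1]) + 1
  out <- vector("list", 0)
  a <- integer(n)
  recurse <- function(i, mx) {
    if (i > n) {
      blocks <- split(0:(n - 1), a)
      out[[length(out) + 1L]] <<- partition(blocks, n)
      return(invisible())
    }
    for (v in 0:(mx + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(mx, v))
    }
  }
  a[1] <- 0L
  recurse(2L, 0L)
  out
}

#' Merge two blocks of a partition
#'
#' @param part a [partition].
#' @param i,j 1-based block indices to merge.
#' @return the coarser [partition].
#' @export
merge_blocks <- function(part, i, j) {
  blocks <- part$blocks
  merged <- c(blocks[[i]], blocks[[j]])
  blocks <- blocks[-c(i, j)]
  blocks[[length(blocks) + 1L]] <- merged
  partition(blocks, part$n_micro)
}

#' Coarse-grain a distribution over states
#'
#' Lumps a probability vector over microstates into block masses (block
#' mass = sum of member masses). Used for the observed/stationary
#' intervention variant, where the macroscale `P(C)` is directly the
#' coarse grain of the microscale `P(C)`; the uniform mode instead
#' regenerates a uniform distribution at each scale.
#'
#' @param pc an `intervention` (or probability vector) over microstates.
#' @param part a [partition].
#' @return an `intervention` over the macrostates.
#' @export
coarsen_distribution <- function(pc, part) {
  w <- if (inherits(pc, "intervention")) pc$weights else as.numeric(pc)
  if (length(w) != part$n_micro) {
    ce_stop("distribution length does not match the partition")
  }
  mode <- if (inherits(pc, "intervention")) pc$mode else "custom"
  macro <- vapply(part$blocks, function(b) sum(w[b + 1L]), numeric(1))
  intervention(macro, mode = if (mode == "uniform") "custom" else mode)
}

lump_vector <- function(v, part) {
  vapply(part$blocks, function(b) sum(v[b + 1L]), numeric(1))
}

#' Dynamical-consistency check for a macroscale
#'
#' Tests whether the macroscale TPM of `part` faithfully summarizes the
#' microscale dynamics: for each macrostate `A` and each horizon
#' `t = 1..horizon`, the uniform distribution over `A`'s microstates is
#' evolved `t` steps under the microscale TPM and then lumped, and
#' compared (total-variation distance) with the point mass on `A` evolved
#' `t` steps under the macroscale TPM. The macroscale is consistent when
#' the largest discrepancy is at most `tol`. This is a lumpability-style
#' random-walker criterion: partitions over exact equivalency classes
#' (identical rows) always pass.
#'
#' @param tm the microscale [tpm].
#' @param part a [partition].
#' @param tol total-variation tolerance.
#' @param horizon number of steps checked.
#' @return an object of class `consistency_result`: list with elements
#'   `consistent`, `max_error`, `horizon_checked`.
#' @export
consistency_check <- function(tm, part, tol = 1e-9, horizon = 3) {
  if (horizon < 1) ce_stop("horizon must be at least 1")
  P <- unclass(tm)
  macro <- coarse_grain_tpm(tm, part)
  M <- unclass(macro)
  k <- n_blocks(part)
  max_err <- 0
  for (a in seq_len(k)) {
    members <- part$blocks[[a]] + 1L
    v <- numeric(nrow(P)); v[members] <- 1 / length(members)
    m <- numeric(k); m[a] <- 1
    for (t in seq_len(horizon)) {
      v <- drop(v %*% P)
      m <- drop(m %*% M)
      tv <- 0.5 * sum(abs(lump_vector(v, part) - m))
      if (tv > max_err) max_err <- tv
    }
  }
  structure(list(consistent = max_err <= tol, max_error = max_err,
                 horizon_checked = as.integer(horizon)),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("Dynamical consistency: %s (max TV error %.3g over %d steps)\n",
              if (x$consistent) "PASS" else "FAIL", x$max_error,
              x$horizon_checked))
  invisible(x)
}
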