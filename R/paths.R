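pc_for_scale <- function(macro_tm, part, pc_mode) {
  if (inherits(pc_mode, "intervention")) {
    coarsen_distribution(pc_mode, part)
  } else {
    pc_mode <- match.arg(pc_mode, c("uniform", "stationary"))
    if (pc_mode == "uniform") uniform_intervention(n_states(macro_tm))
    else stationary_distribution(macro_tm)
  }
}

scale_cp <- function(tm, part, pc_mode = "uniform",
                     measure = c("cp_info", "cp_primitive")) {
  measure <- match.arg(measure)
  macro <- if (n_blocks(part) == n_states(tm)) tm else coarse_grain_tpm(tm, part)
  if (n_blocks(part) < 2) return(0)
  cp_value(macro, pc_for_scale(macro, part, pc_mode), measure)
}

partition_preference <- function(parts) {
  # order: more blocks first, then lexicographically smaller canonical label
  labs <- vapply(parts, format, character(1))
  order(-vapply(parts, n_blocks, integer(1)), labs)
}

#' Exhaustive endpoint search over all coarse grains
#'
#' Enumerates every set partition of the microstates (within the Bell
#' number guard), discards dynamically inconsistent macroscales, computes
#' the combined causal-primitive score of each survivor, and returns the
#' maximizer. Ties at the maximal score are broken in favor of the least
#' dimensionality reduction (most macrostates) — the point past which
#' coarse-graining stops paying — then by lexicographically smallest
#' canonical label.
#'
#' @param tm microscale [tpm].
#' @param pc_mode `"uniform"`, `"stationary"`, or an `intervention` over
#'   the microstates (coarsened at each scale).
#' @param measure `"cp_info"` (determinism + specificity - 1, the
#'   default) or `"cp_primitive"` (sufficiency + necessity - 1).
#' @param consistency_tol,horizon consistency-filter settings, see
#'   [consistency_check()].
#' @param limit enumeration guard passed to [enumerate_partitions()].
#' @return an object of class `endpoint_choice`: list with `partition`,
#'   `cp`, `n_macro_states`, `search_mode`, and `evaluated` (a data frame
#'   of every consistent partition with its score).
#' @export
find_endpoint_exhaustive <- function(tm, pc_mode = "uniform",
                                     measure = c("cp_info", "cp_primitive"),
                                     consistency_tol = 1e-9, horizon = 3,
                                     limit = 10) {
  measure <- match.arg(measure)
  n <- n_states(tm)
  parts <- enumerate_partitions(n, limit = limit)
  keep <- vapply(parts, function(p)
    consistency_check(tm, p, tol = consistency_tol, horizon = horizon)$consistent,
    logical(1))
  parts <- parts[keep]
  cps <- vapply(parts, scale_cp, numeric(1), tm = tm,
                pc_mode = pc_mode, measure = measure)
  best <- max(cps)
  tied <- which(cps >= best - 1e-9)
  pick <- tied[partition_preference(parts[tied])[1]]
  structure(list(
    partition = parts[[pick]],
    cp = cps[pick],
    n_macro_states = n_blocks(parts[[pick]]),
    search_mode = "exhaustive",
    evaluated = data.frame(
      partition = vapply(parts, format, character(1)),
      n_blocks = vapply(parts, n_blocks, integer(1)),
      cp = cps, stringsAsFactors = FALSE)
  ), class = "endpoint_choice")
}

#' Greedy endpoint search with a diminishing-returns stop
#'
#' Starting from the microscale, repeatedly applies the single pairwise
#' block merge that maximizes the gain in CP among dynamically consistent
#' merges. The walk halts when the best available gain has stayed below
#' `epsilon` for `window` consecutive steps (the diminishing-returns
#' transition) or when no consistent merge remains. The endpoint returned
#' is the highest-dimensional scale attaining the maximum CP along the
#' visited trajectory, mirroring the exhaustive tie-break.
#'
#' @inheritParams find_endpoint_exhaustive
#' @param epsilon positive gain threshold for diminishing returns.
#' @param window number of consecutive sub-`epsilon` steps that triggers
#'   the stop.
#' @return an `endpoint_choice` (with `search_mode = "greedy"` and the
#'   visited `trajectory`).
#' @export
find_endpoint_greedy <- function(tm, pc_mode = "uniform",
                                 measure = c("cp_info", "cp_primitive"),
                                 epsilon = 1e-6, window = 3,
                                 consistency_tol = 1e-9, horizon = 3) {
  measure <- match.arg(measure)
  if (epsilon <= 0) ce_stop("epsilon must be positive")
  if (window < 1) ce_stop("window must be at least 1")
  cur <- discrete_partition(n_states(tm))
  visited <- list(cur)
  cps <- scale_cp(tm, cur, pc_mode, measure)
  low_run <- 0L
  while (n_blocks(cur) > 1L) {
    k <- n_blocks(cur)
    cand <- list(); gain <- numeric(0)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      p <- merge_blocks(cur, i, j)
      if (!consistency_check(tm, p, tol = consistency_tol,
                             horizon = horizon)$consistent) next
      cand[[length(cand) + 1L]] <- p
      gain <- c(gain, scale_cp(tm, p, pc_mode, measure) - cps[length(cps)])
    }
    if (length(cand) == 0) break
    top <- which(gain >= max(gain) - 1e-12)
    pick <- top[partition_preference(cand[top])[1]]
    cur <- cand[[pick]]
    visited[[length(visited) + 1L]] <- cur
    cps <- c(cps, cps[length(cps)] + gain[pick])
    low_run <- if (gain[pick] < epsilon) low_run + 1L else 0L
    if (low_run >= window) break
  }
  best <- max(cps)
  tied <- which(cps >= best - 1e-9)
  pick <- tied[1]                        # earliest = most macrostates on a merge walk
  structure(list(
    partition = visited[[pick]],
    cp = cps[pick],
    n_macro_states = n_blocks(visited[[pick]]),
    search_mode = "greedy",
    trajectory = data.frame(
      partition = vapply(visited, format, character(1)),
      n_blocks = vapply(visited, n_blocks, integer(1)),
      cp = cps, stringsAsFactors = FALSE)
  ), class = "endpoint_choice")
}

#' @export
print.endpoint_choice <- function(x, ...) {
  cat(sprintf("Endpoint macroscale (%s search): %s\n", x$search_mode,
              format(x$partition)))
  cat(sprintf("  CP = %.6g over %d macrostates\n", x$cp, x$n_macro_states))
  invisible(x)
}

#' Build a micro-to-macro path to an endpoint
#'
#' Constructs a maximal chain of dynamically consistent partitions from
#' the discrete (microscale) partition to the endpoint, merging one pair
#' of blocks per step where possible (the longest chain). At each step
#' the consistent merge with the largest CP gain is taken (a merge with
#' negative gain is never chosen while a nonnegative alternative exists);
#' ties are broken lexicographically by canonical label, which makes
#' contribution profiles reproducible. If the single-merge chain gets
#' stuck before the endpoint, the path jumps directly to the endpoint and
#' the result is flagged `non_maximal_chain`.
#'
#' @inheritParams find_endpoint_exhaustive
#' @param endpoint a [partition] (or partition string): the final
#'   macroscale; must be dynamically consistent.
#' @return an object of class `ce_path`: list with `scales` (partitions),
#'   `labels`, `cp_values`, `deltas`, `total_ce`, `measure`, `pc_mode`,
#'   `consistency` (per-scale [consistency_check()] results) and `flags`.
#' @export
build_path <- function(tm, endpoint, pc_mode = "uniform",
                       measure = c("cp_info", "cp_primitive"),
                       consistency_tol = 1e-9, horizon = 3) {
  measure <- match.arg(measure)
  n <- n_states(tm)
  if (is.character(endpoint)) endpoint <- parse_partition(endpoint, n)
  end_check <- consistency_check(tm, endpoint, tol = consistency_tol,
                                 horizon = horizon)
  if (!end_check$consistent) {
    ce_stop(sprintf("endpoint %s is not dynamically consistent (max TV error %.3g)",
                    format(endpoint), end_check$max_error),
            class = "ce_inconsistent_endpoint")
  }
  cur <- discrete_partition(n)
  if (!is_refinement(cur, endpoint)) {
    ce_stop("endpoint must be a coarse grain of the microscale")
  }
  scales <- list(cur)
  checks <- list(consistency_check(tm, cur, tol = consistency_tol, horizon = horizon))
  cps <- scale_cp(tm, cur, pc_mode, measure)
  flags <- character(0)
  end_m <- block_membership(endpoint)
  while (n_blocks(cur) > n_blocks(endpoint)) {
    k <- n_blocks(cur)
    cand <- list(); cand_cp <- numeric(0); cand_check <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      # only merges that stay on the way to the endpoint
      if (end_m[cur$blocks[[i]][1] + 1L] != end_m[cur$blocks[[j]][1] + 1L]) next
      p <- merge_blocks(cur, i, j)
      chk <- consistency_check(tm, p, tol = consistency_tol, horizon = horizon)
      if (!chk$consistent) next
      cand[[length(cand) + 1L]] <- p
      cand_check[[length(cand_check) + 1L]] <- chk
      cand_cp <- c(cand_cp, scale_cp(tm, p, pc_mode, measure))
    }
    if (length(cand) == 0) {
      # stuck: finish with a direct (multi-merge) jump to the endpoint
      flags <- c(flags, "non_maximal_chain")
      scales[[length(scales) + 1L]] <- endpoint
      checks[[length(checks) + 1L]] <- end_check
      cps <- c(cps, scale_cp(tm, endpoint, pc_mode, measure))
      break
    }
    top <- which(cand_cp >= max(cand_cp) - 1e-12)
    labs <- vapply(cand[top], format, character(1))
    pick <- top[order(labs)[1]]
    cur <- cand[[pick]]
    scales[[length(scales) + 1L]] <- cur
    checks[[length(checks) + 1L]] <- cand_check[[pick]]
    cps <- c(cps, cand_cp[pick])
  }
  deltas <- if (length(cps) > 1) diff(cps) else numeric(0)
  structure(list(
    scales = scales,
    labels = vapply(scales, format, character(1)),
    cp_values = cps,
    deltas = deltas,
    total_ce = cps[length(cps)] - cps[1],
    measure = measure,
    pc_mode = if (inherits(pc_mode, "intervention")) pc_mode$mode else pc_mode,
    consistency = checks,
    flags = flags
  ), class = "ce_path")
}

#' @export
print.ce_path <- function(x, digits = 4, ...) {
  cat(sprintf("Micro-to-macro path: %d scales, measure = %s, P(C) = %s\n",
              length(x$scales), x$measure, x$pc_mode))
  df <- as.data.frame(x)
  print(df, digits = digits, row.names = FALSE)
  cat(sprintf("Total causal emergence: %.4g\n", x$total_ce))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ce_path <- function(x, ...) {
  data.frame(
    scale = x$labels,
    n_states = vapply(x$scales, n_blocks, integer(1)),
    cp = x$cp_values,
    delta_cp = c(NA, x$deltas),
    stringsAsFactors = FALSE
  )
}

#' Apportion causal contributions along a path
#'
#' Assigns the microscale its baseline CP and each subsequent scale the
#' CP gain of the step that created it; the contributions telescope, so
#' they sum to the CP of the endpoint.
#'
#' @param path a [build_path()] result.
#' @return data frame with columns `scale` and `contribution`.
#' @export
apportion <- function(path) {
  data.frame(
    scale = path$labels,
    contribution = c(path$cp_values[1], path$deltas),
    stringsAsFactors = FALSE
  )
}

#' Upper bound on causal emergence
#'
#' `1 - CP(microscale)`: since CP is at most 1 at any scale and gains
#' telescope, no micro-to-macro path can accumulate more than this. A
#' quick screen before any search across scales.
#'
#' @inheritParams find_endpoint_exhaustive
#' @return a nonnegative number (0 for a permutation microscale).
#' @export
ce_upper_bound <- function(tm, pc_mode = "uniform",
                           measure = c("cp_info", "cp_primitive")) {
  measure <- match.arg(measure)
  1 - cp_value(tm, pc_for_scale(tm, discrete_partition(n_states(tm)), pc_mode),
               measure)
}
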