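#' Multiscale causal-emergence analysis of a Markov system
#'
#' The main entry point: takes a microscale transition probability matrix
#' and apportions the system's causal workings across its hierarchy of
#' scales. The pipeline (1) scores the microscale's causal primitives,
#' (2) selects the endpoint macroscale — the dynamically consistent
#' coarse grain maximizing the combined causal-primitive score CP, with
#' ties broken toward the least dimensionality reduction, (3) builds the
#' longest consistent micro-to-macro path of single block merges to that
#' endpoint, (4) apportions the per-step CP gains to their scales, and
#' (5) summarizes the gain distribution as the emergent-complexity
#' entropy and a contribution-profile label. An effective-information
#' comparison (the single-scale predecessor analysis) and a
#' singular-value reversibility screen are attached alongside.
#'
#' @param x a [tpm], a numeric matrix, or a path/string readable by
#'   [read_tpm()].
#' @param measure `"cp_info"` (determinism + specificity - 1; default,
#'   matching the effectiveness of the earlier effective-information
#'   framework) or `"cp_primitive"` (sufficiency + necessity - 1).
#' @param pc_mode `"uniform"` (default: every state of a scale is an
#'   equally viable intervention), `"stationary"` (the observed long-run
#'   law at each scale), or an `intervention` over the microstates.
#' @param endpoint `"exhaustive"` (brute-force search over all
#'   consistent partitions), `"greedy"` (pairwise merges with a
#'   diminishing-returns stop), or a fixed [partition]/partition string.
#' @param epsilon,window diminishing-returns settings for the greedy
#'   search, see [find_endpoint_greedy()].
#' @param consistency_tol,horizon dynamical-consistency filter settings,
#'   see [consistency_check()].
#' @param limit Bell-number enumeration guard for exhaustive search.
#' @param zero_steps treatment of zero-gain steps in the
#'   emergent-complexity entropy, see [emergent_complexity()].
#' @param heuristics include the singular-value reversibility screen.
#' @return an object of class `causal_emergence` with components
#'   `tpm`, `config`, `micro_scores`, `bound`, `endpoint`, `path`,
#'   `contributions`, `complexity`, `profile`, `ei_comparison` and
#'   `heuristics`. Supports `print()`, `summary()`, `coef()` (per-scale
#'   CP), `plot()` and `simulate()` (trajectories of the fitted chain).
#' @examples
#' sys <- make_cycle_plus_block(4, 4)
#' fit <- causal_emergence(sys)
#' fit
#' coef(fit)
#' @export
causal_emergence <- function(x,
                             measure = c("cp_info", "cp_primitive"),
                             pc_mode = "uniform",
                             endpoint = "exhaustive",
                             epsilon = 1e-6, window = 3,
                             consistency_tol = 1e-9, horizon = 3,
                             limit = 10,
                             zero_steps = c("include", "exclude"),
                             heuristics = TRUE) {
  measure <- match.arg(measure)
  zero_steps <- match.arg(zero_steps)
  tm <- if (inherits(x, "tpm")) x
        else if (is.matrix(x)) tpm(x)
        else read_tpm(x)
  n <- n_states(tm)
  config <- list(measure = measure,
                 pc_mode = if (inherits(pc_mode, "intervention")) pc_mode$mode else pc_mode,
                 endpoint_mode = if (inherits(endpoint, "partition")) "fixed"
                                 else if (endpoint %in% c("exhaustive", "greedy")) endpoint
                                 else "fixed",
                 epsilon = epsilon, window = window,
                 consistency_tol = consistency_tol, horizon = horizon,
                 zero_steps = zero_steps)

  micro_pc <- pc_for_scale(tm, discrete_partition(n), pc_mode)
  micro_scores <- cp_scores(tm, micro_pc)
  bound <- ce_upper_bound(tm, pc_mode, measure)

  ep <- if (inherits(endpoint, "partition") ||
            (is.character(endpoint) && !endpoint %in% c("exhaustive", "greedy"))) {
    part <- if (is.character(endpoint)) parse_partition(endpoint, n) else endpoint
    structure(list(partition = part,
                   cp = scale_cp(tm, part, pc_mode, measure),
                   n_macro_states = n_blocks(part),
                   search_mode = "fixed"), class = "endpoint_choice")
  } else if (endpoint == "greedy") {
    find_endpoint_greedy(tm, pc_mode, measure, epsilon = epsilon,
                         window = window, consistency_tol = consistency_tol,
                         horizon = horizon)
  } else {
    find_endpoint_exhaustive(tm, pc_mode, measure,
                             consistency_tol = consistency_tol,
                             horizon = horizon, limit = limit)
  }

  path <- build_path(tm, ep$partition, pc_mode, measure,
                     consistency_tol = consistency_tol, horizon = horizon)
  contrib <- apportion(path)
  complexity <- if (length(path$deltas) > 0) {
    emergent_complexity(path, zero_steps = zero_steps)
  } else {
    # single-scale path (endpoint = microscale): EC has no steps to distribute
    structure(list(gains = numeric(0), p = numeric(0), ec_bits = NA_real_,
                   ec_normalized = NA_real_, L = 0L, zero_steps = zero_steps,
                   profile = NA_character_, flags = "no_steps"),
              class = "ec_report")
  }
  profile <- classify_profile(path)
  if (!is.null(complexity)) complexity$profile <- profile

  macro_tm <- if (n_blocks(ep$partition) == n) tm
              else coarse_grain_tpm(tm, ep$partition)
  ei_micro <- effective_information(tm, micro_pc)
  ei_macro <- effective_information(macro_tm,
                                    pc_for_scale(macro_tm, ep$partition, pc_mode))
  out <- list(
    tpm = tm,
    config = config,
    micro_scores = micro_scores,
    bound = bound,
    endpoint = ep,
    path = path,
    contributions = contrib,
    complexity = complexity,
    profile = profile,
    ei_comparison = list(ei_micro = ei_micro, ei_endpoint = ei_macro,
                         ei_gain = ei_macro - ei_micro,
                         ce1_emergence = max(0, ei_macro - ei_micro)),
    heuristics = if (heuristics) list(svd_reversibility = svd_reversibility(tm))
                 else NULL,
    call = match.call()
  )
  class(out) <- "causal_emergence"
  out
}

#' @export
print.causal_emergence <- function(x, digits = 4, ...) {
  cat("Multiscale causal-emergence analysis\n")
  cat(sprintf("  %d microstates; measure = %s; P(C) = %s; endpoint search = %s\n",
              n_states(x$tpm), x$config$measure, x$config$pc_mode,
              x$config$endpoint_mode))
  cat(sprintf("  CP(micro) = %.*g   CE bound (1 - CP(micro)) = %.*g\n",
              digits, x$path$cp_values[1], digits, x$bound))
  cat(sprintf("  endpoint: %s  (CP = %.*g)\n", format(x$endpoint$partition),
              digits, x$endpoint$cp))
  cat(sprintf("  total causal emergence = %.*g over %d path steps\n",
              digits, x$path$total_ce, length(x$path$deltas)))
  if (!is.null(x$complexity) && !is.na(x$complexity$ec_bits)) {
    cat(sprintf("  emergent complexity = %.*g bits (normalized %.*g)\n",
                digits, x$complexity$ec_bits, digits,
                x$complexity$ec_normalized))
  }
  cat(sprintf("  contribution profile: %s\n", x$profile))
  invisible(x)
}

#' @export
summary.causal_emergence <- function(object, ...) {
  structure(list(fit = object,
                 path_table = as.data.frame(object$path),
                 contributions = object$contributions),
            class = "summary.causal_emergence")
}

#' @export
print.summary.causal_emergence <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-scale causal apportioning:\n")
  tab <- x$path_table
  tab$contribution <- x$contributions$contribution
  print(tab, digits = digits, row.names = FALSE)
  s <- x$fit$micro_scores
  cat(sprintf("\nMicroscale primitives: suff %.4g  nec %.4g  det %.4g  deg %.4g  EI %.4g bits\n",
              s$suff_sys, s$nec_sys, s$determinism, s$degeneracy, s$ei))
  ei <- x$fit$ei_comparison
  cat(sprintf("EI comparison: micro %.4g bits, endpoint %.4g bits (gain %.4g)\n",
              ei$ei_micro, ei$ei_endpoint, ei$ei_gain))
  invisible(x)
}

#' @export
coef.causal_emergence <- function(object, ...) {
  stats::setNames(object$path$cp_values, object$path$labels)
}

#' Plot the causal apportioning of a fitted analysis
#'
#' Two base-graphics panels: CP along the micro-to-macro path (one point
#' per scale, by decreasing dimensionality) and the per-scale causal
#' contributions (microscale baseline plus per-step gains).
#'
#' @param x a [causal_emergence()] fit.
#' @param ... passed to [barplot()].
#' @export
plot.causal_emergence <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  k <- vapply(x$path$scales, n_blocks, integer(1))
  graphics::plot(seq_along(k), x$path$cp_values, type = "b", pch = 19,
                 xaxt = "n", xlab = "", ylab = "CP",
                 main = "CP along the path", ylim = c(0, 1.05))
  graphics::axis(1, at = seq_along(k), labels = sprintf("%d states", k),
                 las = 2, cex.axis = 0.8)
  graphics::barplot(x$contributions$contribution,
                    names.arg = x$contributions$scale, las = 2,
                    cex.names = 0.6, ylab = expression(Delta * "CP"),
                    main = sprintf("Causal contributions (%s)", x$profile), ...)
  invisible(x)
}

#' Simulate trajectories from the fitted microscale chain
#'
#' @param object a [causal_emergence()] fit.
#' @param nsim trajectory length (number of transitions).
#' @param seed optional RNG seed.
#' @param init 0-based starting state index; default drawn uniformly.
#' @param ... unused.
#' @return character vector of `nsim + 1` visited state labels.
#' @export
simulate.causal_emergence <- function(object, nsim = 100, seed = NULL,
                                      init = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- unclass(object$tpm)
  n <- nrow(P)
  s <- if (is.null(init)) sample.int(n, 1) else as.integer(init) + 1L
  out <- integer(nsim + 1); out[1] <- s
  for (t in seq_len(nsim)) {
    s <- sample.int(n, 1, prob = P[s, ])
    out[t + 1] <- s
  }
  state_labels(object$tpm)[out]
}
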