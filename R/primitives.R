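resolve_pc <- function(tm, pc) {
  if (inherits(pc, "intervention")) {
    if (length(pc$weights) != n_states(tm)) {
      ce_stop("intervention distribution length does not match the TPM")
    }
    return(pc)
  }
  if (is.character(pc)) {
    pc <- match.arg(pc, c("uniform", "stationary"))
    return(switch(pc,
                  uniform = uniform_intervention(n_states(tm)),
                  stationary = stationary_distribution(tm)))
  }
  intervention(pc)
}

#' Sufficiency of a cause for an effect
#'
#' The sufficiency of cause state `c` for effect state `e` is the
#' transition probability `P(e | c)`: the certainty that intervening to
#' set the system in `c` brings about `e` at the next step.
#'
#' @param tm a [tpm].
#' @param c,e 0-based state indices (cause and effect).
#' @return `P(e | c)`.
#' @export
sufficiency <- function(tm, c, e) {
  n <- n_states(tm)
  if (c < 0 || c >= n || e < 0 || e >= n) ce_stop("state index out of range")
  unclass(tm)[c + 1L, e + 1L]
}

#' Necessity of a cause for an effect
#'
#' `nec(e, c) = 1 - P(e | C, not-c)`: one minus the probability of the
#' effect arising from the other causes, drawn from the intervention
#' distribution restricted to causes other than `c` and renormalized.
#' Equals 1 when no other state leads to `e`.
#'
#' @inheritParams sufficiency
#' @param pc intervention distribution `P(C)` (an `intervention`, a
#'   weight vector, or `"uniform"`/`"stationary"`).
#' @return `1 - P(e | C, not-c)` in `[0, 1]`.
#' @export
necessity <- function(tm, c, e, pc = "uniform") {
  n <- n_states(tm)
  if (n < 2) ce_stop("necessity is undefined for a 1-state system (no alternative causes)")
  if (c < 0 || c >= n || e < 0 || e >= n) ce_stop("state index out of range")
  pc <- resolve_pc(tm, pc)
  w <- pc$weights
  rest <- 1 - w[c + 1L]
  if (rest <= 0) ce_stop("P(C) places all mass on the cause; necessity undefined")
  p_e_notc <- sum(w[-(c + 1L)] * unclass(tm)[-(c + 1L), e + 1L]) / rest
  1 - p_e_notc
}

#' System-wide sufficiency and necessity
#'
#' Expectations of per-transition sufficiency and necessity over `(c, e)`
#' pairs weighted by `pc(c) * P(e | c)`, so the weights form a probability
#' measure over realized transitions:
#' `suff_sys = sum_c pc(c) sum_e P(e|c)^2` and
#' `nec_sys  = sum_c pc(c) sum_e P(e|c) * nec(e, c)`.
#'
#' @inheritParams necessity
#' @return a value in `[0, 1]`.
#' @export
system_sufficiency <- function(tm, pc = "uniform") {
  pc <- resolve_pc(tm, pc)
  P <- unclass(tm)
  sum(pc$weights * rowSums(P * P))
}

#' @rdname system_sufficiency
#' @export
system_necessity <- function(tm, pc = "uniform") {
  n <- n_states(tm)
  if (n < 2) ce_stop("system necessity is undefined for a 1-state system")
  pc <- resolve_pc(tm, pc)
  P <- unclass(tm)
  w <- pc$weights
  if (any(1 - w <= 0)) ce_stop("P(C) places all mass on one cause; necessity undefined")
  pe <- drop(w %*% P)                      # P(e | C)
  # P(e | C, not-c) = (pe - w_c P(e|c)) / (1 - w_c); nec = 1 - that
  nec_mat <- 1 - (matrix(pe, n, n, byrow = TRUE) - w * P) / (1 - w)
  sum(w * rowSums(P * nec_mat))
}

#' Determinism coefficient
#'
#' One minus the normalized conditional entropy of effects given causes:
#' `sum_c pc(c) * (1 - H(E | c) / log2(n))`, with `H(E | c)` the entropy
#' of row `c`. Maximal (1) when every row is one-hot; zero when every row
#' is uniform. The information-theoretic generalization of sufficiency.
#'
#' @inheritParams necessity
#' @return a value in `[0, 1]`.
#' @export
determinism_coefficient <- function(tm, pc = "uniform") {
  n <- n_states(tm)
  if (n < 2) ce_stop("determinism coefficient is undefined for a 1-state system")
  pc <- resolve_pc(tm, pc)
  h_rows <- apply(unclass(tm), 1, shannon_entropy)
  sum(pc$weights * (1 - h_rows / log2(n)))
}

#' Degeneracy coefficient and specificity
#'
#' `degeneracy = 1 - H(E) / log2(n)` where `P(e | C) = sum_c pc(c) P(e|c)`
#' is the effect distribution under the intervention prior. High when many
#' causes share effects; zero when every cause has a unique effect.
#' `specificity = 1 - degeneracy`, the inclusive inverse generalization of
#' necessity.
#'
#' @inheritParams necessity
#' @return a value in `[0, 1]`.
#' @export
degeneracy_coefficient <- function(tm, pc = "uniform") {
  n <- n_states(tm)
  if (n < 2) ce_stop("degeneracy coefficient is undefined for a 1-state system")
  pc <- resolve_pc(tm, pc)
  pe <- drop(pc$weights %*% unclass(tm))
  1 - shannon_entropy(pe) / log2(n)
}

#' @rdname degeneracy_coefficient
#' @export
specificity_coefficient <- function(tm, pc = "uniform") {
  1 - degeneracy_coefficient(tm, pc)
}

#' Effective information
#'
#' `EI = (determinism - degeneracy) * log2(n)`, in bits: the mutual
#' information between intervention-distributed causes and their effects.
#' The factor `determinism - degeneracy` is the effectiveness; `log2(n)`
#' is the size term. A 1-state system carries 0 bits.
#'
#' @inheritParams necessity
#' @return bits.
#' @export
effective_information <- function(tm, pc = "uniform") {
  n <- n_states(tm)
  if (n < 2) return(0)
  (determinism_coefficient(tm, pc) - degeneracy_coefficient(tm, pc)) * log2(n)
}

#' All scale-level causal scores for one transition matrix
#'
#' Computes the causal primitives and their information-theoretic
#' generalizations for one scale: system-wide sufficiency and necessity,
#' determinism, degeneracy, specificity, the two combined causal-primitive
#' scores `cp_primitive = suff_sys + nec_sys - 1` and
#' `cp_info = determinism + specificity - 1` (identically
#' `determinism - degeneracy`, the effectiveness), and the effective
#' information. For a 1-state scale all combined scores are 0 by
#' convention (no causal distinctions exist).
#'
#' Combined scores are reported un-clamped: negative values would signal a
#' violation of the expected `[0, 1]` range and are flagged rather than
#' hidden.
#'
#' @inheritParams necessity
#' @return an object of class `cp_scores` (a named list).
#' @export
cp_scores <- function(tm, pc = "uniform") {
  n <- n_states(tm)
  pc_res <- if (n < 2 && is.character(pc)) NULL else resolve_pc(tm, pc)
  mode <- if (inherits(pc_res, "intervention")) pc_res$mode
          else if (is.character(pc)) pc else "custom"
  if (n < 2) {
    out <- list(suff_sys = 1, nec_sys = NA_real_, determinism = NA_real_,
                degeneracy = NA_real_, specificity = NA_real_,
                cp_primitive = 0, cp_info = 0, effectiveness = 0,
                ei = 0, n_states = 1L, pc_mode = mode, flags = character(0))
    class(out) <- "cp_scores"
    return(out)
  }
  suff <- system_sufficiency(tm, pc_res)
  nec <- system_necessity(tm, pc_res)
  det <- determinism_coefficient(tm, pc_res)
  deg <- degeneracy_coefficient(tm, pc_res)
  spec <- 1 - deg
  out <- list(
    suff_sys = suff,
    nec_sys = nec,
    determinism = det,
    degeneracy = deg,
    specificity = spec,
    cp_primitive = suff + nec - 1,
    cp_info = det + spec - 1,
    effectiveness = det - deg,
    ei = (det - deg) * log2(n),
    n_states = as.integer(n),
    pc_mode = mode,
    flags = character(0)
  )
  if (out$cp_primitive < 0) out$flags <- c(out$flags, "negative_cp_primitive")
  if (out$cp_info < 0) out$flags <- c(out$flags, "negative_cp_info")
  class(out) <- "cp_scores"
  out
}

#' @export
print.cp_scores <- function(x, digits = 4, ...) {
  cat(sprintf("Causal scores (%d states, P(C) = %s)\n", x$n_states, x$pc_mode))
  vals <- c(sufficiency = x$suff_sys, necessity = x$nec_sys,
            determinism = x$determinism, degeneracy = x$degeneracy,
            specificity = x$specificity, `CP (suff+nec-1)` = x$cp_primitive,
            `CP (det+spec-1)` = x$cp_info, `EI (bits)` = x$ei)
  print(round(vals, digits))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

cp_value <- function(tm, pc = "uniform", measure = c("cp_info", "cp_primitive")) {
  measure <- match.arg(measure)
  if (n_states(tm) < 2) return(0)
  if (measure == "cp_info") {
    determinism_coefficient(tm, pc) - degeneracy_coefficient(tm, pc)
  } else {
    system_sufficiency(tm, pc) + system_necessity(tm, pc) - 1
  }
}
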