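#' Emergent complexity of a micro-to-macro path
#'
#' Normalizes the per-step CP gains along a path (microscale excluded)
#' into a probability distribution `p_i = delta_i / sum_j delta_j` and
#' returns its Shannon entropy in bits: `EC = -sum p_i log2 p_i`. EC
#' equals `log2(L)` when all `L` steps gain equally (a maximally
#' multiscale system) and 0 when a single scale holds the lone
#' contribution. Zero-gain steps contribute zero entropy; with
#' `zero_steps = "exclude"` they are dropped from the path (shrinking the
#' effective `L`) before normalizing. Negative gains are clamped to 0
#' (and flagged) so that `p` remains a probability distribution. When the
#' total gain is not positive, EC is undefined: reported as `NA` with the
#' flag `no_positive_gain`, to distinguish "no emergence at all" from
#' "all emergence at one scale" (which EC = 0 denotes).
#'
#' @param path a [build_path()] result, or a bare numeric vector of
#'   per-step gains.
#' @param zero_steps `"include"` (default) keeps zero-gain steps in `L`;
#'   `"exclude"` drops them.
#' @return an object of class `ec_report`: list with `gains`, `p`,
#'   `ec_bits`, `ec_normalized`, `L`, `profile`, `flags`.
#' @export
emergent_complexity <- function(path, zero_steps = c("include", "exclude")) {
  zero_steps <- match.arg(zero_steps)
  gains <- if (inherits(path, "ce_path")) path$deltas else as.numeric(path)
  if (length(gains) == 0) {
    ce_stop("path has no steps beyond the microscale; emergent complexity undefined",
            class = "ce_empty_path")
  }
  flags <- character(0)
  clamped <- which(gains < 0)
  if (length(clamped)) {
    flags <- c(flags, sprintf("clamped_negative_steps:%s",
                              paste(clamped, collapse = ",")))
    gains[clamped] <- 0
  }
  eff <- gains
  if (zero_steps == "exclude") eff <- eff[eff > 0]
  L <- length(eff)
  total <- sum(eff)
  if (total <= 0 || L == 0) {
    out <- list(gains = gains, p = rep(NA_real_, length(gains)),
                ec_bits = NA_real_, ec_normalized = NA_real_,
                L = length(gains), zero_steps = zero_steps,
                profile = NA_character_,
                flags = c(flags, "no_positive_gain"))
    class(out) <- "ec_report"
    return(out)
  }
  p <- eff / total
  ec <- shannon_entropy(p)
  out <- list(gains = gains, p = p, ec_bits = ec,
              ec_normalized = if (L > 1) ec / log2(L) else 0,
              L = L, zero_steps = zero_steps,
              profile = NA_character_, flags = flags)
  if (L == 1) out$flags <- c(out$flags, "single_step_normalization")
  class(out) <- "ec_report"
  out
}

#' Normalized emergent complexity
#'
#' `EC / log2(L)`, mapping the entropy of the gain distribution to
#' `[0, 1]` so paths of different lengths compare. Undefined for a
#' single-step path (returned as a flagged 0).
#'
#' @param report an [emergent_complexity()] result.
#' @return a value in `[0, 1]` (or `NA` when EC itself is undefined).
#' @export
normalized_ec <- function(report) {
  if (!inherits(report, "ec_report")) ce_stop("expected an ec_report")
  if (is.na(report$ec_bits)) return(NA_real_)
  if (report$L < 2) return(structure(0, flag = "single_step_normalization"))
  report$ec_bits / log2(report$L)
}

#' Classify the contribution profile of a path
#'
#' Labels where along the micro-to-macro path the causal contributions
#' sit. A step *dominates* when its gain is strictly the largest (by more
#' than `tol`). `top_heavy`: the final step dominates (gains clustered at
#' the endpoint). `mesoscale`: an interior step dominates (an earlier
#' maximum in the contribution profile). `bottom_heavy`: no step
#' dominates and the microscale's own CP exceeds the total path gain
#' (including the degenerate no-gain path). `flat`: no step dominates and
#' the gains carry the weight.
#'
#' @param path a [build_path()] result.
#' @param report optionally, its [emergent_complexity()] report.
#' @param tol dominance tolerance.
#' @return one of `"top_heavy"`, `"mesoscale"`, `"bottom_heavy"`,
#'   `"flat"`.
#' @export
classify_profile <- function(path, report = NULL, tol = 1e-9) {
  gains <- pmax(path$deltas, 0)
  cp_micro <- path$cp_values[1]
  total <- sum(gains)
  if (length(gains) == 0 || total <= tol) return("bottom_heavy")
  mx <- max(gains)
  dominant <- which(gains >= mx - tol)
  if (length(dominant) == 1) {
    if (dominant == length(gains)) return("top_heavy")
    return("mesoscale")
  }
  if (cp_micro > total) return("bottom_heavy")
  "flat"
}

#' @export
print.ec_report <- function(x, digits = 4, ...) {
  cat(sprintf("Emergent complexity over %d path steps (%s zero-gain steps)\n",
              x$L, x$zero_steps))
  if (is.na(x$ec_bits)) {
    cat("  EC undefined: no positive gains along the path\n")
  } else {
    cat(sprintf("  EC = %.4g bits (normalized %.4g)\n", x$ec_bits,
                x$ec_normalized))
  }
  if (!is.na(x$profile)) cat("  profile:", x$profile, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
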