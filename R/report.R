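#' Assemble the analysis report document
#'
#' Collects a fitted analysis into one self-describing list mirroring the
#' JSON report schema: configuration echo, microscale scores, per-scale
#' path table with CP deltas, total causal emergence and its upper bound,
#' the emergent-complexity summary, the effective-information comparison
#' and any heuristics.
#'
#' @param fit a [causal_emergence()] fit.
#' @return a named list (the report document).
#' @export
ce_report <- function(fit) {
  s <- fit$micro_scores
  list(
    config = fit$config,
    scores = list(
      suff_sys = s$suff_sys, nec_sys = s$nec_sys,
      determinism = s$determinism, degeneracy = s$degeneracy,
      specificity = s$specificity, cp_primitive = s$cp_primitive,
      cp_info = s$cp_info, effectiveness = s$effectiveness,
      ei = s$ei, n_states = s$n_states, pc_mode = s$pc_mode,
      flags = s$flags
    ),
    endpoint = list(
      partition = format(fit$endpoint$partition),
      cp = fit$endpoint$cp,
      n_macro_states = fit$endpoint$n_macro_states,
      search_mode = fit$endpoint$search_mode
    ),
    path = list(
      scales = fit$path$labels,
      cp = fit$path$cp_values,
      delta_cp = fit$path$deltas,
      total_ce = fit$path$total_ce,
      consistency_max_error = vapply(fit$path$consistency,
                                     function(cc) cc$max_error, numeric(1)),
      flags = fit$path$flags
    ),
    ce_bound = fit$bound,
    emergent_complexity = if (is.null(fit$complexity)) NULL else list(
      gains = fit$complexity$gains,
      p = fit$complexity$p,
      ec_bits = fit$complexity$ec_bits,
      ec_normalized = fit$complexity$ec_normalized,
      L = fit$complexity$L,
      profile = fit$profile,
      flags = fit$complexity$flags
    ),
    profile = fit$profile,
    ei_comparison = fit$ei_comparison,
    heuristics = if (is.null(fit$heuristics)) NULL else list(
      svd_reversibility = fit$heuristics$svd_reversibility
    )
  )
}

#' Write the JSON analysis report
#'
#' Serializes [ce_report()] with stable key order and floats at 12
#' significant digits, so identical inputs and configuration produce
#' byte-identical files.
#'
#' @param fit a [causal_emergence()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ce_report <- function(fit, path) {
  doc <- ce_report(fit)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(12),
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Write the per-scale path table as TSV
#'
#' A flat extract of the path for downstream plotting: one row per scale
#' with its dimensionality, CP, step gain and apportioned contribution.
#'
#' @param fit a [causal_emergence()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_path_tsv <- function(fit, path) {
  tab <- as.data.frame(fit$path)
  tab$contribution <- fit$contributions$contribution
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
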