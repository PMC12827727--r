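#' @keywords internal
ce_stop <- function(msg, class = "ce_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ce_error")))
}

#' Construct a transition probability matrix
#'
#' A `tpm` is an n x n row-stochastic matrix giving `P(state j at t+1 |
#' state i at t)` for a discrete Markov system, with unique state labels
#' aligned to both rows and columns. State indexing in all user-facing
#' notation (partition strings, error messages) is 0-based.
#'
#' @param probs numeric matrix (or object coercible to one) of transition
#'   probabilities; rows are causes (states at `t`), columns effects
#'   (states at `t+1`).
#' @param labels character vector of state labels; defaults to existing
#'   row names, else `"0", "1", ...`.
#' @param tol row-sum tolerance. Rows whose sums deviate from 1 by at most
#'   `tol` are renormalized exactly; larger deviations are an error.
#' @return an object of class `tpm`: the validated probability matrix with
#'   `dimnames` set to the state labels.
#' @examples
#' tpm(rbind(c(0.5, 0.5), c(0.1, 0.9)), labels = c("A", "B"))
#' @export
tpm <- function(probs, labels = NULL, tol = 1e-9) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) {
    ce_stop(sprintf("TPM must be square; got %d x %d", nrow(probs), ncol(probs)))
  }
  if (!is.numeric(probs)) ce_stop("TPM entries must be numeric")
  n <- nrow(probs)
  if (is.null(labels)) {
    labels <- rownames(probs)
    if (is.null(labels)) labels <- as.character(seq_len(n) - 1L)
  }
  labels <- as.character(labels)
  if (length(labels) != n) {
    ce_stop(sprintf("%d labels supplied for %d states", length(labels), n))
  }
  if (anyDuplicated(labels)) {
    ce_stop(sprintf("duplicate state labels: %s",
                    paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (anyNA(probs)) ce_stop("TPM contains missing values")
  if (any(probs < 0)) {
    bad <- which(probs < 0, arr.ind = TRUE)[1, ]
    ce_stop(sprintf("negative transition probability at row %d, column %d",
                    bad[1] - 1L, bad[2] - 1L))
  }
  if (any(probs > 1 + tol)) ce_stop("transition probabilities must lie in [0, 1]")
  dimnames(probs) <- list(labels, labels)
  structure(probs, class = c("tpm", "matrix", "array")) |>
    validate_stochastic(tol = tol)
}

#' Validate and renormalize a transition matrix
#'
#' Checks every row sum against 1. Rows within `tol` of 1 are renormalized
#' to sum exactly to 1; any row further away raises an error naming the
#' (0-based) row index and its sum.
#'
#' @param tm a [tpm] (or plain matrix).
#' @param tol positive row-sum tolerance.
#' @return the validated `tpm`.
#' @export
validate_stochastic <- function(tm, tol = 1e-9) {
  probs <- unclass(tm)
  sums <- rowSums(probs)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    i <- which(off)[1]
    ce_stop(sprintf("row %d is not stochastic: sum = %.6g (tolerance %g)",
                    i - 1L, sums[i], tol))
  }
  # renormalize only measurable drift: rows already normalized to within a
  # few ulps are left untouched, keeping read/write round-trips bit-identical
  renorm <- abs(sums - 1) > 1e-13
  if (any(renorm)) probs[renorm, ] <- probs[renorm, , drop = FALSE] / sums[renorm]
  structure(probs, class = c("tpm", "matrix", "array"))
}

#' @export
print.tpm <- function(x, digits = 4, ...) {
  cat(sprintf("Transition probability matrix: %d states\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

n_states <- function(tm) nrow(tm)
state_labels <- function(tm) rownames(tm)

#' Read a transition matrix from CSV or JSON
#'
#' CSV dialect: first row holds the comma-separated state labels, each
#' following row one probability row ('.' decimal separator, UTF-8).
#' JSON: an object `{"labels": [...], "probs": [[...], ...]}`.
#'
#' @param source a file path, or a character string holding the document
#'   body itself.
#' @param format `"csv"` or `"json"`; default guesses from the file
#'   extension, falling back to CSV.
#' @param tol row-sum tolerance passed to [tpm()].
#' @return a validated [tpm] preserving label order exactly as given.
#' @export
read_tpm <- function(source, format = NULL, tol = 1e-9) {
  is_path <- length(source) == 1 && !grepl("[\n,{]", source) && file.exists(source)
  if (is.null(format)) {
    format <- if (is_path && grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  text <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else paste(source, collapse = "\n")
  if (format == "json") {
    doc <- jsonlite::fromJSON(text, simplifyMatrix = TRUE)
    if (is.null(doc$probs)) ce_stop("JSON TPM document lacks a 'probs' field")
    return(tpm(doc$probs, labels = doc$labels, tol = tol))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) ce_stop("CSV TPM needs a label header and at least one row")
  labels <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  rows <- lapply(lines[-1], function(l) {
    vals <- suppressWarnings(as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
    if (anyNA(vals)) ce_stop(sprintf("non-numeric CSV entry in row: %s", l))
    vals
  })
  lens <- lengths(rows)
  if (any(lens != length(labels))) {
    ce_stop(sprintf("TPM must be square; header has %d labels but row %d has %d entries",
                    length(labels), which(lens != length(labels))[1] - 1L,
                    lens[lens != length(labels)][1]))
  }
  tpm(do.call(rbind, rows), labels = labels, tol = tol)
}

#' Write a transition matrix to CSV or JSON
#'
#' Inverse of [read_tpm()]; `read -> write -> read` round-trips
#' bit-identically (probabilities serialized at full double precision).
#'
#' @param tm a [tpm].
#' @param path output file path.
#' @param format `"csv"` or `"json"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_tpm <- function(tm, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    doc <- list(labels = state_labels(tm),
                probs = unname(unclass(tm)))
    jsonlite::write_json(doc, path, auto_unbox = FALSE, digits = I(17))
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(state_labels(tm), collapse = ","), con)
    apply(unclass(tm), 1, function(r) {
      writeLines(paste(formatC(r, format = "g", digits = 17), collapse = ","), con)
    })
  }
  invisible(path)
}

#' Intervention distribution over causes
#'
#' The distribution `P(C)` from which interventions (counterfactual
#' causes) are drawn when averaging the causal primitives system-wide.
#' The uniform mode treats all states of a scale equally; the stationary
#' mode uses the observed long-run occupation law of the chain.
#'
#' @param weights nonnegative numeric vector summing to 1 (within 1e-9).
#' @param mode one of `"uniform"`, `"stationary"`, `"custom"`.
#' @return an object of class `intervention`.
#' @export
intervention <- function(weights, mode = "custom") {
  mode <- match.arg(mode, c("uniform", "stationary", "custom"))
  weights <- as.numeric(weights)
  if (any(weights < 0)) ce_stop("intervention weights must be nonnegative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    ce_stop(sprintf("intervention weights sum to %.6g, not 1", s))
  }
  structure(list(weights = weights / s, mode = mode), class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("Intervention distribution P(C) [%s] over %d states\n",
              x$mode, length(x$weights)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Uniform intervention distribution
#'
#' @param n number of states.
#' @return an `intervention` with equal mass `1/n` on every state.
#' @export
uniform_intervention <- function(n) {
  intervention(rep(1 / n, n), mode = "uniform")
}

#' Stationary distribution of a transition matrix
#'
#' Returns the long-run occupation law reached from a uniform start, i.e.
#' the Cesàro (time-averaged) limit `lim (1/T) sum_t u P^t` with `u`
#' uniform. For an irreducible chain this is the unique stationary law
#' (`pi P = pi`); for reducible chains it weights each closed recurrent
#' class by its absorption probability from the uniform start, and for
#' periodic chains it is the time average over the cycle. Computed in
#' closed form: recurrent classes are found by boolean reachability,
#' per-class stationary laws and absorption probabilities by linear solve,
#' so the result satisfies `pi P = pi` to machine precision.
#'
#' @param tm a [tpm].
#' @return an `intervention` with `mode = "stationary"`.
#' @export
stationary_distribution <- function(tm) {
  P <- unclass(tm)
  n <- nrow(P)
  if (n == 1) return(intervention(1, mode = "stationary"))

  # boolean reachability closure (includes self)
  A <- (P > 0) | diag(n) > 0
  R <- A
  k <- 1L
  while (k < n) {                       # repeated squaring: R = (I + A)^n
    R <- (R %*% R) > 0
    k <- k * 2L
  }
  comm <- R & t(R)                      # communicating classes
  class_id <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (class_id[i] == 0L) {
      cid <- cid + 1L
      class_id[comm[i, ]] <- cid
    }
  }
  classes <- split(seq_len(n), class_id)
  closed <- vapply(classes, function(m) {
    out <- setdiff(seq_len(n), m)
    length(out) == 0 || !any(R[m, out, drop = FALSE])
  }, logical(1))
  rec <- classes[closed]

  per_class_pi <- lapply(rec, function(m) {
    Q <- P[m, m, drop = FALSE]
    k <- length(m)
    if (k == 1) return(1)
    # solve pi (Q - I) = 0 with sum(pi) = 1
    M <- rbind(t(Q) - diag(k), rep(1, k))
    b <- c(rep(0, k), 1)
    qr.solve(M, b)
  })

  u <- rep(1 / n, n)
  trans <- setdiff(seq_len(n), unlist(rec))
  w <- vapply(seq_along(rec), function(j) sum(u[rec[[j]]]), numeric(1))
  if (length(trans) > 0) {
    Q <- P[trans, trans, drop = FALSE]
    IQ <- diag(length(trans)) - Q
    for (j in seq_along(rec)) {
      a <- rowSums(P[trans, rec[[j]], drop = FALSE])
      # expected eventual absorption mass into class j; solve (I-Q) b = a
      b <- tryCatch(solve(IQ, a), error = function(e)
        ce_stop("stationary distribution failed: singular transient system",
                class = "ce_numeric_error"))
      w[j] <- w[j] + sum(u[trans] * b)
    }
  }
  pi <- numeric(n)
  for (j in seq_along(rec)) pi[rec[[j]]] <- w[j] * per_class_pi[[j]]
  pi <- pi / sum(pi)
  res <- drop(pi %*% P)
  if (max(abs(res - pi)) > 1e-8) {
    ce_stop("stationary distribution did not satisfy pi P = pi within 1e-8",
            class = "ce_numeric_error")
  }
  intervention(pi, mode = "stationary")
}

#' Shannon entropy of a probability vector, in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`.
#'
#' @param p nonnegative numeric vector with `sum(p) <= 1 + 1e-9`.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) ce_stop("probabilities must be nonnegative")
  if (sum(p) > 1 + 1e-9) ce_stop("probabilities sum to more than 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}
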