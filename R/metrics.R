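#' Evaluate a selected set: M, V, MV and MR
#'
#' Four summaries of a size-`s` selected set, all on the standardized
#' trait scale:
#' * `M` — mean genetic gain: the summed standardized scores of the
#'   selected candidates over all traits, divided by `s * p0`.
#' * `V` — variance of the group mean, `x' G x / s^2`. It uses every
#'   entry of the selected G submatrix, diagonal (self-relatedness)
#'   included, so it matches the quadratic penalty exactly up to the
#'   `1/s^2` factor.
#' * `MV` — gain-to-relatedness ratio `M / sqrt(V)`; higher means more
#'   gain per unit of accumulated relatedness. Undefined (NA, flagged)
#'   when `V` is not positive.
#' * `MR` — mean pairwise relatedness: the average of the strictly
#'   upper-triangular entries of the selected G submatrix. Undefined when
#'   `s = 1` (no pairs).
#'
#' @param result a `selection_result` with status `"optimal"` or
#'   `"heuristic"`.
#' @param y the `std_traits` the problem was built from.
#' @param G the `relationship_matrix` the problem was built from.
#' @param method_label free-text label carried into reports.
#' @return A `metrics_report` object with fields `M`, `V`, `MV`, `MR`,
#'   `s`, `method_label` and a character vector `flags` naming any
#'   undefined entries.
#' @export
compute_metrics <- function(result, y, G, method_label = result$solver) {
  stopifnot(inherits(result, "selection_result"))
  if (!result$status %in% c("optimal", "heuristic"))
    mts_stop("empty_selection", "cannot compute metrics for status '%s'", result$status)
  idx <- result$selected_index
  if (length(idx) == 0L) mts_stop("empty_selection", "no candidates selected")
  yM <- y$y; GM <- if (inherits(G, "relationship_matrix")) G$G else as.matrix(G)
  s <- length(idx); p0 <- ncol(yM)
  flags <- character()
  M <- sum(yM[idx, , drop = FALSE]) / (s * p0)
  sub <- GM[idx, idx, drop = FALSE]
  V <- sum(sub) / s^2
  if (V < -1e-9) mts_warn("negative_variance", "x'Gx/s^2 = %.3g is negative", V)
  if (V > 0) {
    MV <- M / sqrt(V)
  } else {
    MV <- NA_real_
    flags <- c(flags, "MV_undefined")
  }
  if (s >= 2L) {
    MR <- mean(sub[upper.tri(sub)])
  } else {
    MR <- NA_real_
    flags <- c(flags, "MR_undefined")
  }
  structure(list(M = M, V = V, MV = MV, MR = MR, s = s,
                 method_label = method_label, flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics [%s, s = %d]: M = %.3f  V = %.3f  MV = %s  MR = %s\n",
              x$method_label, x$s, x$M, x$V,
              if (is.na(x$MV)) "NA" else sprintf("%.3f", x$MV),
              if (is.na(x$MR)) "NA" else sprintf("%.3f", x$MR)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Relative efficiency of methods on one metric
#'
#' Expresses, in percent, how much the best method outperforms each
#' other method on a given metric. For gain-type metrics (`M`, `MV`,
#' where larger is better) the best value is the maximum and
#' `RE_q = (best / q - 1) * 100`; for relatedness-type metrics (`V`,
#' `MR`, where smaller is better) the best value is the minimum and
#' `RE_q = (q / best - 1) * 100`. The best method scores 0 against
#' itself.
#'
#' The ratio form is ill-behaved when values straddle zero or when the
#' denominator is (near) zero — common for `MR`, which is legitimately
#' negative for well-spread selections. Such entries are computed verbatim
#' but flagged `"unreliable_sign_change"` / `"division_by_zero"` rather
#' than redefined.
#'
#' @param values named numeric vector: one metric value per method. `NA`s
#'   (e.g. infeasible runs) are carried through as `NA` RE.
#' @param metric one of `"M"`, `"V"`, `"MV"`, `"MR"`.
#' @return An `efficiency_report`: `metric`, `best_label`, named `RE`
#'   vector (percent), and a named list `flags`.
#' @export
relative_efficiency <- function(values, metric = c("M", "V", "MV", "MR")) {
  metric <- match.arg(metric)
  if (length(values) < 2L)
    mts_stop("invalid_spec", "need at least two methods to compare")
  if (is.null(names(values)) || anyDuplicated(names(values)))
    mts_stop("invalid_spec", "values must carry unique method names")
  finite <- values[is.finite(values)]
  if (length(finite) < 2L)
    mts_stop("invalid_spec", "need at least two finite metric values")
  larger_better <- metric %in% c("M", "MV")
  best <- if (larger_better) max(finite) else min(finite)
  best_label <- names(finite)[which(finite == best)[1]]
  RE <- vapply(values, function(q) {
    if (!is.finite(q)) return(NA_real_)
    if (larger_better) {
      if (q == 0) return(NA_real_)
      (best / q - 1) * 100
    } else {
      if (best == 0) return(NA_real_)
      (q / best - 1) * 100
    }
  }, numeric(1))
  flags <- lapply(values, function(q) {
    f <- character()
    if (!is.finite(q)) return("missing")
    denom <- if (larger_better) q else best
    if (denom == 0) f <- c(f, "division_by_zero")
    if (is.finite(q) && sign(q) != sign(best) && q != 0 && best != 0)
      f <- c(f, "unreliable_sign_change")
    f
  })
  structure(list(metric = metric, best_label = best_label,
                 RE = RE, flags = flags),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("relative efficiency on %s (best: %s)\n", x$metric, x$best_label))
  for (m in names(x$RE)) {
    fl <- x$flags[[m]]
    cat(sprintf("  %-16s %8s%s\n", m,
                if (is.na(x$RE[[m]])) "NA" else sprintf("%.2f%%", x$RE[[m]]),
                if (length(fl)) paste0("  [", paste(fl, collapse = ","), "]") else ""))
  }
  invisible(x)
}
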