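#' Specify a selection run
#'
#' @param s integer number of candidates to select.
#' @param k nonnegative penalty weight on the group relatedness term
#'   `x' G x`. `k = 1` (the default) weighs genetic gain and relatedness
#'   equally; `k > 1` emphasizes diversity, `k < 1` emphasizes gain, and
#'   `k = 0` recovers the purely linear index.
#' @param R per-trait minimum desired gains in percent (recycled to the
#'   number of constraint traits). `R = 0` imposes no gain floor.
#' @param objective_traits indices (or names) of the traits entering the
#'   objective; default all.
#' @param constraint_traits indices (or names) of the traits carrying gain
#'   constraints; default all. Objective and constraint traits may differ.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(s, k = 1, R = 0,
                           objective_traits = NULL, constraint_traits = NULL) {
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L)
    mts_stop("invalid_size", "s must be a single integer >= 1")
  if (length(k) != 1L || !is.finite(k) || k < 0)
    mts_stop("invalid_penalty", "k must be a single finite value >= 0")
  if (any(!is.finite(R)) || any(R < 0))
    mts_stop("negative_gain", "all R_j must be finite and >= 0")
  structure(list(s = s, k = as.numeric(k), R = as.numeric(R),
                 objective_traits = objective_traits,
                 constraint_traits = constraint_traits),
            class = "selection_spec")
}

#' Assemble a selection problem
#'
#' Binds the standardized, direction-adjusted trait scores, the genomic
#' relationship matrix and the run specification into one object, checking
#' that dimensions and genotype orders agree. The quadratic index chooses
#' the binary vector `x` maximizing
#' `Z = sum_j sum_i y_ji x_i - k x' G x` subject to `sum_i x_i = s` and
#' `sum_i y_ji x_i >= l_j` for every constraint trait, with
#' `l_j = R_j s / 100`.
#'
#' @param y a `std_traits` object (standardized, direction-adjusted).
#' @param G a `relationship_matrix` over the same genotypes, same order
#'   (use [validate_grm()] to reorder).
#' @param spec a [selection_spec()].
#' @return An object of class `selection_problem`.
#' @export
selection_problem <- function(y, G, spec) {
  stopifnot(inherits(y, "std_traits"), inherits(spec, "selection_spec"))
  if (!inherits(G, "relationship_matrix")) G <- relationship_matrix(G)
  n <- nrow(y$y); p0 <- ncol(y$y)
  if (nrow(G$G) != n)
    mts_stop("dimension", "y has %d genotypes but G is %d x %d", n, nrow(G$G), ncol(G$G))
  if (!identical(y$genotype_ids, G$genotype_ids))
    mts_stop("id_mismatch", "genotype id order differs between traits and G")
  if (spec$s > n)
    mts_stop("invalid_size", "s = %d exceeds n = %d", spec$s, n)
  obj <- resolve_traits(spec$objective_traits, y$trait_names, default_all = TRUE)
  con <- resolve_traits(spec$constraint_traits, y$trait_names, default_all = TRUE)
  if (length(obj) == 0L)
    mts_stop("invalid_spec", "objective_traits must be non-empty")
  R <- rep_len(spec$R, length(con))
  l <- gain_thresholds(R, spec$s, n = n)
  structure(list(y = y, G = G, spec = spec,
                 objective_traits = obj, constraint_traits = con,
                 thresholds = l),
            class = "selection_problem")
}

resolve_traits <- function(sel, trait_names, default_all = FALSE) {
  if (is.null(sel)) return(if (default_all) seq_along(trait_names) else integer())
  if (is.character(sel)) {
    idx <- match(sel, trait_names)
    if (anyNA(idx))
      mts_stop("invalid_spec", "unknown trait(s): %s",
               paste(sel[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(sel)
  if (any(idx < 1L | idx > length(trait_names)))
    mts_stop("invalid_spec", "trait index out of range")
  idx
}

# shared pieces -------------------------------------------------------------

problem_parts <- function(problem, k = problem$spec$k) {
  yM <- problem$y$y
  merit <- rowSums(yM[, problem$objective_traits, drop = FALSE])
  Ycon <- t(yM[, problem$constraint_traits, drop = FALSE])   # ncon x n
  list(merit = merit, G = problem$G$G, Ycon = Ycon,
       l = problem$thresholds$l, s = problem$spec$s, k = k)
}

make_result <- function(problem, idx, status, method, k = problem$spec$k) {
  n <- length(problem$y$genotype_ids)
  x <- integer(n)
  if (length(idx)) x[idx] <- 1L
  parts <- problem_parts(problem, k)
  merit_term <- sum(parts$merit[idx])
  penalty_term <- if (length(idx)) sum(parts$G[idx, idx]) else 0
  structure(list(x = x,
                 selected_ids = problem$y$genotype_ids[idx],
                 selected_index = as.integer(idx),
                 objective = if (status %in% c("optimal", "heuristic"))
                   merit_term - k * penalty_term else NA_real_,
                 merit_term = if (status %in% c("optimal", "heuristic"))
                   merit_term else NA_real_,
                 penalty_term = if (status %in% c("optimal", "heuristic"))
                   penalty_term else NA_real_,
                 status = status, solver = method, k = k,
                 s = problem$spec$s),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s, %s]: status %s\n", x$solver,
              if (x$k > 0) sprintf("k = %g", x$k) else "linear", x$status))
  if (x$status %in% c("optimal", "heuristic"))
    cat(sprintf("  s = %d, Z = %.6g (merit %.6g, penalty %.6g)\n  selected: %s\n",
                x$s, x$objective, x$merit_term, x$penalty_term,
                paste(x$selected_ids, collapse = ", ")))
  invisible(x)
}

# diagnostic attached to infeasible results: which single-trait constraint
# is already unattainable by the top-s scores on that trait
infeasibility_diagnostic <- function(problem) {
  parts <- problem_parts(problem)
  bad <- character()
  for (t in seq_len(nrow(parts$Ycon))) {
    best <- sum(sort(parts$Ycon[t, ], decreasing = TRUE)[seq_len(parts$s)])
    if (best < parts$l[t] - 1e-6)
      bad <- c(bad, problem$y$trait_names[problem$constraint_traits[t]])
  }
  if (length(bad))
    sprintf("unsatisfiable even by the top-s genotypes on trait(s): %s",
            paste(bad, collapse = ", "))
  else
    "no single trait is unsatisfiable alone; the constraint combination is"
}

#' Solve the quadratic multi-trait selection index (QPMSI)
#'
#' Maximizes `Z = sum_i c_i x_i - k x' G x` over binary `x` with
#' `sum x = s` and the per-trait gain constraints, where `c_i` is
#' candidate `i`'s summed standardized merit over the objective traits.
#'
#' @param problem a [selection_problem()].
#' @param method `"exact"` (default) runs a branch-and-bound search that
#'   returns a provably optimal set or an infeasibility verdict;
#'   `"brute_force"` enumerates all size-`s` subsets (independent
#'   reference path, capped); `"local_search"` runs greedy construction
#'   plus best-improvement swap moves with random restarts and returns
#'   status `"heuristic"`.
#' @param seed integer; used only by `"local_search"` restarts. Exact
#'   paths are deterministic and ignore it.
#' @param cap subset cap for `"brute_force"` (default `2e6`).
#' @param restarts number of local-search restarts.
#' @return A `selection_result`. Infeasibility is reported as
#'   `status = "infeasible"` (with a diagnostic attribute), not as an
#'   error: a too-demanding `(s, k, R)` configuration is a legitimate
#'   outcome, and the linear index is the recommended fallback.
#' @export
solve_qpmsi <- function(problem, method = c("exact", "brute_force", "local_search"),
                        seed = 1L, cap = 2e6, restarts = 10L) {
  stopifnot(inherits(problem, "selection_problem"))
  method <- match.arg(method)
  switch(method,
         exact = solve_exact(problem, k = problem$spec$k, label = "qpmsi_exact"),
         brute_force = brute_force_select(problem, objective = "qpmsi", cap = cap),
         local_search = solve_local(problem, seed = seed, restarts = restarts))
}

#' Solve the linear multi-trait selection index (LPMSI)
#'
#' Same cardinality and gain constraints as the quadratic index, but the
#' objective is merit only: `Z = sum_j sum_i y_ji x_i`. The penalty weight
#' `k` plays no role. Note that `R_j = 0` still imposes the zero-floor
#' constraints `sum_i y_ji x_i >= 0`: the gain thresholds are always part
#' of the feasible set. When the `s` candidates with the largest summed
#' standardized scores already satisfy every threshold, that set is
#' merit-maximal and feasible, hence optimal (fast path); otherwise the
#' exact search runs with the quadratic term switched off.
#'
#' @param problem a [selection_problem()].
#' @return A `selection_result`; `penalty_term` is still reported (it is
#'   needed by the evaluation metrics) even though it does not enter the
#'   objective.
#' @export
solve_lpmsi <- function(problem) {
  stopifnot(inherits(problem, "selection_problem"))
  parts <- problem_parts(problem, k = 0)
  ord <- order(parts$merit, decreasing = TRUE)
  idx <- sort(ord[seq_len(parts$s)])
  feasible <- all(rowSums(parts$Ycon[, idx, drop = FALSE]) >= parts$l - 1e-6)
  if (feasible)  # merit-maximal and feasible, hence optimal
    return(make_result(problem, idx, "optimal", "lpmsi_top_s", k = 0))
  res <- solve_exact(problem, k = 0, label = "lpmsi_exact")
  res$k <- 0
  res
}

solve_exact <- function(problem, k, label) {
  parts <- problem_parts(problem, k)
  n <- length(parts$merit)
  d <- parts$merit - k * diag(parts$G)
  P <- 2 * k * parts$G
  diag(P) <- 0
  out <- .bb_select_cpp(d, P, parts$Ycon, parts$l, parts$s,
                        feas_tol = 1e-6, tie_tol = 1e-9)
  if (out$status == "infeasible") {
    res <- make_result(problem, integer(), "infeasible", label, k = k)
    attr(res, "diagnostic") <- infeasibility_diagnostic(problem)
    return(res)
  }
  make_result(problem, out$idx, out$status, label, k = k)
}

solve_local <- function(problem, seed, restarts) {
  parts <- problem_parts(problem, problem$spec$k)
  n <- length(parts$merit); s <- parts$s; k <- parts$k
  d <- parts$merit - k * diag(parts$G)
  P <- 2 * k * parts$G
  diag(P) <- 0
  feasible <- function(idx) {
    all(parts$Ycon[, idx, drop = FALSE] %*% rep(1, length(idx)) >= parts$l - 1e-6)
  }
  value <- function(idx) sum(d[idx]) - sum(P[idx, idx]) / 2
  improve <- function(idx) {
    repeat {
      out_set <- setdiff(seq_len(n), idx)
      best_gain <- 1e-9; best_move <- NULL
      v0 <- value(idx)
      for (i in idx) for (j in out_set) {
        cand <- c(setdiff(idx, i), j)
        if (!feasible(cand)) next
        gain <- value(cand) - v0
        if (gain > best_gain) { best_gain <- gain; best_move <- cand }
      }
      if (is.null(best_move)) return(idx)
      idx <- best_move
    }
  }
  set.seed(seed)
  best_idx <- NULL; best_val <- -Inf
  starts <- c(list(order(d, decreasing = TRUE)[seq_len(s)]),
              replicate(max(0L, restarts - 1L),
                        sample.int(n, s), simplify = FALSE))
  for (st in starts) {
    if (!feasible(st)) {
      # steer the start toward feasibility by greedily swapping for slack
      for (rep in seq_len(2L * s)) {
        if (feasible(st)) break
        viol <- which(as.numeric(parts$Ycon[, st, drop = FALSE] %*%
                                   rep(1, s)) < parts$l - 1e-6)[1]
        out_set <- setdiff(seq_len(n), st)
        worst_in <- st[which.min(parts$Ycon[viol, st])]
        best_out <- out_set[which.max(parts$Ycon[viol, out_set])]
        st <- c(setdiff(st, worst_in), best_out)
      }
      if (!feasible(st)) next
    }
    st <- improve(st)
    v <- value(st)
    if (v > best_val + 1e-9) { best_val <- v; best_idx <- sort(st) }
  }
  if (is.null(best_idx)) {
    res <- make_result(problem, integer(), "infeasible", "qpmsi_local_search")
    attr(res, "diagnostic") <- paste("no feasible set found by local search;",
                                     infeasibility_diagnostic(problem))
    return(res)
  }
  make_result(problem, best_idx, "heuristic", "qpmsi_local_search")
}

#' Exhaustive subset enumeration (reference oracle)
#'
#' Enumerates every size-`s` subset in lexicographic order, discards those
#' violating the gain constraints, and returns the feasible maximizer of
#' the requested objective. Kept as an independent pure-R path against
#' which the branch-and-bound solver is verified; ties resolve to the
#' first (lexicographically smallest) subset encountered.
#'
#' @param problem a [selection_problem()].
#' @param objective `"qpmsi"` (merit minus `k` times `x' G x`) or
#'   `"lpmsi"` (merit only).
#' @param cap refuse to enumerate more than this many subsets
#'   (default `2e6`).
#' @return A `selection_result` with solver `"brute_force"`.
#' @export
brute_force_select <- function(problem, objective = c("qpmsi", "lpmsi"), cap = 2e6) {
  stopifnot(inherits(problem, "selection_problem"))
  objective <- match.arg(objective)
  k <- if (objective == "qpmsi") problem$spec$k else 0
  parts <- problem_parts(problem, k)
  n <- length(parts$merit); s <- parts$s
  if (choose(n, s) > cap)
    mts_stop("cap_exceeded", "C(%d, %d) = %g subsets exceeds cap %g",
             n, s, choose(n, s), cap)
  subsets <- utils::combn(n, s)
  best_val <- -Inf; best_idx <- NULL
  for (col in seq_len(ncol(subsets))) {
    idx <- subsets[, col]
    if (any(rowSums(parts$Ycon[, idx, drop = FALSE]) < parts$l - 1e-6)) next
    val <- sum(parts$merit[idx]) - k * sum(parts$G[idx, idx])
    if (val > best_val + 1e-9) { best_val <- val; best_idx <- idx }
  }
  if (is.null(best_idx)) {
    res <- make_result(problem, integer(), "infeasible",
                       paste0(objective, "_brute_force"), k = k)
    attr(res, "diagnostic") <- infeasibility_diagnostic(problem)
    return(res)
  }
  make_result(problem, best_idx, "optimal", paste0(objective, "_brute_force"), k = k)
}
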