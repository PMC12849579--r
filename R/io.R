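#' Read a trait BLUE table from CSV
#'
#' Expected dialect: comma-separated, UTF-8, header row, `.` decimal;
#' first column genotype ID (string), remaining columns one trait each.
#'
#' @param path CSV file path.
#' @param directions per-trait direction flags (length 1 is recycled);
#'   direction metadata always comes from configuration, never from data.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, directions = "higher_is_better") {
  df <- read_table_checked(path, sep = ",")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  trait_table(vals, directions = directions, genotype_ids = ids,
              trait_names = colnames(df)[-1])
}

#' Read a marker dosage matrix from CSV/TSV
#'
#' First column genotype ID, header row of marker names. Files ending in
#' `.tsv` or `.txt` are read tab-separated, anything else comma-separated.
#'
#' @param path file path.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read_table_checked(path, sep = sep)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  marker_matrix(vals, genotype_ids = ids, marker_names = colnames(df)[-1])
}

#' Read a precomputed relationship matrix from CSV
#'
#' Square layout: header row of genotype IDs, first column of genotype
#' IDs, numeric body. The matrix is passed through [validate_grm()].
#'
#' @param path CSV file path.
#' @return A validated `relationship_matrix`.
#' @export
read_grm <- function(path) {
  df <- read_table_checked(path, sep = ",")
  ids <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (!identical(colnames(df)[-1], ids))
    mts_stop("id_mismatch", "row and column genotype ids of G differ")
  validate_grm(relationship_matrix(M, ids))
}

read_table_checked <- function(path, sep) {
  if (!file.exists(path)) mts_stop("parse_error", "file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) mts_stop("parse_error", "cannot parse %s: %s",
                                 path, conditionMessage(e)))
  if (ncol(df) < 2L) mts_stop("parse_error", "%s: need id column plus data", path)
  df
}

#' Write a relationship matrix as CSV
#' @param G a `relationship_matrix`.
#' @param path output CSV path.
#' @export
write_grm <- function(G, path) {
  stopifnot(inherits(G, "relationship_matrix"))
  df <- data.frame(id = G$genotype_ids, G$G, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trait table as CSV
#' @param traits a [trait_table()].
#' @param path output CSV path.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  df <- data.frame(id = traits$genotype_ids, traits$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a marker matrix as CSV
#' @param markers a [marker_matrix()].
#' @param path output CSV path.
#' @export
write_marker_matrix <- function(markers, path) {
  stopifnot(inherits(markers, "marker_matrix"))
  df <- data.frame(id = markers$genotype_ids, markers$dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a run configuration
#'
#' @param traits path to the trait BLUE CSV.
#' @param markers path to the marker CSV/TSV (exclusive with `grm`).
#' @param grm path to a precomputed G CSV (exclusive with `markers`).
#' @param s selection size.
#' @param k_grid penalty weights to evaluate for the quadratic index; the
#'   linear index is always run once alongside.
#' @param R per-trait minimum desired gains (percent).
#' @param directions per-trait direction flags.
#' @param scaling G scaling mode, see [compute_grm()].
#' @param method solver path, see [solve_qpmsi()].
#' @param sd_type standardization convention, see [standardize_traits()].
#' @param seed integer seed (heuristic path only).
#' @param out_dir optional output directory for reports.
#' @return A `run_config` object.
#' @export
run_config <- function(traits, markers = NULL, grm = NULL, s, k_grid = c(0.5, 1, 1.5),
                       R = 0, directions = "higher_is_better",
                       scaling = "column_standardize", method = "exact",
                       sd_type = "sample", seed = 1L, out_dir = NULL) {
  if (is.null(markers) == is.null(grm))
    mts_stop("invalid_config", "provide exactly one of 'markers' or 'grm'")
  if (length(k_grid) < 1L || any(!is.finite(k_grid)) || any(k_grid < 0))
    mts_stop("invalid_config", "k_grid must be non-empty with all k >= 0")
  structure(list(traits = traits, markers = markers, grm = grm,
                 s = as.integer(s), k_grid = as.numeric(k_grid), R = R,
                 directions = directions, scaling = scaling, method = method,
                 sd_type = sd_type, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file with the fields of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mts_stop("parse_error", "config not found: %s", path)
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown))
    mts_stop("invalid_config", "unknown config field(s): %s",
             paste(unknown, collapse = ", "))
  do.call(run_config, fields)
}

#' Load inputs and assemble the selection problem
#'
#' Reads the trait table and either markers (G is then computed) or a
#' precomputed G, standardizes and direction-adjusts the traits, aligns
#' genotype ids (intersection, with a warning when ids are dropped) and
#' assembles a [selection_problem()] for `k = k_grid[1]`.
#'
#' @param config a [run_config()].
#' @return A `selection_problem`.
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  raw <- read_trait_table(config$traits, directions = config$directions)
  G <- if (!is.null(config$markers))
    compute_grm(read_marker_matrix(config$markers), scaling = config$scaling)
  else
    read_grm(config$grm)
  common <- intersect(raw$genotype_ids, G$genotype_ids)
  if (length(common) < 2L)
    mts_stop("id_mismatch", "fewer than 2 genotype ids shared between traits and G")
  orphans <- c(setdiff(raw$genotype_ids, common), setdiff(G$genotype_ids, common))
  if (length(orphans))
    mts_warn("dropped_genotypes", "dropped %d genotype(s) absent from one input: %s",
             length(orphans), paste(orphans, collapse = ", "))
  keep <- raw$genotype_ids[raw$genotype_ids %in% common]
  raw_sub <- trait_table(raw$values[keep, , drop = FALSE],
                         directions = raw$directions,
                         genotype_ids = keep, trait_names = raw$trait_names)
  G <- validate_grm(G, ids = keep)
  y <- adjust_direction(standardize_traits(raw_sub, sd_type = config$sd_type))
  spec <- selection_spec(s = config$s, k = config$k_grid[1], R = config$R)
  selection_problem(y, G, spec)
}

#' Compare the quadratic index over a k-grid against the linear index
#'
#' Runs the linear index once and the quadratic index at every `k` in the
#' grid on the same assembled problem, computes the evaluation metrics for
#' each feasible run, and derives the four relative-efficiency tables.
#' Infeasible quadratic runs stay in the report with blank metrics and a
#' logged recommendation to fall back to the linear index.
#'
#' @param problem a [selection_problem()].
#' @param k_grid penalty weights for the quadratic index.
#' @param method solver path for the quadratic index.
#' @param seed seed for the heuristic path.
#' @return A `comparison_report`: data frame `table` (method, k, status,
#'   M, V, MV, MR), list `results`, list `efficiency` (one
#'   `efficiency_report` per metric), `infeasible` labels.
#' @export
compare_methods <- function(problem, k_grid = c(0.5, 1, 1.5),
                            method = "exact", seed = 1L) {
  stopifnot(inherits(problem, "selection_problem"))
  runs <- list()
  lp <- solve_lpmsi(problem)
  runs[["LPMSI"]] <- lp
  for (k in k_grid) {
    spec_k <- selection_spec(s = problem$spec$s, k = k, R = problem$thresholds$R,
                             objective_traits = problem$objective_traits,
                             constraint_traits = problem$constraint_traits)
    pk <- selection_problem(problem$y, problem$G, spec_k)
    runs[[sprintf("QPMSI_k%g", k)]] <- solve_qpmsi(pk, method = method, seed = seed)
  }
  rows <- list(); mets <- list()
  for (lbl in names(runs)) {
    r <- runs[[lbl]]
    if (r$status %in% c("optimal", "heuristic")) {
      m <- compute_metrics(r, problem$y, problem$G, method_label = lbl)
      mets[[lbl]] <- m
      rows[[lbl]] <- data.frame(method = lbl, k = r$k, status = r$status,
                                M = m$M, V = m$V, MV = m$MV, MR = m$MR)
    } else {
      message(sprintf("%s: %s — consider the linear index (LPMSI) instead", lbl, r$status))
      rows[[lbl]] <- data.frame(method = lbl, k = r$k, status = r$status,
                                M = NA_real_, V = NA_real_, MV = NA_real_,
                                MR = NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  eff <- list()
  for (metric in c("M", "V", "MV", "MR")) {
    vals <- stats::setNames(tab[[metric]], tab$method)
    eff[[metric]] <- if (sum(is.finite(vals)) >= 2L)
      relative_efficiency(vals, metric) else NULL
  }
  structure(list(table = tab, results = runs, metrics = mets, efficiency = eff,
                 infeasible = tab$method[!tab$status %in% c("optimal", "heuristic")]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  tab <- x$table
  tab[c("M", "V", "MV", "MR")] <- lapply(tab[c("M", "V", "MV", "MR")],
                                         function(v) round(v, 3))
  print(tab)
  invisible(x)
}

#' Run a full comparison from a configuration and write reports
#'
#' Loads inputs per the configuration, runs [compare_methods()], and —
#' when `out_dir` is set — writes `comparison.csv` (the metric table),
#' `comparison.json` (table, relative efficiencies, selected ids) and one
#' `selected_<method>.txt` per feasible method (one genotype id per
#' line). Reruns with the same configuration and seed produce identical
#' files.
#'
#' @param config a [run_config()] or path to a YAML/JSON config.
#' @return The `comparison_report`, invisibly when writing files.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  problem <- load_inputs(config)
  report <- compare_methods(problem, k_grid = config$k_grid,
                            method = config$method, seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$table, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    payload <- list(
      table = report$table,
      efficiency = lapply(Filter(Negate(is.null), report$efficiency),
                          function(e) list(metric = e$metric,
                                           best = e$best_label,
                                           RE = as.list(e$RE))),
      selected = lapply(report$results, function(r) r$selected_ids))
    jsonlite::write_json(payload, file.path(config$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (lbl in names(report$results)) {
      r <- report$results[[lbl]]
      if (r$status %in% c("optimal", "heuristic"))
        writeLines(r$selected_ids,
                   file.path(config$out_dir,
                             paste0("selected_", gsub("[^A-Za-z0-9_.]", "_", lbl), ".txt")))
    }
    return(invisible(report))
  }
  report
}
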