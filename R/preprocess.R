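#' Assemble a trait table of raw BLUEs
#'
#' A trait table holds the best linear unbiased estimates (BLUEs) of `n`
#' candidate genotypes for `p0` traits, together with each trait's
#' improvement direction. BLUEs come out of upstream mixed-model analyses
#' of the field trials; they are inputs here, never computed.
#'
#' @param values numeric matrix, `n x p0`, one row per genotype and one
#'   column per trait, in the trait's own units.
#' @param directions character vector of length `p0`; each entry
#'   `"higher_is_better"` or `"lower_is_better"`. Trait polarity is
#'   breeder-supplied metadata and is never inferred from the data.
#' @param genotype_ids character vector of `n` unique genotype identifiers;
#'   defaults to the rownames of `values`.
#' @param trait_names character vector of `p0` trait labels; defaults to
#'   the colnames of `values`.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values,
                        directions = rep("higher_is_better", ncol(values)),
                        genotype_ids = rownames(values),
                        trait_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p0 <- ncol(values)
  if (n < 2L) mts_stop("dimension", "need at least 2 genotypes, got %d", n)
  if (p0 < 1L) mts_stop("dimension", "need at least 1 trait")
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(n))
  if (is.null(trait_names)) trait_names <- paste0("T", seq_len(p0))
  genotype_ids <- as.character(genotype_ids)
  if (anyDuplicated(genotype_ids))
    mts_stop("duplicate_ids", "genotype ids are not unique")
  if (length(genotype_ids) != n || length(trait_names) != p0)
    mts_stop("dimension", "id/name lengths do not match the value matrix")
  if (length(directions) == 1L) directions <- rep(directions, p0)
  check_directions(directions, p0)
  dimnames(values) <- list(genotype_ids, trait_names)
  structure(list(genotype_ids = genotype_ids, values = values,
                 trait_names = trait_names, directions = directions),
            class = "trait_table")
}

check_directions <- function(directions, p0) {
  if (length(directions) != p0)
    mts_stop("length_mismatch", "directions has length %d but there are %d traits",
             length(directions), p0)
  ok <- directions %in% c("higher_is_better", "lower_is_better")
  if (!all(ok))
    mts_stop("bad_direction", "unknown direction flag(s): %s",
             paste(unique(directions[!ok]), collapse = ", "))
  invisible(directions)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d genotypes x %d traits\n",
              nrow(x$values), ncol(x$values)))
  cat("directions:", paste(x$trait_names,
                           ifelse(x$directions == "higher_is_better", "(+)", "(-)"),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Standardize trait BLUEs to z-scores
#'
#' Each trait column is centred to mean zero and scaled to unit standard
#' deviation, putting all traits on a common dimensionless scale so they
#' can be summed in one index: `y_ji = (BLUE_ji - mean_j) / sd_j`.
#'
#' @param raw a [trait_table()].
#' @param sd_type `"sample"` (denominator `n - 1`, the default) or
#'   `"population"` (denominator `n`).
#' @param na_action `"error"` rejects any non-finite cell (the default:
#'   silently imputing or dropping values would distort the per-trait gain
#'   constraints downstream); `"drop"` removes offending genotypes with a
#'   warning.
#' @return A `std_traits` object: the standardized score matrix `y` with
#'   the genotype ids, trait names and directions carried along. No
#'   direction adjustment is applied yet; see [adjust_direction()].
#' @export
standardize_traits <- function(raw, sd_type = c("sample", "population"),
                               na_action = c("error", "drop")) {
  stopifnot(inherits(raw, "trait_table"))
  sd_type <- match.arg(sd_type)
  na_action <- match.arg(na_action)
  vals <- raw$values
  ids <- raw$genotype_ids
  bad <- !is.finite(vals)
  if (any(bad)) {
    if (na_action == "error") {
      cells <- which(bad, arr.ind = TRUE)
      mts_stop("missing_value", "non-finite BLUE for genotype '%s', trait '%s'",
               ids[cells[1, 1]], raw$trait_names[cells[1, 2]])
    }
    drop_rows <- unique(which(bad, arr.ind = TRUE)[, 1])
    mts_warn("dropped_genotypes", "dropped %d genotype(s) with non-finite BLUEs: %s",
             length(drop_rows), paste(ids[drop_rows], collapse = ", "))
    vals <- vals[-drop_rows, , drop = FALSE]
    ids <- ids[-drop_rows]
    if (nrow(vals) < 2L)
      mts_stop("dimension", "fewer than 2 genotypes remain after dropping")
  }
  n <- nrow(vals)
  mu <- colMeans(vals)
  sdev <- apply(vals, 2L, stats::sd)
  if (sd_type == "population") sdev <- sdev * sqrt((n - 1) / n)
  zero <- which(!is.finite(sdev) | sdev == 0)
  if (length(zero))
    mts_stop("zero_variance_trait", "trait(s) with zero variance: %s",
             paste(raw$trait_names[zero], collapse = ", "))
  y <- sweep(sweep(vals, 2L, mu, "-"), 2L, sdev, "/")
  structure(list(genotype_ids = ids, y = y,
                 trait_names = raw$trait_names,
                 directions = raw$directions,
                 adjusted = FALSE),
            class = "std_traits")
}

#' Flip standardized scores of traits where lower is better
#'
#' After standardization, traits where smaller raw values are desirable
#' (disease score, lodging, excessive plant height) still point the wrong
#' way. Negating those columns (`y* = -y`) makes higher standardized
#' scores always reflect more favourable breeding values, so a single
#' maximization treats every trait consistently. Negation preserves the
#' zero mean and unit standard deviation.
#'
#' @param z a `std_traits` object from [standardize_traits()].
#' @param directions per-trait direction flags; defaults to those stored
#'   in `z`. Applying the same flags twice returns the original scores.
#' @return `z` with the flagged columns negated and `adjusted = TRUE`.
#' @export
adjust_direction <- function(z, directions = z$directions) {
  stopifnot(inherits(z, "std_traits"))
  p0 <- ncol(z$y)
  check_directions(directions, p0)
  flip <- directions == "lower_is_better"
  z$y[, flip] <- -z$y[, flip, drop = FALSE]
  z$adjusted <- !isTRUE(z$adjusted)
  z
}

#' Convert per-trait minimum desired gains to constraint thresholds
#'
#' The minimum desired genetic gain `R_j` for trait `j` is a percentage in
#' `[0, 100]` expressing the trait's relative importance. On the
#' standardized scale the selected group of size `s` must satisfy
#' `sum_i y_ji x_i >= l_j` with `l_j = R_j * s / 100`, so `R_j = 0` leaves
#' the trait unconstrained and larger `R_j` forces more of the group's
#' summed standardized merit onto that trait.
#'
#' @param R numeric vector of per-trait percentages, all `>= 0`.
#' @param s integer selection size, `>= 1`.
#' @param n optional population size; when given, `s > n` is rejected.
#' @return A `gain_thresholds` object with components `R` and `l`.
#' @export
gain_thresholds <- function(R, s, n = NULL) {
  if (any(!is.finite(R)) || any(R < 0))
    mts_stop("negative_gain", "all R_j must be finite and >= 0")
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L)
    mts_stop("invalid_size", "s must be a single integer >= 1")
  if (!is.null(n) && s > n)
    mts_stop("invalid_size", "s = %d exceeds the number of candidates n = %d", s, n)
  structure(list(R = as.numeric(R), l = as.numeric(R) * s / 100, s = s),
            class = "gain_thresholds")
}
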