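#' Assemble a marker dosage matrix
#'
#' @param dosages numeric matrix, `n` genotypes x `p` markers, of allele
#'   dosage codes. Any numeric coding works (0/1/2 or -1/0/1): centring
#'   during scaling removes the offset.
#' @param genotype_ids `n` unique identifiers (default: rownames).
#' @param marker_names `p` marker labels (default: colnames).
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(dosages, genotype_ids = rownames(dosages),
                          marker_names = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 2L || p < 1L)
    mts_stop("dimension", "need n >= 2 genotypes and p >= 1 markers (got %d x %d)", n, p)
  if (any(!is.finite(dosages)))
    mts_stop("missing_value", "marker dosages contain non-finite values")
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(n))
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(p))
  genotype_ids <- as.character(genotype_ids)
  if (anyDuplicated(genotype_ids))
    mts_stop("duplicate_ids", "genotype ids are not unique")
  dimnames(dosages) <- list(genotype_ids, marker_names)
  structure(list(genotype_ids = genotype_ids, dosages = dosages,
                 marker_names = marker_names),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d genotypes x %d markers\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Compute the genomic relationship matrix G from marker dosages
#'
#' Default scaling (`"column_standardize"`) centres every marker column
#' and scales it to unit sample standard deviation, then returns
#' `G = W W' / p` with `p` the marker count. Under this scaling `G` has
#' zero row sums and trace `n - 1`. The alternative `"vanraden_freq"`
#' applies the classic allele-frequency form: columns of 0/1/2 dosages are
#' centred by twice the observed allele frequency `2 p_j` and the cross
#' product is divided by `2 * sum_j p_j (1 - p_j)`.
#'
#' Either way `G` is a Gram matrix, hence symmetric and positive
#' semidefinite by construction; its entry `G_ij` measures the genomic
#' relatedness of candidates `i` and `j` and drives the `x' G x` penalty
#' of the quadratic index.
#'
#' @param markers a [marker_matrix()].
#' @param scaling `"column_standardize"` (default) or `"vanraden_freq"`.
#' @param drop_monomorphic under the default scaling a monomorphic marker
#'   (zero column SD) cannot be scaled: `FALSE` (default) raises an error
#'   naming the offending markers, `TRUE` drops them with a warning. Note
#'   that dropping changes `p` and hence the scale of `G`.
#' @return A `relationship_matrix` object holding the symmetric `n x n` G.
#' @export
compute_grm <- function(markers, scaling = c("column_standardize", "vanraden_freq"),
                        drop_monomorphic = FALSE) {
  stopifnot(inherits(markers, "marker_matrix"))
  scaling <- match.arg(scaling)
  M <- markers$dosages
  if (scaling == "column_standardize") {
    sdev <- apply(M, 2L, stats::sd)
    mono <- which(sdev == 0)
    if (length(mono)) {
      if (!drop_monomorphic)
        mts_stop("monomorphic_marker", "monomorphic marker(s): %s",
                 paste(markers$marker_names[mono], collapse = ", "))
      mts_warn("dropped_markers", "dropped %d monomorphic marker(s)", length(mono))
      M <- M[, -mono, drop = FALSE]
      sdev <- sdev[-mono]
      if (ncol(M) == 0L) mts_stop("dimension", "no polymorphic markers remain")
    }
    W <- scale(M, center = TRUE, scale = sdev)
    G <- tcrossprod(W) / ncol(W)
  } else {
    # VanRaden method 1: dosages assumed on the 0..2 scale
    pj <- colMeans(M) / 2
    W <- sweep(M, 2L, 2 * pj, "-")
    denom <- 2 * sum(pj * (1 - pj))
    if (denom <= 0)
      mts_stop("monomorphic_marker", "all markers monomorphic: VanRaden denominator is 0")
    G <- tcrossprod(W) / denom
  }
  G <- (G + t(G)) / 2  # remove floating-point asymmetry
  relationship_matrix(G, markers$genotype_ids)
}

#' Construct a relationship matrix object
#'
#' @param G symmetric numeric `n x n` matrix.
#' @param genotype_ids `n` identifiers (default: rownames of `G`).
#' @return An object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(G, genotype_ids = rownames(G)) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  n <- nrow(G)
  if (n != ncol(G)) mts_stop("dimension", "G must be square (got %d x %d)", n, ncol(G))
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(n))
  genotype_ids <- as.character(genotype_ids)
  if (anyDuplicated(genotype_ids))
    mts_stop("duplicate_ids", "genotype ids are not unique")
  dimnames(G) <- list(genotype_ids, genotype_ids)
  structure(list(genotype_ids = genotype_ids, G = G),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix: %d x %d, diag mean %.3f\n",
              nrow(x$G), ncol(x$G), mean(diag(x$G))))
  invisible(x)
}

#' Validate (and optionally reorder) a relationship matrix
#'
#' Checks intended for externally supplied G matrices: symmetrizes via
#' `(G + G')/2` when the worst asymmetry is at most `1e-6` (beyond that it
#' errors), warns — without failing — when the minimum eigenvalue is
#' slightly negative (between `-1e-4` and `-1e-8`), errors when it is worse,
#' and reorders rows/columns to a supplied genotype-id order.
#'
#' @param G a `relationship_matrix`, or a bare square matrix with ids as
#'   dimnames.
#' @param ids optional character vector: the required genotype order. Must
#'   be a permutation of the ids present in `G`.
#' @return The validated (possibly symmetrized and reordered)
#'   `relationship_matrix`.
#' @export
validate_grm <- function(G, ids = NULL) {
  if (!inherits(G, "relationship_matrix")) G <- relationship_matrix(G)
  M <- G$G
  asym <- max(abs(M - t(M)))
  if (asym > 1e-6)
    mts_stop("asymmetric_matrix", "G is asymmetric (max |G - G'| = %.3g)", asym)
  if (asym > 0) M <- (M + t(M)) / 2
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-4)
    mts_stop("not_psd", "G has eigenvalue %.3g: not positive semidefinite", ev_min)
  if (ev_min < -1e-8)
    mts_warn("near_psd", "G minimum eigenvalue %.3g is slightly negative", ev_min)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (!setequal(ids, G$genotype_ids) || length(ids) != length(G$genotype_ids))
      mts_stop("id_mismatch", "id set does not match G (missing: %s)",
               paste(setdiff(ids, G$genotype_ids), collapse = ", "))
    M <- M[ids, ids, drop = FALSE]
    return(relationship_matrix(M, ids))
  }
  relationship_matrix(M, G$genotype_ids)
}
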