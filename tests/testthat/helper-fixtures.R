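# Build a std_traits object directly from a score matrix (bypasses
# standardization so tests can pin exact y values).
make_std <- function(y, ids = NULL) {
  y <- as.matrix(y)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(y)))
  structure(list(genotype_ids = ids, y = y,
                 trait_names = paste0("T", seq_len(ncol(y))),
                 directions = rep("higher_is_better", ncol(y)),
                 adjusted = TRUE),
            class = "std_traits")
}

# Random PSD matrix via a Gram construction.
random_psd <- function(n) {
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n
}

make_problem <- function(y, G, s, k = 1, R = 0, ids = NULL) {
  z <- make_std(y, ids)
  selection_problem(z, relationship_matrix(G, z$genotype_ids),
                    selection_spec(s = s, k = k, R = R))
}

# One random solvable-size instance for solver cross-checks.
random_instance <- function(n = NULL, s = NULL, k = NULL, p0 = NULL, R = NULL) {
  n <- n %||% sample(6:15, 1)
  s <- s %||% sample(2:5, 1)
  k <- k %||% sample(c(0, 0.5, 1, 1.5), 1)
  p0 <- p0 %||% sample(1:3, 1)
  R <- R %||% sample(c(0, 25), 1)
  make_problem(matrix(rnorm(n * p0), n, p0), random_psd(n), s = s, k = k, R = R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
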