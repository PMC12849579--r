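fake_result <- function(idx, n, k = 1, s = length(idx)) {
  x <- integer(n); x[idx] <- 1L
  structure(list(x = x, selected_ids = paste0("g", idx),
                 selected_index = as.integer(idx),
                 objective = 0, merit_term = 0, penalty_term = 0,
                 status = "optimal", solver = "test", k = k, s = s),
            class = "selection_result")
}

test_that("M, V, MV, MR follow their definitions on pinned examples", {
  # identity G, s = 2: V = x'Ix / 4 = 0.5, MR = 0
  y <- make_std(cbind(c(1.0, 0.1, 0), c(0, 2.0, 0)))
  G <- relationship_matrix(diag(3), y$genotype_ids)
  m <- compute_metrics(fake_result(c(1, 2), 3), y, G)
  expect_equal(m$V, 0.5)
  expect_equal(m$MR, 0)
  # selected values: trait1 {1.0, 0.1}, trait2 {0, 2.0} -> M = 3.1 / 4
  expect_equal(m$M, 0.775)
  expect_equal(m$MV, 0.775 / sqrt(0.5))

  # s = 2 on a general G: MR is exactly the single off-diagonal entry
  G2 <- matrix(c(1, .37, .1, .37, 1, .2, .1, .2, 1), 3, 3)
  m2 <- compute_metrics(fake_result(c(1, 2), 3), y, relationship_matrix(G2))
  expect_equal(m2$MR, 0.37)
  expect_equal(m2$V, sum(G2[1:2, 1:2]) / 4)
})

test_that("published gain-to-relatedness ratio M/sqrt(V) is reproduced", {
  # a printed benchmark row: M = 0.756, V = 0.064 -> MV printed as 2.992
  expect_equal(0.756 / sqrt(0.064), 2.992, tolerance = 0.005)
})

test_that("V equals the full-submatrix mean including diagonal terms", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:15, 1); s <- sample(2:4, 1)
    G <- random_psd(n)
    idx <- sort(sample(n, s))
    y <- make_std(matrix(rnorm(n * 2), n, 2))
    m <- compute_metrics(fake_result(idx, n), y, relationship_matrix(G))
    x <- as.numeric(seq_len(n) %in% idx)
    expect_equal(m$V, drop(t(x) %*% G %*% x) / s^2)
    sub <- G[idx, idx]
    expect_equal(m$MR, mean(sub[lower.tri(sub)]))  # triangle-invariant
  }
})

test_that("single-candidate selections flag MR undefined and V = G_ii", {
  y <- make_std(matrix(rnorm(4), 4, 1))
  G <- relationship_matrix(diag(c(1.3, 1, 1, 1)))
  m <- compute_metrics(fake_result(1, 4), y, G)
  expect_true(is.na(m$MR))
  expect_true("MR_undefined" %in% m$flags)
  expect_equal(m$V, 1.3)
})

test_that("metrics refuse infeasible results and empty selections", {
  y <- make_std(matrix(rnorm(6), 3, 2))
  G <- relationship_matrix(diag(3))
  bad <- fake_result(integer(), 3)
  bad$status <- "infeasible"
  expect_error(compute_metrics(bad, y, G), class = "mtselect_empty_selection")
})

test_that("relative efficiency picks the right reference per metric", {
  # published rice comparison: best MV 5.696 over LPMSI 4.716 -> 20.78%
  re <- relative_efficiency(c(QPMSI_k1 = 5.696, LPMSI = 4.716), "MV")
  expect_identical(re$best_label, "QPMSI_k1")
  expect_equal(unname(re$RE["LPMSI"]), 20.78, tolerance = 0.005)
  expect_equal(unname(re$RE["QPMSI_k1"]), 0)  # best against itself

  # smaller-is-better metrics invert the ratio
  rev_ <- relative_efficiency(c(A = 0.010, B = 0.044), "V")
  expect_identical(rev_$best_label, "A")
  expect_equal(unname(rev_$RE["B"]), (0.044 / 0.010 - 1) * 100)

  # across-dataset published pair at k = 1: 5.652 vs 3.438 -> 64.4%
  re2 <- relative_efficiency(c(QPMSI_k1 = 5.652, LPMSI = 3.438), "MV")
  expect_equal(unname(re2$RE["LPMSI"]), 64.40, tolerance = 0.005)
})

test_that("RE is scale-invariant and flags sign straddles and zero division", {
  vals <- c(A = 5.6, B = 3.4, C = 4.1)
  re1 <- relative_efficiency(vals, "MV")
  re2 <- relative_efficiency(vals * 3.7, "MV")
  expect_equal(re1$RE, re2$RE)

  mixed <- relative_efficiency(c(A = -0.004, B = 0.015), "MR")
  expect_identical(mixed$best_label, "A")
  expect_true("unreliable_sign_change" %in% mixed$flags[["B"]])

  z <- relative_efficiency(c(A = 0, B = 2), "MV")
  expect_true(is.na(z$RE[["A"]]))
  expect_true("division_by_zero" %in% z$flags[["A"]])

  withNA <- relative_efficiency(c(A = 5, B = NA, C = 4), "M")
  expect_true(is.na(withNA$RE[["B"]]))
})
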