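test_that("constant identity penalty reduces QPMSI to top-s selection", {
  pr <- make_problem(c(1.0, 0.9, 0.1), diag(3), s = 2, k = 1)
  r <- solve_qpmsi(pr)
  expect_identical(r$selected_index, c(1L, 2L))
  expect_equal(r$objective, 1.9 - 2)        # penalty x'Ix = s for any set
  expect_equal(r$merit_term, 1.9)
  expect_equal(r$penalty_term, 2)
})

test_that("relatedness penalty flips the choice away from close pairs", {
  G <- matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3, 3)
  pr <- make_problem(c(1.0, 0.9, 0.1), G, s = 2, k = 1)
  for (m in c("exact", "brute_force")) {
    r <- solve_qpmsi(pr, method = m)
    expect_identical(r$selected_index, c(1L, 3L))
    expect_equal(r$objective, 1.1 - 2.0, tolerance = 1e-9)
  }
})

test_that("unsatisfiable gain constraints yield infeasible status, not an error", {
  pr <- make_problem(c(0, 0, 0), diag(3), s = 2, k = 1, R = 50)  # l = 1 > 0
  for (m in c("exact", "brute_force")) {
    r <- if (m == "exact") solve_qpmsi(pr) else brute_force_select(pr, "qpmsi")
    expect_identical(r$status, "infeasible")
    expect_length(r$selected_ids, 0)
    expect_true(is.na(r$objective))
  }
  expect_match(attr(solve_qpmsi(pr), "diagnostic"), "T1")
  lr <- solve_lpmsi(pr)
  expect_identical(lr$status, "infeasible")
})

test_that("LPMSI maximizes merit only and honours active gain constraints", {
  # top-s fast path
  y <- cbind(c(1.0, 0.9, 0.1), c(0.9, 0.3, 0.2))
  pr <- make_problem(y, diag(3), s = 2, k = 1)
  r <- solve_lpmsi(pr)
  expect_identical(r$selected_index, c(1L, 2L))
  expect_identical(r$solver, "lpmsi_top_s")

  # trait-2 constraint excludes the merit-best pair (derived by enumeration)
  y2 <- cbind(c(1.0, 0.9, 0.1), c(0, 0, 2.0))
  pr2 <- make_problem(y2, diag(3), s = 2, k = 1, R = c(0, 50))  # l = (0, 1)
  r2 <- solve_lpmsi(pr2)
  expect_identical(r2$selected_index, c(1L, 3L))
  expect_equal(r2$objective, 3.1)
  bf <- brute_force_select(pr2, "lpmsi")
  expect_identical(bf$selected_index, r2$selected_index)

  # k is irrelevant to the linear index
  pr2b <- make_problem(y2, diag(3), s = 2, k = 7.3, R = c(0, 50))
  expect_identical(solve_lpmsi(pr2b)$selected_index, r2$selected_index)
})

test_that("brute force enumerates C(n, s) subsets and respects its cap", {
  pr <- make_problem(rnorm(5), diag(5), s = 2, k = 1)
  r <- brute_force_select(pr, "qpmsi")
  expect_identical(r$status, "optimal")     # all 10 subsets scanned
  expect_error(brute_force_select(pr, "qpmsi", cap = 5),
               class = "mtselect_cap_exceeded")
})

test_that("exact solver equals the enumeration oracle on random instances", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:200) {
    pr <- random_instance()
    a <- solve_qpmsi(pr, method = "exact")
    b <- brute_force_select(pr, "qpmsi")
    expect_identical(a$status, b$status)
    if (a$status == "optimal") {
      expect_equal(a$objective, b$objective, tolerance = 1e-6)
      expect_identical(a$selected_index, b$selected_index)  # shared tie-break
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("optimal solutions satisfy cardinality and gain constraints exactly", {
  set.seed(19)
  for (rep in 1:40) {
    pr <- random_instance()
    r <- solve_qpmsi(pr)
    if (r$status != "optimal") next
    expect_equal(sum(r$x), pr$spec$s)
    gsum <- colSums(pr$y$y[r$selected_index, , drop = FALSE])
    expect_true(all(gsum >= pr$thresholds$l - 1e-6))
    expect_equal(r$objective, r$merit_term - r$k * r$penalty_term,
                 tolerance = 1e-6)
  }
})

test_that("k = 0 collapses QPMSI onto LPMSI and G = cI makes them agree", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(6:12, 1); p0 <- 2
    y <- matrix(rnorm(n * p0), n, p0)
    pr0 <- make_problem(y, random_psd(n), s = 3, k = 0)
    q <- solve_qpmsi(pr0); l <- solve_lpmsi(pr0)
    if (q$status == "optimal" && l$status == "optimal")
      expect_equal(q$merit_term, l$merit_term, tolerance = 1e-9)

    prc <- make_problem(y, 0.7 * diag(n), s = 3, k = sample(c(0.5, 1, 2), 1))
    qc <- solve_qpmsi(prc); lc <- solve_lpmsi(prc)
    if (qc$status == "optimal" && lc$status == "optimal") {
      expect_equal(qc$merit_term, lc$merit_term, tolerance = 1e-9)
      expect_equal(qc$penalty_term, 0.7 * 3, tolerance = 1e-9)
    }
  }
})

test_that("scalarization: QPMSI never beats LPMSI on merit nor loses on penalty", {
  set.seed(31)
  for (rep in 1:60) {
    pr <- random_instance(k = sample(c(0.5, 1, 1.5), 1))
    q <- solve_qpmsi(pr); l <- solve_lpmsi(pr)
    if (q$status != "optimal" || l$status != "optimal") next
    expect_lte(q$merit_term, l$merit_term + 1e-6)
    expect_lte(q$penalty_term, l$penalty_term + 1e-6)
  }
})

test_that("penalty and merit terms are non-increasing in k", {
  set.seed(37)
  for (rep in 1:15) {
    n <- sample(8:14, 1)
    y <- matrix(rnorm(n * 2), n, 2)
    G <- random_psd(n)
    prev_pen <- Inf; prev_mer <- Inf
    for (k in c(0, 0.25, 0.5, 1, 2, 4)) {
      pr <- make_problem(y, G, s = 4, k = k)
      r <- solve_qpmsi(pr)
      if (r$status != "optimal") break
      if (k > 0) {
        expect_lte(r$penalty_term, prev_pen + 1e-6)
        expect_lte(r$merit_term, prev_mer + 1e-6)
      }
      prev_pen <- r$penalty_term; prev_mer <- r$merit_term
    }
  }
})

test_that("local search is seeded, feasible and close to the exact optimum", {
  set.seed(43)
  pr <- random_instance(n = 14, s = 4, k = 1, p0 = 2, R = 0)
  h1 <- solve_qpmsi(pr, method = "local_search", seed = 99)
  h2 <- solve_qpmsi(pr, method = "local_search", seed = 99)
  expect_identical(h1$selected_index, h2$selected_index)
  expect_identical(h1$status, "heuristic")
  ex <- solve_qpmsi(pr, method = "exact")
  expect_lte(h1$objective, ex$objective + 1e-9)
  gsum <- colSums(pr$y$y[h1$selected_index, , drop = FALSE])
  expect_true(all(gsum >= pr$thresholds$l - 1e-6))
})
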