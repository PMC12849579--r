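test_that("simulation is reproducible from (config, seed) and validates input", {
  cfg <- simulation_config(n_families = 3, family_size = 4, p_markers = 60, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$markers$dosages, d2$markers$dosages)
  expect_identical(d1$traits$values, d2$traits$values)
  d3 <- simulate_dataset(simulation_config(n_families = 3, family_size = 4,
                                           p_markers = 60, seed = 6))
  expect_false(identical(d1$markers$dosages, d3$markers$dosages))

  expect_error(simulation_config(n_families = 1, family_size = 1),
               class = "mtselect_invalid_config")
  expect_error(simulation_config(allele_freq_range = c(0, 0.5)),
               class = "mtselect_invalid_config")
  expect_error(simulation_config(h2 = 0), class = "mtselect_invalid_config")
  bad_corr <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulation_config(trait_corr = bad_corr),
               class = "mtselect_non_psd_correlation")
})

test_that("simulated data pass preprocessing and G construction cleanly", {
  cfg <- simulation_config(n_families = 4, family_size = 5, p_markers = 120,
                           seed = 11)
  ds <- simulate_dataset(cfg)
  expect_identical(dim(ds$markers$dosages), c(20L, 120L))
  expect_no_warning({
    y <- adjust_direction(standardize_traits(ds$traits))
    G <- compute_grm(ds$markers)
  })
  expect_true(all(abs(colMeans(y$y)) < 1e-9))
  expect_equal(sum(diag(G$G)), 19)
})

test_that("full-sib families show elevated within-family relatedness", {
  hits <- 0
  for (seed in 1:20) {
    ds <- simulate_dataset(simulation_config(seed = seed))  # 5 x 10, p = 500
    G <- compute_grm(ds$markers)$G
    fam <- ds$family
    same <- outer(fam, fam, "==") & upper.tri(G)
    diff <- (!outer(fam, fam, "==")) & upper.tri(G)
    if (mean(G[same]) > mean(G[diff])) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("trait correlation targets are recovered at large n", {
  # identity target: sample correlations near 0
  cfg0 <- simulation_config(n_families = 50, family_size = 10, p_markers = 300,
                            trait_corr = diag(3), h2 = 1, seed = 21)
  ds0 <- simulate_dataset(cfg0)
  cc0 <- cor(attr(ds0$traits, "genetic_values"))
  expect_lt(max(abs(cc0[upper.tri(cc0)])), 0.1)

  # strong positive target: 0.8 recovered within +-0.1
  corr <- matrix(0.8, 3, 3); diag(corr) <- 1
  cfg8 <- simulation_config(n_families = 50, family_size = 10, p_markers = 300,
                            trait_corr = corr, h2 = 1, seed = 22)
  ds8 <- simulate_dataset(cfg8)
  cc8 <- cor(attr(ds8$traits, "genetic_values"))
  expect_lt(max(abs(cc8[upper.tri(cc8)] - 0.8)), 0.1)
})

test_that("traits decouple from genomic structure as h2 approaches zero", {
  # permutation association test between trait values and kinship:
  # statistic = cor over pairs of (y_i - y_j)^2 with G_ij
  assoc_p <- function(tvals, G, nperm = 99) {
    ut <- upper.tri(G)
    stat <- function(v) cor(as.numeric(-abs(outer(v, v, "-"))[ut]), G[ut])
    obs <- stat(tvals)
    perms <- replicate(nperm, stat(sample(tvals)))
    mean(c(obs, perms) >= obs)
  }
  sig <- 0
  for (seed in 1:40) {
    cfg <- simulation_config(n_families = 5, family_size = 8, p_markers = 150,
                             trait_corr = diag(2), h2 = 1e-6, seed = 300 + seed)
    ds <- simulate_dataset(cfg)
    G <- compute_grm(ds$markers)$G
    set.seed(seed)
    if (assoc_p(ds$traits$values[, 1], G) <= 0.05) sig <- sig + 1
  }
  expect_lte(sig, 4)   # ~alpha * 40 false positives expected
})
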