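test_that("arrangement counts match both brute force and the generating function", {
  for (G in 1:5) {
    arr <- enumerate_block_arrangements(G)
    expect_equal(arr$n_arr, oracle_arrangement_count(G), info = paste("G =", G))
    expect_equal(arr$n_arr, oracle_gf_count(G), info = paste("G =", G))
    # counters: entries in {0,1,2}, rows sum to G, consistent with pointers
    expect_true(all(arr$counter %in% 0:2))
    expect_true(all(rowSums(arr$counter) == G))
    for (r in seq_len(arr$n_arr))
      expect_equal(tabulate(arr$pointer[r, ], G), arr$counter[r, ])
    # arrangements are distinct as multisets; identity comes first
    keys <- apply(arr$pointer, 1, function(p) paste(sort(p), collapse = "-"))
    expect_equal(anyDuplicated(keys), 0)
    expect_equal(arr$pointer[1, ], seq_len(G))
  }
  expect_equal(enumerate_block_arrangements(4)$n_arr, 19)
  expect_equal(enumerate_block_arrangements(3)$n_arr, 7)
  expect_equal(enumerate_block_arrangements(1)$counter, matrix(1L, 1, 1))
})

test_that("index arithmetic is the documented mixed-radix bijection", {
  expect_equal(unname(index_to_block_indices(1, 19)), c(1, 1, 1))
  expect_equal(unname(index_to_block_indices(1260, 19)), c(4, 10, 6))
  expect_equal(unname(index_to_block_indices(6859, 19)), c(19, 19, 19))
  expect_error(index_to_block_indices(6860, 19))
  expect_error(index_to_block_indices(0, 19))
  # bijectivity at G = 3 (343 samples)
  trip <- t(vapply(1:343, index_to_block_indices, integer(3), n_arr = 7))
  expect_equal(nrow(unique(trip)), 343)
  expect_true(all(trip >= 1 & trip <= 7))
})

test_that("the canonical G = 4 ordering reproduces the published pointer table", {
  arr <- enumerate_block_arrangements(4)
  published_counters <- rbind(
    c(1, 1, 1, 1), c(2, 0, 1, 1), c(2, 1, 0, 1), c(2, 1, 1, 0),
    c(0, 2, 1, 1), c(1, 2, 0, 1), c(1, 2, 1, 0), c(0, 1, 2, 1),
    c(1, 0, 2, 1), c(1, 1, 2, 0), c(0, 1, 1, 2), c(1, 0, 1, 2),
    c(1, 1, 0, 2), c(2, 2, 0, 0), c(2, 0, 2, 0), c(2, 0, 0, 2),
    c(0, 2, 2, 0), c(0, 2, 0, 2), c(0, 0, 2, 2))
  expect_equal(unname(arr$counter), published_counters)
  # row 4 pointer is multiset-equivalent to [1, 2, 3, 1]
  expect_equal(sort(arr$pointer[4, ]), sort(c(1, 2, 3, 1)))
})

test_that("build_sample applies multiset semantics and conserves counts", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  sds <- one_residue_sds(ref_m4_params(), cfg, noisy = TRUE, seed = 5)
  arr <- enumerate_block_arrangements(4)

  # identity sample reproduces the original fit vector
  s1 <- build_sample(1, arr, sds)
  expect_equal(s1$y_star, sds$y)
  expect_equal(s1$y_err_star, sds$y_err)
  expect_equal(s1$Y_star, rep(1, 12))
  expect_equal(s1$multiplicity, rep(1, 9))

  # every sample conserves sum(Y*) = 12, blocks each summing to 4
  set.seed(1)
  for (i in sample(6859, 40)) {
    s <- build_sample(i, arr, sds)
    expect_equal(sum(s$Y_star), 12)
    expect_equal(sum(s$Y_star[1:4]), 4)
    expect_equal(sum(s$Y_star[5:8]), 4)
    expect_equal(sum(s$Y_star[9:12]), 4)
  }

  # a [2,0,2,0]-type J(0) arrangement averages fields 1 and 3, twice each
  r2020 <- which(apply(arr$counter, 1, function(y)
    all(y == c(2, 0, 2, 0))))
  i2020 <- (r2020 - 1) * 19^2 + 1      # l = r2020, m = n = 1
  s <- build_sample(i2020, arr, sds)
  v <- sds$J0[c(1, 1, 3, 3)]; e <- sds$J0_err[c(1, 1, 3, 3)]
  expect_equal(s$J0_mean, weighted_mean_j0(v, e))
  expect_equal(s$J0_mean_err, jackknife_j0_se(v, e))
})

test_that("conventional bootstrap sd follows the closed forms and the ensemble runs at G = 3", {
  # closed forms of the sample-deviation formula
  expect_equal(unname(naive_sd(cbind(c(2, 2, 2)))), 0)
  expect_equal(unname(naive_sd(cbind(c(1, 3)))), 2 / sqrt(2))
  vals <- c(0.3, 0.5, 0.2, 0.9, 0.6)
  mu <- sum(vals) / 5
  expect_equal(unname(naive_sd(cbind(vals))),
               sqrt(sum((vals - mu)^2) / 4))

  cfg <- mf_config(fixed_tau_m_residues = 1L)
  sds <- one_residue_sds(ref_m4_params(), cfg,
                         fields = c(600, 800, 900), noisy = TRUE, seed = 5)
  sel <- select_model(sds, cfg)
  bt <- conventional_bootstrap_sd(sds, sel, cfg, keep_replicates = TRUE)
  expect_equal(bt$B, 343)
  expect_equal(nrow(bt$params) + bt$n_dropped, 343)
  expect_true(all(bt$sd[c("Ss2", "tau_s")] > 0))
  # identity replicate equals the original best fit
  expect_equal(unname(bt$params[1, "Ss2"]), sel$fit$params$Ss2,
               tolerance = 1e-5)
})
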