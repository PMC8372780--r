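test_that("smoothed_sd matches the unrolled double-loop oracle", {
  # B = 3 toy with hand-listed counters and parameter values
  Y <- rbind(c(1, 1, 1, 1), c(2, 0, 1, 1), c(0, 2, 1, 1))
  mu <- cbind(a = c(0.8, 0.9, 0.7), b = c(1.0, 1.0, 1.0))
  s <- smoothed_sd(mu, Y)
  expect_equal(unname(s), oracle_smoothed_sd(mu, Y), tolerance = 1e-14)
  # constant parameter -> zero smoothed sd
  expect_equal(unname(s["b"]), 0)
  # shift invariance
  mu2 <- mu; mu2[, "a"] <- mu[, "a"] + 5
  expect_equal(smoothed_sd(mu2, Y), s, tolerance = 1e-14)
  # larger random toy against the oracle
  set.seed(8)
  Y3 <- matrix(sample(0:2, 60, replace = TRUE), 5, 12)
  mu3 <- matrix(rnorm(15), 5, 3)
  expect_equal(unname(smoothed_sd(mu3, Y3)), oracle_smoothed_sd(mu3, Y3),
               tolerance = 1e-13)
  # 1/N-scaled variant
  expect_equal(unname(smoothed_sd(mu3, Y3, scale_by_N = TRUE)),
               oracle_smoothed_sd(mu3, Y3) / sqrt(12), tolerance = 1e-13)
  expect_error(smoothed_sd(mu[1, , drop = FALSE], Y[1, , drop = FALSE]),
               "at least two")
})

test_that("mixed-model aggregation follows the null-value conventions", {
  # two-sample toy: Model 2 with Sf2 = 0.8 and Model 3 (Sf2 fixed at 1)
  reps <- rbind(c(17.5e-9, 0.8, 1.0, 0.05e-9, 0),
                c(17.5e-9, 1.0, 0.6, 0, 0.5e-9))
  colnames(reps) <- c("tau_m", "Sf2", "Ss2", "tau_f", "tau_s")
  expect_equal(mean(reps[, "Sf2"]), 0.9)             # (0.8 + 1)/2
  expect_equal(unname(naive_sd(reps[, "Sf2", drop = FALSE])), 0.1 * sqrt(2))
})

test_that("bagging a decisive residue reproduces the conventional analysis", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  sds <- one_residue_sds(ref_m4_params(), cfg)       # zero noise
  bag <- bagged_fit(sds, cfg)
  expect_equal(unname(bag$model_fractions["model4"]), 1)
  expect_equal(sum(bag$model_fractions), 1, tolerance = 1e-9)
  sel <- bag$selection
  expect_equal(unname(bag$smoothed["S2"]), sel$fit$params$S2,
               tolerance = 1e-7)
  expect_equal(unname(bag$smoothed["tau_s"]), sel$fit$params$tau_s,
               tolerance = 1e-6)
  # identical replicates up to optimizer jitter (chi2 tol 1e-10 implies
  # parameter scatter of order 1e-5)
  expect_true(all(bag$smoothed_sd < 1e-4))
})

test_that("bagged ensemble structure and Efron inequality hold on a noisy residue", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  sds <- one_residue_sds(mf_params(17.5e-9, 0.87, 0.93, 0.036e-9, 0.9e-9),
                         cfg, noisy = TRUE, seed = 23)
  bag <- bagged_fit(sds, cfg)
  expect_equal(bag$B, 6859)
  expect_equal(nrow(bag$replicate_matrix), bag$B_used)
  expect_equal(dim(bag$Y_matrix), c(bag$B_used, 12))
  expect_true(all(rowSums(bag$Y_matrix) == 12))
  expect_equal(sum(bag$model_fractions), 1, tolerance = 1e-9)
  # identity sample present and equal to the original selection
  expect_equal(bag$models[1], bag$selection$best)
  # smoothed sd below the naive sd for every parameter
  expect_true(all(bag$smoothed_sd <= bag$naive_sd + 1e-12))
  # smoothed S2 aggregates per-sample products and stays in [0, 1]
  expect_equal(unname(bag$smoothed["S2"]),
               mean(bag$replicate_matrix[, "Sf2"] *
                      bag$replicate_matrix[, "Ss2"]))
  expect_gte(unname(bag$smoothed["S2"]), 0)
  expect_lte(unname(bag$smoothed["S2"]), 1)
  # smoothed sd recomputed from the returned matrices matches
  expect_equal(bag$smoothed_sd,
               smoothed_sd(bag$replicate_matrix, bag$Y_matrix,
                           bag$smoothed))
  # replicate histogram dump is consistent
  h <- replicate_histogram(bag)
  expect_equal(nrow(h), 6 * bag$B_used)
  expect_true(all(h$value[h$parameter == "tau_f" & h$model_id == 4] == 0))
})

test_that("an ambiguous residue splits its model mass and interpolates tau_f", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  # two-timescale generator with a weak fast component: Models 4 and 5
  # trade places under resampling
  sds <- one_residue_sds(mf_params(17.5e-9, 0.7, 0.35, 0.02e-9, 0.85e-9),
                         cfg, noisy = TRUE, seed = 31)
  bag <- bagged_fit(sds, cfg)
  f45 <- bag$model_fractions["model4"] + bag$model_fractions["model5"]
  expect_gt(unname(f45), 0.9)
  m5 <- bag$models == 5
  if (any(m5) && any(!m5)) {
    tf5 <- mean(bag$replicate_matrix[m5, "tau_f"])
    expect_gte(unname(bag$smoothed["tau_f"]), 0)
    expect_lte(unname(bag$smoothed["tau_f"]), tf5)
  }
})
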