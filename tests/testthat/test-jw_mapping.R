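test_that("mapping round-trips the algebraic inversion to machine precision", {
  # Oracle: synthesize rates directly from arbitrary (J0, JwN, JwH087)
  # triples with the inverse linear relations, written out here from
  # scratch, then map back and compare.
  const <- nmr_constants()
  grid <- expand.grid(J0 = c(0.5, 1.7, 4) * 1e-9,
                      JwN = c(0.05, 0.15, 0.3) * 1e-9,
                      JwH = c(0.002, 0.01, 0.05) * 1e-9)
  for (field in c(600, 900)) {
    ic <- interaction_constants(field, const)
    for (r in seq_len(nrow(grid))) {
      J0 <- grid$J0[r]; JwN <- grid$JwN[r]; JwH <- grid$JwH[r]
      sigma <- 5 / 4 * const$d_NH^2 * JwH
      R1 <- ic$denom * JwN / 4 + 1.249 * sigma
      R2 <- ic$denom * J0 / 6 + 0.5 * R1 + 0.454 * sigma
      NOE <- 1 + sigma * const$gamma_H / (R1 * const$gamma_N)
      df <- data.frame(residue = 1, field_MHz = field,
                       R1 = R1, R1_err = 0.01, R2 = R2, R2_err = 0.01,
                       NOE = NOE, NOE_err = 0.01)
      jw <- map_relaxation_to_jw(df, const)
      expect_equal(jw$J0, J0, tolerance = 1e-10)
      expect_equal(jw$JwN, JwN, tolerance = 1e-10)
      expect_equal(jw$JwH087, JwH, tolerance = 1e-10)
    }
  }
})

test_that("NOE = 1 gives zero cross-relaxation and zero J(0.87wH)", {
  df <- data.frame(residue = 1, field_MHz = 600,
                   R1 = 1.3, R1_err = 0.02, R2 = 12, R2_err = 0.2,
                   NOE = 1, NOE_err = 0.02)
  jw <- map_relaxation_to_jw(df)
  expect_identical(jw$JwH087, 0)
  expect_gt(jw$J0, 0)
})

test_that("error propagation is first-order homogeneous", {
  df <- one_residue_rates(ref_m4_params())
  jw1 <- map_relaxation_to_jw(df)
  df2 <- df
  df2[c("R1_err", "R2_err", "NOE_err")] <- 2 * df[c("R1_err", "R2_err", "NOE_err")]
  jw2 <- map_relaxation_to_jw(df2)
  expect_equal(jw2$J0_err, 2 * jw1$J0_err, tolerance = 1e-12)
  expect_equal(jw2$JwN_err, 2 * jw1$JwN_err, tolerance = 1e-12)
  expect_equal(jw2$JwH087_err, 2 * jw1$JwH087_err, tolerance = 1e-12)
  # strictly increasing in each error source where the partial is nonzero
  for (col in c("R1_err", "R2_err", "NOE_err")) {
    df3 <- df
    df3[[col]] <- 1.5 * df[[col]]
    jw3 <- map_relaxation_to_jw(df3)
    affected <- switch(col,
      R1_err = c("J0_err", "JwN_err", "JwH087_err"),
      R2_err = "J0_err",
      NOE_err = c("J0_err", "JwN_err", "JwH087_err"))
    for (a in affected) expect_true(all(jw3[[a]] > jw1[[a]]))
  }
})

test_that("mapping rejects invalid records", {
  df <- one_residue_rates(ref_m4_params())
  bad <- df; bad$R1[2] <- -1
  expect_error(map_relaxation_to_jw(bad), "invalid relaxation record")
  bad <- df; bad$field_MHz[1] <- 0
  expect_error(map_relaxation_to_jw(bad), "invalid relaxation record")
})

test_that("weighted mean J(0) behaves as inverse-variance weighting", {
  expect_equal(weighted_mean_j0(c(2, 4), c(1, 1)), 3)
  expect_equal(weighted_mean_j0(5, 0.3), 5)                 # G = 1
  expect_equal(weighted_mean_j0(rep(7, 4), c(1, 2, 3, 4)), 7)
  # closer to the better-determined value
  expect_lt(abs(weighted_mean_j0(c(2, 4), c(0.1, 1)) - 2), 0.1)
  expect_error(weighted_mean_j0(c(1, 2), c(0, 1)), "degenerate")
})

test_that("jackknife J(0) uncertainty matches the explicit loop oracle", {
  expect_equal(jackknife_j0_se(rep(3, 4), c(1, 2, 1, 2)), 0)
  v <- c(0, 2, 4, 6); e <- rep(1, 4)
  expect_equal(jackknife_j0_se(v, e), oracle_jackknife(v, e))
  # unequal errors, several sizes
  set.seed(42)
  for (G in c(2, 3, 5)) {
    v <- rnorm(G, 1.7, 0.1); e <- runif(G, 0.01, 0.1)
    expect_equal(jackknife_j0_se(v, e), oracle_jackknife(v, e))
    # permutation invariance
    p <- sample(G)
    expect_equal(jackknife_j0_se(v[p], e[p]), jackknife_j0_se(v, e))
  }
  # G = 1 fallback: propagated error of the single value
  expect_equal(jackknife_j0_se(2, 0.4), 0.4)
})

test_that("spectral density set assembles the 1 + 2G fit vector in frequency order", {
  sds <- one_residue_sds(ref_m4_params())
  expect_s3_class(sds, "spectral_density_set")
  expect_identical(sds$G, 4L)
  expect_length(sds$y, 9)
  expect_length(sds$y_raw, 12)
  expect_false(is.unsorted(sds$omega))
  expect_equal(sds$y[1], weighted_mean_j0(sds$J0, sds$J0_err))
  # G = 3 variant
  sds3 <- one_residue_sds(ref_m4_params(), fields = c(600, 800, 900))
  expect_length(sds3$y, 7)
})
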