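test_that("chi2 matches an explicit hand loop", {
  y <- c(1.0, 2.0, 3.0); e <- c(0.1, 0.2, 0.4); m <- c(1.05, 1.9, 3.3)
  acc <- 0
  for (j in 1:3) acc <- acc + ((y[j] - m[j]) / e[j])^2
  expect_equal(chi2_stat(y, e, m), acc)
  expect_equal(chi2_stat(y, e, y), 0)
  expect_equal(chi2_stat(1, 0.3, 1.3), 1)            # residual = sigma
  expect_error(chi2_stat(y, c(0.1, 0, 0.4), m), "> 0")
})

test_that("aicc follows the chi2 + 2k + small-sample form", {
  expect_equal(aicc(10, 2, 9), 16)
  expect_equal(aicc(0, 5, 9), 30)                    # 10 + 60/3
  expect_true(is.na(aicc(1, 5, 6)))                  # n <= k + 1 -> NA
  # approaches chi2 + 2k from above as n grows
  vals <- vapply(c(10, 100, 1000), function(n) aicc(3, 2, n), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[3], 3 + 4, tolerance = 1e-2)
})

test_that("select_best_aicc is argmin with parsimony tie-break", {
  expect_equal(select_best_aicc(c(67.9, NA, 57.2, 33.3, 34.2)), 4L)
  expect_equal(select_best_aicc(c(20, 20, NA, 20, 25)), 1L)
  expect_error(select_best_aicc(rep(NA_real_, 5)), "no applicable")
})

test_that("noise-free synthetic data are recovered by the generating model", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  # Model 2 generator (fixed tau_m)
  p2 <- mf_params(17.5e-9, 0.88, 1, 0.04e-9, 0)
  f2 <- fit_model(one_residue_sds(p2, cfg), 2, cfg)
  expect_true(f2$converged)
  expect_equal(f2$params$Sf2, 0.88, tolerance = 1e-6)
  expect_equal(f2$params$tau_f, 0.04e-9, tolerance = 1e-6)
  expect_lt(f2$chi2, 1e-8)
  # Model 4 generator, local tau_m policy
  cfg_loc <- mf_config()
  p4 <- ref_m4_params()
  f4 <- fit_model(one_residue_sds(p4, cfg_loc), 4, cfg_loc)
  expect_equal(f4$params$tau_m, 17.5e-9, tolerance = 1e-4)
  expect_equal(f4$params$Sf2, 0.754, tolerance = 1e-4)
  expect_equal(f4$params$Ss2, 0.292, tolerance = 1e-4)
  expect_equal(f4$params$tau_s, 0.838e-9, tolerance = 1e-4)
  # k bookkeeping: fixed tau_m excludes it from the count
  expect_equal(f2$k, 2)
  expect_equal(f4$k, 4)
})

test_that("chi2 nesting inequalities hold across noisy inputs", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  gens <- list(mf_params(17.5e-9, 0.9), ref_m4_params(),
               mf_params(17.5e-9, 0.87, 0.93, 0.036e-9, 0.9e-9))
  for (g in seq_along(gens)) {
    for (seed in 1:3) {
      sds <- one_residue_sds(gens[[g]], cfg, noisy = TRUE,
                             seed = 100 * g + seed)
      ch <- vapply(1:5, function(m)
        fit_model(sds, m, cfg)$chi2, numeric(1))
      tol <- 1e-6
      expect_lte(ch[5], ch[4] + tol)
      expect_lte(ch[4], ch[1] + tol)
      expect_lte(ch[5], ch[2] + tol)
      expect_lte(ch[2], ch[1] + tol)
    }
  }
})

test_that("selection labels the single-timescale fit by the 0.15 ns threshold", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  # slow single timescale -> Model 3 applicable, Model 2 NA
  sds_slow <- one_residue_sds(mf_params(17.5e-9, 1, 0.5, 0, 0.8e-9), cfg,
                              noisy = TRUE, seed = 11)
  sel_slow <- select_model(sds_slow, cfg)
  expect_equal(sel_slow$label23, 3)
  expect_true(is.na(sel_slow$table$aicc[2]))
  expect_false(is.na(sel_slow$table$aicc[3]))
  expect_equal(sel_slow$best, 3)
  # fast single timescale -> Model 2
  sds_fast <- one_residue_sds(mf_params(17.5e-9, 0.85, 1, 0.06e-9, 0), cfg,
                              noisy = TRUE, seed = 12)
  sel_fast <- select_model(sds_fast, cfg)
  expect_equal(sel_fast$label23, 2)
  expect_true(is.na(sel_fast$table$aicc[3]))
  # best minimizes aicc among applicable models
  tab <- sel_fast$table
  expect_equal(which(tab$best), which.min(tab$aicc))
})

test_that("model selection recovers well-separated generators at low noise", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  gens <- list(`1` = mf_params(17.5e-9, 0.88),
               `3` = mf_params(17.5e-9, 1, 0.5, 0, 0.8e-9),
               `4` = ref_m4_params())
  hits <- 0; total <- 0
  for (gm in names(gens)) {
    for (seed in 1:8) {
      sds <- one_residue_sds(gens[[gm]], cfg, r_frac = 0.005,
                             noe_abs = 0.005, noisy = TRUE,
                             seed = 1000 + 17 * seed + as.integer(gm))
      best <- select_model(sds, cfg)$best
      hits <- hits + (best == as.integer(gm))
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("Monte Carlo uncertainties are deterministic, scale with noise, and vanish without it", {
  cfg <- mf_config(fixed_tau_m_residues = 1L)
  sds <- one_residue_sds(ref_m4_params(), cfg, noisy = TRUE, seed = 3)
  sel <- select_model(sds, cfg)
  mc1 <- monte_carlo_sd(sds, sel, n_sims = 60, seed = 9, config = cfg)
  mc2 <- monte_carlo_sd(sds, sel, n_sims = 60, seed = 9, config = cfg)
  expect_identical(mc1$sd, mc2$sd)                   # bitwise determinism
  expect_true(all(mc1$sd[c("Sf2", "Ss2", "tau_s", "S2")] > 0))

  # zero stated uncertainties -> every replicate identical -> all sd 0
  sds0 <- sds
  sds0$y_err <- rep(0, length(sds0$y_err))
  mc0 <- monte_carlo_sd(sds0, sel, n_sims = 10, seed = 1, config = cfg)
  expect_true(all(mc0$sd == 0))

  # doubling the data uncertainties roughly doubles parameter sd
  sds2 <- one_residue_sds(ref_m4_params(), cfg, noisy = TRUE, seed = 3)
  sds2$y_err <- 2 * sds$y_err
  mcA <- monte_carlo_sd(sds, sel, n_sims = 400, seed = 21, config = cfg)
  mcB <- monte_carlo_sd(sds2, sel, n_sims = 400, seed = 22, config = cfg)
  ratio <- mcB$sd["S2"] / mcA$sd["S2"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.5)
})
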