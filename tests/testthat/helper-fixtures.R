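# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as plain transcriptions (loops, direct
# formulas) so they stay independent of the package's vectorized /
# compiled implementation paths.

FIELDS4 <- c(600, 700, 800, 900)

# relaxation table for one residue from model-free parameters,
# optionally with Gaussian noise (fractional on R1/R2, absolute on NOE)
one_residue_rates <- function(params, fields = FIELDS4, residue = 1,
                              r_frac = 0.02, noe_abs = 0.02,
                              noisy = FALSE, seed = 1) {
  fr <- forward_rates(params, fields)
  n <- nrow(fr)
  R1_sd <- r_frac * fr$R1
  R2_sd <- r_frac * fr$R2
  NOE_sd <- rep(noe_abs, n)
  R1 <- fr$R1; R2 <- fr$R2; NOE <- fr$NOE
  if (noisy) {
    set.seed(seed)
    R1 <- R1 + rnorm(n) * R1_sd
    R2 <- R2 + rnorm(n) * R2_sd
    NOE <- NOE + rnorm(n) * NOE_sd
  }
  data.frame(residue = residue, field_MHz = fields,
             R1 = R1, R1_err = R1_sd,
             R2 = R2, R2_err = R2_sd,
             NOE = NOE, NOE_err = NOE_sd)
}

one_residue_sds <- function(params, config = mf_config(), ...) {
  spectral_density_set(map_relaxation_to_jw(
    one_residue_rates(params, ...), config$constants), config)
}

# disordered two-timescale reference parameters used in many tests
ref_m4_params <- function() mf_params(17.5e-9, 0.754, 0.292, 0, 0.838e-9)

# --- oracles -------------------------------------------------------------

# term-by-term transcription of the extended model-free function
oracle_mf_J <- function(omega, tau_m, Sf2, Ss2, tau_f, tau_s) {
  lor <- function(tau, w) if (tau <= 0) 0 else tau / (1 + w^2 * tau^2)
  t1 <- if (tau_s > 0) 1 / (1 / tau_m + 1 / tau_s) else 0
  t2 <- if (tau_f > 0) 1 / (1 / tau_m + 1 / tau_f) else 0
  t3 <- if (tau_f > 0 && tau_s > 0)
    1 / (1 / tau_m + 1 / tau_s + 1 / tau_f) else 0
  vapply(omega, function(w)
    2 / 5 * (Sf2 * Ss2 * lor(tau_m, w) +
               Sf2 * (1 - Ss2) * lor(t1, w) +
               (1 - Sf2) * Ss2 * lor(t2, w) +
               (1 - Sf2) * (1 - Ss2) * lor(t3, w)),
    numeric(1))
}

# delete-one jackknife SE of the inverse-variance weighted mean, as an
# explicit G-iteration loop
oracle_jackknife <- function(values, errors) {
  G <- length(values)
  wm <- function(v, e) sum(v / e^2) / sum(1 / e^2)
  th <- numeric(G)
  for (i in seq_len(G)) th[i] <- wm(values[-i], errors[-i])
  sqrt((G - 1) / G * sum((th - mean(th))^2))
}

# brute force: all G^G pointer vectors deduplicated as multisets,
# filtered to per-item multiplicity <= 2
oracle_arrangement_count <- function(G) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(G)), G)))
  keys <- apply(grid, 1, function(p) paste(sort(p), collapse = "-"))
  keys <- unique(keys)
  ok <- vapply(strsplit(keys, "-"), function(p)
    max(table(p)) <= 2, logical(1))
  sum(ok)
}

# coefficient of x^G in (1 + x + x^2)^G by polynomial multiplication
oracle_gf_count <- function(G) {
  poly <- 1
  for (i in seq_len(G)) poly <- convolve(c(poly, 0, 0), rev(c(1, 1, 1)),
                                         type = "open")
  round(poly[G + 1])
}

# Efron plug-in smoothed SD as a fully unrolled double loop
oracle_smoothed_sd <- function(mu_mat, Y_mat) {
  B <- nrow(mu_mat); N <- ncol(Y_mat); K <- ncol(mu_mat)
  out <- numeric(K)
  for (k in seq_len(K)) {
    mk <- mean(mu_mat[, k])
    ssq <- 0
    for (j in seq_len(N)) {
      yb <- mean(Y_mat[, j])
      cv <- 0
      for (i in seq_len(B))
        cv <- cv + (Y_mat[i, j] - yb) * (mu_mat[i, k] - mk)
      ssq <- ssq + (cv / B)^2
    }
    out[k] <- sqrt(ssq)
  }
  out
}
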