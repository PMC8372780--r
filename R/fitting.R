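#' Weighted residual sum of squares
#'
#' @param y,err observed values and strictly positive uncertainties.
#' @param model_J model values at the same frequencies.
#' @return \eqn{\chi^2 = \sum_j (y_j - J_{model}(\omega_j))^2/\sigma_j^2}.
#' @export
chi2_stat <- function(y, err, model_J) {
  stopifnot(length(y) == length(err), length(y) == length(model_J))
  if (any(err <= 0)) stop("all uncertainties must be > 0")
  sum(((y - model_J) / err)^2)
}

#' Small-sample Akaike information criterion
#'
#' Chi-square form with measurement variances treated as known:
#' \deqn{AICc = \chi^2 + 2k + \frac{2k(k+1)}{n-k-1}.}
#' Returns `NA` when `n <= k + 1` (model not applicable at this sample
#' size), mirroring the "NA" convention of per-model report tables.
#'
#' @param chi2 weighted residual sum of squares.
#' @param k number of free parameters.
#' @param n number of fitted data points.
#' @return AICc value, or `NA_real_` when the correction diverges.
#' @export
aicc <- function(chi2, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  chi2 + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Pick the optimal model from per-model AICc values
#'
#' Argmin over the applicable (non-NA) models; exact ties are resolved
#' toward the model with fewer free parameters.  Model ids 1-5 are ordered
#' by increasing parameter count, so the first minimum wins.
#'
#' @param aicc_values numeric vector of length 5, ordered by model id;
#'   `NA` marks a non-applicable model.
#' @return the winning model id (integer).
#' @export
select_best_aicc <- function(aicc_values) {
  stopifnot(length(aicc_values) == 5)
  if (all(is.na(aicc_values))) stop("no applicable model")
  as.integer(which.min(aicc_values))
}

.tau_m_free <- function(residue, config) {
  !(as.integer(residue) %in% config$fixed_tau_m_residues)
}

.fit_vec_ns <- function(sds) {
  list(y = sds$y * 1e9, sig = sds$y_err * 1e9, omega = sds$omega * 1e-9)
}

.par5_to_mf <- function(par5_ns) {
  mf_params(par5_ns[1] * 1e-9, par5_ns[2], par5_ns[3],
            par5_ns[4] * 1e-9, par5_ns[5] * 1e-9)
}

# start matrix for a single fixed model id (forms share layouts)
.model_starts <- function(model_id, config, tau_m_free) {
  grid <- .start_matrices(config, tau_m_free)
  grid[[c(1, 2, 2, 3, 4)[model_id]]]
}

#' Fit one model-free model to a spectral density set
#'
#' Bounded weighted least-squares minimization over the model's free
#' parameters from a multi-start grid (best-of-starts).  Models 2 and 3
#' share the single-internal-timescale functional form; here their internal
#' correlation time is restricted to its side of the configured threshold.
#'
#' @param sds a [spectral_density_set()].
#' @param model_id integer 1-5.
#' @param config an [mf_config()] object.
#' @param starts optional start matrix (rows of free-parameter vectors in
#'   ns; leading tau_m column when tau_m is fitted locally, -1 = coarse
#'   scan).  Defaults to the configured grid.
#' @return Object of class `fit_result`: `model_id`, `params`
#'   ([mf_params()]), `chi2`, `k`, `aicc`, `n_data`, `converged`,
#'   `tau_m_policy`.
#' @export
fit_model <- function(sds, model_id, config = mf_config(), starts = NULL) {
  stopifnot(inherits(sds, "spectral_density_set"), model_id %in% 1:5)
  tmf <- .tau_m_free(sds$residue, config)
  fv <- .fit_vec_ns(sds)
  if (is.null(starts)) starts <- .model_starts(model_id, config, tmf)
  out <- cpp_fit_model(fv$y, fv$sig, fv$omega, as.integer(model_id),
                       .cpp_cfg(config, tmf), starts)
  n <- length(fv$y)
  if (!isTRUE(out$converged)) {
    res <- list(model_id = as.integer(model_id), params = NULL,
                chi2 = NA_real_, k = NA_integer_, aicc = NA_real_,
                n_data = n, converged = FALSE,
                tau_m_policy = if (tmf) "local" else "fixed")
  } else {
    res <- list(model_id = as.integer(model_id),
                params = .par5_to_mf(out$par5),
                chi2 = out$chi2, k = out$k,
                aicc = aicc(out$chi2, out$k, n),
                n_data = n, converged = TRUE,
                tau_m_policy = if (tmf) "local" else "fixed",
                xfree = out$xfree)
  }
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model %d fit: chi2 = %.4g, k = %d, AICc = %.4g (%s tau_m)\n",
              x$model_id, x$chi2, x$k, x$aicc, x$tau_m_policy))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Fit all candidate models and select the optimal one by AICc
#'
#' Models 1, 4 and 5 are fitted directly.  Models 2 and 3 share one
#' functional form (one order parameter, one internal correlation time);
#' that form is fitted once with the internal time free over its full range
#' and labelled Model 2 when the fitted time falls below the configured
#' threshold (default 0.15 ns), Model 3 otherwise.  The model minimizing
#' AICc among applicable models wins; exact ties go to the model with fewer
#' free parameters.
#'
#' @inheritParams fit_model
#' @param starts optional list of four start matrices (Model 1, single
#'   timescale, Model 4, Model 5 forms).
#' @return Object of class `selection_result`: `best` (model id), `fit`
#'   (the winning [fit_model()]-style result), `table` (per-model
#'   data.frame with chi2, k, aicc and parameters; non-applicable models
#'   are NA), `label23`, `par_form` (ns-unit per-form parameter matrix used
#'   for warm starts).
#' @export
select_model <- function(sds, config = mf_config(), starts = NULL) {
  stopifnot(inherits(sds, "spectral_density_set"))
  tmf <- .tau_m_free(sds$residue, config)
  fv <- .fit_vec_ns(sds)
  if (is.null(starts)) starts <- .start_matrices(config, tmf)
  out <- cpp_select_model(fv$y, fv$sig, fv$omega,
                          .cpp_cfg(config, tmf), starts)
  n <- length(fv$y)

  tab <- data.frame(model = 1:5, chi2 = NA_real_, k = NA_integer_,
                    aicc = NA_real_, tau_m = NA_real_, Sf2 = NA_real_,
                    Ss2 = NA_real_, tau_f = NA_real_, tau_s = NA_real_,
                    S2 = NA_real_, best = FALSE)
  form_of <- c(1, 2, 2, 3, 4)
  for (m in 1:5) {
    if (is.na(out$aicc[m])) next
    q <- form_of[m]
    p5 <- out$par_form[q, ]
    if (m == 3) p5 <- c(p5[1], 1, p5[2], 0, p5[4])
    tab$chi2[m] <- out$chi2_form[q]
    tab$k[m] <- out$k[m]
    tab$aicc[m] <- out$aicc[m]
    tab$tau_m[m] <- p5[1] * 1e-9
    tab$Sf2[m] <- p5[2]; tab$Ss2[m] <- p5[3]
    tab$tau_f[m] <- p5[4] * 1e-9; tab$tau_s[m] <- p5[5] * 1e-9
    tab$S2[m] <- p5[2] * p5[3]
  }
  if (out$best < 1) stop("no model converged for residue ", sds$residue)
  tab$best[out$best] <- TRUE

  fit <- list(model_id = out$best,
              params = .par5_to_mf(out$best_par5),
              chi2 = out$best_chi2,
              k = out$k[out$best],
              aicc = out$aicc[out$best],
              n_data = n, converged = TRUE,
              tau_m_policy = if (tmf) "local" else "fixed")
  class(fit) <- "fit_result"

  res <- list(residue = sds$residue, best = out$best, fit = fit,
              table = tab, label23 = out$label23,
              par_form = out$par_form,
              tau_m_free = tmf, n_data = n)
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Residue %s: best model %d (AICc %.3g)\n",
              x$residue, x$best, x$fit$aicc))
  print(x$table[, c("model", "chi2", "k", "aicc", "best")], row.names = FALSE)
  invisible(x)
}

#' Monte Carlo uncertainties for the selected model
#'
#' Perturbs every fit-vector entry with independent Gaussian noise of its
#' stated uncertainty, refits the fixed best model, and returns the sample
#' standard deviation of each model-free parameter over the replicates
#' (parametric-bootstrap error estimate).  Replicates that fail to converge
#' are dropped; a warning is issued when more than 10% drop.
#'
#' @param sds a [spectral_density_set()].
#' @param selection a [select_model()] result (fixes the refitted model).
#' @param n_sims number of simulations (default from `config`).
#' @param seed integer seed; same seed gives bitwise-identical results.
#' @param config an [mf_config()] object.
#' @return List with `sd` (named: tau_m, Sf2, Ss2, tau_f, tau_s, S2),
#'   `n_sims`, `n_dropped`, and the replicate matrix `params`.
#' @export
monte_carlo_sd <- function(sds, selection, n_sims = NULL, seed = 1,
                           config = mf_config()) {
  stopifnot(inherits(selection, "selection_result"))
  if (is.null(n_sims)) n_sims <- config$n_mc
  stopifnot(n_sims >= 2)
  tmf <- selection$tau_m_free
  fv <- .fit_vec_ns(sds)
  sig_fit <- ifelse(fv$sig > 0, fv$sig, 1)
  warm <- .warm_starts(selection$par_form, config, tmf)
  form_of <- c(1, 2, 2, 3, 4)
  starts <- warm[[form_of[selection$best]]]
  ccfg <- .cpp_cfg(config, tmf)

  set.seed(as.integer(seed))
  reps <- matrix(NA_real_, n_sims, 5)
  for (i in seq_len(n_sims)) {
    y_star <- fv$y + stats::rnorm(length(fv$y)) * fv$sig
    out <- cpp_fit_model(y_star, sig_fit, fv$omega, selection$best,
                         ccfg, starts)
    if (isTRUE(out$converged)) reps[i, ] <- out$par5
  }
  ok <- !is.na(reps[, 1])
  if (sum(!ok) > 0.1 * n_sims)
    warning(sum(!ok), " of ", n_sims, " Monte Carlo replicates dropped")
  reps <- reps[ok, , drop = FALSE]
  pm <- cbind(reps, S2 = reps[, 2] * reps[, 3])
  colnames(pm) <- c("tau_m", "Sf2", "Ss2", "tau_f", "tau_s", "S2")
  pm[, c("tau_m", "tau_f", "tau_s")] <-
    pm[, c("tau_m", "tau_f", "tau_s")] * 1e-9
  list(sd = apply(pm, 2, stats::sd),
       n_sims = n_sims, n_dropped = sum(!ok), params = pm)
}
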