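#' Plug-in smoothed standard deviation of bagged parameters
#'
#' Efron's smoothed-bootstrap uncertainty: with counter vectors
#' \eqn{Y_i^*} recording how often each original datum enters the i-th
#' bootstrap sample, and replicate parameter values \eqn{\tilde\mu_{ik}^*},
#' \deqn{\widehat{cov}_{jk} = \frac{1}{B}\sum_i (Y_{ij}^* - \bar Y_j^*)
#'   (\tilde\mu_{ik}^* - \tilde\mu_k), \qquad
#'   \tilde\sigma_k = \Big[\sum_j \widehat{cov}_{jk}^2\Big]^{1/2}.}
#' A 1/N-scaled variant (dividing the sum of squared covariances by N) is
#' available behind `scale_by_N`.
#'
#' @param replicate_matrix B x K matrix of per-replicate parameter values.
#' @param Y_matrix B x N matrix of concatenated counter vectors (N = 3G raw
#'   spectral density values, pre-averaging).
#' @param smoothed_params optional length-K vector of bagged means
#'   (defaults to column means of `replicate_matrix`).
#' @param scale_by_N use the 1/N-scaled variant (default `FALSE`).
#' @return Named length-K vector of smoothed standard deviations.
#' @export
smoothed_sd <- function(replicate_matrix, Y_matrix, smoothed_params = NULL,
                        scale_by_N = FALSE) {
  replicate_matrix <- as.matrix(replicate_matrix)
  Y_matrix <- as.matrix(Y_matrix)
  B <- nrow(replicate_matrix)
  if (B < 2) stop("smoothed_sd requires at least two bootstrap replicates")
  stopifnot(nrow(Y_matrix) == B)
  if (is.null(smoothed_params)) smoothed_params <- colMeans(replicate_matrix)
  Yc <- sweep(Y_matrix, 2, colMeans(Y_matrix))
  Mc <- sweep(replicate_matrix, 2, smoothed_params)
  covjk <- crossprod(Yc, Mc) / B            # N x K
  s <- sqrt(colSums(covjk^2))
  if (scale_by_N) s <- s / sqrt(ncol(Y_matrix))
  stats::setNames(s, colnames(replicate_matrix))
}

#' Naive bootstrap standard deviation of bagged parameters
#'
#' The plain sample standard deviation (1/(B-1) normalization) applied
#' across the mixed-model bootstrap replicates.  Serves as the upper
#' reference for the smoothed uncertainty: `smoothed_sd()` <= `naive_sd()`
#' column-wise.
#'
#' @param replicate_matrix B x K matrix of per-replicate parameter values.
#' @return Named length-K vector of sample standard deviations.
#' @export
naive_sd <- function(replicate_matrix) {
  replicate_matrix <- as.matrix(replicate_matrix)
  if (nrow(replicate_matrix) < 2) stop("need at least two replicates")
  apply(replicate_matrix, 2, stats::sd)
}

#' Bootstrap aggregation (bagging) of model-free analysis
#'
#' Runs the full model selection (all candidate models, AICc, 0.15 ns
#' single-timescale split) on every sample of the enumerated
#' block-constrained bootstrap ensemble.  The winning model's parameters
#' enter the replicate matrix with null conventions for fixed parameters
#' (order parameters 1, internal times 0), so the bagged estimate of each
#' parameter is the plain mean over all B replicates, mixing models in
#' proportion to how often they are selected.  Uncertainties are the
#' plug-in [smoothed_sd()] together with the [naive_sd()] upper reference.
#'
#' The derived order parameter S2 is bagged as the mean of the per-sample
#' products Sf2 * Ss2; the product of the bagged factors is also reported
#' (`S2_product`) for transparency.
#'
#' @param sds a [spectral_density_set()].
#' @param config an [mf_config()] object.
#' @param selection optional precomputed [select_model()] result for the
#'   original data (used for warm starts; computed when missing).
#' @param keep_matrices keep the B x 6 replicate matrix and B x N counter
#'   matrix in the result (default `TRUE`).
#' @return Object of class `bagged_result`: `residue`, `B`, `B_used`,
#'   `model_fractions` (length 5, sums to 1 over converged replicates),
#'   `smoothed` (bagged means), `smoothed_sd`, `naive_sd`, `S2_product`,
#'   `selection`, and optionally `replicate_matrix`, `Y_matrix`, `models`.
#' @export
bagged_fit <- function(sds, config = mf_config(), selection = NULL,
                       keep_matrices = TRUE) {
  stopifnot(inherits(sds, "spectral_density_set"))
  if (is.null(selection)) selection <- select_model(sds, config)
  tmf <- selection$tau_m_free
  starts <- .warm_starts(selection$par_form, config, tmf)
  ens <- .run_ensemble(sds, config, tmf, starts, do_select = TRUE)

  ok <- ens$converged
  if (any(!ok))
    warning(sum(!ok), " of ", ens$B, " bootstrap samples dropped ",
            "(no model converged); fractions renormalized")
  pm <- .replicate_matrix(ens$par[ok, , drop = FALSE])
  Y <- ens$Y[ok, , drop = FALSE]
  models <- ens$model[ok]
  B_used <- sum(ok)

  frac <- tabulate(models, nbins = 5) / B_used
  mu <- colMeans(pm)
  res <- list(residue = sds$residue,
              B = ens$B, B_used = B_used,
              model_fractions = stats::setNames(frac, paste0("model", 1:5)),
              smoothed = mu,
              smoothed_sd = smoothed_sd(pm, Y, mu,
                                        config$smoothed_sd_scale_by_N),
              naive_sd = naive_sd(pm),
              S2_product = unname(mu["Sf2"] * mu["Ss2"]),
              selection = selection)
  if (keep_matrices) {
    res$replicate_matrix <- pm
    res$Y_matrix <- Y
    res$models <- models
  }
  class(res) <- "bagged_result"
  res
}

#' @export
print.bagged_result <- function(x, ...) {
  cat(sprintf("Bagged model-free result: residue %s, B = %d (%d used)\n",
              x$residue, x$B, x$B_used))
  cat("  model fractions:",
      paste(sprintf("%d: %.3f", 1:5, x$model_fractions), collapse = ", "),
      "\n")
  tab <- rbind(smoothed = x$smoothed, smoothed_sd = x$smoothed_sd,
               naive_sd = x$naive_sd)
  tms <- c("tau_m", "tau_f", "tau_s")
  tab[, tms] <- tab[, tms] * 1e9
  colnames(tab)[colnames(tab) %in% tms] <- paste0(tms, "_ns")
  print(signif(tab, 4))
  invisible(x)
}

#' Replicate histogram table for one bagged residue
#'
#' Long-format dump of the per-replicate parameter values with the model
#' selected for each bootstrap sample, suitable for plotting parameter
#' distributions.  Null values (order parameters fixed at 1, internal
#' times fixed at 0) are retained and flagged.
#'
#' @param bag a [bagged_fit()] result with `keep_matrices = TRUE`.
#' @return data.frame with columns `residue`, `sample`, `model_id`,
#'   `parameter`, `value`, `is_null`.
#' @export
replicate_histogram <- function(bag) {
  stopifnot(inherits(bag, "bagged_result"),
            !is.null(bag$replicate_matrix))
  pm <- bag$replicate_matrix
  nulls <- list(model1 = c("Ss2", "tau_f", "tau_s"),
                model2 = c("Ss2", "tau_s"),
                model3 = c("Sf2", "tau_f"),
                model4 = "tau_f", model5 = character(0))
  out <- do.call(rbind, lapply(colnames(pm), function(p) {
    data.frame(residue = bag$residue,
               sample = seq_len(nrow(pm)),
               model_id = bag$models,
               parameter = p,
               value = pm[, p],
               is_null = vapply(bag$models, function(m)
                 p %in% nulls[[m]], logical(1)))
  }))
  rownames(out) <- NULL
  out
}
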