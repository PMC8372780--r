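#' Analysis configuration
#'
#' Central configuration for model fitting, model selection and the
#' bootstrap/bagging machinery.  All times are SI seconds.
#'
#' @param tau_m_fixed overall rotational correlation time (s) used for
#'   residues listed in `fixed_tau_m_residues`; default 17.5 ns.
#' @param fixed_tau_m_residues integer vector of residue numbers for which
#'   tau_m is held at `tau_m_fixed` rather than fitted locally (typically
#'   disordered segments).
#' @param threshold internal-timescale split (s): the single-timescale fit
#'   is labelled Model 2 when its correlation time is below the threshold
#'   and Model 3 otherwise; also the boundary between the tau_f and tau_s
#'   boxes in Models 4 and 5.  Default 0.15 ns.
#' @param tau_m_bounds search box for a locally fitted tau_m (s).
#' @param tau_s_max upper search bound for the slow internal correlation
#'   time (s); the constraint tau_s <= tau_m is additionally enforced
#'   inside the objective.
#' @param n_mc number of Monte Carlo simulations for conventional
#'   uncertainties; default 500.
#' @param tol convergence tolerance on the weighted residual sum of squares.
#' @param maxit maximum optimizer iterations per start.
#' @param smoothed_sd_scale_by_N if `TRUE`, scale the plug-in smoothed
#'   standard deviation by 1/sqrt(N); default `FALSE` (Efron's estimator).
#' @param j0_uncertainty how to set the uncertainty of the weighted-mean
#'   J(0) used in fitting: `"jackknife"` (delete-one jackknife SE, default)
#'   or `"combined"` (quadrature sum of jackknife SE and the propagated
#'   error of the weighted mean).
#' @param s2_starts,tau_starts multi-start grids for the order parameters
#'   (dimensionless) and the internal correlation times (s) used when
#'   fitting the original data.
#' @param constants an [nmr_constants()] object.
#' @return An object of class `mf_config`.
#' @export
mf_config <- function(tau_m_fixed = 17.5e-9,
                      fixed_tau_m_residues = integer(),
                      threshold = 0.15e-9,
                      tau_m_bounds = c(1e-9, 100e-9),
                      tau_s_max = 100e-9,
                      n_mc = 500L,
                      tol = 1e-10,
                      maxit = 500L,
                      smoothed_sd_scale_by_N = FALSE,
                      j0_uncertainty = c("jackknife", "combined"),
                      s2_starts = c(0.5, 0.9),
                      tau_starts = c(10e-12, 50e-12, 500e-12),
                      constants = nmr_constants()) {
  j0_uncertainty <- match.arg(j0_uncertainty)
  stopifnot(threshold > 0, tau_m_fixed > 0,
            length(tau_m_bounds) == 2, tau_m_bounds[1] > 0,
            tau_m_bounds[2] > tau_m_bounds[1],
            n_mc >= 2, tol > 0, maxit >= 1)
  cfg <- list(tau_m_fixed = tau_m_fixed,
              fixed_tau_m_residues = as.integer(fixed_tau_m_residues),
              threshold = threshold,
              tau_m_bounds = tau_m_bounds,
              tau_s_max = tau_s_max,
              n_mc = as.integer(n_mc),
              tol = tol,
              maxit = as.integer(maxit),
              smoothed_sd_scale_by_N = isTRUE(smoothed_sd_scale_by_N),
              j0_uncertainty = j0_uncertainty,
              s2_starts = s2_starts,
              tau_starts = tau_starts,
              constants = constants)
  class(cfg) <- "mf_config"
  cfg
}

# configuration list handed to the C++ layer; times converted to ns
.cpp_cfg <- function(config, tau_m_free) {
  list(tau_m_lo = config$tau_m_bounds[1] * 1e9,
       tau_m_hi = config$tau_m_bounds[2] * 1e9,
       threshold = config$threshold * 1e9,
       tau_s_hi = config$tau_s_max * 1e9,
       tau_m_free = isTRUE(tau_m_free),
       tau_m_fixed = config$tau_m_fixed * 1e9,
       tol = config$tol,
       maxit = config$maxit,
       j0_combined = identical(config$j0_uncertainty, "combined"))
}

# Multi-start matrices for the four fitted functional forms
# (Model 1, single-timescale Model 2/3, Model 4, Model 5).
# Rows are free-parameter vectors in ns units; when tau_m is locally
# fitted a leading column holds the tau_m start, with -1 meaning "use the
# per-sample coarse scan".
.start_matrices <- function(config, tau_m_free) {
  s2 <- config$s2_starts
  tauns <- config$tau_starts * 1e9
  thr <- config$threshold * 1e9
  tf <- tauns[tauns < thr]
  ts <- tauns[tauns >= thr]
  if (!length(tf)) tf <- thr / 3
  if (!length(ts)) ts <- 2 * thr
  m1 <- cbind(Sf2 = s2)
  m23 <- as.matrix(expand.grid(S2 = s2, tau = tauns))
  m4 <- as.matrix(expand.grid(Sf2 = s2, Ss2 = s2, tau_s = ts[1]))
  m5 <- as.matrix(expand.grid(Sf2 = s2, Ss2 = s2,
                              tau_f = tf[1], tau_s = ts[1]))
  add_tm <- function(m) if (tau_m_free) cbind(tau_m = -1, m) else m
  lapply(list(m1, m23, m4, m5), add_tm)
}

# Warm starts for ensemble refits, derived from the original-data
# per-form parameter matrix (par_form, ns units) of cpp_select_model.
.warm_starts <- function(par_form, config, tau_m_free) {
  thr <- config$threshold * 1e9
  rows <- list(
    par_form[1, 2, drop = TRUE],                       # M1: Sf2
    c(par_form[2, 2], par_form[2, 4]),                 # M2/3: S2, tau
    par_form[3, c(2, 3, 5)],                           # M4: Sf2, Ss2, tau_s
    par_form[4, 2:5])                                  # M5
  mats <- vector("list", 4)
  grid <- .start_matrices(config, tau_m_free)
  for (q in 1:4) {
    x <- as.numeric(rows[[q]])
    if (anyNA(x)) {
      mats[[q]] <- grid[[q]][1, , drop = FALSE]
      next
    }
    if (tau_m_free) x <- c(par_form[q, 1], x)
    mats[[q]] <- rbind(x, grid[[q]][1, , drop = FALSE])
    colnames(mats[[q]]) <- colnames(grid[[q]])
  }
  mats
}
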