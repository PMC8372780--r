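#' Enumerate the within-block resampling arrangements
#'
#' A block arrangement is a multiset of size G drawn from the G
#' field-ordered values of one spectral-density class, with no value
#' appearing more than twice.  Writing the counter vector
#' \eqn{Y \in \{0,1,2\}^G, \sum Y = G}, every arrangement has d duplicated
#' fields and d omitted fields for some d, so the count is
#' \eqn{\sum_d \binom{G}{d}\binom{G-d}{d}}: 19 arrangements at G = 4 and 7
#' at G = 3.  Arrangements are ordered canonically: the identity first,
#' then by the number of duplicated fields, then lexicographically by the
#' duplicated-field set and by the omitted-field set.  (For G = 4 this
#' reproduces the published ordering on which the worked index example
#' below relies.)  Pointer vectors are the nondecreasing expansions of the
#' counters.
#'
#' @param G number of static magnetic fields (>= 1).
#' @return Object of class `block_arrangements`: list with `G`, `n_arr`,
#'   integer matrices `pointer` and `counter` (n_arr x G, pointers 1-based).
#' @export
enumerate_block_arrangements <- function(G) {
  stopifnot(G >= 1)
  counters <- list()
  for (d in 0:(G %/% 2)) {
    dup_sets <- if (d == 0) list(integer(0)) else
      utils::combn(G, d, simplify = FALSE)
    for (D in dup_sets) {
      rest <- setdiff(seq_len(G), D)
      # guard: combn(x, m) with scalar x would enumerate over 1:x
      omit_sets <- if (d == 0) list(integer(0)) else
        if (length(rest) == 1) list(rest) else
          utils::combn(rest, d, simplify = FALSE)
      for (O in omit_sets) {
        ctr <- rep(1L, G)
        ctr[D] <- 2L
        ctr[O] <- 0L
        counters[[length(counters) + 1L]] <- ctr
      }
    }
  }
  counter <- do.call(rbind, counters)
  pointer <- t(apply(counter, 1, function(ct) rep(seq_len(G), ct)))
  if (G == 1) pointer <- matrix(1L, nrow(counter), 1)
  storage.mode(pointer) <- "integer"
  out <- list(G = as.integer(G), n_arr = nrow(counter),
              pointer = pointer, counter = counter)
  class(out) <- "block_arrangements"
  out
}

#' @export
print.block_arrangements <- function(x, ...) {
  cat(sprintf("%d block arrangements for G = %d (ensemble size %d^3 = %d)\n",
              x$n_arr, x$G, x$n_arr, x$n_arr^3))
  invisible(x)
}

#' Map a bootstrap sample index to its block-arrangement triple
#'
#' The 1-based sample index i is decomposed in mixed radix base `n_arr`
#' with the most significant digit assigned to the J(0) block:
#' l = (i-1) div n_arr^2 + 1, m = ((i-1) div n_arr) mod n_arr + 1,
#' n = (i-1) mod n_arr + 1.  Sample 1 is the identity sample (original
#' data); with the canonical G = 4 ordering, sample 1260 selects
#' arrangements (4, 10, 6) for the J(0), J(omega_N) and J(0.87 omega_H)
#' blocks.
#'
#' @param i 1-based sample index, 1 <= i <= n_arr^3.
#' @param n_arr arrangements per block.
#' @return Integer vector `c(l, m, n)`.
#' @export
index_to_block_indices <- function(i, n_arr) {
  stopifnot(i >= 1, i <= n_arr^3)
  i0 <- i - 1
  c(l = as.integer(i0 %/% n_arr^2 + 1),
    m = as.integer((i0 %/% n_arr) %% n_arr + 1),
    n = as.integer(i0 %% n_arr + 1))
}

#' Construct one bootstrap sample of a spectral density set
#'
#' Applies the three pointer vectors selected by the sample index to the
#' field-ordered J(0), J(omega_N) and J(0.87 omega_H) value lists,
#' concatenates the counter vectors in that block order into `Y_star`
#' (length N = 3G), and recomputes the weighted-mean J(0) and its
#' delete-one jackknife uncertainty on the resampled J(0) multiset
#' (duplicates entering as distinct draws), exactly as for the original
#' data.
#'
#' A bootstrap draw resamples (value, frequency) data points, so duplicated
#' high-frequency values keep their own frequencies: the sample is
#' represented both as the selected pairs (`y_star`, `y_err_star`,
#' `omega_star`, in pointer order) and, equivalently for fitting, as the
#' original fit vector with per-point multiplicities (`multiplicity`).
#'
#' @param i 1-based sample index.
#' @param arr a [enumerate_block_arrangements()] object with `G == sds$G`.
#' @param sds a [spectral_density_set()].
#' @return Object of class `bootstrap_sample`: `index`, `block_indices`,
#'   `Y_star`, the resampled pairs `y_star`, `y_err_star`, `omega_star`,
#'   the fit-vector `multiplicity` (length 1 + 2G), and the resampled
#'   `J0_mean`, `J0_mean_err`.
#' @export
build_sample <- function(i, arr, sds) {
  stopifnot(inherits(arr, "block_arrangements"), arr$G == sds$G)
  idx <- index_to_block_indices(i, arr$n_arr)
  p0 <- arr$pointer[idx[1], ]
  pN <- arr$pointer[idx[2], ]
  pH <- arr$pointer[idx[3], ]

  J0v <- sds$J0[p0]; J0e <- sds$J0_err[p0]
  J0_mean <- weighted_mean_j0(J0v, J0e)
  J0_se <- jackknife_j0_se(J0v, J0e)
  if (J0_se <= 1e-12 * abs(J0_mean)) J0_se <- J0e[1]

  G <- sds$G
  omN <- sds$omega[2:(1 + G)]
  omH <- sds$omega[(2 + G):(1 + 2 * G)]
  out <- list(index = i,
              block_indices = idx,
              Y_star = c(arr$counter[idx[1], ], arr$counter[idx[2], ],
                         arr$counter[idx[3], ]),
              J0_mean = J0_mean, J0_mean_err = J0_se,
              y_star = c(J0_mean, sds$JwN[pN], sds$JwH087[pH]),
              y_err_star = c(J0_se, sds$JwN_err[pN], sds$JwH087_err[pH]),
              omega_star = c(0, omN[pN], omH[pH]),
              multiplicity = c(1, arr$counter[idx[2], ],
                               arr$counter[idx[3], ]))
  class(out) <- "bootstrap_sample"
  out
}

# shared driver for the C++ ensemble loop
.run_ensemble <- function(sds, config, tau_m_free, starts,
                          do_select, fixed_model = 0L) {
  arr <- enumerate_block_arrangements(sds$G)
  cpp_ensemble(sds$J0 * 1e9, sds$J0_err * 1e9,
               sds$JwN * 1e9, sds$JwN_err * 1e9,
               sds$JwH087 * 1e9, sds$JwH087_err * 1e9,
               sds$omega[2:(1 + sds$G)] * 1e-9,
               sds$omega[(2 + sds$G):(1 + 2 * sds$G)] * 1e-9,
               arr$pointer, .cpp_cfg(config, tau_m_free), starts,
               do_select, as.integer(fixed_model))
}

# replicate parameter matrix in SI units with derived S2 column
.replicate_matrix <- function(par_ns) {
  pm <- cbind(par_ns, par_ns[, 2] * par_ns[, 3])
  colnames(pm) <- c("tau_m", "Sf2", "Ss2", "tau_f", "tau_s", "S2")
  pm[, c("tau_m", "tau_f", "tau_s")] <-
    pm[, c("tau_m", "tau_f", "tau_s")] * 1e-9
  pm
}

#' Conventional bootstrap uncertainties for a fixed model
#'
#' Refits the fixed optimal model to every sample of the enumerated
#' bootstrap ensemble and returns the sample standard deviation over the B
#' replicates for each model-free parameter.
#'
#' @param sds a [spectral_density_set()].
#' @param selection a [select_model()] result (fixes the refitted model).
#' @param config an [mf_config()] object.
#' @param keep_replicates keep the B x 6 replicate matrix in the result.
#' @return List with `sd` (named per parameter), `B`, `n_dropped`, `model`,
#'   and optionally `params`.
#' @export
conventional_bootstrap_sd <- function(sds, selection, config = mf_config(),
                                      keep_replicates = FALSE) {
  stopifnot(inherits(selection, "selection_result"))
  tmf <- selection$tau_m_free
  warm <- .warm_starts(selection$par_form, config, tmf)
  form_of <- c(1, 2, 2, 3, 4)
  starts <- list(warm[[form_of[selection$best]]])
  ens <- .run_ensemble(sds, config, tmf, starts,
                       do_select = FALSE, fixed_model = selection$best)
  ok <- ens$converged
  if (any(!ok))
    warning(sum(!ok), " of ", ens$B, " bootstrap replicates dropped")
  pm <- .replicate_matrix(ens$par[ok, , drop = FALSE])
  res <- list(sd = apply(pm, 2, stats::sd), B = ens$B,
              n_dropped = sum(!ok), model = selection$best)
  if (keep_replicates) res$params <- pm
  res
}
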