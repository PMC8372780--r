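#' Read a multi-field relaxation table
#'
#' Reads a CSV or TSV file with one row per residue x field and the exact
#' header `residue, field_MHz, R1, R1_err, R2, R2_err, NOE, NOE_err`.
#' Rates are s^-1, the NOE is dimensionless.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv`/`.tab` for tab, comma otherwise).
#' @return A validated data.frame.
#' @export
read_relaxation <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("residue", "field_MHz", "R1", "R1_err",
                "R2", "R2_err", "NOE", "NOE_err")
  if (!identical(names(df), expected))
    stop("relaxation table header must be exactly: ",
         paste(expected, collapse = ", "))
  validate_relaxation(df)
  df
}

validate_relaxation <- function(df) {
  bad <- which(!(df$R1 > 0 & df$R2 > 0 & df$field_MHz > 0 &
                   df$R1_err >= 0 & df$R2_err >= 0 & df$NOE_err >= 0))
  if (length(bad))
    stop("invalid relaxation record in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (rates and fields must be positive, errors non-negative)")
  invisible(df)
}

#' Reduced spectral density mapping of one or more relaxation records
#'
#' Transforms `R1`, `R2` and the steady-state NOE measured at a 1H Larmor
#' frequency into the three reduced spectral density values
#' \deqn{J(0.87\omega_H) = 4\sigma_{NH} / (5 d_{NH}^2)}
#' \deqn{J(\omega_N) = 4 (R_1 - 1.249\,\sigma_{NH}) / (3 d_{NH}^2 + 4 c_{NH}^2)}
#' \deqn{J(0) = 6 (R_2 - 0.5 R_1 - 0.454\,\sigma_{NH}) / (3 d_{NH}^2 + 4 c_{NH}^2)}
#' with \eqn{\sigma_{NH} = (\mathrm{NOE}-1) R_1 \gamma_N/\gamma_H}, the
#' cross-relaxation rate.  Uncertainties are first-order (delta-method)
#' propagations of the independent Gaussian measurement errors; the mapping
#' is linear in (R1, R2, sigma_NH) so first order is exact.
#'
#' @param df data.frame in the [read_relaxation()] layout (one or more rows).
#' @param const an [nmr_constants()] object.
#' @return data.frame with columns `residue`, `field_MHz`, `J0`, `J0_err`,
#'   `JwN`, `JwN_err`, `JwH087`, `JwH087_err` (s/rad) and the sampled
#'   angular frequencies `omega_N`, `omega_H087` (rad/s, magnitudes).
#' @export
map_relaxation_to_jw <- function(df, const = nmr_constants()) {
  validate_relaxation(df)
  ic <- interaction_constants(df$field_MHz, const)
  g <- const$gamma_N / const$gamma_H
  sigma_NH <- (df$NOE - 1) * df$R1 * g

  JwH087 <- 4 * sigma_NH / (5 * const$d_NH^2)
  JwN <- 4 * (df$R1 - 1.249 * sigma_NH) / ic$denom
  J0 <- 6 * (df$R2 - 0.5 * df$R1 - 0.454 * sigma_NH) / ic$denom

  # partial derivatives for the delta method
  dsig_dR1 <- (df$NOE - 1) * g
  dsig_dNOE <- df$R1 * g
  JwH087_err <- 4 / (5 * const$d_NH^2) *
    sqrt((dsig_dR1 * df$R1_err)^2 + (dsig_dNOE * df$NOE_err)^2)
  JwN_err <- 4 / ic$denom *
    sqrt(((1 - 1.249 * dsig_dR1) * df$R1_err)^2 +
           (1.249 * dsig_dNOE * df$NOE_err)^2)
  J0_err <- 6 / ic$denom *
    sqrt((df$R2_err)^2 +
           ((0.5 + 0.454 * dsig_dR1) * df$R1_err)^2 +
           (0.454 * dsig_dNOE * df$NOE_err)^2)

  data.frame(residue = df$residue, field_MHz = df$field_MHz,
             J0 = J0, J0_err = J0_err,
             JwN = JwN, JwN_err = JwN_err,
             JwH087 = JwH087, JwH087_err = JwH087_err,
             omega_N = ic$abs_omega_N, omega_H087 = ic$omega_H087)
}

#' Inverse-variance weighted mean
#'
#' @param values,errors numeric vectors of equal length; all errors must be
#'   strictly positive.
#' @return \eqn{\sum (v_i/\sigma_i^2) / \sum (1/\sigma_i^2)}.
#' @export
weighted_mean_j0 <- function(values, errors) {
  stopifnot(length(values) == length(errors), length(values) >= 1)
  if (any(errors <= 0)) stop("all uncertainties must be > 0 (degenerate weight)")
  w <- 1 / errors^2
  sum(w * values) / sum(w)
}

#' Delete-one jackknife standard error of the weighted-mean J(0)
#'
#' Recomputes the inverse-variance weighted mean G times leaving one field
#' out and returns \eqn{\sqrt{(G-1)/G\,\sum_i(\hat\theta_{(i)} -
#' \bar\theta_{(\cdot)})^2}}.  For a single field (G = 1) the propagated
#' error of that value is returned as a documented fallback.
#'
#' @inheritParams weighted_mean_j0
#' @return jackknife standard error (same units as `values`).
#' @export
jackknife_j0_se <- function(values, errors) {
  stopifnot(length(values) == length(errors), length(values) >= 1)
  G <- length(values)
  if (G == 1) return(errors[1])
  theta <- vapply(seq_len(G), function(i)
    weighted_mean_j0(values[-i], errors[-i]), numeric(1))
  sqrt((G - 1) / G * sum((theta - mean(theta))^2))
}

#' Assemble a per-residue spectral density set
#'
#' Collapses the G field-specific J(0) values to their inverse-variance
#' weighted mean with jackknife uncertainty and assembles the fit vector
#' (mean J(0), G values of J(omega_N), G values of J(0.87 omega_H)), ordered
#' by increasing eigenfrequency, for a total of 1 + 2G data points.
#'
#' @param jw data.frame from [map_relaxation_to_jw()] restricted to a single
#'   residue (one row per field).
#' @param config an [mf_config()] object (controls the mean-J(0) error).
#' @return Object of class `spectral_density_set` with elements `residue`,
#'   `fields_MHz`, per-field `J0`, `JwN`, `JwH087` values/errors, the raw
#'   pre-averaging vector `y_raw` (length N = 3G), `J0_mean`, `J0_mean_err`,
#'   and the fit vectors `y`, `y_err`, `omega` (length 1 + 2G).
#' @export
spectral_density_set <- function(jw, config = mf_config()) {
  stopifnot(length(unique(jw$residue)) == 1)
  jw <- jw[order(jw$field_MHz), , drop = FALSE]
  if (anyDuplicated(jw$field_MHz))
    stop("duplicate field for residue ", jw$residue[1])
  G <- nrow(jw)

  J0_mean <- weighted_mean_j0(jw$J0, jw$J0_err)
  jack <- jackknife_j0_se(jw$J0, jw$J0_err)
  if (config$j0_uncertainty == "combined") {
    prop <- sqrt(1 / sum(1 / jw$J0_err^2))
    J0_mean_err <- sqrt(jack^2 + prop^2)
  } else {
    J0_mean_err <- jack
  }
  # degenerate jackknife (identical values up to rounding): fall back to
  # the propagated error of the first field
  if (J0_mean_err <= 1e-12 * abs(J0_mean)) J0_mean_err <- jw$J0_err[1]

  omega <- c(0, jw$omega_N, jw$omega_H087)
  if (is.unsorted(omega)) stop("eigenfrequency ordering violated")

  out <- list(residue = jw$residue[1],
              fields_MHz = jw$field_MHz,
              G = G,
              J0 = jw$J0, J0_err = jw$J0_err,
              JwN = jw$JwN, JwN_err = jw$JwN_err,
              JwH087 = jw$JwH087, JwH087_err = jw$JwH087_err,
              y_raw = c(jw$J0, jw$JwN, jw$JwH087),
              J0_mean = J0_mean, J0_mean_err = J0_mean_err,
              y = c(J0_mean, jw$JwN, jw$JwH087),
              y_err = c(J0_mean_err, jw$JwN_err, jw$JwH087_err),
              omega = omega)
  class(out) <- "spectral_density_set"
  out
}

#' Split a mapped table into per-residue spectral density sets
#'
#' @param jw data.frame from [map_relaxation_to_jw()].
#' @inheritParams spectral_density_set
#' @return Named list of [spectral_density_set()] objects, one per residue.
#' @export
spectral_density_sets <- function(jw, config = mf_config()) {
  res <- split(jw, jw$residue)
  out <- lapply(res, spectral_density_set, config = config)
  names(out) <- vapply(out, function(s) as.character(s$residue), "")
  out[order(as.numeric(names(out)))]
}

#' @export
print.spectral_density_set <- function(x, ...) {
  cat(sprintf("Spectral density set: residue %s, G = %d fields (%s MHz)\n",
              x$residue, x$G, paste(x$fields_MHz, collapse = ", ")))
  cat(sprintf("  mean J(0) = %.4f +/- %.4f ns/rad; fit vector length %d\n",
              x$J0_mean * 1e9, x$J0_mean_err * 1e9, length(x$y)))
  invisible(x)
}
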