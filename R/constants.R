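#' Physical constants for amide 15N relaxation analysis
#'
#' Bundle of the physical constants entering the dipolar and chemical shift
#' anisotropy (CSA) interaction strengths of a backbone amide 15N-1H spin
#' pair.  All values are SI.  The dipolar coupling constant is
#' \deqn{d_{NH} = (\mu_0/4\pi)\,\hbar\,\gamma_H \gamma_N\, r_{NH}^{-3}}
#' (rad/s) and the CSA coefficient at a given field is
#' \eqn{c_{NH} = \Delta\sigma\,\omega_N/\sqrt{3}}.
#'
#' @param gamma_H 1H gyromagnetic ratio (rad s^-1 T^-1).
#' @param gamma_N 15N gyromagnetic ratio (rad s^-1 T^-1, negative).
#' @param r_NH N-H bond length (m); default 1.02 Angstrom.
#' @param delta_sigma 15N CSA (dimensionless; default -172 ppm).
#' @param mu0_over_4pi vacuum permeability over 4 pi (T m A^-1).
#' @param hbar reduced Planck constant (J s).
#' @return An object of class `nmr_constants`: a list of the inputs plus the
#'   derived field-independent dipolar constant `d_NH` (rad/s).
#' @export
nmr_constants <- function(gamma_H = 2.6752218744e8,
                          gamma_N = -2.7126e7,
                          r_NH = 1.02e-10,
                          delta_sigma = -172e-6,
                          mu0_over_4pi = 1e-7,
                          hbar = 1.054571817e-34) {
  stopifnot(gamma_H > 0, gamma_N < 0, r_NH > 0)
  const <- list(gamma_H = gamma_H, gamma_N = gamma_N, r_NH = r_NH,
                delta_sigma = delta_sigma, mu0_over_4pi = mu0_over_4pi,
                hbar = hbar)
  const$d_NH <- mu0_over_4pi * hbar * gamma_H * gamma_N / r_NH^3
  class(const) <- "nmr_constants"
  const
}

#' Field-dependent interaction frequencies and coefficients
#'
#' @param field_MHz 1H Larmor frequency in MHz (numeric vector).
#' @param const an [nmr_constants()] object.
#' @return List with `omega_H`, `omega_N` (signed, rad/s), their magnitudes
#'   `abs_omega_N`, the reduced-mapping frequency `omega_H087 = 0.87
#'   |omega_H|`, the CSA coefficient `c_NH` (rad/s) and the squared-coupling
#'   denominator `denom = 3 d_NH^2 + 4 c_NH^2`.
#' @export
interaction_constants <- function(field_MHz, const = nmr_constants()) {
  stopifnot(all(field_MHz > 0))
  omega_H <- 2 * pi * field_MHz * 1e6
  omega_N <- omega_H * const$gamma_N / const$gamma_H
  c_NH <- const$delta_sigma * abs(omega_N) / sqrt(3)
  list(omega_H = omega_H,
       omega_N = omega_N,
       abs_omega_N = abs(omega_N),
       omega_H087 = 0.87 * omega_H,
       c_NH = c_NH,
       d_NH = const$d_NH,
       denom = 3 * const$d_NH^2 + 4 * c_NH^2)
}
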