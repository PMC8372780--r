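#' Extended model-free parameter set
#'
#' Constructs and validates the five-parameter vector
#' \{tau_m, Sf2, Ss2, tau_f, tau_s\} of the extended model-free formalism,
#' together with the derived generalized order parameter S2 = Sf2 * Ss2 and
#' the composite correlation times
#' 1/tau_1 = 1/tau_m + 1/tau_s, 1/tau_2 = 1/tau_m + 1/tau_f,
#' 1/tau_3 = 1/tau_m + 1/tau_s + 1/tau_f (a zero internal time removes the
#' corresponding terms).
#'
#' @param tau_m overall rotational correlation time (s), > 0.
#' @param Sf2 fast-motion squared order parameter in [0, 1].
#' @param Ss2 slow-motion squared order parameter in [0, 1].
#' @param tau_f fast internal correlation time (s), >= 0.
#' @param tau_s slow internal correlation time (s), >= 0; when both internal
#'   times are nonzero, tau_f < tau_s is required.
#' @return Object of class `mf_params`.
#' @export
mf_params <- function(tau_m, Sf2 = 1, Ss2 = 1, tau_f = 0, tau_s = 0) {
  stopifnot(tau_m > 0, tau_f >= 0, tau_s >= 0)
  if (Sf2 < 0 || Sf2 > 1 || Ss2 < 0 || Ss2 > 1)
    stop("order parameters must lie in [0, 1]")
  if (tau_f > 0 && tau_s > 0 && tau_f >= tau_s)
    stop("tau_f must be smaller than tau_s when both are nonzero")
  p <- list(tau_m = tau_m, Sf2 = Sf2, Ss2 = Ss2,
            tau_f = tau_f, tau_s = tau_s,
            S2 = Sf2 * Ss2,
            tau_1 = if (tau_s > 0) 1 / (1 / tau_m + 1 / tau_s) else 0,
            tau_2 = if (tau_f > 0) 1 / (1 / tau_m + 1 / tau_f) else 0,
            tau_3 = if (tau_f > 0 && tau_s > 0)
              1 / (1 / tau_m + 1 / tau_s + 1 / tau_f) else 0)
  class(p) <- "mf_params"
  p
}

#' @export
print.mf_params <- function(x, ...) {
  cat(sprintf(
    "mf_params: tau_m=%.3f ns, Sf2=%.3f, Ss2=%.3f, tau_f=%.4f ns, tau_s=%.4f ns (S2=%.3f)\n",
    x$tau_m * 1e9, x$Sf2, x$Ss2, x$tau_f * 1e9, x$tau_s * 1e9, x$S2))
  invisible(x)
}

#' Extended model-free spectral density function
#'
#' \deqn{J(\omega) = \frac{2}{5}\Big[\frac{S_f^2 S_s^2 \tau_m}{1+\omega^2\tau_m^2}
#'  + \frac{S_f^2(1-S_s^2)\tau_1}{1+\omega^2\tau_1^2}
#'  + \frac{(1-S_f^2)S_s^2\tau_2}{1+\omega^2\tau_2^2}
#'  + \frac{(1-S_f^2)(1-S_s^2)\tau_3}{1+\omega^2\tau_3^2}\Big]}
#' A Lorentzian whose correlation time is zero contributes exactly zero
#' (the limit convention used when internal modes are removed from a model).
#'
#' @param omega angular frequency (rad/s), vectorized.
#' @param params an [mf_params()] object, or the first of five numeric
#'   arguments `tau_m, Sf2, Ss2, tau_f, tau_s` (s).
#' @param Sf2,Ss2,tau_f,tau_s see [mf_params()].
#' @return spectral density J(omega) in s/rad.
#' @export
model_free_J <- function(omega, params, Sf2 = 1, Ss2 = 1,
                         tau_f = 0, tau_s = 0) {
  if (!inherits(params, "mf_params"))
    params <- mf_params(params, Sf2, Ss2, tau_f, tau_s)
  par_ns <- c(params$tau_m, params$Sf2, params$Ss2,
              params$tau_f, params$tau_s) * c(1e9, 1, 1, 1e9, 1e9)
  cpp_model_free_J(omega * 1e-9, par_ns) * 1e-9
}

#' Nested model definitions
#'
#' The five nested models are generated from the full five-parameter
#' function by fixing parameters at their null values:
#' Model 1 fixes \{Ss2 = 1, tau_f = 0, tau_s = 0\};
#' Model 2 fixes \{Ss2 = 1, tau_s = 0\};
#' Model 3 fixes \{Sf2 = 1, tau_f = 0\};
#' Model 4 fixes \{tau_f = 0\};
#' Model 5 fixes nothing.
#'
#' @param model_id integer 1-5.
#' @param tau_m_policy `"local"` (tau_m fitted per residue; counted as a
#'   free parameter) or `"fixed"` (held at the configured value).
#' @return Object of class `model_spec` with `model_id`, `free` (ordered
#'   names of free parameters), `fixed` (named fixed values) and `k` (free
#'   parameter count).
#' @export
model_spec <- function(model_id, tau_m_policy = c("local", "fixed")) {
  tau_m_policy <- match.arg(tau_m_policy)
  stopifnot(model_id %in% 1:5)
  fixed <- switch(model_id,
    `1` = c(Ss2 = 1, tau_f = 0, tau_s = 0),
    `2` = c(Ss2 = 1, tau_s = 0),
    `3` = c(Sf2 = 1, tau_f = 0),
    `4` = c(tau_f = 0),
    `5` = stats::setNames(numeric(0), character(0)))
  all_par <- c("Sf2", "Ss2", "tau_f", "tau_s")
  free <- setdiff(all_par, names(fixed))
  if (tau_m_policy == "local") free <- c("tau_m", free)
  spec <- list(model_id = as.integer(model_id),
               tau_m_policy = tau_m_policy,
               free = free, fixed = fixed, k = length(free))
  class(spec) <- "model_spec"
  spec
}

#' Embed free parameter values into the full five-parameter vector
#'
#' @param spec a [model_spec()] object.
#' @param free_values numeric vector of length `spec$k`, ordered as
#'   `spec$free` (all times in seconds).
#' @param tau_m_fixed tau_m value (s) used when the policy is `"fixed"`.
#' @return An [mf_params()] object (invariant-checked).
#' @export
model_param_vector <- function(spec, free_values, tau_m_fixed = 17.5e-9) {
  stopifnot(inherits(spec, "model_spec"),
            length(free_values) == spec$k)
  v <- c(tau_m = NA_real_, Sf2 = 1, Ss2 = 1, tau_f = 0, tau_s = 0)
  v[names(spec$fixed)] <- spec$fixed
  v[spec$free] <- free_values
  if (spec$tau_m_policy == "fixed") v["tau_m"] <- tau_m_fixed
  mf_params(v[["tau_m"]], v[["Sf2"]], v[["Ss2"]], v[["tau_f"]], v[["tau_s"]])
}
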