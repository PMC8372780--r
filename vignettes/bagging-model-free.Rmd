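---
title: "Bootstrap-aggregated model-free analysis of 15N spin relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-aggregated model-free analysis of 15N spin relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Backbone amide ^15^N laboratory-frame relaxation experiments measure, at
each static magnetic field, three rate constants per residue: the
longitudinal rate $R_1$, the transverse rate $R_2$ and the steady-state
heteronuclear NOE.  These are linear combinations of the spectral density
function $J(\omega)$ of the N–H bond-vector orientational correlation
function, sampled at eigenfrequencies of the spin system.  The model-free
formalism parameterizes $J(\omega)$ with a small number of physically
interpretable quantities — generalized order parameters and effective
internal correlation times — without committing to a specific motional
model.  Because a *family* of nested parameterizations is fitted and one
member is selected by a penalized fitness statistic, the reported
parameters inherit *model selection error*: a different noise realization
of the same experiment can flip the selected model and shift every
reported parameter systematically.  This package implements bootstrap
aggregation (bagging) over an enumerated, block-constrained bootstrap
ensemble as a remedy: model selection is repeated inside every bootstrap
replicate and the reported estimate averages over the model distribution
rather than conditioning on a single winner.

## From rates to spectral densities

With $\sigma_{NH} = (\mathrm{NOE}-1)\,R_1\,\gamma_N/\gamma_H$ the
dipolar cross-relaxation rate, reduced spectral density mapping gives

$$J(0.87\,\omega_H) = \frac{4\,\sigma_{NH}}{5 d_{NH}^2},\qquad
J(\omega_N) = \frac{4\,(R_1 - 1.249\,\sigma_{NH})}{3 d_{NH}^2 + 4 c_{NH}^2},\qquad
J(0) = \frac{6\,(R_2 - 0.5 R_1 - 0.454\,\sigma_{NH})}{3 d_{NH}^2 + 4 c_{NH}^2},$$

where $d_{NH} = (\mu_0/4\pi)\hbar\gamma_H\gamma_N r_{NH}^{-3}$ and
$c_{NH} = \Delta\sigma\,\omega_N/\sqrt{3}$, with $r_{NH} = 1.02$ Å and
$\Delta\sigma = -172$ ppm by default (`nmr_constants()`).  Note that
$\hbar$ must appear in $d_{NH}$ for dimensional consistency — some
presentations of the mapping omit it typographically; without it the
coupling constant is wrong by thirty-four orders of magnitude.
Uncertainties propagate to first order, which is exact here because the
mapping is linear in $(R_1, R_2, \sigma_{NH})$.

At $G$ fields the $G$ values of $J(0)$ estimate the same quantity, so they
are collapsed to an inverse-variance weighted mean whose uncertainty is a
delete-one jackknife standard error.  The per-residue fit vector is
therefore $(\,\bar J(0),\; J(\omega_N)\times G,\; J(0.87\omega_H)\times
G\,)$ — nine points at $G = 4$ — ordered by increasing frequency.

Whether the fitted $\bar J(0)$ uncertainty should also include the
propagated error of the weighted mean is ambiguous; the default uses the
jackknife SE alone, and `mf_config(j0_uncertainty = "combined")` adds the
propagated error in quadrature (consistently in the original fit and in
every bootstrap replicate).

## The nested model family

The extended model-free spectral density is

$$J(\omega) = \frac{2}{5}\left[
\frac{S_f^2 S_s^2 \tau_m}{1+\omega^2\tau_m^2} +
\frac{S_f^2 (1-S_s^2) \tau_1}{1+\omega^2\tau_1^2} +
\frac{(1-S_f^2) S_s^2 \tau_2}{1+\omega^2\tau_2^2} +
\frac{(1-S_f^2)(1-S_s^2) \tau_3}{1+\omega^2\tau_3^2}\right]$$

with $\tau_1^{-1} = \tau_m^{-1}+\tau_s^{-1}$, $\tau_2^{-1} =
\tau_m^{-1}+\tau_f^{-1}$, $\tau_3^{-1} =
\tau_m^{-1}+\tau_s^{-1}+\tau_f^{-1}$ and $\tau_f < \tau_s$.  A vanishing
internal correlation time removes its Lorentzian entirely (the
$\tau \to 0$ limit), so the five nested models are obtained by fixing
parameters at null values:

| Model | free parameters           | fixed                          |
|-------|---------------------------|--------------------------------|
| 1     | $\tau_m, S_f^2$           | $S_s^2{=}1,\ \tau_f{=}\tau_s{=}0$ |
| 2     | $\tau_m, S_f^2, \tau_f$   | $S_s^2{=}1,\ \tau_s{=}0$       |
| 3     | $\tau_m, S_s^2, \tau_s$   | $S_f^2{=}1,\ \tau_f{=}0$       |
| 4     | $\tau_m, S_f^2, S_s^2, \tau_s$ | $\tau_f{=}0$              |
| 5     | all five                  | —                              |

$\tau_m$ counts as a free parameter only for residues where it is fitted
locally; for residues in disordered segments it is conventionally fixed
(default 17.5 ns, `mf_config(tau_m_fixed, fixed_tau_m_residues)`).
Overall rotational diffusion is assumed isotropic; anisotropic tensors
are out of scope.

Models 2 and 3 are the *same* functional form — one order parameter, one
internal correlation time — distinguished only by the timescale of the
internal motion.  The package fits that form once with the internal time
free over its full range and labels the result Model 2 when
$\tau < 0.15$ ns and Model 3 otherwise, so the two never compete in the
same selection.  The 0.15 ns threshold (configurable) also separates the
$\tau_f \in [0, 0.15\,\mathrm{ns}]$ and $\tau_s \in [0.15\,\mathrm{ns},
\tau_m]$ boxes in Models 4 and 5, which keeps the two timescales
identifiable and ordered; the additional constraint $\tau_s \le \tau_m$
prevents internal/overall timescale swaps.

Selection minimizes the small-sample Akaike criterion in its $\chi^2$
form, treating the measurement variances as known:

$$\mathrm{AICc} = \chi^2 + 2k + \frac{2k(k+1)}{n-k-1},
\qquad \chi^2 = \sum_j \frac{(y_j - J(\omega_j;\mu))^2}{\sigma_j^2},$$

with $n = 1 + 2G$ fitted points.  When $n \le k+1$ the model is marked
non-applicable (`NA`).  Exact ties go to the model with fewer free
parameters.

## The enumerated block bootstrap

Spectral density values of the three classes $J(0)$, $J(\omega_N)$,
$J(0.87\omega_H)$ live on different scales and must not be interchanged
by resampling; unrestricted with-replacement draws can also produce
degenerate samples (a class missing entirely, or one value dominating).
Both problems are avoided by resampling *within* classes under the
constraint that no value appears more than twice.  A within-block
arrangement is then a multiset of size $G$ over the $G$ field-specific
values with per-value multiplicity $\le 2$; there are 19 such
arrangements at $G = 4$ and 7 at $G = 3$, and the full ensemble takes one
arrangement independently per class: $B = 19^3 = 6859$ (or $7^3 = 343$)
samples, enumerated exhaustively rather than drawn at random — the
ensemble needs no seed.  Sample $i$ maps to its arrangement triple
$(l, m, n)$ by mixed-radix decomposition of $i-1$ with the most
significant digit assigned to the $J(0)$ block, so sample 1 is always the
identity sample (the original data).

Arrangements are ordered canonically: identity first, then by the number
of duplicated fields, then lexicographically by the duplicated-field set
and the omitted-field set.  A bootstrap sample duplicates and omits
*data points*, i.e. (value, frequency) pairs: the counter vector $Y_i^*$
(length $N = 3G$, concatenated over the blocks in class order) enters the
objective as per-point multiplicities, which is algebraically identical
to fitting the duplicated pairs.  The $J(0)$ block of every sample is
recollapsed to the weighted mean and jackknife SE of the resampled
multiset, duplicates entering as distinct draws, exactly as for the
original data.

## Bagging and the plug-in smoothed uncertainty

Three uncertainty procedures share this machinery (`run_pipeline()`
modes):

* **mc** — conventional analysis: the model selected on the original data
  is refitted to Monte Carlo perturbations of the fit vector (default
  500), giving $\hat\sigma_k$;
* **boot** — same selection, but the fixed model is refitted to every
  enumerated bootstrap sample, and $\hat\sigma^*_k$ is the sample SD over
  the $B$ replicates;
* **bag** — the *full selection* is rerun inside every bootstrap sample;
  the winning model's parameter vector is recorded with null conventions
  (order parameters 1, internal times 0, for parameters the winner
  fixes), and the smoothed estimate $\tilde\mu_k$ is the plain mean over
  all $B$ replicates.  Model fractions report how often each model won.

The smoothed standard deviation uses Efron's plug-in principle: with
$\widehat{\mathrm{cov}}_{jk} = B^{-1}\sum_i (Y^*_{ij}-\bar
Y^*_j)(\tilde\mu^*_{ik}-\tilde\mu_k)$,

$$\tilde\sigma_k = \Big[\textstyle\sum_{j=1}^{N}
\widehat{\mathrm{cov}}_{jk}^2\Big]^{1/2}.$$

The typeset source of this formula can be read with or without a $1/N$
factor inside the root; the package follows the smoothed-bootstrap
estimator as originally defined (no $1/N$), under which the defining
inequality $\tilde\sigma_k \le \hat\sigma^u_k$ — with $\hat\sigma^u_k$
the naive sample SD over the mixed-model replicates — holds on every
synthetic residue in the test suite.  The $1/N$-scaled variant remains
available via `mf_config(smoothed_sd_scale_by_N = TRUE)` for comparison.
The derived order parameter $S^2 = S_f^2 S_s^2$ is bagged as the mean of
the per-sample products (the product of the bagged factors is reported
separately as `S2_product`).

## Numerical choices

* **Units.**  All public R interfaces are SI (seconds, rad/s, s/rad).
  Internally the compiled fitting core works in ns and rad/ns so every
  optimized parameter is within a few orders of magnitude of one; output
  tables print times in ns and spectral densities in ns/rad.
* **Optimizer.**  Bounded Nelder–Mead (projection onto the box) on the
  free parameters, convergence at $10^{-10}$ relative spread in $\chi^2$,
  at most 500 iterations per start.  The original-data fit multi-starts
  from a grid ($S^2 \in \{0.5, 0.9\}$, internal times
  $\{10, 50, 500\}$ ps); a locally fitted $\tau_m$ is initialized from a
  coarse 1-D scan exploiting that Model 1 is linear in $S_f^2$ (closed
  form weighted LS per grid point).  Ensemble refits warm-start from the
  original-data optima.
* **Nesting by construction.**  Each richer model additionally starts
  from the embedded optimum of the model it nests (Model 1 →
  single-timescale → Model 4 → Model 5), so the $\chi^2$ ordering of
  nested models holds to optimizer tolerance on every input.
* **Degenerate jackknife.**  When all resampled $J(0)$ values coincide
  (always at zero noise) the jackknife SE collapses to rounding noise;
  below $10^{-12}$ relative it falls back to the propagated per-field
  error.
* **Dropped replicates.**  Bootstrap samples where no model converges are
  excluded from the smoothed means, the covariances and the model
  fractions, with $B$ adjusted consistently and a warning.

## The synthetic-data generator

`gcn4_like_scenario()` emulates a partially disordered coiled-coil
domain measured at 600/700/800/900 MHz with $\tau_m \approx 17.5$ ns: an
ordered block ($S^2 \approx 0.9$, at most one fast internal timescale), a
disordered block (two order parameters, $\tau_s \approx 0.8$ ns,
$\tau_m$ fixed), and boundary residues with both internal timescales
active where candidate models are nearly tied.  Rates are synthesized
through the exact algebraic inverse of the reduced mapping, so the
mapping stage is testable in isolation (round trip to $10^{-10}$); this
deliberately embeds the reduced-mapping approximation
$J(\omega_H\pm\omega_N) \approx J(0.87\omega_H)$ rather than full
dipolar/CSA rate expressions.  Gaussian noise is applied to the *rates*
(2% of $R_1$ and $R_2$, 0.02 absolute on the NOE by default), mirroring
the experimental error path, and the error columns carry the generating
standard deviations.

Two features of real data are *not* emulated: chemical-exchange
contributions to $R_2$ (assumed removed beforehand) and anisotropic
overall diffusion.  A green end-to-end test therefore establishes
correctness of the statistical machinery under the stated error model,
not the validity of those physical assumptions for any particular
protein.

One consequence of the rate-level noise path is worth stating plainly:
the mapped $J(0)$, $J(\omega_N)$ and $J(0.87\omega_H)$ errors at one
field share the same $R_1$ and NOE noise and are therefore correlated,
while the fitting and all three uncertainty procedures treat the fit
vector as independent Gaussians.  In the test suite this inflates the
true seed-to-seed scatter of the bagged $\tilde S^2$ by roughly 40%
relative to every resampling-based uncertainty, so nominal $3\tilde\sigma$
coverage lands near 85% rather than the nominal level; with noise
injected directly and independently on the spectral density values the
coverage is nominal.  This is a property of the method's independence
assumption, not of the bagging machinery.

## Limitations

* Isotropic overall diffusion only; no global diffusion-tensor
  optimization (local $\tau_m$ per ordered residue instead).
* No chemical-exchange decomposition of $R_2$; no F-test or BIC
  selection; no Bayesian or AIC-weight model averaging.
* The Model 2/3 split is a fixed threshold, not a clustering of the
  bootstrap distribution of internal times.
* Smoothed uncertainties inherit the independence assumption discussed
  above and should be read as lower bounds when rate-level error
  correlation is plausible.
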