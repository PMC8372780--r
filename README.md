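# bagmf — bootstrap-aggregated model-free analysis of ¹⁵N spin relaxation

`bagmf` is an R package for analyzing backbone amide ¹⁵N NMR relaxation
data (R₁, R₂, steady-state NOE) measured at several static magnetic
fields.  It is aimed at NMR spectroscopists studying protein backbone
dynamics who want parameter estimates that are robust to *model selection
error* — the fact that random noise in the data can flip which member of
the nested model-free family is "optimal", systematically shifting every
reported parameter.

The pipeline:

1. **Reduced spectral density mapping.**  Per residue and field,
   (R₁, R₂, NOE) → J(0), J(ω_N), J(0.87 ω_H) with first-order error
   propagation; the G values of J(0) are collapsed to an inverse-variance
   weighted mean with a delete-one jackknife uncertainty, giving a fit
   vector of 1 + 2G points (nine at G = 4).
2. **Model-free fitting and AICc selection.**  The extended model-free
   spectral density
   J(ω) = (2/5)[S_f²S_s²τ_m/(1+ω²τ_m²) + S_f²(1−S_s²)τ₁/(1+ω²τ₁²) +
   (1−S_f²)S_s²τ₂/(1+ω²τ₂²) + (1−S_f²)(1−S_s²)τ₃/(1+ω²τ₃²)]
   is fitted as five nested models (weighted least squares, bounded
   multi-start optimization); the winner minimizes
   AICc = χ² + 2k + 2k(k+1)/(n−k−1).  Models 2 and 3 share one
   single-timescale form, labelled by a 0.15 ns threshold on the fitted
   internal correlation time.
3. **Enumerated block bootstrap.**  Resampling within the three
   spectral-density classes with per-value multiplicity ≤ 2 gives 19
   arrangements per block at G = 4 and an exhaustive ensemble of
   B = 19³ = 6859 samples (7³ = 343 at G = 3); sample 1 is always the
   original data.
4. **Bagging.**  Model selection is rerun inside every bootstrap sample;
   the smoothed estimate μ̃_k is the mean over replicates (with null
   conventions for parameters a winning model fixes), and its uncertainty
   is Efron's plug-in smoothed standard deviation
   σ̃_k = [Σⱼ cov̂²ⱼₖ]^½ built from the covariances between the resampling
   counter vectors Y* and the replicate parameters, which satisfies
   σ̃_k ≤ σ̂ᵘ_k (the naive replicate SD).  Conventional Monte Carlo and
   fixed-model bootstrap uncertainties are available for comparison.

A synthetic-data module generates multi-field data sets with known
ground-truth dynamics (a GCN4-bZip-like partially disordered scenario is
built in), so the whole pipeline is testable without downloads.

## Worked example

Simulate a disordered two-timescale residue (true S_f² = 0.75,
S_s² = 0.30, τ_s = 0.84 ns, τ_m fixed at 17.5 ns, 2% rate noise) at
600/700/800/900 MHz, select a model, and bag it:

```r
library(bagmf)

sc  <- gcn4_like_scenario(seed = 42)
ds  <- generate_dataset(sc)
cfg <- mf_config(fixed_tau_m_residues = 16:30)

jw  <- map_relaxation_to_jw(ds$data, cfg$constants)
sds <- spectral_density_sets(jw, cfg)[["16"]]
sel <- select_model(sds, cfg)
bag <- bagged_fit(sds, cfg, selection = sel)
print(sel); print(bag)
```

```
Residue 16: best model 4 (AICc 11.9)
 model         chi2  k        aicc  best
     1 10821.851263  1 10824.42269 FALSE
     2           NA NA          NA FALSE
     3  2086.562047  2  2092.56205 FALSE
     4     1.050523  3    11.85052  TRUE
     5     1.050523  4    19.05052 FALSE
Bagged model-free result: residue 16, B = 6859 (6859 used)
  model fractions: 1: 0.000, 2: 0.000, 3: 0.000, 4: 1.000, 5: 0.000
            tau_m_ns      Sf2      Ss2 tau_f_ns tau_s_ns       S2
smoothed        17.5 0.753400 0.298000        0 0.830700 0.224500
smoothed_sd      0.0 0.002006 0.001992        0 0.003258 0.001844
naive_sd         0.0 0.002191 0.002172        0 0.003563 0.002009
```

Reading this: the single-timescale fit was labelled Model 3 (its internal
time exceeded 0.15 ns), so the Model 2 column is not applicable (`NA`);
Model 4 wins the AICc comparison decisively, and all 6859 bootstrap
samples agree — a point-mass model fraction, so bagging reproduces the
conventional analysis and the smoothed S² = 0.2245 ± 0.0018 brackets the
generating value 0.225.  For genuinely ambiguous residues the fractions
split (e.g. between Models 4 and 5) and the smoothed parameters average
over the competing models; that is where bagging earns its keep.

## Command line

```sh
Rscript inst/cli/bagmf.R simulate --scenario gcn4like --seed 1 -o out/
Rscript inst/cli/bagmf.R mapjw -i out/rates.csv -o out/
Rscript inst/cli/bagmf.R fit --mode bag -i out/rates.csv -o out/ --config cfg.json
Rscript inst/cli/bagmf.R report -i out/params_bag.csv
```

Input CSV/TSV header (one row per residue × field):
`residue, field_MHz, R1, R1_err, R2, R2_err, NOE, NOE_err`.
Outputs: `jw.csv` (spectral densities, ns/rad), `selection.csv`
(per-model AICc table, `NA` marks non-applicable models),
`params_{mc|boot|bag}.csv` (times in ns), optional `ensemble.csv`
audit dump, `run.log`.

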