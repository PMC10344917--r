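# ternarySAR

Quantitative analysis of PROTAC-induced ternary-complex formation and
targeted protein degradation, for biophysicists and medicinal chemists
running degrader campaigns.

A PROTAC (P) links an E3-ligase ligand to a target-protein warhead so that
degradation proceeds through a ternary complex L·P·T. The package connects
the biophysics of that complex to cellular degradation readouts:

* **Three-body equilibrium.** Binary affinities `K_LP`, `K_TP`, ternary
  affinity `K_LPT`, cooperativity `α = K_LP / K_LPT`. The exact equilibrium
  is solved numerically for arbitrary totals (`solve_ternary`,
  `hook_curve` — including the hook effect at excess PROTAC), and the
  surface-assay limit has the closed form

  ```
  [LPT]max / [L]t ≅ α / (α + β),   β = (√(K_LP/K_TP) + 1)² / 25
  ```

  (`max_ternary_fraction`, `beta_factor`).
* **Ubiquitination initial rate.** Rapid-equilibrium rate law
  `v/Vmax = α / (α + 2(K_LP + [P]t)/D − 1)` with its linear regime
  `[P]t/(2 K_LPT)` and saturation regime `α[T]t/(2[P]t)`
  (`ubiquitination_rate`, `normalized_rate`, `linear_rate`,
  `saturation_rate`).
* **SPR reduction.** Closed-form 1:1 Langmuir simulation and fitting
  (multi- and single-cycle without regeneration), steady-state affinity,
  complex half-life `t½ = ln2/koff` (`simulate_sensorgram`,
  `fit_langmuir`, `fit_steady_state`, `reference_subtract`).
* **Degradation metrics.** POC normalisation, variable-slope 4PL with a
  censoring-aware DC50/Dmax, unit-spacing trapezoid AUC, one-phase-decay
  half-life and initial degradation rate `100·0.693/t½`
  (`normalize_poc`, `fit_dose_response`, `auc_trapezoid`,
  `fit_time_course`).
* **Correlation SAR.** Pearson/Spearman with explicit linear/log10 scale
  flags and two-tailed significance over per-compound tables
  (`sar_cor`, `build_sar_table`, packaged fixtures via `compound_table`).
* **Ternary-model geometry.** Clash counting and assembly filtering,
  COG/principal-axis pose pruning, Kabsch RMSD, strain/RMSD model
  selection, Shrake–Rupley SASA and buried surface area
  (`count_clashes`, `assembly_filter`, `warhead_similarity`,
  `kabsch_rmsd`, `model_selection`, `sasa`, `buried_surface_area`,
  `read_ternary_pdb`).
* **Synthetic data.** Seeded generators for sensorgrams, dose-response /
  time-course tables and toy complexes with analytically known burial
  (`generate_spr_dataset`, `generate_degradation_dataset`,
  `generate_toy_complex`).

See the vignette `vignettes/ternary-complex-sar.Rmd` for the model,
assumptions, numerical choices and limitations.

## Worked example

```r
library(ternarySAR)

# cooperativity drives the degradation rate for the BRD4-BD2 panel
bd2 <- compound_table("brd4_bd2")
sar_cor(bd2$alpha, bd2$initial_rate, x_scale = "log10")
#> r = 0.99 (n = 6, two-tailed p = 0.000134) [x: log10, y: linear]
sar_cor(bd2$k_lpt, bd2$initial_rate)
#> r = -0.90 (n = 6, two-tailed p = 0.0133) [x: linear, y: linear]

# the MZ1/BD2 system: high cooperativity, near-complete surface saturation
p <- eq_params(k_lp = 20.5, k_tp = 20.5, k_lpt = 1.5)
p
#> Ternary binding parameters (nM)
#>   K_LP  = 20.5
#>   K_TP  = 20.5
#>   K_LPT = 1.5
#>   alpha = 13.67   beta = 0.16 (target excess 25 x K_TP)
max_ternary_fraction(p$alpha, p$beta)
#> [1] 0.9884282

# exact titration of the same system in the surface limit: the hook-curve
# peak matches the closed form
hc <- hook_curve(0.01, 25 * 20.5, 10^seq(-2, 5, length.out = 80), p)
hc$p_total[which.max(hc$LPT)]   # optimum ~269 nM
max(hc$LPT) / 0.01              # peak fraction 0.988

# long-lived ternary complex: koff 0.00533 1/s gives t1/2 ~ 130 s
d <- generate_spr_dataset(kon = 1e-3, koff = 0.00533, noise_sd = 1, seed = 1)
fit_langmuir(d$sensorgram)
#> 1:1 Langmuir fit
#>   kon  = 0.0009967 1/(nM s)
#>   koff = 0.005327 1/s
#>   KD   = 5.345 nM
#>   Rmax = 100 RU
#>   t1/2 = 130.1 s
#>   RMSE = 1.03 RU
```

The correlations read: across the six BD2-engaging PROTACs, initial
degradation rate rises with log-cooperativity (r = 0.99) and falls with
ternary dissociation constant (r = −0.90) — cooperative, high-affinity
ternary complexes degrade fastest. The equilibrium example shows why: at
α ≈ 13.7 with matched binary affinities, essentially all surface ligase
(99%) can be drawn into the ternary complex at the titration optimum.

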