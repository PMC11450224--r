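# pollenvar

Desk-scale machinery for reconstructing the **strength of tree pollen
seasons** from daily station counts, for aerobiologists and atmospheric
modellers who want to study seasonal source inversion without a
supercomputer. The package implements, end to end and on synthetic data:

- the **double-threshold heat-sum source term** for alder, birch and olive
  pollen: ready-to-fly pollen develops at rate
  `S φ ξ N_tot (T − T_co)/ΔH · h(T − T_co) · p_fs(H/H_fs) · p_fe(R)` once the
  accumulated heat sum `H` crosses the mapped flowering-start threshold, and
  is released as `p_rdy (1 − e^{−Δt/τ}) f_wind f_thr(q) f_thr(P)` under
  favourable wind, humidity and precipitation;
- a **linear, adjoint-equipped 2-D transport operator** (upwind advection,
  explicit diffusion, Stokes-settling deposition in a well-mixed boundary
  layer) whose discrete adjoint is exact to round-off;
- an **extended 4D-VAR** that estimates the per-cell, per-year unitless
  correction `ξ = exp(ζ)` to the climatological seasonal pollen production
  `N_tot` by minimising
  `J(ζ) = ½(y − Ox)ᵀΦ⁻¹(y − Ox) + ½ζᵀB⁻¹ζ` over a whole flowering season,
  with a Gaussian background correlation (`ρ ≈ 250 km`) and
  **truncated-iteration regularization**: iterations stop where the slope of
  a hyperbola fitted to the (background-deviation, observation-deviation)
  L-curve falls to 5% of its initial value (a 20-fold reduction);
- station-side machinery: two-day averaging, the completeness (≥ 30 valid
  days), non-zero (≥ 5) and correlation (> 0.3) quality filters, the
  semi-random 80/20 assimilation/evaluation split with mandatory isolated
  stations, and the seasonal pollen integral (SPIn, pollen·day·m⁻³);
- the **post-assimilation bias recalibration**: whole-period station ratios
  `r_s = SPIn_mdl / SPIn_obs`, interpolated over the domain with a
  linear-kernel radial basis function (smoothing 10) and divided out of the
  emission map, validated by the co-located ratio `r_st = Σ obs / Σ mdl`;
- synthetic generators (meteorology, landscapes, station networks, truth
  correction fields, noisy observations) so the whole pipeline runs as an
  observing-system simulation experiment with known truth.

## Worked example

```r
library(pollenvar)

g  <- grid_spec(0, 12, 45, 55, 12, 10)          # 1-degree cells
sc <- build_scenario(grid = g, taxon = "birch", n_stations = 30,
                     noise_sigma = 0.3, seed = 21)
da <- run_da(sc, cov = cov_config(background_scale = 10))
da$result
#> assimilation_result: stop at iteration 1 of 40, RMSE ratio assim 0.719, eval 0.784

cor(as.vector(da$result$xi), as.vector(sc$xi_true))  # recovered vs true field
#> [1] 0.741
```

The scenario hides a "true" correction field `xi_true` in `[0.5, 2]`, sells
the model noisy daily counts at 30 stations, and `run_da()` recovers the
field: the evaluation-station RMSE at the stopping iteration is 0.784 of the
unconstrained run's RMSE (values below 1 mean the assimilation generalises
to stations it never saw), and the recovered map correlates with the hidden
truth at r = 0.74. `run_calibration()` and `run_final()` then remove the
residual amplitude bias; `compute_diagnostics()` builds the standard
validation tables (SPIn correlations, quantile agreement, `r_st` ratios,
two-day correlations, footprint maps).

Shipped parameter sets (`taxon_params("alder")`, `"birch"`, `"olive"`) carry
the published source-term constants: cut-off temperatures 4 / 3.5 / 0 °C,
standard seasonal release 10⁸ / 10⁸ / 3×10⁸ grains m⁻² yr⁻¹, release time
constant 1 h, humidity thresholds 50–80/90/80 %, precipitation threshold
0.5 mm h⁻¹, grain diameters 22 / 22 / 28 μm at 800 kg m⁻³, and the per-taxon
assimilation windows (alder 5 Jan–31 May, birch 10 Mar–1 Jul, olive
1 Apr–31 Jul).

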