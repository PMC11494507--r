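# mtrkit

Mechanistic analysis of general-acid catalysis by alkyl-transferase
ribozymes such as MTR1, connecting two experimental and computational
threads of evidence for a two-step mechanism — proton transfer from a
protonated cytosine general acid (TS1) followed by rate-controlling alkyl
transfer to an adenine nucleophile (TS2):

* **Kinetics.** Biphasic progress curves
  `f(t) = A [p (1 − e^(−k_fast t)) + (1 − p)(1 − e^(−k_slow t))]`, where
  the fast phase reports alkyl transfer and the slow phase the refolding of
  an initially inactive conformer; activity–pH profiles
  `k_obs = k_int / (1 + 10^(pH − pKa))` for the apparent pKa of the general
  acid (with an optional bell-shaped two-pKa variant); Brønsted analysis
  `β_nuc = d log10 k / d pKa_nuc` of nucleophile reactivity.
* **Free-energy landscapes.** Gridded 2D surfaces G(ξ_PT, ξ_AT) over the
  proton-transfer and alkyl-transfer difference-of-distances coordinates
  (Å, kcal/mol), C¹ bicubic interpolation, a string-method minimum
  free-energy path solver (32 images, equal-arc reparameterization)
  validated against an exhaustive grid-minimax oracle, Eyring
  transition-state-theory conversions `k = (k_B T/h) e^(−ΔG‡/RT)`, a
  from-scratch MBAR solver (self-consistent iteration with Newton polish,
  asymptotic covariances, overlap diagnostics) for umbrella-sampling PMF
  reconstruction and 25-λ-window alchemical pKa shifts
  `ΔpKa = ΔΔG/(RT ln 10)`.

Every stage has a synthetic-data generator with known ground truth
(progress curves, pH-rate replicates, MTR1-like free-energy surfaces,
overdamped-Langevin umbrella trajectories, Gaussian alchemical windows), so
parameter recovery is testable end to end. The package is aimed at RNA
enzymologists and simulators who want a desk-scale, fully reproducible
reconstruction of this style of analysis.

## Worked example

Simulate a progress curve at the unmodified ribozyme's measured rate
(0.60 min⁻¹ at pH 6.0), refit it, and fit a seeded pH-rate dataset:

```r
library(mtrkit)

times <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 7, 10, 15, 25, 40, 60, 90, 120,
           160, 200, 250, 300)
tc  <- gen_time_course(times, k_fast = 0.60, k_slow = 0.01, frac_fast = 0.8,
                       noise_sd = 0.02, seed = 1)
fit <- fit_double_exponential(tc)
fit
#> <kinetic_fit: double exponential> converged
#>   k_fast = 0.5954 /min (se 0.025), k_slow = 0.006466 /min, frac_fast = 0.777
#>   plateau = 1.045, residual rms = 0.0165 (n = 20)

ds <- gen_ph_rate_data(k_int = 0.839, pka_acid = 6.4, cv = 0.1,
                       n_reps = 3, seed = 1)
fit_ph_profile(ds, "single_pka")
#> <ph_fit: single_pka>
#>   k_int = 0.8319 /min, pKa(acid) = 6.417 (se 0.026)
```

The fast phase recovers the generating 0.60 min⁻¹ within its standard
error, and the apparent pKa comes back at 6.42 ± 0.03 against a generating
value of 6.4. `tidy()`/`glance()` return the same results as tibbles, and
`autoplot()` draws data with the fitted curve.

Build the MTR1-like free-energy surface calibrated to the 16.3 kcal/mol
rate-controlling barrier, locate the minimum free-energy path, and extract
the stationary states:

```r
surface <- mtr1_surface(barrier = 16.3)
basins  <- attr(surface, "basins")
path    <- string_mfep(surface, basins$R, basins$P, until_converged = TRUE,
                       waypoints = rbind(basins$I))
profile_along_path(surface, path)$states
#> # A tibble: 5 x 5
#>   label   arc   xi_pt  xi_at      G
#> 1 R     0     -1.44   -2.41   0
#> 2 TS1   0.210 -0.0341 -2.05  11.6
#> 3 I     0.391  1.18   -1.75   3.61
#> 4 TS2   0.609  1.29   -0.242 16.3
#> 5 P     1      1.46    2.47  -0.233
```

The rate-controlling saddle TS2 sits at ξ_AT ≈ −0.24 Å — an "early"
transition state where nucleophilic attack is less advanced than
leaving-group departure. Converting barriers to rates and estimating the
alchemical pKa shift:

```r
ctx <- thermo_ctx(298.15)
eyring_rate(16.3, ctx)                      # 7.0 /s intrinsic rate
relative_rate_from_barriers(16.3, 15.7, ctx) # 2.75-fold for C10(n1c,c5n)

est <- alchemical_ddg(gen_alchemical_samples(ddg_true = 2.86,
                                             n_windows = 25, seed = 1))
delta_pka_from_ddg(est$ddg, ctx)            # 2.13 (true shift 2.1)
ribozyme_pka(4.2, delta_pka_from_ddg(est$ddg, ctx))  # 6.33 (calc pKa 6.3)

bronsted_beta(data.frame(pka_nuc = c(3.7, 5.3), rate = c(1.0, 6.1)))$beta_nuc
#> 0.491   — beta_nuc ~ 0.5: substantial C-N bond formation at TS2
```

`run_pipeline(mtr_config(seed = 1, outdir = "out"))` chains all stages —
simulate, refit, landscape, alchemical — into measured-rate and
thermodynamic summary tables with checksummed CSV/JSON artifacts, and
`reproduce_published_tables()` re-derives every derivable cell of the published
summary tables (relative rates, pKa sums, TST rate ratios) from their
primitive inputs and diffs them against the printed values.

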