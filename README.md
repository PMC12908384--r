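# nkbind

Quantifying the **evolutionary double bind** between radiotherapy (RT)
and natural-killer (NK) cell therapy in mixed cultures of
radiation-sensitive (S) and radiation-resistant (R) prostate-cancer
cells. Resistance to irradiation comes with up-regulated NK stress
ligands, so NK cells preferentially kill the cells that escape RT —
adapting to the first therapy increases vulnerability to the second.
`nkbind` is for modellers and experimentalists who want to estimate
that preference from co-culture growth curves and reason about what it
buys in combination therapy.

## The model

Abundances in units of 10^5 cells, time in hours. S and R compete in a
Lotka–Volterra system; NK cells (N) grow logistically with no tumour
feedback and kill each tumour type at its own rate:

    dS/dt = r_S S (1 - (S + a_SR R)/K_S) - l_SN S N
    dR/dt = r_R R (1 - (R + a_RS S)/K_R) - l_RN R N
    dN/dt = r_N N (1 - N/K_N)

The double bind is the sign of `l_RN - l_SN`: positive means NK cells
hit resistant cells harder. The package provides:

* `simulate_lv()` — the forward model (deSolve, lsoda, rtol 1e-8);
* `generate_dataset()` — a synthetic co-culture generator matching the
  assay design (7 seeding fractions, 12 replicates, 6-h imaging over
  150 h, 2000 cells/well, 5:1 NK:target) with mean-one lognormal
  observation noise;
* `staged_fit()` — bounded least-squares inference per replicate
  (minpack.lm), untreated arm first, treated arms with carrying
  capacities fixed at the untreated means;
* `analyze_summary()` — double-bind score, cost of resistance
  (`r_S - r_R`) and competition-regime classification;
* `sweep_delta()` / `sweep_B()` — treatment sweeps of a reduced model
  with an explicit RT dose effect (delta) and double-bind parameter
  (B = fraction of NK kill aimed at resistant cells);
* `run_pipeline()` and a thin CLI (`inst/scripts/nkbind`) driving all
  stages from JSON configs.

## Worked example

Generate a noisy 3-replicate co-culture from the packaged reference
estimates, re-fit it, and test for the double bind:

```r
library(nkbind)

truth <- reference_params()          # packaged per-condition estimates
d     <- experiment_design(n_replicates = 3, conditions = c("UT", "NK"))
ds    <- generate_dataset(truth, d, noise_model(cv = 0.10, seed = 42))
res   <- staged_fit(ds, fit_config(n_multistart = 2, seed = 42), d)
report <- analyze_summary(summarize_fits(res), res)
print(report)
```

    Double-bind analysis (score = lambda_RN - lambda_SN, /unit N/h)
     condition double_bind_score score_sem cost_of_resistance interaction_class double_bind
            UT                NA        NA          -0.004414       competition       FALSE
            NK           0.02388  0.001133          -0.009948       competition        TRUE

The NK arm recovers a positive score (truth: 0.0558 − 0.0308 = 0.025):
NK cells kill resistant cells about twice as fast as sensitive ones, a
double bind. The cost of resistance is *negative* — resistant cells
grow faster — so the bind does not rely on a classical fitness cost;
both arms classify as competition, with suppression of S by R much
stronger than the reverse.

The reduced model shows why the preference matters. Sweeping the
double-bind parameter B under combined RT+NK (lambda = 0.05, K = 1e5):

```r
sweep_B(seq(0, 1, 0.25))
```

      sweep_value  final_S  final_R resistant_fraction
    1        0.00 5.80e-07 9.99e+04           1.00e+00
    2        0.25 6.48e-03 4.86e+04           1.00e+00
    3        0.50 9.62e+00 6.24e+02           9.85e-01
    4        0.75 4.33e+03 9.33e-01           2.16e-04
    5        1.00 9.64e+04 6.26e-06           6.49e-11

A weak bind (B near 0) wastes the second therapy on cells RT already
controls and resistance takes over; a strong bind (B near 1) suppresses
the resistant population while RT holds the sensitive one. See
`vignette("double-bind-dynamics")` for the model assumptions, fitting
staging, numerical safeguards and limitations.

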