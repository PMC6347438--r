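# rbcdosim

Labeling kinetics and MIRD internal dosimetry for radiolabeled-erythrocyte
blood-pool agents.

Red blood cells labeled with a positron-emitting glucose analog (FDG enters
erythrocytes through the GLUT1 transporter and stays largely trapped) make a
PET blood-pool agent: the activity remains in the vascular compartment, so
vessels and cardiac chambers are imaged rather than tissue uptake. Bringing
such an agent toward clinical use requires a chain of desk calculations that
this package implements as tested, reusable code:

1. **Labeling mass balance and kinetics** — decay-corrected percent
   incorporation and compartment (wash) fractions from dose-calibrator
   measurement series; saturating uptake fits
   `F(t) = f_inf (1 - exp(-k t))`; linear leakage fits with prediction;
   batch yield prediction `A0 · f · 2^(-t_prep/T1/2)`.
2. **Blood-pool biodistribution** — under the well-mixed assumption each
   organ's fraction of the injected dose equals its fractional blood volume
   (packaged ICRP Publication 89 table), giving time-integrated activity
   coefficients `ã = f · T1/2 / ln 2` per source region; an excretion
   scenario routes a free-tracer sub-pool through a dynamic voiding bladder
   (first-order entry, periodic complete voiding, closed-form integral).
3. **MIRD dose engine** — `D(target) = Σ_sources ã(source) · S(target←source)`
   over a user-supplied (or synthetic) S-value matrix; hollow-organ wall
   correction replacing the luminal electron surface term
   `½ ã Δe/m_contents` with wall self-absorption `ã Δe/m_wall`; ICRP-60
   effective dose `E = Σ w_T H_T`; 21 CFR 361.1 single/annual dose limits
   and the maximum-administrations calculation.
4. **Synthetic data** — generators for labeling runs, leakage series,
   blood-volume tables and S-value matrices with known ground truth, so the
   whole chain is testable with no external downloads.

S-values are input, never computed: phantom tables belong to phantom
software. The packaged reference organ-dose table (adult male, stylised
phantom, two scenarios) is a fixture consumed by the effective-dose, limit
and comparison steps.

## Worked example

```r
library(rbcdosim)
f18 <- get_nuclide("F-18")

run <- read_labeling_run(system.file("extdata", "demo_labeling_run.csv",
                                     package = "rbcdosim"))
percent_incorporation(run)
#> [1] 0.5841584

leak <- fit_leakage(c(46, 76, 106), c(10.5, 19.4, 23.7))
predict_leakage_at(leak, 60)
#> [1] 14.34667

predict_yield(740, 0.582, prep_time_min = 65, nuclide = f18)
#> [1] 285.6937

lim <- admin_limits(reference_dose_vector("no_leakage"),
                    effective = 3.90e-2, activity_per_admin_mbq = 370)
lim$limiting_organ;  lim$max_annual_admins
#> [1] "heart_wall"
#> [1] 5

total_effective_dose(3.90e-2, c(185, 370))
#> [1]  7.2 14.4
```

Reading: a 740 MBq labeling batch releases ≈286 MBq of cell-bound activity
after a 65-minute preparation; about 14% of the intracellular tracer leaks
back to plasma within the first hour; at 370 MBq per administration the
heart wall is the dose-limiting organ under the research-use annual limit
(150 mSv / 28.8 mSv ≈ 5 administrations per year), and a planned 185–370
MBq injection delivers 7.2–14.4 mSv effective dose.

The `analysis/` directory holds the four numbered drivers that walk the
whole chain (simulation → labeling kinetics → biodistribution and dose
engine → limits and comparison), writing their tables under `results/`.

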