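# neocreat

Dynamic serum creatinine modelling for extremely low birth weight (ELBW,
≤ 1000 g) neonates, and quantification of the transient creatinine rise
caused by a 3-day ibuprofen course at different gestational and postnatal
ages.

## Who this is for

Neonatal clinical pharmacologists and pharmacometricians who need a
quantitative baseline for interpreting serum creatinine in extreme preterms:
what trajectory is *expected* from renal maturation alone, and how much of a
creatinine rise a nephrotoxic exposure such as ibuprofen (given for patent
ductus arteriosus) should add on top, as a function of gestational age (GA)
and postnatal age.

## The model

Serum creatinine concentration C (mg/dl) follows a one-compartment turnover
model with constant endogenous input R (mg/day) and a first-order
elimination rate that matures with postnatal age t (days):

    dC/dt = R / Vd_dl − ket(t) · C,        ket(t) = CL_adj(t) / Vd

    CL(t) = CL_BL + emax · t^H / (t50^H + t^H)

with `CL_BL = 0.075 L/day × (1 + 2.55) = 0.26625 L/day` and
`Vd = 0.7 L/kg × weight`. While an ibuprofen course is active, clearance is
reduced by a constant **absolute** amount, 0.0094 ml/min = 0.013536 L/day
(`CL_adj = CL − 0.013536`), the same at every age — so the *proportional*
effect falls from about −5% at birth to about −2% by week 5 as clearance
matures. The free parameters (per-GA `emax` and `R`, maturation half-time
`t50` and steepness `H` with log-linear GA covariates) are calibrated to
reference trajectory tables for four typical neonates (GA 24/27/29/32
weeks; 621/779/840/889 g). See the methods vignette
(`vignettes/creatinine-maturation-model.Rmd`) for the calibration design,
including how a printed-consistency constraint resolves the
maturation-speed non-identifiability of the anchor set.

## Worked example

```r
library(neocreat)

fit <- default_calibration()      # multi-start fit to the packaged anchors
fit
#> Creatinine model calibration
#>   18 starts, converged: TRUE
#>   objective (SSR): 6.391e-05 mg/dl^2; RMS residual 0.00179 mg/dl
#>   shape at GA 27: t50 = 12.98 d, hill = 1.389; GA slopes -0.1148, 0.0128 /wk
#>  ga_weeks      emax production_rate       t50     hill
#>        24 0.7996157        2.909500 18.313203 1.336869
#>        27 0.7786686        2.912232 12.978836 1.389061
#>        29 0.7534742        2.901717 10.316919 1.424984
#>        32 0.7148177        2.876291  7.311752 1.480617
```

The fitted maturation half-time falls from 18.3 days at GA 24 to 7.3 days
at GA 32: more mature kidneys accelerate earlier. Simulating the GA-24
neonate (621 g, 0.383 mg/dl at birth) through an ibuprofen course on days
1–3:

```r
prof <- reference_profiles()[[1]]
pars <- fit$parameters[["24"]]
traj <- simulate_concentration(prof, pars, list(treatment_course(1)))
traj[traj$time_day %in% c(0, 1, 2, 3, 14), ]
#>      time_day concentration_mg_dl clearance_l_day exposed
#> 1           0              0.3830          0.2527    TRUE
#> 201         1              0.7131          0.2688    TRUE
#> 401         2              0.8656          0.2921    TRUE
#> 601         3              0.9078          0.3181    TRUE
#> 2801       14              0.5015          0.5950   FALSE
```

Creatinine climbs from 0.383 to 0.908 mg/dl by the end of the course
(0.876 without ibuprofen — a 0.032 mg/dl drug signal), then falls back as
clearance matures. The full study replication and the out-of-sample check
against the reference difference table:

```r
run_study(fit)
#> End-of-course differences, ibuprofen minus no ibuprofen (mg/dl):
#>  ga_weeks period_1 period_2 period_3
#>        24    0.032    0.010    0.006
#>        27    0.027    0.008    0.005
#>        29    0.026    0.007    0.005
#>        32    0.024    0.006    0.005

validate_treatment_effect(fit)[1:4, c(1:3, 5:6)]
#>   ga_weeks period predicted_mg_dl reference_mg_dl error_mg_dl
#> 1       24      1         0.03174           0.030    1.74e-03
#> 2       24      2         0.01001           0.010    9.25e-06
#> 3       24      3         0.00631           0.006    3.14e-04
#> 4       27      1         0.02726           0.026    1.26e-03
```

The drug signal is strong in week 1 and nearly vanishes by weeks 3 and 5 —
the proportional clearance reduction for the GA-24 neonate is −5.08% at
birth but only −1.71% at day 30.

A command-line wrapper covering the pipeline stages (`calibrate`,
`replicate-study`, `simulate`, `generate-cohort`, `recovery`) is installed
at `inst/scripts/neocreat`:

```sh
Rscript inst/scripts/neocreat calibrate --output-dir out/cal
Rscript inst/scripts/neocreat replicate-study --output-dir out/study \
        --parameters out/cal/calibration_parameters.csv
```

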