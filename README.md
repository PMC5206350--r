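# phytodev

Phytomer growth and development analysis for grass tillers.

A vegetative grass tiller is a stack of *phytomers* — repeating units of
leaf blade, leaf sheath, node and internode. Their elongation is tightly
coordinated: each phytomer's length, normalized by its final length
(*f*<sub>L</sub> = *L*<sub>a</sub>/*L*<sub>p</sub>), follows one logistic
time course

&nbsp;&nbsp;&nbsp;&nbsp;*f*(*x*) = 1 / {1 + exp[(*x*₀ − *x*)/*b*]},&nbsp;&nbsp;*x*₀ = 1.82 d, *b* = 1.81 d,

in days after tip emergence; growth is all blade up to 50 % of final
length, the blade finishes at a 66 % share by 75 %, the sheath completes
its 14 % share by 80 %, and the last 20 % is internode; and successive
phytomers are offset by one phyllochron (≈ 2.3 d). The catch for anyone
analysing such data is censoring: roughly the first quarter of a
phytomer's growth happens invisibly inside the whorl of enclosing sheaths,
and a ruler only measures the distance from an emerged tip to the nearest
older visible ligule, to 0.5 mm, once a day.

`phytodev` is for plant growth modellers and quantitative ecophysiologists
who need this analysis as a tested, reusable pipeline. It provides:

* a **seeded forward simulator** of a 2 × 2 nitrogen × VPD growth-chamber
  experiment (64 tillers) with an explicit 1-D height model that produces
  exactly the two tables such experiments yield — daily tip-to-ligule
  ruler observations and an end-of-experiment dissection table — including
  emergence censoring, 0.5 mm rounding and the > 4 mm dissection rule;
* the **reconstruction pipeline**: emergence-lag correction, per-tiller
  phyllochron, cessation detection, per-tiller extrapolation of final
  lengths over rank, backwards reconstruction of the visible time course,
  phyllochron-offset dating of unemerged phytomers, and the within- and
  between-phytomer coordination tables;
* **logistic curve fitting** (Levenberg–Marquardt, 2- and 3-parameter,
  plus ordinary least squares for the internode line) with `tidy()` /
  `glance()` methods;
* **treatment summaries**: per-tiller parameters, treatment means ± SE,
  grand means and percent treatment effects with half-up reporting
  rounding.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe.

## Worked example

Simulate the default experiment, reconstruct the complete time course of
phytomer development, and refit the logistic:

```r
library(phytodev)

exp <- generate_experiment(generator_config(seed = 1))
exp
#> <phyto_experiment>
#>   64 tillers, 13243 observation rows, 1152 dissected phytomers (seed 1)

recon <- reconstruct_experiment(exp$observations, exp$dissection)
recon
#> <phyto_reconstruction>
#>   1104 emergence events (363 reliable), 506 time-course points (372 visible / 134 initial)

fit <- fit_sigmoid2(recon$timecourse, x = age, y = f_L)
fit
#> <phyto_fit>
#>   <sigmoid_curve>  y = 1 / {1 + exp[(1.739 - x)/1.818]}
#>   R^2 = 0.990, RSE = 0.02735, n = 506, converged: TRUE
```

The generator grew every phytomer on the curve (1.82, 1.81); after
censoring, 0.5 mm rounding, noisy final-length extrapolation and
phyllochron-offset dating of the unemerged phytomers, the pipeline
recovers (1.74, 1.82) with *R*² = 0.99 — the midpoint within ~4 % and the
scale within ~1 %. Treatment summaries come from the same objects:

```r
sm <- summarize_tillers(recon, exp$observations)
grand_means(treatment_means(sm))
#> # A tibble: 6 x 2
#>   parameter                  grand_mean
#>   <chr>                           <dbl>
#> 1 mean_final_phytomer_length      97.2
#> 2 n_phytomers                     14.8
#> 3 n_tillers                       20.1
#> 4 n_visibly_growing                5.12
#> 5 phyllochron                      2.33
#> 6 visible_growth_duration         11.2
```

The recovered phyllochron grand mean (2.33 d) matches the configured
per-treatment values (2.4, 2.4, 2.1, 2.4 d), and the ~11.2 d visible
growth duration is what a 0.5 mm ruler reports for a curve that crosses
99 % at 10.1 d. Closed-form pieces are exported directly:

```r
eval_sigmoid(coordination_rules()$timecourse, 2)  # 0.525 -> "52 %"
thermal_time(37, 25, 0)                           # 925 degree days
partition_components(0.75)                        # blade 0.66, sheath 0.09
```

`plot_timecourse(recon$timecourse, fit)`, `plot_rank_profile()` and
`plot_coordination()` give the standard diagnostic figures.

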