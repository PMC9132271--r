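# pcmpr

Seasonal population dynamics of the Asian tiger mosquito (*Aedes
albopictus*) in temperate climates, simulated from daily weather.  The
package is aimed at vector ecologists and epidemiological modellers who
want a mechanistic, climate-driven abundance model that can be calibrated
against routine weekly trap counts and then run under altered climate
series.

## The model

Five stages — active eggs *E*, diapausing eggs *E*<sub>dia</sub>, larvae
*L*, pupae *P*, adult females *A* — evolve in continuous time:

```
Ė     = (1 − z₁) o_v A − (m_E + d_E) E + z₂ E_dia
Ė_dia = z₁ o_v A − z₂ E_dia
L̇     = d_E E − (m_L + d_L + L/K) L
Ṗ     = d_L L − (m_P + d_P) P
Ȧ     = d_P P − m_A A
```

with temperature-dependent development (*d*), mortality (*m*), and
oviposition (*o_v*) rates; water temperature drives the aquatic stages and
air temperature the adults.  Two climate couplings distinguish the model:

* **Egg diapause** — while days shorten, eggs enter diapause with
  probability *z₁*, a product of sigmoids in weekly mean photoperiod and
  air temperature; while days lengthen, they re-activate with probability
  *z₂*, gated by weekly photoperiod and *water* temperature.
* **Rainfall-responsive carrying capacity** —
  *K* = κ<sub>max</sub> (W/W\*)<sup>ν</sup>, with soil water *W* from a
  bucket water balance; ν = 0 fixes the capacity, ν = 1 makes it track
  soil moisture.

Weekly trap counts are Poisson with mean = capture rate × weekly mean
simulated adults, and a simulated-annealing Metropolis sampler maximises
that likelihood over κ<sub>max</sub> and the diapause parameters.  A
seeded synthetic weather and trap-count generator makes the whole pipeline
testable offline.  See `vignettes/pcmp-model.Rmd` for the full account.

## Worked example

```r
library(pcmpr)

wx   <- generate_weather(weather_gen_config(seed = 1), n_years = 4)
env  <- build_environment(wx, tokyo_site())
traj <- simulate_population(env, model_params())       # nu = 1 defaults
s1   <- summarize_scenario(traj, years = 2002:2004)    # year 2001 is burn-in
glance(s1)
#> # A tibble: 1 × 5
#>    peak peak_week onset_week termination_week n_years
#>   <dbl>     <int>      <int>            <int>   <int>
#> 1  726.        30         18               45       3
```

The averaged seasonal cycle peaks at about 726 adult females in week 30 —
midsummer, the same peak week reported for the Tokyo system — with an
active season (weeks at ≥ 5 % of peak) from week 18 to week 45.  Running
the rain-insensitive variant on the same weather and comparing:

```r
s0 <- summarize_scenario(
  simulate_population(env, model_params(capacity = capacity_params(100, 0))),
  years = 2002:2004)
compare_models(s1, s0)
#> [1] 0.83
```

so under this particular (rather dry) synthetic climate the
rainfall-responsive model reaches only 83 % of the fixed-capacity peak;
`compute_bias()`, `scenario_shift()`, and `driver_histogram()` support the
same comparisons between climate inputs.  Calibration is one call:

```r
gen <- generate_trap_counts(wx, trap_gen_config(seed = 1))
fit <- calibrate_model(gen$observations, env, model_params(),
                       calibration_config(free = c("kappa_max", "beta_d1", "beta_d2"),
                                          seed = 1))
tidy(fit)    # estimates with transforms
glance(fit)  # log-likelihood, acceptance rate
```

A thin command-line front end over these functions is included at
`inst/cli/pcmp.R` (`synth`, `calibrate`, `project` subcommands).

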