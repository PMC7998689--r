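# surftens

Surface tension of liquid organic acids from three fluid constants, via a
small neural network benchmarked against classical corresponding-states
correlations.

## The problem

The surface tension σ(T) of a liquid decreases with temperature and vanishes
at the critical point. For organic acids (carboxylic, aliphatic,
polyfunctional), compiled experimental corpora are heterogeneous: points per
fluid range from a handful to well over a hundred, several sources report
conflicting values at the same temperature, and coverage extends to reduced
temperatures T<sub>r</sub> = T/T<sub>c</sub> near 0.9 where σ is almost
zero and percent deviations blow up. Classical corresponding-states (CSP)
correlations — Brock–Bird, Sastri–Rao, Pitzer-type, and a molecular-weight
form — predict σ from critical constants but are not tailored to acids and
miss badly on many of them.

`surftens` implements the alternative: a feed-forward multilayer perceptron

σ = f(T<sub>r</sub>, T<sub>b</sub>, ω)

with one sigmoid hidden layer and a linear output neuron, trained by a
damped Gauss–Newton (Levenberg–Marquardt) optimiser on min–max-normalised
variables with RMSE as the target function. The data are split at random
into training (75%), test (15%) and prediction (10%) subsets; the test set
drives early stopping and restart selection, the prediction set stays blind.
Accuracy is summarised by the signed percent deviation
PD<sub>i</sub> = 100·(σ(T<sub>i</sub>) − σ<sub>i</sub>)/σ<sub>i</sub>, its
per-set mean of absolute values (AAD), its maximum (PDm), RMSE in N/m, and
R². A reference (3, 41, 1) architecture carries 206 trainable coefficients.

The package also provides effect-factor ranking of nine candidate inputs
(a multilinear sensitivity surrogate on normalised variables), a
hidden-layer-size sweep (2–50 neurons, multi-restart) for architecture
selection, a synthetic-corpus generator that emulates the statistical
structure of compiled acid datasets, and a CLI
(`simulate | csp | effects | sweep | fit | predict | evaluate`).

## Worked example

```r
library(surftens)

data <- simulate_dataset(n_fluids = 30, seed = 42)   # 1203 rows, 30 fluids

# classical baselines
csp_benchmark(data) |> tidy()
#>   model       n_fluids n_data   N10 maxAAD minAAD overallAAD
#> 1 brock_bird        30   1203     4  256.    1.91       45.8
#> 2 sastri_rao        30   1203     3   79.1   2.93       29.3
#> 3 pitzer            30   1203     4  322.    3.46      112.
#> 4 gharagheizi       30   1203     0  111.   19.5        57.3

# the network
fit <- data |>
  st_split(seed = 42) |>
  mlp_fit(hidden = 12, restarts = 5, seed = 42,
          control = mlp_control(max_iter = 300))
fit
#> <st_mlp> (3,12,1) perceptron on (Tr, Tb_K, omega)
#>   61 parameters; restart 5 of 5 (seed 42)
#>      subset    n  AAD   PDm      RMSE     R2
#>    training  902 1.63 31.75 0.0002409 0.9992
#>        test  180 2.30 42.74 0.0002642 0.9992
#>  prediction  121 1.51 24.65 0.0002332 0.9993
#>    complete 1203 1.72 42.74 0.0002438 0.9992
```

Reading the report: every CSP baseline has an overall AAD above 20% on this
corpus while the 12-neuron network reaches 1.7% — close to the 1% noise the
generator injected — with similar deviations on the held-out test and blind
prediction subsets (no overfitting). The large PDm sits at the
highest-temperature points, where σ is nearly zero and a tiny absolute miss
is a large percentage. `autoplot(fit)` shows exactly that pattern;
`tidy(fit)` lists the 61 weights; `predict(fit, newdata)` adds `sigma_calc`
and an `extrapolated` flag to any table of fluid constants plus
temperatures; `mlp_save()`/`mlp_load()` round-trip the model as JSON.

Feature ranking and architecture selection:

```r
effect_factors(data)                      # Tr first, negative sign
architecture_sweep(data, hidden = c(2, 4, 8, 16), restarts = 5, seed = 1)
```

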