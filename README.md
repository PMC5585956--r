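# masemsim

Fixed-effects **meta-analytic structural equation modeling (MASEM)** and a
Monte Carlo harness for studying how **unequal primary-study sample sizes**
affect it.

In MASEM a set of k independent studies, each contributing a sample
correlation matrix R_i of the same p variables with sample size n_i, is
analyzed in two stages:

1. **Stage 1 — pooling.** The study matrices are combined into one pooled
   correlation matrix, and the homogeneity hypothesis (all studies share
   one population matrix) is tested. Four estimators are implemented:
   - **UNIr** — element-wise n-weighted means of the r_i (Hunter–Schmidt),
     homogeneity by Bonferroni-adjusted at-least-one (BA1) element tests;
   - **UNIz** — element-wise (n−3)-weighted means of Fisher transforms
     z = atanh(r) (Hedges–Olkin), BA1 on the z scale;
   - **MGLS** — generalized least squares on the stacked correlation
     vectors with Olkin–Siotani large-sample weight matrices evaluated at
     a common pooled plug-in, homogeneity by
     Q_GLS = Σ_i (r_i − ρ̂)′Ψ_i⁻¹(r_i − ρ̂), df = 6(k−1);
   - **TSSEM** — constrained multigroup normal maximum likelihood under
     Σ_g = D_g R D_g (common correlation matrix R, free group scalings),
     homogeneity by likelihood ratio against the saturated model.
2. **Stage 2 — structural model.** A recursive path model with two
   exogenous variables X1, X2, a mediator Y1 and an outcome Y2
   (Y = ΓX + BY + ζ, no direct X2 → Y2 path, 1 df of overidentification)
   is fitted to the pooled matrix — by normal-theory **ML** at the total
   sample size for the univariate routes, or by **WLS (ADF)** with the
   stage-1 asymptotic covariance as weight for the multivariate routes.

The simulation layer reproduces a complete operating-characteristics
study: k ∈ {5, 10, 15} studies with average sizes n̄ ∈ {50, …, 1000}
allocated **e**qually, **m**oderately unequally (60% small at 0.6 n̄, 40%
large at 1.6 n̄) or **h**ighly unequally (40%/20%/40% at 0.4/1.0/1.6 n̄),
with an optional fraction of studies drawn from a second fixed population
matrix (mixture heterogeneity, assigned to the smallest studies). It
reports type I error and power of the homogeneity tests, relative
percentage bias of pooled correlations, and parameter/SE bias and model
chi-square behaviour of the stage-2 fits.

## Worked example

Simulate one meta-analysis of five studies (n̄ = 100, highly unequal
sizes), pool it with TSSEM, and fit the path model by WLS:

```r
library(masemsim)
cfg <- sim_cell_config(k = 5, nbar = 100, design = "H",
                       het_fraction = 0, replications = 1, seed = 2024)
ss <- simulate_meta(cfg, replicate = 1)
ss
#> study_set: 5 studies, total N = 500
#>   sizes: 40, 40, 100, 160, 160
#>   labels: sigma, sigma, sigma, sigma, sigma

s1 <- pool_tssem(ss)
s1
#> Stage 1 (TSSEM): k = 5 studies, total N = 500
#> pooled correlations:
#>    r21    r31    r41    r32    r42    r43
#> 0.6626 0.4757 0.5423 0.5244 0.3120 0.1443
#> homogeneity LR = 20.921, df = 24, p = 0.6434, retain

s2 <- fit_wls(s1$pooled, s1$acov)
s2
#> Stage 2 (WLS): chisq(df = 1) = 0.3929, p = 0.5308
#>         estimate     se
#> gamma11   0.4059 0.0318
#> gamma12   0.4841 0.0305
#> gamma21   0.2705 0.0355
#> beta21    0.5343 0.0324
#> phi12     0.1445 0.0438
#> psi11     0.5440 0.0329
#> psi22     0.5038 0.0318
```

The homogeneity test retains the (true) single-population hypothesis
(LR = 20.9 on 24 df), the pooled correlations sit near the population
values (0.65, 0.50, 0.58, 0.55, 0.35, 0.20), and the stage-2 WLS fit
recovers the generating parameters (0.4, 0.5, 0.3, 0.5, 0.2, 0.51, 0.51)
within sampling error, with a well-behaved chi-square on 1 df.

`acceptance_band(0.05, 1000)` gives the 95% Monte Carlo band
(3.65%, 6.35%) used to flag empirical rejection rates of a nominal 5%
test over 1000 replications.

Monte Carlo summaries come from `run_cell()` (one design cell) or
`run_grid()` (a whole grid, with CSV/JSON export). Externally supplied
meta-analyses enter through `read_studyset()`, a directory of per-study
correlation CSVs plus a JSON manifest of sample sizes.

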