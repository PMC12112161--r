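# slmeco

Macroecology of experimental microbial communities under the Stochastic
Logistic Model (SLM) of growth.

High-replication serial-dilution ("transfer-cycle") experiments grow dozens
of replicate microcosms from one progenitor community, diluting an aliquot
into fresh medium every 48 hours, sometimes adding migrants — either from
the fixed progenitor (regional, mainland–island migration) or from a pool of
all replicates (global, metacommunity migration). `slmeco` is for
quantitative ecologists who want to ask whether the macroecological patterns
seen in such experiments — and the effects of migration on them — are
explained by a minimal stochastic model, and to infer that model's
parameters from data.

The core model is the SLM for the relative abundance x_i of each ASV,

    dx_i = x_i/tau_i (1 - x_i/K_i) dt + sqrt(sigma_i/tau_i) x_i dW_i ,

whose stationary abundance is gamma distributed with mean K(1 − σ/2) and
squared CV σ/(2 − σ) = 1/β. From this follow the gamma abundance
fluctuation distribution (AFD), Taylor's Law with exponent 2, a lognormal
mean abundance distribution (MAD), and a closed-form occupancy prediction
under multinomial read sampling:

    <o_i> = 1 - (1/M) Σ_m ( β_i / (β_i + x̄_i N_m) )^β_i .

The package provides:

* a transfer-cycle SLM simulator (Euler–Maruyama core in C++) with
  bottlenecks, regional/global migration, and multinomial read sampling;
* a synthetic-community generator (lognormal progenitor, logistic
  presence model, lognormal carrying capacities, empirical depth model);
* fitters for the gamma AFD, Taylor's Law and the truncated-lognormal MAD,
  plus occupancy curves and AFD rescaling/KS-shift statistics;
* migration-specific statistics with permutation nulls (Fisher's Z
  correlation shift, progenitor-dependence regressions, log-ratio CV tests,
  an F statistic comparing CVs);
* rejection ABC (`slm_abc()`) to infer {τ, σ} from observed summary
  statistics, with posterior-predictive checks and {τ, σ} grid scans.

## Worked example

```r
library(slmeco)

prog <- generate_progenitor(1000, seed = 1)     # synthetic source community
params <- assign_slm_params(prog, sigma = 0.7, tau = 1, seed = 2)
design <- transfer_design(M = 30)               # 18 x 48 h cycles, 1:125 bottleneck
ct <- simulate_experiment(design, params, treatment = "none", prog = prog,
                          sequenced_cycles = c(12, 18), seed = 3)

fit_taylor_table(subset_table(ct, transfer = 18))
#> Taylor's Law fit (n = 29 ASVs):
#>   exponent  1.9071 (se 0.0584)
#>   intercept -0.4671 (se 0.0980)

fit_truncated_lognormal(gamma_afd_table(subset_table(ct, transfer = 18))$mean)
#> Truncated-lognormal MAD fit (n = 29, c = 0.00385):
#>   mu = -3.8529, s = 0.9972, logLik = 71.56

mean_ks_shift(subset_table(ct, transfer = 12),
              subset_table(ct, transfer = 18))$mean_ks
#> [1] 0.1540998
```

Of 1000 progenitor ASVs, 29 establish (the ~100-fold richness drop). The
Taylor exponent ≈ 1.91 is the model's "exponent 2" seen through multinomial
sampling noise, which flattens the low-abundance end slightly. The MAD of
the 29 established ASVs is lognormal with scale s ≈ 1, and the mean KS
shift ≈ 0.15 between transfers 12 and 18 quantifies how much the rescaled
AFDs drift between snapshots; under migration this shift is larger and is
the statistic `slm_abc()` can match.

Parameter inference takes an observed summary and a prior box:

```r
obs <- abc_summary("pattern", ct_observed, design)
fit <- slm_abc(obs, abc_config(summary = "pattern"), design, params,
               treatment = "regional", prog = prog, seed = 1)
coef(fit)          # selected tau (h) and sigma
predictive_check(fit)  # observed inside the 95% predictive interval?
```

A thin command-line wrapper over the same functions lives at
`inst/cli/slmeco.R` (`generate`, `simulate`, `patterns`, `migration-stats`,
`abc`), driven by a YAML config; every stage writes a manifest sufficient to
reproduce its outputs bit-identically.

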