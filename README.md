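# targetsearch

Kinetic theory and fitting pipeline for the target search of
sequence-specific DNA-binding proteins — transcription factors and
repair/modifying enzymes that must locate one specific site among a vast
excess of nonspecific but structurally similar DNA. The package is aimed at
biophysicists analyzing stopped-flow target-association kinetics
(fluorescent probe duplex + nonspecific competitor DNA under
pseudo-first-order conditions) and at modelers studying facilitated
diffusion: sliding, dissociation/re-association and intersegment transfer.

## The model

The apparent second-order association rate constant for a protein searching
a probe duplex with `L` binding sites (target at site `m`, footprint `B`,
so `L = A − B + 1` for an `A`-bp duplex) in the presence of a competitor
duplex with `M` sites is

    k_a = S / (K_d,N + (φL − S)·D_tot + φM·C_tot) · 1/τ_N
    τ_N = 1 / (k_off,N + k_IT,N·(φL·D_tot + φM·C_tot))
    λ   = sqrt(D_1·τ_N)

with no quasi-equilibrium assumption for the nonspecific interactions.
`S(λ, L, m)` is the *antenna size*: the summed splitting probabilities of
reaching the target by sliding before leaving the chain, a function of the
effective sliding length `λ` (bp). The same quantity factors exactly as

    k_a = ρ · η · S · k_on,N ,   k_on,N = k_off,N / K_d,N

where `ρ ≤ 1` is the untrapped fraction (attenuation by sequestration at
distant nonspecific sites), `η ≥ 1` the intersegment-transfer enhancement
and `S` the antenna enhancement. Because `S`, `ρ`, `η` and `k_on,N` depend
on ionic strength in opposite directions, the composed `k_a(KCl)` can peak
at an intermediate salt concentration — the "optimal search" phenomenon the
decomposition quantifies.

The package implements the closed form and its decomposition
(`search_rate()`, `search_decompose()`), stage-1 trace analysis
(`fit_monoexp()`, `fit_titration()`), stage-2 nonlinear least-squares
estimation of `(D_1, λ)` from DNA-length series, `(k_off,N, k_IT,N)` from
competitor series, and all three jointly (`fit_length_dependence()`,
`fit_competition()`, `fit_simultaneous()`), stage-3 log-log ionic-strength
laws with profile and optimum finder (`fit_power_law()`,
`decomposition_profile()`, `find_optimum()`), two independent validators
(`antenna_oracle()`, a first-passage linear solve; `gillespie_search_rate()`,
a compiled stochastic simulation), and synthetic-data generators with
embedded ground truth (`gen_trace()`, `gen_titration()`,
`gen_rate_dataset()`). Everything is tidyverse-flavored: data frames in,
tibbles out, `tidy()`/`glance()`/`augment()` on fits, `autoplot()` on every
result type.

## Worked example

Decompose the search rate for a 113-bp probe (105 sites, 9-bp footprint,
target at position 2) at 2.5 nM with 2 μM of a 28-bp competitor (20 sites),
using a 150 mM KCl-like parameter set:

```r
library(targetsearch)
p    <- nonspecific_params(D1 = 2.7e6, k_off_N = 920, k_IT_N = 1.15e7,
                           K_d_N = 16e-6)
cond <- assay_condition(probe_len_bp = 113, D_tot_M = 2.5e-9, C_tot_M = 2e-6)
search_decompose(cond, p)
#>    tau_N_s     S   rho   eta   k_on_N        k_a
#>   0.000542  39.4 0.166  2.01 57500000 754422704.
```

Read: the nonspecific complex lives 0.54 ms, long enough to slide
`λ ≈ 38 bp`; ~39 of the 105 probe sites act as an antenna (39-fold
enhancement), transfer doubles the effective turnover (`η ≈ 2`), but 83% of
protein is sequestered on nonspecific sites (`ρ ≈ 0.17`), leaving
`k_a ≈ 7.5 × 10⁸ M⁻¹s⁻¹ = ρ·η·S·k_on,N` exactly.

Fit the transfer and dissociation rate constants from a noisy synthetic
competitor titration and compare with the generating truth:

```r
d   <- gen_rate_dataset(p, covariate = "competitor", noise_frac = 0.05,
                        seed = 42)
fit <- fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N)
fit
#> <search_fit> variant = with_IT, n = 6, rss = 6.24751e+15
#>     term    estimate       se   se_log10 identifiable
#>  k_off_N     1040.06 6.82e+01 0.02846869         TRUE
#>   k_IT_N 10561300.00 1.61e+06 0.06640441         TRUE
```

Both estimates bracket the truth (920 s⁻¹, 1.15 × 10⁷ M⁻¹s⁻¹) within two
standard errors. Cross-check the closed form against the stochastic
simulator on a small configuration:

```r
g <- gillespie_search_rate(nonspecific_params(900, 50, 1.18e6, 2e-6),
                           assay_condition(33, D_tot_M = 5e-8, C_tot_M = 1e-6),
                           n_traj = 1e4, seed = 1)
g$k_a      # 10208526 — closed form gives 10040386; |z| < 3
```

The methods vignette (`vignettes/target-search-theory.Rmd`) documents the
model, the numerical evaluation of the antenna size, the fitting
conventions, the simulator's assumptions, and known limitations.

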