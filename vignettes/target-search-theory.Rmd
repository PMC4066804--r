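---
title: "Target-search kinetics on DNA: model, fitting pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-search kinetics on DNA: model, fitting pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetsearch)
library(dplyr)
```

## The model

A sequence-specific DNA-binding protein finds its target by facilitated
diffusion: three-dimensional association to nonspecific sites, one-dimensional
sliding along the duplex, dissociation, and direct intersegment transfer
between duplexes. `targetsearch` implements a closed-form expression for the
apparent second-order target-association rate constant $k_a$ of a protein
searching a fluorescent probe duplex (the one carrying the target) in the
presence of nonspecific competitor DNA, without assuming quasi-equilibrium for
the nonspecific interactions:

$$k_a \;=\; \frac{S}{K_{d,N} + (\phi L - S)\,D_\mathrm{tot} + \phi M\,C_\mathrm{tot}}
\cdot \frac{1}{\tau_N},$$

where $L$ and $M$ are the binding-site counts of probe and competitor
($L = A - B + 1$ for a duplex of $A$ bp and a protein footprint of $B$ bp),
$\phi$ is the number of binding orientations per site (2 for a monomer on
pseudo-twofold duplex DNA, 1 for a symmetric dimer), $K_{d,N}$ the per-site
nonspecific dissociation constant, and $D_\mathrm{tot}$, $C_\mathrm{tot}$ the
duplex concentrations. The nonspecific-complex lifetime combines dissociation
and intersegment transfer,

$$\tau_N = \left[k_{\mathrm{off},N} +
  k_{\mathrm{IT},N}\,(\phi L D_\mathrm{tot} + \phi M C_\mathrm{tot})\right]^{-1},$$

and the antenna size $S$ — the effective number of sites funneling the protein
into the target by sliding — is the sum over the chain of the splitting
probabilities of reaching the target (site $m$ from the duplex edge, reflecting
ends) before leaving the chain. It is a function of the effective sliding
length $\lambda = \sqrt{D_1 \tau_N}$ (bp), where $D_1$ is the one-dimensional
diffusion coefficient in bp$^2$ s$^{-1}$ (numerically the per-direction
single-step sliding rate in s$^{-1}$ on a 1-bp lattice).

The same rate constant factors exactly as

$$k_a = \rho\,\eta\,S\,k_{\mathrm{on},N}, \qquad
  k_{\mathrm{on},N} = k_{\mathrm{off},N}/K_{d,N},$$

with $\rho \le 1$ the fraction of proteins *not* trapped at nonspecific sites
(the trapping attenuation), $\eta \ge 1$ the intersegment-transfer enhancement
$1 + k_{\mathrm{IT},N}(\phi L D_\mathrm{tot} + \phi M C_\mathrm{tot})/k_{\mathrm{off},N}$,
and $S$ the antenna enhancement. `search_rate()` evaluates the direct form;
`search_decompose()` returns every factor. The two routes agree to machine
precision, and the test suite asserts this identity on randomized inputs —
it is an algebraic property of the implementation, not a fitted statement.

```{r decompose}
p <- nonspecific_params(D1 = 2.7e6, k_off_N = 920, k_IT_N = 1.15e7,
                        K_d_N = 16e-6)
cond <- assay_condition(probe_len_bp = 113, D_tot_M = 2.5e-9, C_tot_M = 2e-6)
search_decompose(cond, p)
```

## Numerical evaluation of the antenna size

The textbook form of $S$ involves $y^{-L}$, where $y \in (0,1)$ is the root of
$y^2 - (2 + \lambda^{-2})y + 1 = 0$; for small $\lambda$ and large $L$ this
overflows double precision. `antenna_size()` therefore works in the hyperbolic
domain: with $u = -\ln y$ (so $\cosh u = 1 + \lambda^{-2}/2$, evaluated
stably as $u = 2\,\mathrm{asinh}(1/2\lambda)$),

$$S = \frac{\cosh(u/2)\,\sinh(Lu)}
  {2\,\sinh(u/2)\,\cosh\!\big((2m-1)u/2\big)\,\cosh\!\big((2L-2m+1)u/2\big)},$$

with $\log\sinh$/$\log\cosh$ asymptotics beyond argument 30. This is exact and
stable for $\lambda \ge 10^{-2}$ and $L \le 10^4$. Below $\lambda = 10^{-6}$
the known limit $S = 1$ is returned directly rather than evaluated. Two
independent validators pin the implementation down:

* `antenna_oracle()` solves the first-passage splitting-probability linear
  system for the same chain and must agree to $10^{-8}$ relative (observed:
  $\sim 10^{-13}$) across a grid of $\lambda \in \{0.5, 2, 10, 38, 122\}$,
  $L \in \{10, 25, 105, 135\}$ and edge/near-edge/middle target positions;
* `gillespie_search_rate()` simulates the full search scheme event by event
  and must agree with the closed form within three ensemble standard errors.

Two boundary facts are worth recording. First, the often-quoted range
$1 < S < 2\lambda$ is a continuum statement: the exact discrete-lattice
antenna can exceed $2\lambda$ at small sliding lengths, approaching
$\sqrt{4\lambda^2 + 1}$ for a mid-duplex target on a long chain
($S = \sqrt{5} \approx 2.236$ at $\lambda = 1$, not $2$). The tests assert the
exact discrete bound everywhere and the $2\lambda$ form only where it holds.
Second, the mid-duplex reduction $S \approx 2\lambda\tanh(L/2\lambda)$
(`antenna_size_midpoint()`) is an approximation, not an identity; at
$\lambda = 38$, $L = 105$, $m = 53$ it differs from the exact form by
$\sim 8\times 10^{-5}$ relative, and the package reports rather than assumes
this discrepancy.

## The fitting pipeline

Stage 1 — traces. Under pseudo-first-order conditions
($D_\mathrm{tot} \ll P_\mathrm{tot} \ll C_\mathrm{tot}$) association time
courses are mono-exponential; `fit_monoexp()` extracts $k_\mathrm{app}$ by
Levenberg–Marquardt with data-derived starts (plateau from the tail mean, rate
from a log-linearized early decay) and a rate-grid multi-start fallback. The
fit is parameterized in $(I_\infty, I_0, \ln k_\mathrm{app})$, so the rate is
positive by construction and either direction of fluorescence change is
accepted. `fit_titration()` then reads $k_a$ as the slope of
$k_\mathrm{app}$ versus $P_\mathrm{tot}$. An intercept is allowed by default —
it absorbs any back reaction such as target dissociation, which the rate model
does not treat explicitly — and the zero-intercept convention is available;
with a hidden baseline the zero-intercept slope is biased, which the test
suite demonstrates rather than hides. When per-point SEs are supplied the
regression is $1/\mathrm{se}^2$-weighted and the SEs are treated as absolute
uncertainties (covariance $(X^\top W X)^{-1}$ without reduced-chi-square
rescaling), which gives calibrated 2-SE coverage under the generators'
multiplicative noise.

Stage 2 — microscopic parameters. All rate/diffusion parameters are fitted in
natural-log space (positivity without constraints) by Levenberg–Marquardt from
a deterministic log-spaced multi-start grid (5×5 per parameter pair, fixed
enumeration order), minimizing the unweighted sum of squared $k_a$ residuals
by default with an optional $1/\mathrm{se}^2$ weighting flag:

* `fit_length_dependence()` estimates $(D_1, \lambda)$ from $k_a$ versus probe
  length. Here $\tau_N \equiv \lambda^2/D_1$, so the length series never
  references $k_{\mathrm{off},N}$ or $k_{\mathrm{IT},N}$; the weak
  concentration dependence of the lifetime across the fixed-competitor series
  is absorbed into $\lambda$. For each $\lambda$ on the start grid the model
  is linear in $D_1$, so the conditionally optimal $D_1$ is closed-form — the
  multi-start profiles over $\lambda$ only.
* `fit_competition()` estimates $(k_{\mathrm{off},N}, k_{\mathrm{IT},N})$ from
  $k_a$ versus competitor concentration at fixed probe, with $D_1$ supplied
  from stage 2a and $\tau_N$, $\lambda$, $S$ all recomputed per concentration.
  The `without_IT` variant pins $k_{\mathrm{IT},N} = 0$ — the nested
  no-transfer model, whose residual sum of squares can never undercut the full
  model's. Designs spanning less than a 4-fold concentration range are
  rejected as unidentifiable.
* `fit_simultaneous()` fits $(D_1, k_{\mathrm{off},N}, k_{\mathrm{IT},N})$
  jointly to both series, with the lifetime evaluated from the rate constants
  at every point's own geometry and concentrations. Length data alone cannot
  constrain three parameters and is rejected.

Standard errors come from the Gauss–Newton covariance at the optimum
(central-difference Jacobian on the log scale, delta method back to the
natural scale); a seeded residual bootstrap (`bootstrap_se()`) is available as
an alternative. Since reported uncertainties in this field rarely state their
estimator, both are provided without claiming either matches any particular
published value. A parameter whose log$_{10}$-scale SE reaches 1 (an SE
spanning a decade) is flagged `identifiable = FALSE`; a length series with no
curvature — probe lengths all $\ll 2\lambda$ — triggers exactly this flag for
$\lambda$.

Stage 3 — ionic strength. Counterion-condensation theory predicts log–log
linear salt dependence for rate and affinity constants;
`fit_power_law()`/`eval_power_law()` handle laws of the form
$\log_{10} x = a \log_{10}[\mathrm{KCl}] + b$ (base 10 fixed as the serialized
convention; slope/intercept pairs are base-consistent either way).
`decomposition_profile()` evaluates the four laws
($D_1$, $k_{\mathrm{off},N}$, $k_{\mathrm{IT},N}$, $K_{d,N}$) across a KCl
grid and returns the full $\rho/\eta/S/k_a$ decomposition per point;
`find_optimum()` locates the fastest-search salt concentration by grid argmax
plus continuous golden-section refinement between the bracketing grid points,
flagging boundary maxima and non-unimodal profiles. With the dissociation law
anchored on measured endpoints (0.20 s$^{-1}$ at 40 mM, 920 s$^{-1}$ at
150 mM — a slope of 6.38), the five-point affinity law (1.4–16 μM over
40–150 mM), and negative-slope transfer/diffusion laws consistent with sliding
lengths of 122 bp (40 mM) and 38 bp (150 mM), the profile reproduces the
qualitative physics: $S$ and $\eta$ fall with salt, $\rho$ rises, and the
composed $k_a$ is the compromise between them. Because the diffusion and
transfer coefficients underlying any particular published optimum curve are
not available as printed numbers, the optimum is reported for the model
composition only, never asserted to equal a measured optimum.

```{r profile}
laws <- bind_rows(
  fit_power_law(data.frame(KCl_mM = c(40, 150), value = c(0.20, 920)),
                "k_off_N"),
  fit_power_law(data.frame(KCl_mM = c(40, 60, 80, 110, 150),
                           value = c(1.4, 3.6, 4.6, 9.6, 16) * 1e-6),
                "K_d_N"),
  power_law("k_IT_N", -2, log10(2e8) + 2 * log10(40)),
  power_law("D1", -3.33, 13.7)
)
prof <- suppressWarnings(decomposition_profile(laws, cond,
                                               KCl_mM = seq(40, 400, 20)))
head(prof[c("KCl_mM", "lambda_bp", "S", "rho", "eta", "k_a")])
```

## The stochastic simulator

`gillespie_search_rate()` is the operational check that the closed form needs
no quasi-equilibrium assumption. One protein is simulated over the states
{free; bound at (duplex, site, orientation)}: association at
$k_{\mathrm{on},N}$ per site-orientation weighted by duplex concentration,
sliding at $D_1$ per direction with reflecting ends, dissociation at
$k_{\mathrm{off},N}$, and transfer at $k_{\mathrm{IT},N}$ times the total
site concentration with a concentration-weighted, within-duplex-uniform
landing site. Three conventions are deliberately frozen to match the model
being tested: the per-direction hop rate equals $D_1$ (the characteristic
equation of the resulting discrete chain, $y + 1/y = 2 + 1/(\mathrm{hop}\,\tau)$,
reproduces the sliding root exactly with $\lambda^2 = \mathrm{hop}\,\tau$);
wrong-orientation probe sites are pure traps, matching the $(\phi L - S)$
bookkeeping in which the antenna is counted once; and transfer lands uniformly
on the destination duplex, the minimal assumption and the one that keeps
$\tau_N$ destination-independent. The estimate is
$k_a = 1/(\overline{T}\,D_\mathrm{tot})$ with a delta-method ensemble SE;
censored trajectories are counted and a censoring fraction above 1% flags the
estimate. The event loop is compiled (Rcpp) because typical configurations
take $10^3$–$10^5$ events per trajectory; it draws from R's RNG, so `set.seed`
(or the `seed` argument) makes runs bit-identical. Agreement with the closed
form is asserted within 3 SE at $10^4$ trajectories for a small configuration
(33-bp probe, 25 sites; 28-bp competitor, 20 sites; rates giving a ~3-site
sliding length and moderate trapping). As the probe concentration grows toward
$K_{d,N}$ the pseudo-first-order premise weakens and agreement degrades; that
regime boundary is documented here, not asserted away.

## Synthetic data and what passing tests mean

`gen_trace()`, `gen_titration()` and `gen_rate_dataset()` forward-simulate the
study designs with known truth embedded in attributes, so every fixture is
regenerable from configuration alone. The default designs are the study's:
probe lengths {33, 48, 63, 88, 113, 143} bp, competitor 28 bp at
{0.5, 1, 2, 4, 8, 16} μM, protein {20, 50, 100, 200, 400} nM, probe 2.5 nM,
footprint 9 bp, target position 2, $\phi = 2$. Noise on rate constants is
multiplicative log-normal, 5% by default where noise is requested (rate
constants are positive and their scatter on log plots looks multiplicative);
traces get additive Gaussian noise. A seed is mandatory whenever noise is
generated, and generation restores the caller's RNG state.

One generator convention matters for round-trip exactness: for the length
covariate the lifetime is generated as $\tau_N = \lambda^2/D_1$ — the same
convention the length fit uses — so noiseless generation followed by
`fit_length_dependence()` is the identity on $(D_1, \lambda)$ and the
embedded truth is well defined. Had the generator instead recomputed
$\tau_N$ from the rate constants at each probe length, the probe-term
$\phi L D_\mathrm{tot}$ in the transfer flux would make $\lambda$ vary by
~0.1–0.3% across the series and "the true $\lambda$" would be ambiguous at
the 0.1% recovery tolerance. That full-model generation is available as
`tau_model = "rates"` and is what exercises `fit_simultaneous()`, whose model
matches it exactly.

The generators emulate idealized pseudo-first-order kinetics: no instrument
dead time, no photobleaching, no pipetting error in the design variables, no
deviation from mono-exponentiality at partial target saturation. Passing
recovery tests therefore show that the pipeline inverts its own forward model
at the stated noise level — a necessary condition, not evidence that real
data meet the model's assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use: the 60-point oracle grid; 1000
randomized parameter sets for the factor identity ($10^{-12}$ tolerance); 100
seeded replicates for each coverage simulation (5% noise, ±2 SE, ≥90/100 for
the sliding-length fit; ≥95/100 for the weighted titration slope); $10^4$
Gillespie trajectories for the 3-SE agreement; and 5000-point dense grids as
the brute-force argmax reference for the optimum finder. Optimizer
convergence tolerances are $10^{-14}$ (ftol/ptol); noiseless recoveries are
asserted at 0.1% (length) and 0.5% (competitor/joint), comfortably above
optimizer noise. Ties and degeneracies: a constant-intensity trace, an
all-zero decay channel, a sub-4-fold competitor span, and a length-only
three-parameter fit are rejected with explanatory errors rather than fitted;
a non-unimodal salt profile returns the global grid maximum with a warning;
golden-section refinement is accepted only when it does not undercut the best
grid value.

## Known limitations

* Intra-molecular transfer between distant sites of one long duplex is not
  modeled (duplexes here are shorter than the persistence length).
* Hopping is not a separate mode; short-range dissociation/re-association is
  folded into $k_{\mathrm{off},N}$.
* The salt laws are empirical log–log fits; no mechanistic
  counterion-condensation model is fitted, and $K_{d,N}$ values are inputs.
* The Gauss–Newton SEs are linearization-based; at 5% multiplicative noise
  their 2-SE coverage for the sliding length is ~90–93%, not the Gaussian
  95% — the bootstrap option exists for exactly this reason.
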