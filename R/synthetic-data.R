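# Generators that emulate the study's data with known, embedded ground
# truth: mono-exponential stopped-flow traces, protein titrations and k_a
# series against probe length, competitor concentration or KCl. Every
# generator records its truth and seed in attributes so each fixture is
# regenerable from configuration alone.

# register seed restoration in the caller's frame, then set the seed
seed_guard <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

mult_noise <- function(x, noise_frac) {
  if (noise_frac == 0) return(x)
  # multiplicative log-normal scatter; log-sd equals the fractional level
  x * exp(rnorm(length(x), mean = 0, sd = noise_frac))
}

check_noise <- function(noise_frac, seed) {
  if (noise_frac < 0 || noise_frac > 0.5)
    abort("`noise_frac` must lie in [0, 0.5].")
  if (noise_frac > 0 && is.null(seed))
    abort("A seed is mandatory whenever noise is generated.")
}

#' Synthetic mono-exponential fluorescence trace
#'
#' Generates `I(t) = I_inf + (I0 - I_inf) exp(-k_app t)` on a uniform time
#' grid with optional additive Gaussian noise, emulating a stopped-flow
#' target-association time course under pseudo-first-order conditions.
#'
#' @param k_app Apparent rate constant, 1/s (> 0).
#' @param I0,I_inf Initial and plateau intensities (arbitrary units; either
#'   direction of fluorescence change is allowed).
#' @param n_points Number of points (>= 10).
#' @param t_max End of the observation window, s (default five relaxation
#'   times). A window shorter than one relaxation time triggers an
#'   under-sampling warning.
#' @param noise_sd Additive Gaussian noise standard deviation, intensity
#'   units.
#' @param seed Integer seed; mandatory when `noise_sd > 0`. RNG state is
#'   restored on exit.
#' @return A trace tibble (`time_s`, `intensity`) with the generating truth
#'   in `attr(, "truth")`.
#' @examples
#' tr <- gen_trace(k_app = 0.05, noise_sd = 0.01, seed = 7)
#' fit_monoexp(tr)
#' @export
gen_trace <- function(k_app, I0 = 1, I_inf = 0, n_points = 200,
                      t_max = 5 / k_app, noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(k_app), k_app > 0, n_points >= 10, t_max > 0)
  if (noise_sd > 0 && is.null(seed))
    abort("A seed is mandatory whenever noise is generated.")
  if (t_max * k_app < 1)
    warn("Observation window shorter than one relaxation time (t_max * k_app < 1); the decay is under-sampled.")
  seed_guard(seed)
  t <- seq(0, t_max, length.out = n_points)
  I <- I_inf + (I0 - I_inf) * exp(-k_app * t)
  if (noise_sd > 0) I <- I + rnorm(n_points, sd = noise_sd)
  out <- tibble::tibble(time_s = t, intensity = I)
  attr(out, "truth") <- list(k_app = k_app, I0 = I0, I_inf = I_inf,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic protein titration of apparent rate constants
#'
#' Generates `k_app = k_a_true * P_tot + baseline` over a protein
#' concentration series with optional multiplicative log-normal noise,
#' emulating the pseudo-first-order titration from which the second-order
#' `k_a` is read as the slope.
#'
#' @param k_a_true Generating apparent association rate constant, M^-1 s^-1.
#' @param P_tot_M Protein concentrations, M (default 20-400 nM).
#' @param baseline Intercept, 1/s (e.g. target dissociation back-rate).
#' @param noise_frac Multiplicative log-normal noise level (fraction).
#' @param seed Integer seed; mandatory when `noise_frac > 0`.
#' @return A tibble (`P_tot_M`, `k_app_per_s`) with truth attributes; when
#'   noise is generated a `se_per_s` column carries the per-point scatter
#'   scale so the titration fit can weight.
#' @export
gen_titration <- function(k_a_true, P_tot_M = c(20, 50, 100, 200, 400) * 1e-9,
                          baseline = 0, noise_frac = 0, seed = NULL) {
  stopifnot(k_a_true > 0, length(P_tot_M) >= 2, all(P_tot_M > 0))
  check_noise(noise_frac, seed)
  seed_guard(seed)
  expected <- k_a_true * P_tot_M + baseline
  k_app <- mult_noise(expected, noise_frac)
  out <- tibble::tibble(P_tot_M = P_tot_M, k_app_per_s = k_app)
  # multiplicative scatter has a known per-point scale; report it so the
  # titration fit can weight, as replicate SEMs would in a real assay
  if (noise_frac > 0) out$se_per_s <- noise_frac * expected
  attr(out, "truth") <- list(k_a = k_a_true, baseline = baseline,
                             noise_frac = noise_frac, seed = seed)
  out
}

#' Synthetic rate-constant datasets over the study's designs
#'
#' Forward-simulates apparent association rate constants `k_a` from the
#' closed-form search model over one experimental design axis, with optional
#' multiplicative log-normal noise and the generating truth embedded in
#' attributes:
#'
#' * `covariate = "length"`: `k_a` versus probe duplex length (default
#'   33-143 bp series at fixed 2 uM competitor). By default
#'   (`tau_model = "sliding_length"`) the series is generated with a single
#'   lifetime `tau_N = lambda^2 / D1` — the same convention the length fit
#'   uses, so noiseless generation + [fit_length_dependence()] is the
#'   identity on `(D1, lambda)`. With `tau_model = "rates"` the lifetime is
#'   recomputed from `k_off_N`/`k_IT_N` at each point's own concentrations
#'   (use this to exercise [fit_simultaneous()]).
#' * `covariate = "competitor"`: `k_a` versus competitor concentration
#'   (default 0.5-16 uM) with the full concentration-dependent lifetime.
#' * `covariate = "KCl"`: `k_a` versus KCl with the microscopic parameters
#'   drawn from ionic-strength power `laws`.
#' * `covariate = "protein"`: apparent first-order `k_app = k_a * P_tot`
#'   over a protein series (the titration design).
#'
#' @param params A [nonspecific_params()] object (ignored for
#'   `covariate = "KCl"`, where `laws` supplies the parameters).
#' @param condition Single-row [assay_condition()] template providing the
#'   non-covariate fields; defaults to the 113-bp / 2.5 nM probe with 2 uM
#'   28-bp competitor.
#' @param covariate Design axis, see above.
#' @param design Covariate values: bp for `"length"`, M for `"competitor"`
#'   and `"protein"`, mM for `"KCl"`. `NULL` uses the study design.
#' @param lambda_bp Sliding length used by the `"length"` generator's
#'   `sliding_length` convention; `NULL` derives it from `params` and the
#'   template condition's lifetime.
#' @param tau_model Lifetime convention for the `"length"` covariate.
#' @param laws Power-law tibble for `covariate = "KCl"`.
#' @param noise_frac Multiplicative log-normal noise level on `k_a`.
#' @param seed Integer seed; mandatory when `noise_frac > 0`.
#' @return A tibble with the covariate column (`probe_len_bp` + `n_sites`,
#'   `C_tot_M`, `KCl_mM`, or `P_tot_M`), the response (`k_a`, or
#'   `k_app_per_s` for `"protein"`), and truth attributes.
#' @examples
#' p <- nonspecific_params(2.7e6, 920, 1.15e7, 16e-6)
#' gen_rate_dataset(p, covariate = "length")
#' @export
gen_rate_dataset <- function(params,
                             condition = assay_condition(
                               113, D_tot_M = 2.5e-9, C_tot_M = 2e-6),
                             covariate = c("length", "competitor", "KCl",
                                           "protein"),
                             design = NULL, lambda_bp = NULL,
                             tau_model = c("sliding_length", "rates"),
                             laws = NULL, noise_frac = 0, seed = NULL) {
  covariate <- match.arg(covariate)
  tau_model <- match.arg(tau_model)
  check_noise(noise_frac, seed)
  stopifnot(nrow(condition) == 1L)
  if (!is.null(design) && length(design) == 0)
    abort("Empty design list for the requested covariate.")
  seed_guard(seed)
  fx <- NULL
  if (covariate != "KCl") {
    stopifnot(inherits(params, "nonspecific_params"))
    fx <- fixed_from_condition(condition, params$K_d_N, params$phi)
  }

  if (covariate == "length") {
    probe_len <- design %||% c(33, 48, 63, 88, 113, 143)
    L <- site_count(probe_len, condition$footprint_bp)
    if (tau_model == "sliding_length") {
      if (is.null(lambda_bp))
        lambda_bp <- sqrt(params$D1 * nonspecific_lifetime(params, condition))
      k_a <- ka_model_length(params$D1, lambda_bp, L, fx)
    } else {
      k_a <- ka_model_rates(params$D1, params$k_off_N, params$k_IT_N, L,
                            condition$C_tot_M, fx)
    }
    out <- tibble::tibble(probe_len_bp = probe_len, n_sites = L,
                          k_a = mult_noise(k_a, noise_frac))
    truth <- list(params = params, lambda_bp = lambda_bp,
                  tau_model = tau_model)
  } else if (covariate == "competitor") {
    C_tot <- design %||% (c(0.5, 1, 2, 4, 8, 16) * 1e-6)
    k_a <- ka_model_rates(params$D1, params$k_off_N, params$k_IT_N,
                          fx$L_sites, C_tot, fx)
    out <- tibble::tibble(C_tot_M = C_tot, k_a = mult_noise(k_a, noise_frac))
    truth <- list(params = params)
  } else if (covariate == "KCl") {
    if (is.null(laws))
      abort("`covariate = \"KCl\"` needs a `laws` power-law tibble.")
    KCl <- design %||% c(40, 60, 80, 110, 150)
    lk <- laws_lookup(laws)
    phi <- if (!missing(params) && inherits(params, "nonspecific_params"))
      params$phi else 2
    k_a <- vapply(KCl, function(s)
      decompose_core(params_at_KCl(lk, s, phi), condition)$k_a, numeric(1))
    out <- tibble::tibble(KCl_mM = KCl, k_a = mult_noise(k_a, noise_frac))
    truth <- list(laws = laws, phi = phi)
  } else { # protein
    P_tot <- design %||% (c(20, 50, 100, 200, 400) * 1e-9)
    k_a_true <- decompose_core(params, condition)$k_a
    out <- tibble::tibble(P_tot_M = P_tot,
                          k_app_per_s = mult_noise(k_a_true * P_tot,
                                                   noise_frac))
    truth <- list(params = params, k_a = k_a_true)
  }
  attr(out, "truth") <- c(truth, list(condition = condition,
                                      covariate = covariate,
                                      noise_frac = noise_frac, seed = seed))
  out
}
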