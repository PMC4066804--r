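# Stage 3: log-log ionic-strength laws for the microscopic parameters and
# the antenna/trapping/transfer profile across KCl, including the optimum
# search condition. Counterion-condensation theory predicts
# log10(value) = a log10([KCl]) + b for rate and affinity constants; the
# laws here are empirical fits of that form (base-10 throughout).

#' Construct a log-log ionic-strength law
#'
#' A power law `log10(value) = slope * log10(KCl_mM) + intercept` for one
#' microscopic parameter, valid over a stated KCl domain.
#'
#' @param quantity Label, one of `"D1"`, `"k_off_N"`, `"k_IT_N"`, `"K_d_N"`.
#' @param slope,intercept Coefficients on the base-10 log-log scale
#'   (concentration in mM).
#' @param KCl_min_mM,KCl_max_mM Fit/validity domain, mM.
#' @return A one-row tibble of class `power_law`.
#' @export
power_law <- function(quantity, slope, intercept,
                      KCl_min_mM = 40, KCl_max_mM = 400) {
  if (!quantity %in% c("D1", "k_off_N", "k_IT_N", "K_d_N"))
    abort("`quantity` must be one of D1, k_off_N, k_IT_N, K_d_N.")
  if (!is.finite(slope) || !is.finite(intercept))
    abort("Power-law coefficients must be finite.")
  if (!(KCl_min_mM > 0 && KCl_max_mM > KCl_min_mM))
    abort("The KCl domain must be non-degenerate and positive.")
  out <- tibble::tibble(quantity = quantity, slope = slope,
                        intercept = intercept, KCl_min_mM = KCl_min_mM,
                        KCl_max_mM = KCl_max_mM)
  class(out) <- c("power_law", class(out))
  out
}

#' Fit a log-log ionic-strength law to measured parameter values
#'
#' Least squares on `(log10 KCl, log10 value)`; with exactly two points the
#' line interpolates them exactly. All values and concentrations must be
#' positive (the law lives on the log scale).
#'
#' @param points A data frame with columns `KCl_mM` and `value` (>= 2 rows,
#'   all positive).
#' @param quantity Label for the parameter the law describes.
#' @return A one-row `power_law` tibble with `slope`, `intercept`, the fitted
#'   domain and `r_squared` (NA for two-point laws).
#' @examples
#' fit_power_law(data.frame(KCl_mM = c(40, 150), value = c(0.20, 920)),
#'               "k_off_N")
#' @export
fit_power_law <- function(points, quantity) {
  if (!all(c("KCl_mM", "value") %in% names(points)))
    abort("`points` needs columns `KCl_mM` and `value`.")
  if (nrow(points) < 2)
    abort("A power law needs at least 2 points.")
  if (any(points$KCl_mM <= 0) || any(points$value <= 0))
    abort("Power laws are fit on log scales; all KCl and values must be > 0.")
  if (length(unique(points$KCl_mM)) < 2)
    abort("Need at least 2 distinct KCl concentrations.")
  x <- log10(points$KCl_mM)
  y <- log10(points$value)
  fit <- lm(y ~ x)
  law <- power_law(quantity, unname(coef(fit)[2]), unname(coef(fit)[1]),
                   min(points$KCl_mM), max(points$KCl_mM))
  # exact (two-point or perfectly collinear) laws trip lm's perfect-fit
  # caution; the slope/intercept themselves are what we keep
  law$r_squared <- if (nrow(points) > 2)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  law
}

#' Evaluate an ionic-strength power law
#'
#' @param law A one-row `power_law` tibble.
#' @param KCl_mM KCl concentrations, mM (> 0); vectorized. Queries outside
#'   the law's fitted domain are answered but raise an extrapolation
#'   warning.
#' @return Parameter value(s) `10^(slope * log10(KCl_mM) + intercept)`.
#' @export
eval_power_law <- function(law, KCl_mM) {
  stopifnot(nrow(law) == 1L)
  if (any(KCl_mM <= 0)) abort("`KCl_mM` must be > 0.")
  outside <- KCl_mM < law$KCl_min_mM | KCl_mM > law$KCl_max_mM
  if (any(outside))
    warn(sprintf(
      "Extrapolating the %s law outside its fitted domain [%g, %g] mM KCl.",
      law$quantity, law$KCl_min_mM, law$KCl_max_mM))
  10^(law$slope * log10(KCl_mM) + law$intercept)
}

laws_lookup <- function(laws) {
  need <- c("D1", "k_off_N", "k_IT_N", "K_d_N")
  missing_q <- setdiff(need, laws$quantity)
  if (length(missing_q))
    abort(paste("Profile needs laws for all four parameters; missing:",
                paste(missing_q, collapse = ", ")))
  setNames(lapply(need, function(q) laws[laws$quantity == q, ][1, ]), need)
}

params_at_KCl <- function(lk, KCl, phi) {
  suppressWarnings(nonspecific_params(
    D1 = eval_power_law(lk$D1, KCl),
    k_off_N = eval_power_law(lk$k_off_N, KCl),
    k_IT_N = eval_power_law(lk$k_IT_N, KCl),
    K_d_N = eval_power_law(lk$K_d_N, KCl),
    phi = phi
  ))
}

#' Antenna/trapping/transfer decomposition across ionic strength
#'
#' Evaluates the four ionic-strength power laws at each KCl grid point,
#' builds the microscopic parameter set, and computes the full search-rate
#' decomposition ([search_decompose()]) at a fixed assay condition: the
#' profile of the antenna size `S`, untrapped fraction `rho`, transfer
#' enhancement `eta`, intrinsic rate `k_on_N = k_off_N / K_d_N` and composed
#' `k_a = rho * eta * S * k_on_N` as functions of KCl.
#'
#' @param laws A `power_law` tibble (rows for `D1`, `k_off_N`, `k_IT_N`,
#'   `K_d_N`), e.g. from [fit_power_law()] stacked with
#'   [dplyr::bind_rows()].
#' @param condition A single-row [assay_condition()]; the default is the
#'   113-bp probe at 2.5 nM with 2 uM of 28-bp competitor.
#' @param KCl_mM Strictly increasing grid, mM, within 20-500.
#' @param phi Orientations per site (default 2).
#' @return A tibble of class `ionic_profile`: one row per grid point with
#'   the four parameter values, `lambda_bp`, `tau_N_s`, `S`, `rho`, `eta`,
#'   `k_on_N` and `k_a`. The laws and condition travel along as attributes
#'   so [find_optimum()] can refine between grid points.
#' @export
decomposition_profile <- function(laws,
                                  condition = assay_condition(
                                    113, D_tot_M = 2.5e-9, C_tot_M = 2e-6),
                                  KCl_mM = seq(40, 400, by = 5), phi = 2) {
  stopifnot(nrow(condition) == 1L)
  if (any(diff(KCl_mM) <= 0)) abort("`KCl_mM` grid must be strictly increasing.")
  if (min(KCl_mM) < 20 || max(KCl_mM) > 500)
    abort("Profile grid outside the supported 20-500 mM KCl range.")
  lk <- laws_lookup(laws)
  vals <- suppressWarnings(purrr::map(lk, eval_power_law, KCl_mM = KCl_mM))
  dec <- eval_decomposition(
    vals$D1, vals$k_off_N, vals$k_IT_N, vals$K_d_N, phi,
    L = site_count(condition$probe_len_bp, condition$footprint_bp),
    M = site_count(condition$competitor_len_bp, condition$footprint_bp),
    target_pos = condition$target_pos,
    D_tot = condition$D_tot_M, C_tot = condition$C_tot_M
  )
  rows <- dplyr::bind_cols(
    tibble::tibble(KCl_mM = KCl_mM, D1 = vals$D1, k_off_N = vals$k_off_N,
                   k_IT_N = vals$k_IT_N, K_d_N = vals$K_d_N),
    dec[c("lambda_bp", "tau_N_s", "S", "rho", "eta", "k_on_N", "k_a")]
  )
  structure(rows, class = c("ionic_profile", class(rows)),
            laws = laws, condition = condition, phi = phi)
}

#' Ionic strength of fastest target search
#'
#' Locates the maximum of the composed `k_a(KCl)` in an ionic profile from
#' [decomposition_profile()]: the grid argmax, refined by continuous
#' golden-section search between the bracketing grid points. A maximum on
#' the edge of the grid is flagged as a boundary (the true optimum may lie
#' outside the profiled range); a profile with several interior local maxima
#' is flagged non-unimodal and the global grid maximum is returned.
#'
#' @param profile An `ionic_profile` tibble (>= 5 grid points).
#' @return A one-row tibble: `KCl_opt_mM`, `k_a_opt`, `boundary`,
#'   `unimodal`.
#' @export
find_optimum <- function(profile) {
  stopifnot(inherits(profile, "ionic_profile"))
  if (nrow(profile) < 5)
    abort("Need a profile with at least 5 grid points.")
  ka <- profile$k_a
  grid <- profile$KCl_mM
  i <- which.max(ka)
  boundary <- i == 1L || i == nrow(profile)
  sign_changes <- diff(sign(diff(ka)))
  n_local_max <- sum(sign_changes < 0)
  unimodal <- n_local_max <= 1L
  if (!unimodal)
    warn("k_a(KCl) profile is not unimodal; returning the global grid maximum.")
  KCl_opt <- grid[i]
  k_a_opt <- ka[i]
  if (!boundary && unimodal) {
    lk <- laws_lookup(attr(profile, "laws"))
    cond <- attr(profile, "condition")
    phi <- attr(profile, "phi")
    ka_cont <- function(s) decompose_core(params_at_KCl(lk, s, phi), cond)$k_a
    opt <- optimize(ka_cont, lower = grid[i - 1L], upper = grid[i + 1L],
                    maximum = TRUE, tol = 1e-6)
    # the refinement must never fall below the best grid value
    if (opt$objective >= k_a_opt) {
      KCl_opt <- opt$maximum
      k_a_opt <- opt$objective
    }
  }
  tibble::tibble(KCl_opt_mM = KCl_opt, k_a_opt = k_a_opt,
                 boundary = boundary, unimodal = unimodal)
}
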