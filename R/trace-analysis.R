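#' Mono-exponential fit of a stopped-flow fluorescence trace
#'
#' Under pseudo-first-order conditions (probe << protein << competitor) the
#' target-association time course is mono-exponential,
#' `I(t) = I_inf + (I0 - I_inf) exp(-k_app t)`. This fits the apparent rate
#' constant `k_app` by nonlinear least squares. The sign of the amplitude is
#' free: fluorescence may rise or fall on binding.
#'
#' Starting values are derived from the data (plateau from the tail mean,
#' initial intensity from the first point, rate from a log-linearized early
#' decay), with a multi-start fallback over a rate grid when the first
#' attempt fails to converge.
#'
#' @param trace A data frame with numeric columns `time_s` (strictly
#'   increasing, >= 0) and `intensity` (arbitrary units); at least 10 points.
#' @param label Optional trace label used in error messages and reports.
#' @return An object of class `monoexp_fit` with elements `k_app` (1/s),
#'   `I0`, `I_inf`, their standard errors, `rss`, `converged`, `n`, `label`
#'   and the underlying Levenberg-Marquardt fit. [tidy()], [glance()],
#'   [augment()] and [autoplot()] methods are provided.
#' @examples
#' tr <- gen_trace(k_app = 0.05, n_points = 100, t_max = 100)
#' fit_monoexp(tr)
#' @export
fit_monoexp <- function(trace, label = NULL) {
  trace <- validate_trace(trace, label)
  t <- trace$time_s
  I <- trace$intensity
  amp_scale <- diff(range(I))
  if (amp_scale <= 0 || amp_scale < 1e-12 * max(abs(I), 1))
    abort(trace_msg("Trace intensity is constant; no kinetics to fit", label))

  n_tail <- max(3L, ceiling(length(I) * 0.2))
  I_inf0 <- mean(tail(I, n_tail))
  I00 <- I[1]
  k0 <- init_rate(t, I, I00, I_inf0)
  starts <- unique(c(k0, k0 * c(0.1, 10), 1 / max(t), 10 / max(t)))

  # parameters (I_inf, I0, log k): the rate stays positive by construction
  resid_fn <- function(p) I - (p[1] + (p[2] - p[1]) * exp(-exp(p[3]) * t))
  best <- NULL
  for (k_start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(I_inf0, I00, log(k_start)), fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    abort(trace_msg("Mono-exponential fit failed to converge", label))
  k_app <- exp(best$par[3])
  # a trace that never curves (rate pinned at ~0) carries no rate information
  if (k_app * max(t) < 1e-6)
    abort(trace_msg("Trace shows no measurable decay over the observed window",
                    label))
  J <- num_jacobian(resid_fn, best$par)
  sigma2 <- best$deviance / (length(t) - 3)
  se <- tryCatch(sqrt(pmax(diag(solve(crossprod(J))) * sigma2, 0)),
                 error = function(e) rep(NA_real_, 3))
  structure(
    list(k_app = k_app, I0 = best$par[2], I_inf = best$par[1],
         se_k_app = k_app * se[3], se_I0 = se[2], se_I_inf = se[1],
         rss = best$deviance, converged = TRUE, n = length(t), label = label,
         fit = best, data = tibble::as_tibble(trace)),
    class = "monoexp_fit"
  )
}

validate_trace <- function(trace, label = NULL) {
  if (!all(c("time_s", "intensity") %in% names(trace)))
    abort("A trace needs columns `time_s` and `intensity`.")
  trace <- tibble::as_tibble(trace)
  if (nrow(trace) < 10)
    abort(trace_msg("A trace needs at least 10 points", label))
  if (any(!is.finite(trace$time_s)) || any(!is.finite(trace$intensity)))
    abort(trace_msg("Trace contains non-finite values", label))
  if (any(diff(trace$time_s) <= 0) || trace$time_s[1] < 0)
    abort(trace_msg("`time_s` must be strictly increasing and >= 0", label))
  trace
}

trace_msg <- function(msg, label) {
  if (is.null(label)) paste0(msg, ".") else sprintf("%s (trace '%s').", msg, label)
}

# rate guess from log-linearized early decay toward the tail plateau
init_rate <- function(t, I, I0, I_inf) {
  resid <- I - I_inf
  sgn <- sign(I0 - I_inf)
  use <- which(sgn * resid > 0.05 * abs(I0 - I_inf))
  use <- use[use <= ceiling(length(t) * 0.7)]
  if (length(use) >= 3) {
    sl <- coef(lm(log(sgn * resid[use]) ~ t[use]))[2]
    if (is.finite(sl) && sl < 0) return(unname(-sl))
  }
  3 / max(t)
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat("<monoexp_fit>", if (!is.null(x$label)) sprintf("'%s'", x$label), "\n")
  cat(sprintf("  k_app = %.6g 1/s  (I0 = %.4g, I_inf = %.4g, n = %d, rss = %.4g)\n",
              x$k_app, x$I0, x$I_inf, x$n, x$rss))
  invisible(x)
}

#' Apparent second-order rate constant from a protein titration
#'
#' Under pseudo-first-order conditions the apparent rate constant grows
#' linearly with protein concentration, `k_app = k_a P_tot (+ intercept)`.
#' This fits the line by (optionally `1/se^2`-weighted) linear regression;
#' the slope is the apparent association rate constant `k_a` (M^-1 s^-1).
#' The intercept term absorbs any back reaction (target dissociation); the
#' zero-intercept convention is available with `intercept = FALSE`.
#'
#' @param series A data frame with columns `P_tot_M` (> 0, molar) and
#'   `k_app_per_s`; optional `se_per_s` enables weighting.
#' @param intercept Include an intercept term (default `TRUE`). With an
#'   intercept at least 3 distinct protein concentrations are required;
#'   without, 2.
#' @param weighted Weight by `1/se^2` when `se_per_s` is present (default
#'   `TRUE` if the column exists). Supplied SEs are treated as absolute
#'   uncertainties: the slope standard error is then `sqrt((X'WX)^-1)`
#'   without rescaling by the reduced chi-square.
#' @return An object of class `titration_fit` with elements `k_a`, `se`,
#'   `intercept`, `intercept_se`, `rss`, `n` and the underlying `lm` fit;
#'   `tidy()`/`glance()` methods are provided.
#' @examples
#' ti <- gen_titration(k_a_true = 2e8)
#' fit_titration(ti)
#' @export
fit_titration <- function(series, intercept = TRUE, weighted = NULL) {
  if (!all(c("P_tot_M", "k_app_per_s") %in% names(series)))
    abort("A titration needs columns `P_tot_M` and `k_app_per_s`.")
  series <- tibble::as_tibble(series)
  if (any(series$P_tot_M <= 0)) abort("All `P_tot_M` must be > 0.")
  n_distinct <- length(unique(series$P_tot_M))
  need <- if (intercept) 3L else 2L
  if (n_distinct < need)
    abort(sprintf("Need >= %d distinct protein concentrations (%s intercept); got %d.",
                  need, if (intercept) "with" else "without", n_distinct))
  has_se <- "se_per_s" %in% names(series) && all(is.finite(series$se_per_s)) &&
    all(series$se_per_s > 0)
  weighted <- weighted %||% has_se
  if (weighted && !has_se)
    abort("Weighted fit requested but no usable `se_per_s` column.")
  w <- if (weighted) 1 / series$se_per_s^2 else NULL
  fml <- if (intercept) k_app_per_s ~ P_tot_M else k_app_per_s ~ P_tot_M + 0
  fit <- lm(fml, data = series, weights = w)
  # noiseless synthetic series fit exactly; that "perfect fit" caution from
  # summary.lm is expected there, not actionable
  cf <- coef(suppressWarnings(summary(fit)))
  if (weighted) {
    # supplied SEs are absolute uncertainties: parameter covariance is
    # (X' W X)^-1 without rescaling by the reduced chi-square
    X <- stats::model.matrix(fit)
    cv <- solve(crossprod(X * sqrt(w), X * sqrt(w)))
    cf[, "Std. Error"] <- sqrt(diag(cv))
  }
  structure(
    list(k_a = cf["P_tot_M", "Estimate"], se = cf["P_tot_M", "Std. Error"],
         intercept = if (intercept) cf["(Intercept)", "Estimate"] else 0,
         intercept_se = if (intercept) cf["(Intercept)", "Std. Error"] else NA_real_,
         rss = sum(residuals(fit)^2), n = nrow(series),
         weighted = weighted, has_intercept = intercept,
         fit = fit, data = series),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit>\n")
  cat(sprintf("  k_a = %.6g +/- %.3g 1/(M s)  [slope of k_app vs P_tot, n = %d]\n",
              x$k_a, x$se, x$n))
  if (x$has_intercept)
    cat(sprintf("  intercept = %.4g +/- %.3g 1/s\n", x$intercept, x$intercept_se))
  invisible(x)
}
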