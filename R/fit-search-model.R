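# Stage 2 of the pipeline: nonlinear least-squares estimation of the
# microscopic search parameters from k_a series. All rate/diffusion
# parameters are fitted in natural-log space (positivity without
# constraints); optimization is Levenberg-Marquardt from a deterministic
# log-spaced multi-start grid; standard errors come from the Gauss-Newton
# covariance at the optimum (delta method back to the natural scale).

# k_a model for a length series under the length-fit convention
# tau_N = lambda^2 / D1 (lifetime treated as length-independent, so the
# series never references k_off_N / k_IT_N).
ka_model_length <- function(D1, lambda, L, fx) {
  tau <- lambda^2 / D1
  S <- antenna_size(lambda, L, fx$target_pos)
  denom <- fx$K_d_N + (fx$phi * L - S) * fx$D_tot_M +
    fx$phi * fx$M_sites * fx$C_tot_M
  S / denom / tau
}

# full model: lifetime from the rate constants at each point's concentrations
ka_model_rates <- function(D1, k_off, k_IT, L, C_tot, fx) {
  site_conc <- fx$phi * (L * fx$D_tot_M + fx$M_sites * C_tot)
  tau <- 1 / (k_off + k_IT * site_conc)
  lambda <- sqrt(D1 * tau)
  S <- antenna_size(lambda, L, fx$target_pos)
  denom <- fx$K_d_N + (fx$phi * L - S) * fx$D_tot_M + fx$phi * fx$M_sites * C_tot
  S / denom / tau
}

# deterministic multi-start Levenberg-Marquardt over log-parameters
ls_multistart <- function(resid_fn, start_grid) {
  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    p0 <- log(as.numeric(start_grid[i, ]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$deviance) best <- fit
  }
  if (is.null(best))
    abort("Nonlinear least-squares failed from every start of the grid.")
  best
}

# central-difference Jacobian of the residual vector wrt log-parameters
num_jacobian <- function(resid_fn, par, h = 1e-6) {
  r0 <- resid_fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  J
}

gn_standard_errors <- function(resid_fn, par_log, n_par_free) {
  r <- resid_fn(par_log)
  dof <- length(r) - n_par_free
  sigma2 <- if (dof > 0) sum(r^2) / dof else NA_real_
  J <- num_jacobian(resid_fn, par_log)
  se_log <- rep(NA_real_, length(par_log))
  cv <- tryCatch(chol2inv(chol(crossprod(J))),
                 error = function(e) MASS::ginv(crossprod(J)))
  if (is.finite(sigma2))
    se_log <- sqrt(pmax(diag(cv) * sigma2, 0))
  se_log
}

new_search_fit <- function(terms, par_log, se_log, rss, fixed, variant,
                           data, predict_fn, n_obs, obs, w, model_log_fn) {
  est <- exp(par_log)
  estimates <- tibble::tibble(
    term = terms,
    estimate = est,
    se = est * se_log,                 # delta method from log scale
    se_log10 = se_log / log(10),
    identifiable = is.finite(se_log) & se_log / log(10) < 1
  )
  structure(
    list(estimates = estimates, fixed = fixed, rss = rss, variant = variant,
         converged = TRUE, n = n_obs, data = data, predict_fn = predict_fn,
         par_log = par_log, obs = obs, w = w, model_log_fn = model_log_fn),
    class = "search_fit"
  )
}

#' Seeded residual-bootstrap standard errors for a search-model fit
#'
#' Alternative to the default Gauss-Newton covariance: resamples the fit
#' residuals with replacement, adds them back onto the fitted curve, refits
#' (Levenberg-Marquardt started from the optimum) and reports the standard
#' deviation of the bootstrap estimates for each parameter.
#'
#' @param fit A `search_fit` object.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed (mandatory; the resampling is stochastic).
#' @return A tibble with columns `term`, `estimate`, `se_boot`.
#' @export
bootstrap_se <- function(fit, n_boot = 200, seed = 1) {
  stopifnot(inherits(fit, "search_fit"), n_boot >= 2)
  seed_guard(seed)
  fitted <- fit$model_log_fn(fit$par_log)
  res <- fit$obs - fitted
  boots <- matrix(NA_real_, n_boot, length(fit$par_log))
  for (b in seq_len(n_boot)) {
    obs_b <- fitted + sample(res, replace = TRUE)
    refit <- tryCatch(
      minpack.lm::nls.lm(par = fit$par_log,
                         fn = function(p) fit$w * (obs_b - fit$model_log_fn(p)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (!is.null(refit)) boots[b, ] <- exp(refit$par)
  }
  tibble::tibble(
    term = fit$estimates$term,
    estimate = fit$estimates$estimate,
    se_boot = apply(boots, 2, sd, na.rm = TRUE)
  )
}

#' @export
print.search_fit <- function(x, ...) {
  cat(sprintf("<search_fit> variant = %s, n = %d, rss = %.6g\n",
              x$variant, x$n, x$rss))
  df <- as.data.frame(x$estimates)
  df$estimate <- signif(df$estimate, 6)
  df$se <- signif(df$se, 3)
  print(df, row.names = FALSE)
  if (any(!x$estimates$identifiable))
    cat("  note: parameters with se_log10 >= 1 are practically unidentifiable",
        "from this design.\n")
  invisible(x)
}

#' Predicted rate constants from a fitted search model
#' @param object A `search_fit` object.
#' @param newdata Optional data frame with the fit's covariate column;
#'   defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of model `k_a` values.
#' @export
predict.search_fit <- function(object, newdata = NULL, ...) {
  object$predict_fn(newdata %||% object$data)
}

fixed_from_condition <- function(condition, K_d_N, phi) {
  validate_assay_condition(condition)
  stopifnot(nrow(condition) == 1L, is.numeric(K_d_N), K_d_N > 0)
  list(
    K_d_N = K_d_N, phi = phi,
    footprint_bp = condition$footprint_bp,
    target_pos = condition$target_pos,
    D_tot_M = condition$D_tot_M, C_tot_M = condition$C_tot_M,
    M_sites = site_count(condition$competitor_len_bp, condition$footprint_bp),
    L_sites = site_count(condition$probe_len_bp, condition$footprint_bp)
  )
}

prep_weights <- function(data, weighted) {
  if (!weighted) return(rep(1, nrow(data)))
  if (!"se" %in% names(data) || any(!is.finite(data$se)) || any(data$se <= 0))
    abort("Weighted fit requested but no usable `se` column in the data.")
  1 / data$se
}

#' Sliding parameters from the DNA-length dependence of the search rate
#'
#' Estimates the one-dimensional diffusion coefficient `D1` and the effective
#' sliding length `lambda` from apparent rate constants `k_a` measured with
#' probe duplexes of different lengths at fixed concentrations. In this fit
#' the nonspecific lifetime is tied to the two parameters as
#' `tau_N = lambda^2 / D1`, so the length series never references the
#' dissociation or transfer rate constants; the (weak) concentration
#' dependence of the lifetime across the fixed-competitor series is absorbed
#' into `lambda`.
#'
#' @param data A data frame with columns `probe_len_bp` (or `n_sites`) and
#'   `k_a` (M^-1 s^-1); optional `se` enables `weighted = TRUE`. At least 3
#'   distinct lengths.
#' @param K_d_N Fixed per-site nonspecific dissociation constant, M.
#' @param condition Single-row [assay_condition()] giving the shared
#'   geometry and concentrations (its `probe_len_bp` is ignored; the
#'   covariate supplies it). Default: the 113-bp / 2.5 nM probe, 28-bp /
#'   2 uM competitor design.
#' @param phi Orientations per site (default 2).
#' @param weighted Minimize `sum(((obs - model)/se)^2)` instead of the
#'   unweighted sum of squares.
#' @return A `search_fit` object with estimates for `D1` (bp^2/s) and
#'   `lambda` (bp), Gauss-Newton standard errors, an identifiability flag
#'   per parameter, the fixed-parameter record and the residual sum of
#'   squares. `tidy()`/`glance()`/`autoplot()` methods apply.
#' @examples
#' p <- nonspecific_params(2.7e6, 920, 1.15e7, 16e-6)
#' d <- gen_rate_dataset(p, covariate = "length")
#' fit_length_dependence(d, K_d_N = 16e-6)
#' @export
fit_length_dependence <- function(data, K_d_N,
                                  condition = assay_condition(
                                    113, D_tot_M = 2.5e-9, C_tot_M = 2e-6),
                                  phi = 2, weighted = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"n_sites" %in% names(data)) {
    if (!"probe_len_bp" %in% names(data))
      abort("Length data needs a `probe_len_bp` (bp) or `n_sites` column.")
    data$n_sites <- site_count(data$probe_len_bp, condition$footprint_bp)
  }
  if (!"k_a" %in% names(data)) abort("Length data needs a `k_a` column.")
  if (length(unique(data$n_sites)) < 3)
    abort("Need >= 3 distinct probe lengths to fit (D1, lambda).")
  fx <- fixed_from_condition(condition, K_d_N, phi)
  L <- data$n_sites
  w <- prep_weights(data, weighted)
  obs <- data$k_a

  model_log_fn <- function(p) ka_model_length(exp(p[1]), exp(p[2]), L, fx)
  resid_fn <- function(p) w * (obs - model_log_fn(p))
  # profile starts: given lambda, the model is linear in D1, so the
  # conditionally optimal D1 is closed-form; polish the 5x5 grid around it
  lam_grid <- 10^seq(log10(0.5), log10(5 * max(L)), length.out = 5)
  starts <- purrr::map_dfr(lam_grid, function(lam) {
    f1 <- ka_model_length(1, lam, L, fx)
    D1_opt <- max(sum(w^2 * obs * f1) / sum(w^2 * f1^2), 1e-12)
    tibble::tibble(D1 = D1_opt * c(0.04, 0.2, 1, 5, 25), lambda = lam)
  })
  best <- ls_multistart(resid_fn, starts)
  se_log <- gn_standard_errors(resid_fn, best$par, 2L)
  pred_fn <- function(nd) {
    Lq <- if ("n_sites" %in% names(nd)) nd$n_sites
          else site_count(nd$probe_len_bp, fx$footprint_bp)
    ka_model_length(exp(best$par[1]), exp(best$par[2]), Lq, fx)
  }
  new_search_fit(c("D1", "lambda"), best$par, se_log, best$deviance,
                 fx, "length", data, pred_fn, nrow(data),
                 obs, w, model_log_fn)
}

#' Dissociation and intersegment-transfer rates from competitor dependence
#'
#' Estimates `k_off_N` and `k_IT_N` from apparent rate constants measured at
#' different nonspecific-competitor concentrations with a fixed probe. In
#' this fit the nonspecific lifetime, sliding length and antenna size all
#' vary with `C_tot` through
#' `tau_N = 1/(k_off_N + k_IT_N (phi L D_tot + phi M C_tot))`,
#' `lambda = sqrt(D1 tau_N)`; the diffusion coefficient `D1` is supplied
#' (typically from [fit_length_dependence()]). The `"without_IT"` variant
#' pins `k_IT_N = 0` (the nested no-transfer model) and fits `k_off_N` only.
#'
#' @param data A data frame with columns `C_tot_M` and `k_a`; optional `se`.
#'   The concentrations must span at least a 4-fold range (identifiability
#'   floor for separating the two rate constants).
#' @param D1 Fixed one-dimensional diffusion coefficient, bp^2/s.
#' @param variant `"with_IT"` (both rates) or `"without_IT"` (`k_IT_N = 0`).
#' @inheritParams fit_length_dependence
#' @return A `search_fit` object; the variant and any pinned parameter are
#'   recorded in `variant` and `fixed`.
#' @examples
#' p <- nonspecific_params(2.7e6, 920, 1.15e7, 16e-6)
#' d <- gen_rate_dataset(p, covariate = "competitor")
#' fit_competition(d, D1 = 2.7e6, K_d_N = 16e-6)
#' @export
fit_competition <- function(data, D1, K_d_N,
                            condition = assay_condition(
                              113, D_tot_M = 2.5e-9, C_tot_M = 2e-6),
                            variant = c("with_IT", "without_IT"),
                            phi = 2, weighted = FALSE) {
  variant <- match.arg(variant)
  data <- tibble::as_tibble(data)
  if (!all(c("C_tot_M", "k_a") %in% names(data)))
    abort("Competition data needs columns `C_tot_M` and `k_a`.")
  n_par <- if (variant == "with_IT") 2L else 1L
  if (length(unique(data$C_tot_M)) < n_par + 1L)
    abort("Too few distinct competitor concentrations for this fit.")
  if (max(data$C_tot_M) / min(data$C_tot_M) < 4)
    abort(paste("Competitor concentrations span less than 4-fold;",
                "k_off_N and k_IT_N are not separable from such a design."))
  stopifnot(is.numeric(D1), D1 > 0)
  fx <- fixed_from_condition(condition, K_d_N, phi)
  L <- fx$L_sites
  C <- data$C_tot_M
  w <- prep_weights(data, weighted)
  obs <- data$k_a

  if (variant == "with_IT") {
    model_log_fn <- function(p) ka_model_rates(D1, exp(p[1]), exp(p[2]), L, C, fx)
    resid_fn <- function(p) w * (obs - model_log_fn(p))
    starts <- tidyr::expand_grid(
      k_off_N = 10^seq(-2, 6, length.out = 5),
      k_IT_N = 10^seq(3, 10, length.out = 5)
    )
    best <- ls_multistart(resid_fn, starts)
    se_log <- gn_standard_errors(resid_fn, best$par, 2L)
    pred_fn <- function(nd)
      ka_model_rates(D1, exp(best$par[1]), exp(best$par[2]), L, nd$C_tot_M, fx)
    fx$D1 <- D1
    new_search_fit(c("k_off_N", "k_IT_N"), best$par, se_log, best$deviance,
                   fx, "with_IT", data, pred_fn, nrow(data),
                   obs, w, model_log_fn)
  } else {
    model_log_fn <- function(p) ka_model_rates(D1, exp(p[1]), 0, L, C, fx)
    resid_fn <- function(p) w * (obs - model_log_fn(p))
    starts <- tibble::tibble(k_off_N = 10^seq(-2, 6, length.out = 25))
    best <- ls_multistart(resid_fn, starts)
    se_log <- gn_standard_errors(resid_fn, best$par, 1L)
    pred_fn <- function(nd)
      ka_model_rates(D1, exp(best$par[1]), 0, L, nd$C_tot_M, fx)
    fx$D1 <- D1
    fx$k_IT_N <- 0
    new_search_fit("k_off_N", best$par, se_log, best$deviance,
                   fx, "without_IT", data, pred_fn, nrow(data),
                   obs, w, model_log_fn)
  }
}

#' Simultaneous fit of sliding, dissociation and transfer parameters
#'
#' Joint nonlinear least squares over a DNA-length series and a
#' competitor-concentration series sharing one parameter set
#' `(D1, k_off_N, k_IT_N)`. In the joint model the lifetime is everywhere
#' `tau_N = 1/(k_off_N + k_IT_N (phi L D_tot + phi M C_tot))` evaluated at
#' each point's own geometry and concentrations, and
#' `lambda = sqrt(D1 tau_N)`. Length data alone cannot constrain three
#' parameters and is rejected.
#'
#' @param length_data As in [fit_length_dependence()].
#' @param competition_data As in [fit_competition()]; required.
#' @inheritParams fit_length_dependence
#' @return A `search_fit` object with estimates for `D1`, `k_off_N`,
#'   `k_IT_N`.
#' @export
fit_simultaneous <- function(length_data, competition_data, K_d_N,
                             condition = assay_condition(
                               113, D_tot_M = 2.5e-9, C_tot_M = 2e-6),
                             phi = 2, weighted = FALSE) {
  if (missing(competition_data) || is.null(competition_data))
    abort(paste("The simultaneous fit estimates three parameters and needs",
                "both a length series and a competitor series; length data",
                "alone is an insufficient design."))
  length_data <- tibble::as_tibble(length_data)
  competition_data <- tibble::as_tibble(competition_data)
  fx <- fixed_from_condition(condition, K_d_N, phi)
  if (!"n_sites" %in% names(length_data))
    length_data$n_sites <- site_count(length_data$probe_len_bp, fx$footprint_bp)
  if (!all(c("C_tot_M", "k_a") %in% names(competition_data)))
    abort("Competition data needs columns `C_tot_M` and `k_a`.")
  L_len <- length_data$n_sites
  obs <- c(length_data$k_a, competition_data$k_a)
  w <- c(prep_weights(length_data, weighted),
         prep_weights(competition_data, weighted))

  model_all <- function(D1, k_off, k_IT) {
    c(ka_model_rates(D1, k_off, k_IT, L_len, fx$C_tot_M, fx),
      ka_model_rates(D1, k_off, k_IT, fx$L_sites, competition_data$C_tot_M, fx))
  }
  model_log_fn <- function(p) model_all(exp(p[1]), exp(p[2]), exp(p[3]))
  resid_fn <- function(p) w * (obs - model_log_fn(p))
  starts <- tidyr::expand_grid(
    D1 = 10^seq(2, 8, length.out = 5),
    k_off_N = 10^seq(-1, 5, length.out = 5),
    k_IT_N = 10^seq(4, 9, length.out = 5)
  )
  best <- ls_multistart(resid_fn, starts)
  se_log <- gn_standard_errors(resid_fn, best$par, 3L)
  joint_data <- dplyr::bind_rows(
    dplyr::mutate(length_data, series = "length"),
    dplyr::mutate(competition_data, series = "competitor")
  )
  pred_fn <- function(nd) {
    est <- exp(best$par)
    out <- numeric(nrow(nd))
    is_len <- nd$series == "length"
    if (any(is_len))
      out[is_len] <- ka_model_rates(est[1], est[2], est[3],
                                    nd$n_sites[is_len], fx$C_tot_M, fx)
    if (any(!is_len))
      out[!is_len] <- ka_model_rates(est[1], est[2], est[3], fx$L_sites,
                                     nd$C_tot_M[!is_len], fx)
    out
  }
  new_search_fit(c("D1", "k_off_N", "k_IT_N"), best$par, se_log,
                 best$deviance, fx, "simultaneous", joint_data, pred_fn,
                 nrow(joint_data), obs, w, model_log_fn)
}
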