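# broom-style tidy()/glance()/augment() methods for the fitted objects

#' @export
tidy.monoexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_app", "I0", "I_inf"),
    estimate = c(x$k_app, x$I0, x$I_inf),
    std.error = c(x$se_k_app, x$se_I0, x$se_I_inf)
  )
}

#' @export
glance.monoexp_fit <- function(x, ...) {
  tibble::tibble(k_app = x$k_app, rss = x$rss, n = x$n,
                 converged = x$converged)
}

#' @export
augment.monoexp_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = x$I_inf + (x$I0 - x$I_inf) * exp(-x$k_app * .data$time_s),
                .resid = .data$intensity - .data$.fitted)
}

#' @export
tidy.titration_fit <- function(x, ...) {
  out <- tibble::tibble(term = "k_a", estimate = x$k_a, std.error = x$se)
  if (x$has_intercept)
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "intercept", estimate = x$intercept, std.error = x$intercept_se))
  out
}

#' @export
glance.titration_fit <- function(x, ...) {
  tibble::tibble(k_a = x$k_a, se = x$se, rss = x$rss, n = x$n,
                 weighted = x$weighted, has_intercept = x$has_intercept)
}

#' @export
tidy.search_fit <- function(x, ...) {
  dplyr::rename(x$estimates, std.error = "se")
}

#' @export
glance.search_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, rss = x$rss, n = x$n,
                 converged = x$converged,
                 n_param = nrow(x$estimates))
}

#' @export
augment.search_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = predict(x),
                .resid = .data$k_a - .data$.fitted)
}
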