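# ggplot2 views of the fitted objects and profiles

#' @export
autoplot.monoexp_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), color = "firebrick") +
    ggplot2::labs(
      x = "time (s)", y = "fluorescence (a.u.)",
      title = sprintf("Mono-exponential fit: k_app = %.4g 1/s", object$k_app)
    )
}

#' @export
autoplot.titration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$P_tot_M * 1e9,
                               y = .data$k_app_per_s)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$k_a * 1e-9,
                         intercept = object$intercept,
                         color = "firebrick") +
    ggplot2::labs(x = "P_tot (nM)", y = "k_app (1/s)",
                  title = sprintf("k_a = %.3g 1/(M s)", object$k_a))
}

#' @export
autoplot.search_fit <- function(object, ...) {
  aug <- augment(object)
  if (object$variant == "length") {
    xvar <- "n_sites"; xlab <- "probe sites L"
  } else if (object$variant %in% c("with_IT", "without_IT")) {
    xvar <- "C_tot_M"; xlab <- "competitor C_tot (M)"
  } else {
    aug$covariate <- ifelse(aug$series == "length", aug$n_sites, aug$C_tot_M)
    xvar <- "covariate"; xlab <- "covariate (sites | M)"
  }
  p <- ggplot2::ggplot(aug, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data$k_a)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), color = "firebrick") +
    ggplot2::labs(x = xlab, y = "k_a (1/(M s))",
                  title = sprintf("Search-model fit (%s)", object$variant))
  if (object$variant == "simultaneous")
    p <- p + ggplot2::facet_wrap(~series, scales = "free_x")
  p
}

#' Plot an ionic-strength decomposition profile
#'
#' Shows the antenna size `S`, untrapped fraction `rho`, transfer
#' enhancement `eta` and composed `k_a` against KCl on log-log axes.
#'
#' @param object An `ionic_profile` from [decomposition_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ionic_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("KCl_mM", "S", "rho", "eta", "k_a")],
    cols = c("S", "rho", "eta", "k_a"),
    names_to = "factor", values_to = "value")
  long$factor <- factor(long$factor, levels = c("S", "rho", "eta", "k_a"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$KCl_mM, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "[KCl] (mM)", y = NULL,
                  title = "Antenna / trapping / transfer decomposition")
}
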