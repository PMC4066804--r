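test_that("noiseless length series returns the generating sliding parameters", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "length")
  truth <- attr(d, "truth")
  fit <- fit_length_dependence(d, K_d_N = p$K_d_N)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_rel(est[["D1"]], p$D1, 1e-3)
  expect_rel(est[["lambda"]], truth$lambda_bp, 1e-3)
  # the stored model reproduces the reported rss
  rss_re <- sum((d$k_a - predict(fit))^2)
  expect_lt(abs(rss_re - fit$rss), 1e-9 * max(fit$rss, 1e-30) + 1e-30)
})

test_that("a flat length dependence flags the sliding length as unidentifiable", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "length", lambda_bp = 1e6,
                        noise_frac = 0.05, seed = 11)
  fit <- fit_length_dependence(d, K_d_N = p$K_d_N)
  lam_row <- fit$estimates[fit$estimates$term == "lambda", ]
  expect_false(lam_row$identifiable)
})

test_that("noisy length series: median recovery and 2-SE coverage", {
  p <- study_params()
  lam_true <- attr(gen_rate_dataset(p, covariate = "length"), "truth")$lambda_bp
  res <- vapply(1:100, function(s) {
    d <- gen_rate_dataset(p, covariate = "length", noise_frac = 0.05,
                          seed = s)
    fit <- fit_length_dependence(d, K_d_N = p$K_d_N)
    e <- fit$estimates
    lam <- e$estimate[e$term == "lambda"]
    c(lam = lam, hit = abs(lam - lam_true) <= 2 * e$se[e$term == "lambda"])
  }, numeric(2))
  expect_rel(median(res["lam", ]), lam_true, 0.05)
  expect_gte(sum(res["hit", ]), 90)
})

test_that("noiseless competitor series returns both rate constants", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "competitor")
  fit <- fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_rel(est[["k_off_N"]], p$k_off_N, 5e-3)
  expect_rel(est[["k_IT_N"]], p$k_IT_N, 5e-3)
})

test_that("transfer-free truth yields a vanishing transfer estimate", {
  p0 <- nonspecific_params(2.7e6, 920, 0, 16e-6)
  d <- gen_rate_dataset(p0, covariate = "competitor")
  fit <- fit_competition(d, D1 = p0$D1, K_d_N = p0$K_d_N)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_rel(est[["k_off_N"]], 920, 1e-3)
  # transfer flux at the largest competitor load is negligible vs k_off_N
  expect_lt(est[["k_IT_N"]] * 2 * 20 * 16e-6, 1e-3 * 920)
})

test_that("the transfer model never fits worse than its nested reduction", {
  p <- study_params()
  for (s in 1:5) {
    d <- gen_rate_dataset(p, covariate = "competitor", noise_frac = 0.05,
                          seed = 100 + s)
    f_with <- fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N,
                              variant = "with_IT")
    f_without <- fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N,
                                 variant = "without_IT")
    expect_lte(f_with$rss, f_without$rss * (1 + 1e-10))
    expect_identical(f_without$fixed$k_IT_N, 0)
  }
})

test_that("narrow competitor designs are rejected", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "competitor",
                        design = c(1, 1.5, 2, 3) * 1e-6)
  expect_error(fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N),
               "4-fold")
})

test_that("joint fit recovers all three parameters from shared truth", {
  p <- study_params()
  dL <- gen_rate_dataset(p, covariate = "length", tau_model = "rates")
  dC <- gen_rate_dataset(p, covariate = "competitor")
  fit <- fit_simultaneous(dL, dC, K_d_N = p$K_d_N)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_rel(est[["D1"]], p$D1, 5e-3)
  expect_rel(est[["k_off_N"]], p$k_off_N, 5e-3)
  expect_rel(est[["k_IT_N"]], p$k_IT_N, 5e-3)
})

test_that("without transfer the joint fit matches the two-stage route", {
  p0 <- nonspecific_params(2.7e6, 920, 0, 16e-6)
  dL <- gen_rate_dataset(p0, covariate = "length", tau_model = "rates")
  dC <- gen_rate_dataset(p0, covariate = "competitor")
  joint <- fit_simultaneous(dL, dC, K_d_N = p0$K_d_N)
  stage1 <- fit_length_dependence(dL, K_d_N = p0$K_d_N)
  D1_two_stage <- stage1$estimates$estimate[stage1$estimates$term == "D1"]
  stage2 <- fit_competition(dC, D1 = D1_two_stage, K_d_N = p0$K_d_N)
  ej <- setNames(joint$estimates$estimate, joint$estimates$term)
  e2 <- setNames(stage2$estimates$estimate, stage2$estimates$term)
  expect_rel(ej[["D1"]], D1_two_stage, 0.01)
  expect_rel(ej[["k_off_N"]], e2[["k_off_N"]], 0.01)
})

test_that("length data alone cannot support the three-parameter fit", {
  p <- study_params()
  dL <- gen_rate_dataset(p, covariate = "length")
  expect_error(fit_simultaneous(dL, NULL, K_d_N = p$K_d_N),
               "insufficient design")
})

test_that("covariate units do not change the estimates", {
  p <- study_params()
  d_bp <- gen_rate_dataset(p, covariate = "length")
  d_sites <- dplyr::select(d_bp, n_sites, k_a)
  f1 <- fit_length_dependence(d_bp, K_d_N = p$K_d_N)
  f2 <- fit_length_dependence(d_sites, K_d_N = p$K_d_N)
  expect_equal(f1$estimates$estimate, f2$estimates$estimate,
               tolerance = 1e-10)
})

test_that("bootstrap and covariance uncertainties agree in order of magnitude", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "length", noise_frac = 0.05, seed = 21)
  fit <- fit_length_dependence(d, K_d_N = p$K_d_N)
  bs <- bootstrap_se(fit, n_boot = 100, seed = 2)
  expect_identical(bs$term, fit$estimates$term)
  ratio <- bs$se_boot / fit$estimates$se
  expect_true(all(ratio > 0.2 & ratio < 5))
})

test_that("search-fit tidiers report estimates and fit summary", {
  p <- study_params()
  d <- gen_rate_dataset(p, covariate = "competitor", noise_frac = 0.03,
                        seed = 8)
  fit <- fit_competition(d, D1 = p$D1, K_d_N = p$K_d_N)
  td <- tidy(fit)
  expect_setequal(td$term, c("k_off_N", "k_IT_N"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$variant, "with_IT")
  expect_identical(gl$n, 6L)
  aug <- augment(fit)
  expect_equal(sum(aug$.resid^2), fit$rss, tolerance = 1e-9)
})
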