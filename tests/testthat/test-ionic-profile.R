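test_that("two-point salt laws interpolate their anchors exactly", {
  law <- fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = c(0.20, 920)), "k_off_N")
  # slope of the printed dissociation endpoints: log10(920/0.20)/log10(150/40)
  expect_equal(law$slope, log10(4600) / log10(3.75), tolerance = 1e-12)
  expect_equal(eval_power_law(law, 40), 0.20, tolerance = 1e-10)
  expect_equal(eval_power_law(law, 150), 920, tolerance = 1e-10)
})

test_that("the five-point affinity law rises and reproduces each point", {
  law <- fit_power_law(kd_points(), "K_d_N")
  expect_gt(law$slope, 0)
  pred <- eval_power_law(law, kd_points()$KCl_mM)
  ratio <- pred / kd_points()$value
  expect_true(all(ratio < 2 & ratio > 0.5))
})

test_that("flat data give a zero slope and constant evaluation", {
  law <- fit_power_law(
    data.frame(KCl_mM = c(40, 80, 160), value = rep(5, 3)), "D1")
  expect_equal(law$slope, 0, tolerance = 1e-12)
  expect_equal(eval_power_law(law, 100), 5, tolerance = 1e-12)
})

test_that("power-law fitting rejects degenerate input", {
  expect_error(fit_power_law(data.frame(KCl_mM = 40, value = 1), "D1"),
               "at least 2 points")
  expect_error(fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = c(-1, 2)), "D1"), "> 0")
  expect_error(power_law("bogus", 1, 1), "quantity")
})

test_that("out-of-domain queries are answered with an extrapolation warning", {
  law <- fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = c(0.20, 920)), "k_off_N")
  expect_warning(v <- eval_power_law(law, 300), "Extrapolating")
  expect_equal(v, 10^(law$slope * log10(300) + law$intercept))
  expect_error(eval_power_law(law, -5), "> 0")
})

test_that("flat laws give a flat decomposition profile", {
  laws <- dplyr::bind_rows(
    power_law("D1", 0, log10(2.7e6)),
    power_law("k_off_N", 0, log10(920)),
    power_law("k_IT_N", 0, log10(1.15e7)),
    power_law("K_d_N", 0, log10(16e-6))
  )
  prof <- decomposition_profile(laws, KCl_mM = seq(40, 400, by = 20))
  for (col in c("S", "rho", "eta", "k_a"))
    expect_lt(diff(range(prof[[col]])) / mean(prof[[col]]), 1e-12)
})

test_that("endpoint-anchored laws give the expected salt directionality", {
  prof <- suppressWarnings(
    decomposition_profile(endpoint_laws(), KCl_mM = seq(40, 400, by = 5)))
  expect_true(all(diff(prof$S) < 0))
  expect_true(all(diff(prof$eta) < 0))
  expect_true(all(diff(prof$rho) > 0))
  # the construction pins the sliding length at the printed values
  expect_equal(prof$lambda_bp[prof$KCl_mM == 40], 122, tolerance = 1e-6)
  expect_equal(prof$lambda_bp[prof$KCl_mM == 150], 38, tolerance = 1e-6)
  # factor invariants hold at every grid point
  expect_true(all(prof$rho > 0 & prof$rho <= 1))
  expect_true(all(prof$eta >= 1))
  expect_true(all(prof$S >= 1 & prof$S <= 105))
})

test_that("a single-point profile equals a direct decomposition call", {
  p <- study_params()
  laws <- dplyr::bind_rows(
    power_law("D1", 0, log10(p$D1)),
    power_law("k_off_N", 0, log10(p$k_off_N)),
    power_law("k_IT_N", 0, log10(p$k_IT_N)),
    power_law("K_d_N", 0, log10(p$K_d_N))
  )
  prof <- decomposition_profile(laws, KCl_mM = 150)
  dec <- search_decompose(study_condition(), p)
  expect_equal(prof$k_a, dec$k_a, tolerance = 1e-12)
  expect_equal(prof$S, dec$S, tolerance = 1e-12)
  expect_equal(prof$rho, dec$rho, tolerance = 1e-12)
})

test_that("monotone-decreasing profiles flag a boundary optimum", {
  prof <- suppressWarnings(
    decomposition_profile(endpoint_laws(), KCl_mM = seq(40, 400, by = 10)))
  opt <- find_optimum(prof)
  expect_true(opt$boundary)
  expect_equal(opt$KCl_opt_mM, 40)
})

test_that("opposed trapping and intrinsic-rate trends create an interior optimum", {
  prof <- suppressWarnings(
    decomposition_profile(optimum_laws(), KCl_mM = seq(40, 400, by = 10)))
  expect_true(all(diff(prof$rho) > 0))
  expect_true(all(diff(prof$k_on_N) < 0))
  opt <- find_optimum(prof)
  expect_false(opt$boundary)
  dense <- suppressWarnings(
    decomposition_profile(optimum_laws(), KCl_mM = seq(40, 400,
                                                       length.out = 5000)))
  argmax_dense <- dense$KCl_mM[which.max(dense$k_a)]
  expect_lt(abs(opt$KCl_opt_mM - argmax_dense), 10)
  # refinement never undercuts the best grid value
  expect_gte(opt$k_a_opt, max(prof$k_a))
})

test_that("golden-section refinement matches dense-grid argmax on random laws", {
  set.seed(99)
  for (i in 1:20) {
    laws <- dplyr::bind_rows(
      power_law("k_off_N", runif(1, 0.5, 3), runif(1, -2, 0)),
      power_law("K_d_N", runif(1, 1, 2.5), runif(1, -10, -9)),
      power_law("k_IT_N", runif(1, -3, -1), runif(1, 8, 10)),
      power_law("D1", runif(1, -1, 2), runif(1, 2, 5))
    )
    prof <- suppressWarnings(
      decomposition_profile(laws, KCl_mM = seq(40, 400, by = 10)))
    opt <- suppressWarnings(find_optimum(prof))
    dense <- suppressWarnings(
      decomposition_profile(laws, KCl_mM = seq(40, 400, length.out = 5000)))
    expect_lt(abs(opt$KCl_opt_mM - dense$KCl_mM[which.max(dense$k_a)]),
              10 + 1e-6)
  }
})

test_that("profiles validate their grid and law set", {
  laws <- optimum_laws()
  expect_error(decomposition_profile(laws, KCl_mM = c(100, 50)),
               "strictly increasing")
  expect_error(decomposition_profile(laws, KCl_mM = c(10, 50)),
               "20-500")
  expect_error(decomposition_profile(laws[1:3, ], KCl_mM = c(50, 100)),
               "missing")
  prof <- suppressWarnings(
    decomposition_profile(laws, KCl_mM = seq(40, 80, by = 10)))
  expect_error(find_optimum(prof[1:3, ]), "at least 5")
})
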