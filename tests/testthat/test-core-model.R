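test_that("site counts follow the footprint convention", {
  expect_identical(site_count(113, 9), 105L)
  expect_identical(site_count(28, 9), 20L)
  expect_identical(site_count(9, 9), 1L)
  expect_error(site_count(8, 9), "shorter than the protein footprint")
  expect_error(site_count(10, 0), "footprint")
})

test_that("the sliding-walk root matches its closed form and quadratic", {
  expect_equal(sliding_root(1), (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_lt(1 - sliding_root(1e8), 1e-7)
  # root of y^2 - (2 + lambda^-2) y + 1 = 0 across the working range
  for (lam in c(0.1, 0.5, 1, 2, 10, 38, 122, 1e4)) {
    y <- sliding_root(lam)
    expect_lt(abs(y^2 - (2 + lam^-2) * y + 1), 1e-10)
    expect_true(y > 0 && y < 1)
  }
  # lambda = 0.1: y + 1/y = 2 + lambda^-2 = 102
  y <- sliding_root(0.1)
  expect_equal(y + 1 / y, 102, tolerance = 1e-12)
  expect_error(sliding_root(0), "finite and > 0")
  expect_error(sliding_root(-3), "finite and > 0")
  expect_error(sliding_root(Inf), "finite and > 0")
})

test_that("antenna size has the no-sliding and whole-duplex limits", {
  expect_equal(antenna_size(1e-3, 105, 2), 1, tolerance = 1e-4)
  expect_equal(antenna_size(1e6, 105, 2), 105, tolerance = 1e-3)
  expect_equal(antenna_size(38, 1, 1), 1, tolerance = 1e-12)
  expect_error(antenna_size(38, 105, 106), "target_pos")
  expect_error(antenna_size(-1, 105, 2), "finite and > 0")
})

test_that("antenna size is symmetric, bounded and monotone in duplex length", {
  grid <- expand.grid(lambda = c(0.5, 2, 10, 38, 122),
                      L = c(10, 25, 105, 135))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; L <- grid$L[i]
    for (m in unique(c(1, 2, ceiling((L + 1) / 2)))) {
      S <- antenna_size(lam, L, m)
      expect_gte(S, 1)
      expect_lte(S, L)
      # the discrete-lattice antenna bound; its continuum limit is 2*lambda,
      # which the exact formula can exceed by O(lambda^-2) at small lambda
      expect_lte(S, sqrt(4 * lam^2 + 1) * (1 + 1e-12))
      if (lam >= 10) expect_lt(S, 2 * lam * 1.002)
      expect_equal(S, antenna_size(lam, L, L + 1 - m), tolerance = 1e-12)
    }
  }
  # S non-decreasing in L at fixed (lambda, m)
  S_path <- antenna_size(10, 5:80, 2)
  expect_true(all(diff(S_path) >= -1e-12))
})

test_that("antenna size stays finite and accurate deep in the stiff regime", {
  # small lambda and long chains overflow y^-L in the naive form
  expect_equal(antenna_size(1e-2, 1e4, 5000), 1, tolerance = 1e-3)
  S <- antenna_size(0.5, 1e4, 5000)
  expect_true(is.finite(S) && S >= 1 && S < 2)
})

test_that("mid-duplex reduction approaches its two limits and tracks the exact form", {
  expect_equal(antenna_size_midpoint(1e6, 105), 105, tolerance = 1e-3)
  expect_equal(antenna_size_midpoint(5, 1e4), 10, tolerance = 1e-3)
  # discrepancy against the exact expression at an odd-L midpoint is small
  # and reported, not assumed zero
  rel <- abs(antenna_size_midpoint(38, 105) - antenna_size(38, 105, 53)) /
    antenna_size(38, 105, 53)
  expect_lt(rel, 1e-3)
})

test_that("nonspecific lifetime combines dissociation and transfer channels", {
  cond <- study_condition()
  p_no_it <- nonspecific_params(2.7e6, 920, 0, 16e-6)
  expect_equal(nonspecific_lifetime(p_no_it, cond), 1 / 920, tolerance = 1e-12)
  # single transfer channel: rate k_IT_N * site concentration
  X <- 2 * (105 * 2.5e-9 + 20 * 2e-6)
  p_it <- nonspecific_params(2.7e6, 0, 1e3 / X, 16e-6)
  expect_equal(nonspecific_lifetime(p_it, cond), 1e-3, tolerance = 1e-9)
  # with dissociation off and probe term negligible, doubling C_tot halves tau
  cond2 <- assay_condition(113, D_tot_M = 0, C_tot_M = 4e-6)
  cond1 <- assay_condition(113, D_tot_M = 0, C_tot_M = 2e-6)
  expect_equal(nonspecific_lifetime(p_it, cond1) /
                 nonspecific_lifetime(p_it, cond2), 2, tolerance = 1e-12)
  p_dead <- nonspecific_params(2.7e6, 0, 0, 16e-6)
  expect_error(nonspecific_lifetime(p_dead, cond), "no decay channel")
})

test_that("direct closed form and factor decomposition are the same number", {
  set.seed(7)
  for (i in 1:1000) {
    p <- nonspecific_params(
      D1 = 10^runif(1, 2, 8), k_off_N = 10^runif(1, -1, 4),
      k_IT_N = 10^runif(1, 4, 9), K_d_N = 10^runif(1, -7, -4),
      phi = sample(c(1, 2), 1))
    cond <- assay_condition(
      probe_len_bp = sample(33:143, 1), D_tot_M = 10^runif(1, -10, -8),
      C_tot_M = 10^runif(1, -7, -4), target_pos = 2)
    dec <- search_decompose(cond, p)
    expect_lt(abs(dec$k_a - dec$rho * dec$eta * dec$S * dec$k_on_N) / dec$k_a,
              1e-12)
  }
})

test_that("decomposition factors hit their structural special cases", {
  cond <- study_condition()
  # no transfer: eta is exactly 1
  dec <- search_decompose(cond, nonspecific_params(2.7e6, 920, 0, 16e-6))
  expect_identical(dec$eta, 1)
  # no nonspecific pool: rho is exactly 1
  cond0 <- assay_condition(113, D_tot_M = 0, C_tot_M = 0)
  dec0 <- search_decompose(cond0, study_params())
  expect_identical(dec0$rho, 1)
  # hand evaluation of the untrapped fraction at the study condition
  dec1 <- search_decompose(cond, study_params())
  rho_hand <- 16e-6 /
    (16e-6 + (2 * 105 - dec1$S) * 2.5e-9 + 2 * 20 * 2e-6)
  expect_equal(dec1$rho, rho_hand, tolerance = 1e-12)
})

test_that("the search rate collapses to intrinsic binding without DNA context", {
  # vanishing concentrations, no transfer, no sliding: k_a -> k_on_N
  p <- nonspecific_params(D1 = 1e-10, k_off_N = 920, k_IT_N = 0,
                          K_d_N = 16e-6)
  cond <- assay_condition(9, D_tot_M = 0, C_tot_M = 0, competitor_len_bp = 9,
                          target_pos = 1)
  expect_equal(search_rate(cond, p)$k_a, 920 / 16e-6, tolerance = 1e-6)
})

test_that("the search rate falls as competitor sequesters the protein", {
  p <- nonspecific_params(2.7e6, 920, 0, 16e-6)
  ka <- vapply(c(0.5, 1, 2, 4, 8, 16) * 1e-6, function(C)
    search_rate(assay_condition(113, D_tot_M = 2.5e-9, C_tot_M = C), p)$k_a,
    numeric(1))
  expect_true(all(diff(ka) < 0))
})
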