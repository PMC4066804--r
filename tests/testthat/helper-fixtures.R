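# Shared fixtures: the study's reference parameter set and condition, and
# ionic-strength law constructions used across test files. All fixtures are
# built in code; nothing is read from disk.

# 150 mM KCl-like parameter set: printed k_off_N and K_d_N; D1 and k_IT_N
# chosen so the sliding length is ~38 bp and transfer roughly doubles the
# nonspecific turnover at the reference condition.
study_params <- function() {
  nonspecific_params(D1 = 2.7e6, k_off_N = 920, k_IT_N = 1.15e7,
                     K_d_N = 16e-6, phi = 2)
}

# 113-bp probe at 2.5 nM with 2 uM of 28-bp competitor (9-bp footprint,
# target at position 2)
study_condition <- function() {
  assay_condition(probe_len_bp = 113, D_tot_M = 2.5e-9, C_tot_M = 2e-6)
}

# printed five-point K_d_N law (40-150 mM KCl, values in M)
kd_points <- function() {
  data.frame(KCl_mM = c(40, 60, 80, 110, 150),
             value = c(1.4, 3.6, 4.6, 9.6, 16) * 1e-6)
}

# laws anchored on the printed endpoints: k_off_N through 0.20 (40 mM) and
# 920 1/s (150 mM); K_d_N through the five printed points; k_IT_N with a
# negative slope; D1 constructed so the sliding length hits 122 bp at 40 mM
# and 38 bp at 150 mM at the reference condition.
endpoint_laws <- function() {
  law_koff <- fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = c(0.20, 920)), "k_off_N")
  law_kd <- fit_power_law(kd_points(), "K_d_N")
  law_kit <- fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = c(2e8, 2e8 * (40 / 150)^2)),
    "k_IT_N")
  X <- 2 * (105 * 2.5e-9 + 20 * 2e-6) # total site concentration, M
  D1_pts <- vapply(c(40, 150), function(s) {
    lam <- if (s == 40) 122 else 38
    lam^2 * (eval_power_law(law_koff, s) + eval_power_law(law_kit, s) * X)
  }, numeric(1))
  law_d1 <- fit_power_law(
    data.frame(KCl_mM = c(40, 150), value = D1_pts), "D1")
  dplyr::bind_rows(law_koff, law_kd, law_kit, law_d1)
}

# law set with an interior search optimum: transfer negligible, trapping
# releases (rho rises toward 1) while the intrinsic rate k_on_N falls
optimum_laws <- function() {
  a_off <- 0.5
  dplyr::bind_rows(
    power_law("k_off_N", a_off, log10(920) - a_off * log10(150)),
    fit_power_law(kd_points(), "K_d_N"),
    power_law("k_IT_N", -2, log10(1e3) + 2 * log10(150)),
    power_law("D1", a_off, log10(38^2 * 920) - a_off * log10(150))
  )
}

# small, fast Gillespie configuration: 33-bp probe (25 sites), 28-bp
# competitor (20 sites), rates giving a ~3-site sliding length and a
# manageable number of events per trajectory
sim_params <- function() nonspecific_params(900, 50, 1.18e6, 2e-6)
sim_condition <- function() {
  assay_condition(probe_len_bp = 33, D_tot_M = 5e-8, C_tot_M = 1e-6)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
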