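#' Number of protein binding sites on a duplex
#'
#' A protein covering `footprint_bp` base pairs has `A - B + 1` distinct
#' binding positions on a duplex of `A` bp. For a 9-bp footprint this gives
#' 105 sites on a 113-bp probe and 20 sites on a 28-bp competitor.
#'
#' @param duplex_len_bp Duplex length, bp.
#' @param footprint_bp Base pairs covered by one bound protein.
#' @return Integer site count(s).
#' @examples
#' site_count(113, 9) # 105
#' site_count(28, 9)  # 20
#' @export
site_count <- function(duplex_len_bp, footprint_bp) {
  stopifnot(is.numeric(duplex_len_bp), is.numeric(footprint_bp))
  if (any(footprint_bp < 1))
    abort("`footprint_bp` must be >= 1 bp.")
  if (any(duplex_len_bp < footprint_bp))
    abort(sprintf(
      "Duplex (%s bp) is shorter than the protein footprint (%s bp): no site.",
      paste(duplex_len_bp, collapse = ","), paste(footprint_bp, collapse = ",")))
  as.integer(duplex_len_bp - footprint_bp + 1)
}

# log(cosh(x)) and log(sinh(x)) without overflow; x may exceed 700 where
# cosh/sinh themselves overflow double precision.
log_cosh <- function(x) {
  x <- abs(x)
  ifelse(x < 30, log(cosh(x)), x - log(2) + log1p(exp(-2 * x)))
}
log_sinh <- function(x) {
  ifelse(x < 30, log(sinh(x)), x - log(2) + log1p(-exp(-2 * x)))
}

check_lambda <- function(lambda_bp) {
  if (any(!is.finite(lambda_bp) | lambda_bp <= 0))
    abort("`lambda_bp` (effective sliding length) must be finite and > 0.")
  invisible(lambda_bp)
}

#' Characteristic root of the sliding random walk
#'
#' The decay factor per lattice step of the stationary capture profile of a
#' 1-bp-step sliding walk with effective sliding length `lambda_bp`: the root
#' in (0, 1) of `y^2 - (2 + lambda^-2) y + 1 = 0`,
#' `y = 1 + lambda^-2/2 - sqrt(lambda^-2 + lambda^-4/4)`.
#' Evaluated as `exp(-2 asinh(1/(2 lambda)))`, which is algebraically
#' identical and keeps full precision for large `lambda_bp` where the direct
#' form cancels catastrophically.
#'
#' @param lambda_bp Effective sliding length, bp (> 0).
#' @return The root `y` in (0, 1); vectorized.
#' @examples
#' sliding_root(1) # (3 - sqrt(5))/2
#' @export
sliding_root <- function(lambda_bp) {
  check_lambda(lambda_bp)
  exp(-2 * asinh(1 / (2 * lambda_bp)))
}

#' Effective antenna size of the target on a finite duplex
#'
#' The expected number of binding sites whose occupancy funnels the protein
#' into the target by sliding before it leaves the duplex: the sum over all
#' `L` sites of the splitting probability of reaching the target (site
#' `target_pos`) before dissociation or transfer, for a walk with sliding
#' length `lambda_bp` and reflecting duplex ends. `1 <= S <= L`; `S -> 1` as
#' `lambda_bp -> 0` and `S -> L` as `lambda_bp -> Inf`.
#'
#' The closed form is evaluated in the hyperbolic domain (`u = -log y`,
#' `cosh u = 1 + lambda^-2/2`) with log-scale sinh/cosh, so it is stable for
#' sliding lengths down to 1e-2 bp and duplexes up to 1e4 sites where powers
#' `y^-L` overflow. Below `lambda_bp = 1e-6` the known limit `S = 1` is
#' returned directly.
#'
#' @param lambda_bp Effective sliding length, bp (> 0); vectorized.
#' @param n_sites Number of binding sites `L` on the duplex.
#' @param target_pos 1-based target site index from the duplex edge.
#' @return Antenna size `S` in sites.
#' @seealso [antenna_size_midpoint()] for the mid-duplex approximation,
#'   [antenna_oracle()] for the independent linear-solve validator.
#' @examples
#' antenna_size(38, 105, 2)
#' @export
antenna_size <- function(lambda_bp, n_sites, target_pos) {
  check_lambda(lambda_bp)
  if (any(n_sites < 1)) abort("`n_sites` must be >= 1.")
  if (any(target_pos < 1 | target_pos > n_sites))
    abort("`target_pos` must lie in 1..n_sites.")
  out <- recycle3(lambda_bp, n_sites, target_pos)
  lambda_bp <- out[[1]]; L <- out[[2]]; m <- out[[3]]
  S <- rep(1, length(lambda_bp))
  live <- lambda_bp >= 1e-6 & L > 1
  if (any(live)) {
    u <- 2 * asinh(1 / (2 * lambda_bp[live]))
    Ll <- L[live]; ml <- m[live]
    S[live] <- exp(
      log_cosh(u / 2) + log_sinh(Ll * u) - log(2) - log_sinh(u / 2) -
        log_cosh((2 * ml - 1) * u / 2) - log_cosh((2 * Ll - 2 * ml + 1) * u / 2)
    )
  }
  S
}

recycle3 <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  list(rep_len(a, n), rep_len(b, n), rep_len(c, n))
}

#' Antenna size for a mid-duplex target
#'
#' When the target sits near the middle of the duplex the antenna size
#' becomes independent of the target position and reduces to
#' `S = 2 lambda tanh(L / (2 lambda))`: the whole duplex (`S -> L`) for
#' `lambda >> L` and a `2 lambda` antenna for `lambda << L`.
#'
#' @inheritParams antenna_size
#' @return Approximate antenna size in sites; vectorized.
#' @export
antenna_size_midpoint <- function(lambda_bp, n_sites) {
  check_lambda(lambda_bp)
  if (any(n_sites < 1)) abort("`n_sites` must be >= 1.")
  2 * lambda_bp * tanh(n_sites / (2 * lambda_bp))
}

#' Mean lifetime of a nonspecific protein-DNA complex
#'
#' A nonspecific complex ends by dissociation (`k_off_N`) or by intersegment
#' transfer to any site on another duplex
#' (`k_IT_N * (phi L D_tot + phi M C_tot)`):
#' `tau_N = 1 / (k_off_N + k_IT_N (phi L D_tot + phi M C_tot))`.
#'
#' @param params A [nonspecific_params()] object.
#' @param conditions An [assay_condition()] tibble (any number of rows).
#' @return Lifetime(s) `tau_N` in seconds, one per condition row.
#' @export
nonspecific_lifetime <- function(params, conditions) {
  stopifnot(inherits(params, "nonspecific_params"))
  validate_assay_condition(conditions)
  L <- conditions$probe_len_bp - conditions$footprint_bp + 1
  M <- conditions$competitor_len_bp - conditions$footprint_bp + 1
  site_conc <- params$phi * (L * conditions$D_tot_M + M * conditions$C_tot_M)
  decay <- params$k_off_N + params$k_IT_N * site_conc
  if (any(decay <= 0))
    abort(paste("Nonspecific complex has no decay channel (k_off_N = 0 and",
                "no transfer flux): lifetime is infinite."))
  1 / decay
}

# Fully vectorized evaluation of the search model: parameter vectors and
# geometry/concentration vectors are recycled against each other.
eval_decomposition <- function(D1, k_off_N, k_IT_N, K_d_N, phi,
                               L, M, target_pos, D_tot, C_tot,
                               tau_N = NULL) {
  if (is.null(tau_N)) {
    decay <- k_off_N + k_IT_N * phi * (L * D_tot + M * C_tot)
    if (any(decay <= 0))
      abort(paste("Nonspecific complex has no decay channel (k_off_N = 0 and",
                  "no transfer flux): lifetime is infinite."))
    tau_N <- 1 / decay
  }
  lambda <- sqrt(D1 * tau_N)
  S <- antenna_size(lambda, L, target_pos)
  denom <- K_d_N + (phi * L - S) * D_tot + phi * M * C_tot
  tibble::tibble(
    n_sites = L, n_sites_competitor = M,
    y = sliding_root(lambda), lambda_bp = lambda, tau_N_s = tau_N,
    S = S,
    rho = K_d_N / denom,
    eta = 1 + k_IT_N * phi * (L * D_tot + M * C_tot) / k_off_N, # Inf at k_off_N = 0
    k_on_N = k_off_N / K_d_N,
    k_a = S / denom / tau_N
  )
}

# evaluate one parameter set across the rows of a condition tibble;
# tau_N may be supplied (length-fit convention tau_N = lambda^2/D1)
decompose_core <- function(params, conditions, tau_N = NULL) {
  L <- conditions$probe_len_bp - conditions$footprint_bp + 1
  M <- conditions$competitor_len_bp - conditions$footprint_bp + 1
  eval_decomposition(params$D1, params$k_off_N, params$k_IT_N, params$K_d_N,
                     params$phi, L, M, conditions$target_pos,
                     conditions$D_tot_M, conditions$C_tot_M, tau_N = tau_N)
}

#' Apparent target-association rate constant
#'
#' Closed-form second-order rate constant `k_a` (M^-1 s^-1) for association
#' of a protein with its target site on a probe duplex in the presence of
#' nonspecific competitor DNA, without assuming quasi-equilibrium of the
#' nonspecific interactions:
#' `k_a = S / (K_d_N + (phi L - S) D_tot + phi M C_tot) / tau_N`,
#' with the antenna size `S` from [antenna_size()] at
#' `lambda = sqrt(D1 tau_N)` and the lifetime `tau_N` from
#' [nonspecific_lifetime()].
#'
#' @param conditions An [assay_condition()] tibble; one result per row.
#' @param params A [nonspecific_params()] object.
#' @return The input conditions with a `k_a` column appended (tibble).
#' @seealso [search_decompose()] for the antenna/trapping/transfer factors.
#' @examples
#' p <- nonspecific_params(2.7e6, 920, 1.15e7, 16e-6)
#' cond <- assay_condition(113, D_tot_M = 2.5e-9, C_tot_M = 2e-6)
#' search_rate(cond, p)
#' @export
search_rate <- function(conditions, params) {
  dec <- decompose_core(params, conditions)
  out <- tibble::as_tibble(conditions)
  out$k_a <- dec$k_a
  out
}

#' Decompose the search rate into antenna, trapping and transfer factors
#'
#' Evaluates the full decomposition `k_a = rho * eta * S * k_on_N`:
#' `S` is the antenna enhancement (sites funneling the protein to the target
#' by sliding), `rho` the untrapped fraction
#' `K_d_N / (K_d_N + (phi L - S) D_tot + phi M C_tot)` (attenuation by
#' sequestration at distant nonspecific sites), `eta` the intersegment
#' transfer enhancement `1 + k_IT_N (phi L D_tot + phi M C_tot) / k_off_N`,
#' and `k_on_N = k_off_N / K_d_N` the intrinsic per-site association rate.
#' The `k_a` column itself is computed through the direct closed form
#' ([search_rate()]); the product of the factors equals it to machine
#' precision, which the test suite asserts as an algebraic identity.
#'
#' @inheritParams search_rate
#' @return A tibble, one row per condition, with columns `n_sites`,
#'   `n_sites_competitor`, `y`, `lambda_bp`, `tau_N_s`, `S`, `rho`, `eta`,
#'   `k_on_N`, `k_a`.
#' @examples
#' p <- nonspecific_params(2.7e6, 920, 1.15e7, 16e-6)
#' search_decompose(assay_condition(113, D_tot_M = 2.5e-9, C_tot_M = 2e-6), p)
#' @export
search_decompose <- function(conditions, params) {
  validate_assay_condition(conditions)
  dec <- decompose_core(params, conditions)
  keep <- intersect(c("KCl_mM", "D_tot_M", "C_tot_M"), names(conditions))
  dplyr::bind_cols(tibble::as_tibble(conditions)[keep], dec)
}
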