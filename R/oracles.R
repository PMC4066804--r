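#' Capture probabilities of the sliding chain by direct linear solve
#'
#' Independent numerical validator of the closed-form antenna size. A protein
#' bound at site `i` of an `n_sites` chain hops to each existing neighbor at
#' `hop_rate` (reflecting ends) and leaves the chain at `death_rate`
#' (dissociation plus transfer). The splitting probability `p_i` of reaching
#' the target site before leaving satisfies a tridiagonal linear system
#' (`p_target = 1`); the effective antenna size is `sum(p_i)`. With
#' `hop_rate / death_rate = lambda^2` this must reproduce [antenna_size()],
#' which is the first-passage identity the closed form is built on.
#'
#' @param n_sites Chain length `L` in sites.
#' @param target_pos 1-based target site index.
#' @param hop_rate Per-direction sliding rate, 1/s (equals `D1` on a 1-bp
#'   lattice).
#' @param death_rate Rate of leaving the chain, 1/s (equals `1/tau_N`).
#' @return `antenna_capture_profile()`: a tibble with columns `site` and
#'   `p_capture`; `antenna_oracle()`: the scalar antenna size `sum(p_capture)`.
#' @examples
#' antenna_oracle(105, 2, hop_rate = 38^2, death_rate = 1)
#' antenna_size(38, 105, 2) # closed form, same number
#' @export
antenna_capture_profile <- function(n_sites, target_pos, hop_rate, death_rate) {
  stopifnot(n_sites >= 1, target_pos >= 1, target_pos <= n_sites)
  if (hop_rate < 0 || death_rate < 0 || hop_rate + death_rate <= 0)
    abort("Rates must be >= 0 with hop_rate + death_rate > 0.")
  L <- as.integer(n_sites)
  m <- as.integer(target_pos)
  if (L == 1L)
    return(tibble::tibble(site = 1L, p_capture = 1))
  A <- matrix(0, L, L)
  b <- numeric(L)
  for (i in seq_len(L)) {
    if (i == m) {
      A[i, i] <- 1
      b[i] <- 1
      next
    }
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= L]
    A[i, i] <- death_rate + hop_rate * length(nb)
    A[i, nb] <- -hop_rate
  }
  p <- solve(A, b)
  tibble::tibble(site = seq_len(L), p_capture = p)
}

#' @rdname antenna_capture_profile
#' @export
antenna_oracle <- function(n_sites, target_pos, hop_rate, death_rate) {
  sum(antenna_capture_profile(n_sites, target_pos, hop_rate, death_rate)$p_capture)
}

#' Stochastic-simulation estimate of the target-association rate constant
#'
#' Gillespie simulation of a single protein searching for its target under
#' pseudo-first-order conditions, used as an independent check of the closed
#' form in [search_rate()]. The protein cycles between free solution and
#' nonspecific sites on the probe and competitor duplexes (association at
#' `k_on_N` per site-orientation weighted by duplex concentration, sliding at
#' `D1` per direction with reflecting ends, dissociation at `k_off_N`,
#' intersegment transfer at `k_IT_N` times the total site concentration with
#' a concentration-weighted, within-duplex-uniform landing site). The target
#' is the designated orientation of site `target_pos` on the probe;
#' wrong-orientation sites are pure traps. The apparent rate constant is
#' `k_a = 1 / (mean first-passage time * D_tot)` with a standard error from
#' the trajectory ensemble (delta method).
#'
#' @param params A [nonspecific_params()] object.
#' @param condition A single-row [assay_condition()] with `D_tot_M > 0`.
#' @param n_traj Number of trajectories.
#' @param seed Optional integer seed (sets R's RNG locally; identical seeds
#'   give bit-identical estimates).
#' @param max_time Censoring horizon in seconds; trajectories still searching
#'   at `max_time` are excluded from the mean and counted. A censoring
#'   fraction above 1% flags the estimate.
#' @return A one-row tibble: `k_a`, `se`, `mfpt_s`, `n_traj`, `n_censored`,
#'   `censor_frac`, `flagged`, `seed`.
#' @examples
#' p <- nonspecific_params(900, 50, 1.18e6, 2e-6)
#' cond <- assay_condition(33, D_tot_M = 5e-8, C_tot_M = 1e-6)
#' gillespie_search_rate(p, cond, n_traj = 200, seed = 1)
#' @export
gillespie_search_rate <- function(params, condition, n_traj = 1e4,
                                  seed = NULL, max_time = Inf) {
  stopifnot(inherits(params, "nonspecific_params"), nrow(condition) == 1L,
            n_traj >= 1, max_time > 0)
  validate_assay_condition(condition)
  if (condition$D_tot_M <= 0)
    abort("Gillespie estimate needs D_tot_M > 0 (the target concentration).")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  L <- site_count(condition$probe_len_bp, condition$footprint_bp)
  M <- site_count(condition$competitor_len_bp, condition$footprint_bp)
  k_on <- params$k_off_N / params$K_d_N
  sim <- gillespie_fpt_cpp(
    as.integer(n_traj), L, M, as.integer(condition$target_pos),
    as.integer(params$phi), params$D1, params$k_off_N, params$k_IT_N, k_on,
    condition$D_tot_M, condition$C_tot_M,
    if (is.finite(max_time)) max_time else .Machine$double.xmax
  )
  ok <- !sim$censored
  n_cens <- sum(!ok)
  if (!any(ok))
    abort("All trajectories censored before reaching the target; raise `max_time`.")
  fpt <- sim$fpt[ok]
  mfpt <- mean(fpt)
  k_a <- 1 / (mfpt * condition$D_tot_M)
  rel_se <- sd(fpt) / sqrt(length(fpt)) / mfpt
  tibble::tibble(
    k_a = k_a, se = k_a * rel_se, mfpt_s = mfpt,
    n_traj = as.integer(n_traj), n_censored = as.integer(n_cens),
    censor_frac = n_cens / n_traj,
    flagged = n_cens / n_traj > 0.01,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}
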