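#' Microscopic nonspecific-interaction parameter set
#'
#' Bundles the rate and affinity constants that govern a protein's
#' interaction with nonspecific DNA sites: the one-dimensional sliding
#' diffusion coefficient, the dissociation and intersegment-transfer rate
#' constants, the per-site nonspecific dissociation constant and the number
#' of binding orientations per site.
#'
#' On a 1-bp lattice the diffusion coefficient `D1` (bp^2/s) is numerically
#' equal to the per-direction single-step sliding rate constant (1/s).
#' The intrinsic per-site association rate constant `k_on_N = k_off_N / K_d_N`
#' is derived, not stored. `phi = 2` for proteins binding duplex DNA as a
#' monomer (the two orientations of the pseudo-twofold duplex are distinct
#' sites); `phi = 1` for symmetric dimers.
#'
#' @param D1 One-dimensional diffusion coefficient for sliding, bp^2 s^-1.
#' @param k_off_N Dissociation rate constant of a nonspecific complex, s^-1.
#' @param k_IT_N Second-order rate constant for intersegment transfer between
#'   nonspecific sites on distinct duplexes, M^-1 s^-1.
#' @param K_d_N Per-site nonspecific dissociation constant, M.
#' @param phi Binding orientations per nonspecific site (1 or 2).
#'
#' @return An object of class `nonspecific_params` (a named list).
#' @examples
#' nonspecific_params(D1 = 2.7e6, k_off_N = 920, k_IT_N = 1.15e7,
#'                    K_d_N = 16e-6)
#' @export
nonspecific_params <- function(D1, k_off_N, k_IT_N, K_d_N, phi = 2) {
  stopifnot(is.numeric(D1), is.numeric(k_off_N), is.numeric(k_IT_N),
            is.numeric(K_d_N), length(D1) == 1L, length(k_off_N) == 1L,
            length(k_IT_N) == 1L, length(K_d_N) == 1L)
  if (!is.finite(D1) || D1 <= 0)
    abort("`D1` must be a finite positive diffusion coefficient (bp^2/s).")
  if (!is.finite(k_off_N) || k_off_N < 0)
    abort("`k_off_N` must be finite and >= 0 (s^-1).")
  if (!is.finite(k_IT_N) || k_IT_N < 0)
    abort("`k_IT_N` must be finite and >= 0 (M^-1 s^-1).")
  if (!is.finite(K_d_N) || K_d_N <= 0)
    abort("`K_d_N` must be finite and > 0 (M).")
  if (!phi %in% c(1, 2))
    abort("`phi` must be 1 (symmetric dimer) or 2 (monomer).")
  structure(
    list(D1 = as.numeric(D1), k_off_N = as.numeric(k_off_N),
         k_IT_N = as.numeric(k_IT_N), K_d_N = as.numeric(K_d_N),
         phi = as.numeric(phi)),
    class = "nonspecific_params"
  )
}

#' @export
print.nonspecific_params <- function(x, ...) {
  cat("<nonspecific_params>\n")
  cat(sprintf("  D1      : %g bp^2/s (= per-direction sliding rate, 1/s)\n", x$D1))
  cat(sprintf("  k_off_N : %g 1/s\n", x$k_off_N))
  cat(sprintf("  k_IT_N  : %g 1/(M s)\n", x$k_IT_N))
  cat(sprintf("  K_d_N   : %g M\n", x$K_d_N))
  cat(sprintf("  phi     : %d orientation(s)/site\n", as.integer(x$phi)))
  cat(sprintf("  k_on_N  : %g 1/(M s)  [k_off_N / K_d_N]\n", x$k_off_N / x$K_d_N))
  invisible(x)
}

#' Experimental geometry and concentrations for one search assay
#'
#' Describes one stopped-flow condition: the fluorescent probe duplex that
#' carries the target site, the nonspecific competitor duplex, the protein
#' footprint that converts duplex length to binding-site count
#' (`L = A - B + 1`), the 1-based target position counted from the duplex
#' edge, and the total concentrations of the species. Several conditions can
#' be combined with [dplyr::bind_rows()] and passed to vectorized model
#' functions such as [search_decompose()].
#'
#' @param probe_len_bp Probe duplex length, bp.
#' @param D_tot_M Total probe duplex concentration, M.
#' @param C_tot_M Total competitor duplex concentration, M.
#' @param competitor_len_bp Competitor duplex length, bp (default 28).
#' @param footprint_bp Base pairs covered by one bound protein (default 9).
#' @param target_pos 1-based index of the target site from the duplex edge
#'   (default 2).
#' @param P_tot_M Optional total protein concentration, M.
#' @param KCl_mM Optional ionic-strength label, mM KCl.
#'
#' @return A tibble with one row per condition and class `assay_condition`.
#' @examples
#' assay_condition(probe_len_bp = 113, D_tot_M = 2.5e-9, C_tot_M = 2e-6)
#' @export
assay_condition <- function(probe_len_bp, D_tot_M, C_tot_M,
                            competitor_len_bp = 28, footprint_bp = 9,
                            target_pos = 2, P_tot_M = NA_real_,
                            KCl_mM = NA_real_) {
  cond <- tibble::tibble(
    probe_len_bp = as.numeric(probe_len_bp),
    competitor_len_bp = as.numeric(competitor_len_bp),
    footprint_bp = as.numeric(footprint_bp),
    target_pos = as.numeric(target_pos),
    D_tot_M = as.numeric(D_tot_M),
    C_tot_M = as.numeric(C_tot_M),
    P_tot_M = as.numeric(P_tot_M),
    KCl_mM = as.numeric(KCl_mM)
  )
  validate_assay_condition(cond)
  class(cond) <- c("assay_condition", class(cond))
  cond
}

validate_assay_condition <- function(cond) {
  L <- cond$probe_len_bp - cond$footprint_bp + 1
  M <- cond$competitor_len_bp - cond$footprint_bp + 1
  if (any(L < 1))
    abort("Probe duplex shorter than the protein footprint: no binding site.")
  if (any(M < 1))
    abort("Competitor duplex shorter than the protein footprint.")
  if (any(cond$target_pos < 1 | cond$target_pos > L))
    abort("`target_pos` must lie in 1..L (L = probe_len_bp - footprint_bp + 1).")
  conc <- c(cond$D_tot_M, cond$C_tot_M)
  if (any(!is.finite(conc) | conc < 0))
    abort("Concentrations must be finite and >= 0 (molar).")
  invisible(cond)
}
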