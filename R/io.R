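# CSV readers with mandatory unit suffixes, JSON serialization for power
# laws and run configuration. The study's tables mix nM, uM, M and bp;
# requiring the unit in every column header and normalizing to molar / bp /
# seconds at the boundary keeps the core single-unit.

conc_suffix <- c(nM = 1e-9, uM = 1e-6, mM = 1e-3, M = 1)

read_csv_checked <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in names(raw)) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad))
      abort(sprintf("Non-numeric value in column `%s` of %s at data row %s.",
                    col, basename(path), paste(bad, collapse = ", ")))
    raw[[col]] <- num
  }
  raw
}

# map one unit-suffixed header to (internal name, scale factor)
normalize_column <- function(name, path) {
  if (name %in% c("probe_len_bp", "n_sites", "KCl_mM", "time_s", "intensity",
                  "k_app_per_s", "se_per_s"))
    return(list(name = name, scale = 1))
  if (name == "k_a_per_M_per_s") return(list(name = "k_a", scale = 1))
  if (name == "k_a_1e8_per_M_per_s") return(list(name = "k_a", scale = 1e8))
  if (name == "se_per_M_per_s") return(list(name = "se", scale = 1))
  if (name == "se_1e8_per_M_per_s") return(list(name = "se", scale = 1e8))
  m <- regmatches(name, regexec("^([DCP]_tot)_(nM|uM|mM|M)$", name))[[1]]
  if (length(m) == 3)
    return(list(name = paste0(m[2], "_M"), scale = conc_suffix[[m[3]]]))
  abort(sprintf(
    "Column `%s` in %s has no recognized unit suffix; headers must carry units (e.g. C_tot_nM, k_a_per_M_per_s).",
    name, basename(path)))
}

normalize_units <- function(raw, path) {
  out <- tibble::tibble(.rows = nrow(raw))
  conversions <- character()
  for (col in names(raw)) {
    spec <- normalize_column(col, path)
    out[[spec$name]] <- raw[[col]] * spec$scale
    if (spec$scale != 1 || spec$name != col)
      conversions <- c(conversions, sprintf("%s -> %s (x%g)", col, spec$name,
                                            spec$scale))
  }
  attr(out, "provenance") <- list(file = path, n_rows = nrow(raw),
                                  conversions = conversions)
  out
}

#' Read a rate-constant dataset from a unit-suffixed CSV
#'
#' Reads a `(covariate, k_a)` series and normalizes it to internal units
#' (molar, bp, seconds). Headers must carry their unit: recognized columns
#' are `probe_len_bp` / `n_sites`, `C_tot_nM|uM|mM|M`, `P_tot_*`, `D_tot_*`,
#' `KCl_mM`, `k_a_per_M_per_s` (or `k_a_1e8_per_M_per_s`) and the matching
#' `se_*` columns. The covariate kind is inferred from the columns present.
#' Malformed cells raise errors naming the row; duplicated covariate values
#' are only accepted when standard errors are provided.
#'
#' @param path CSV file path.
#' @return A normalized tibble with a `covariate` attribute (`"length"`,
#'   `"competitor"`, `"KCl"` or `"protein"`) and file/row/conversion
#'   provenance in `attr(, "provenance")`.
#' @export
read_rate_dataset <- function(path) {
  out <- normalize_units(read_csv_checked(path), path)
  cov <- dplyr::case_when(
    "probe_len_bp" %in% names(out) || "n_sites" %in% names(out) ~ "length",
    "C_tot_M" %in% names(out) ~ "competitor",
    "KCl_mM" %in% names(out) ~ "KCl",
    "P_tot_M" %in% names(out) ~ "protein",
    TRUE ~ NA_character_
  )
  if (is.na(cov))
    abort(sprintf("No covariate column recognized in %s.", basename(path)))
  cov_col <- switch(cov, length = intersect(c("probe_len_bp", "n_sites"),
                                            names(out))[1],
                    competitor = "C_tot_M", KCl = "KCl_mM", protein = "P_tot_M")
  if (anyDuplicated(out[[cov_col]]) && !"se" %in% names(out))
    abort(sprintf(
      "Duplicate `%s` values without standard errors in %s; replicates need an `se` column.",
      cov_col, basename(path)))
  attr(out, "covariate") <- cov
  out
}

#' Read a stopped-flow fluorescence trace CSV
#'
#' Expects columns `time_s` and `intensity`.
#'
#' @param path CSV file path.
#' @return A trace tibble suitable for [fit_monoexp()].
#' @export
read_trace <- function(path) {
  out <- normalize_units(read_csv_checked(path), path)
  if (!all(c("time_s", "intensity") %in% names(out)))
    abort(sprintf("%s is not a trace file (needs time_s, intensity).",
                  basename(path)))
  out
}

#' Read a protein-titration CSV
#'
#' Expects `P_tot_nM` (or another unit suffix) and `k_app_per_s`, optionally
#' `se_per_s`; concentrations are normalized to molar.
#'
#' @param path CSV file path.
#' @return A titration tibble suitable for [fit_titration()].
#' @export
read_titration <- function(path) {
  out <- normalize_units(read_csv_checked(path), path)
  if (!all(c("P_tot_M", "k_app_per_s") %in% names(out)))
    abort(sprintf("%s is not a titration file (needs P_tot_* and k_app_per_s).",
                  basename(path)))
  out
}

#' Serialize ionic-strength power laws to JSON
#'
#' @param laws A `power_law` tibble (any number of rows).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_power_laws <- function(laws, path) {
  need <- c("quantity", "slope", "intercept", "KCl_min_mM", "KCl_max_mM")
  stopifnot(all(need %in% names(laws)))
  jsonlite::write_json(
    list(format = "targetsearch_power_laws", version = 1L,
         log_base = 10L, laws = as.data.frame(laws[need])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ionic-strength power laws from JSON
#'
#' @param path JSON path written by [write_power_laws()].
#' @return A `power_law` tibble.
#' @export
read_power_laws <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "targetsearch_power_laws"))
    abort(sprintf("%s is not a power-law file.", basename(path)))
  laws <- tibble::as_tibble(obj$laws)
  class(laws) <- c("power_law", class(laws))
  laws
}

#' Export an ionic profile as CSV
#'
#' Writes the per-KCl decomposition (`KCl_mM`, `S`, `rho`, `eta`, `k_on_N`,
#' `k_a` and the parameter values) for human consumption.
#'
#' @param profile An `ionic_profile` from [decomposition_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    footprint_bp = 9, target_pos = 2, phi = 2, log_base = 10,
    K_d_N_by_KCl = data.frame(KCl_mM = c(40, 60, 80, 110, 150),
                              K_d_N_uM = c(1.4, 3.6, 4.6, 9.6, 16)),
    variant = "with_IT", weighted = FALSE, seed = 1L, output_dir = "."
  )
}

#' Read and validate a run configuration JSON
#'
#' A run configuration carries the fitting conventions (protein footprint,
#' target position, orientations per site, log base of the salt laws), the
#' fixed per-KCl nonspecific dissociation constants, the model variant, seed
#' and output directory. Unknown keys are rejected rather than silently
#' ignored; omitted keys fall back to the package defaults (the 9-bp
#' footprint / position-2 / two-orientation conventions and the 40-150 mM
#' `K_d_N` table).
#'
#' @param path JSON file path.
#' @return A named list of validated configuration values; the `K_d_N`
#'   table is returned with concentrations in molar (`K_d_N_M`).
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    abort(sprintf("Unknown run-config key(s): %s.",
                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$phi %in% c(1, 2)) abort("Config `phi` must be 1 or 2.")
  if (cfg$footprint_bp < 1) abort("Config `footprint_bp` must be >= 1.")
  if (!cfg$variant %in% c("with_IT", "without_IT"))
    abort("Config `variant` must be with_IT or without_IT.")
  if (!identical(as.numeric(cfg$log_base), 10))
    abort("Only base-10 salt laws are supported.")
  tbl <- as.data.frame(cfg$K_d_N_by_KCl)
  if (!all(c("KCl_mM", "K_d_N_uM") %in% names(tbl)))
    abort("Config `K_d_N_by_KCl` needs columns KCl_mM and K_d_N_uM.")
  cfg$K_d_N_by_KCl <- tibble::tibble(KCl_mM = as.numeric(tbl$KCl_mM),
                                     K_d_N_M = as.numeric(tbl$K_d_N_uM) * 1e-6)
  cfg
}
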