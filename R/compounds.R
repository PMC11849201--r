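#' Glass-transition reference parameters
#'
#' Reference constants of the hydrogen-bonding model linking the dry glass
#' transition temperature of a carbohydrate plasticizer to its effective
#' number of hydrogen-bonding sites. `tg_w` is the glass transition of pure
#' water (139 K) and `tg_inf` the glass transition of the reference large
#' polymer towards which the plasticizer family converges. For glucans
#' (maltopolymer/starch reference) `tg_inf = 475` K; for fructans the
#' consistent reference is 447.5 K, obtained by inverting the site-count
#' relation against well-characterised fructo-oligosaccharides and inulins.
#' Water carries `noh_w = 2` hydrogen-bonding sites per molecule.
#'
#' @param structure_class `"glucan"`, `"fructan"` or `"other"` (treated as
#'   glucan-like).
#' @param tg_inf Optional override of the reference polymer Tg in K.
#' @return A list with elements `tg_w`, `tg_inf` and `noh_w`.
#' @examples
#' glass_params("glucan")$tg_inf   # 475
#' glass_params("fructan")$tg_inf  # 447.5
#' @export
glass_params <- function(structure_class = "glucan", tg_inf = NULL) {
  structure_class <- match.arg(structure_class, c("glucan", "fructan", "other"))
  default_inf <- c(glucan = 475, fructan = 447.5, other = 475)[[structure_class]]
  list(tg_w = 139, tg_inf = tg_inf %||% default_inf, noh_w = 2)
}

#' Effective hydrogen-bonding sites from the dry glass transition
#'
#' Carbohydrate plasticizers depress a polymer glass transition in proportion
#' to the density of hydrogen-bonding sites they expose; conversely the dry
#' Tg of the plasticizer itself encodes how many of its hydroxyls are
#' effectively available (intramolecular hydrogen bonds remove some). The
#' closed form is
#' \deqn{N_{OH,s} = \frac{2\,(T_{g\infty} - T_{g,w})}{T_{g\infty} - T_g}}
#' which equals 2 (the water value) at `tg_dry = tg_w` and diverges as the
#' plasticizer approaches the reference polymer Tg.
#'
#' @param tg_dry Dry glass transition temperature(s) in K.
#' @param glass Output of [glass_params()].
#' @return Effective number of hydrogen-bonding sites per molecule (>= 2).
#' @examples
#' noh_from_tg(389)  # glucose syrup, 7.81 sites
#' noh_from_tg(421, glass_params("fructan"))  # long-chain inulin
#' @seealso [tg_from_noh()] for the algebraic inverse.
#' @export
noh_from_tg <- function(tg_dry, glass = glass_params()) {
  stopifnot(is.numeric(tg_dry))
  if (any(tg_dry < glass$tg_w)) {
    abort("`tg_dry` below the pure-water glass transition (139 K) is outside the model domain.")
  }
  if (any(tg_dry >= glass$tg_inf)) {
    abort(sprintf(
      "`tg_dry` >= tg_inf (%.1f K): the effective site count diverges.", glass$tg_inf
    ))
  }
  2 * (glass$tg_inf - glass$tg_w) / (glass$tg_inf - tg_dry)
}

#' Dry glass transition from the effective site count
#'
#' Algebraic inverse of [noh_from_tg()]: `Tg = Tg_inf - 2 (Tg_inf - Tg_w) / N`.
#'
#' @param noh Effective hydrogen-bonding sites per molecule (>= 2).
#' @inheritParams noh_from_tg
#' @return Dry glass transition temperature(s) in K.
#' @export
tg_from_noh <- function(noh, glass = glass_params()) {
  stopifnot(is.numeric(noh))
  if (any(noh < 2)) {
    abort("`noh` < 2 is outside the model domain (water has 2 sites).")
  }
  glass$tg_inf - 2 * (glass$tg_inf - glass$tg_w) / noh
}

#' Molar volume of a compound
#'
#' @param mw Molar mass in g/mol.
#' @param rho Mass density in kg/m^3.
#' @return Molar volume in cm^3/mol (`mw / (rho/1000)`).
#' @examples
#' molar_volume(18, 1000)  # water: 18 cm^3/mol
#' @export
molar_volume <- function(mw, rho) {
  stopifnot(all(mw > 0), all(rho > 0))
  mw / (rho / 1000)
}

#' Hydrogen-bonding sites per molar volume
#'
#' The intrinsic plasticizing strength of a compound: effective
#' hydrogen-bonding sites per cm^3/mol of molar volume, reported on the
#' conventional 10^-3 mol/cm^3 scale (water = 111.1).
#'
#' @param noh Effective sites per molecule.
#' @inheritParams molar_volume
#' @return `1000 * noh / molar_volume(mw, rho)` in 10^-3 mol/cm^3.
#' @export
noh_per_volume <- function(noh, mw, rho) {
  stopifnot(all(noh > 0))
  1000 * noh / molar_volume(mw, rho)
}

compound_cols <- c("name", "structure_class", "mw_g_mol", "density_kg_m3",
                   "tg_dry_K", "noh_s", "chi_s")

validate_compounds <- function(df, file = "registry") {
  missing <- setdiff(compound_cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required columns: %s",
                  file, paste(missing, collapse = ", ")))
  }
  bad <- character(0)
  if (any(df$mw_g_mol <= 0, na.rm = TRUE)) bad <- c(bad, "mw_g_mol must be > 0")
  if (any(df$density_kg_m3 <= 0, na.rm = TRUE)) bad <- c(bad, "density_kg_m3 must be > 0")
  if (any(df$tg_dry_K < 139, na.rm = TRUE)) bad <- c(bad, "tg_dry_K must be >= 139 K")
  if (any(df$noh_s < 2, na.rm = TRUE)) bad <- c(bad, "noh_s must be >= 2")
  if (any(df$chi_s < 0 | df$chi_s > 2, na.rm = TRUE)) bad <- c(bad, "chi_s must lie in [0, 2]")
  if (!all(df$structure_class %in% c("glucan", "fructan", "other"))) {
    bad <- c(bad, "structure_class must be one of glucan/fructan/other")
  }
  if (anyDuplicated(df$name)) bad <- c(bad, "compound names must be unique")
  if (length(bad) > 0) {
    abort(paste0("Invalid compound registry (", file, "):\n  ",
                 paste(bad, collapse = "\n  ")))
  }
  invisible(df)
}

#' Packaged compound registry
#'
#' Physico-chemical properties of water, dextrose, a glucose syrup (Myl) and
#' seven soluble fibres: fructo-oligosaccharides (FOS, OFP), inulins of
#' increasing chain length (CLR, IQ, TEX) and polydextrose (PDX). Columns:
#' molar mass (g/mol), density (kg/m^3), dry glass transition (K), effective
#' hydrogen-bonding sites, sites per molar volume (10^-3 mol/cm^3, the
#' reference reporting scale) and the Flory-Huggins water interaction
#' parameter `chi_s` (lower = more hygroscopic).
#'
#' The tabulated `noh_s` and `noh_per_volume` values are the registry of
#' record; recomputing them through [noh_from_tg()] and [noh_per_volume()] is
#' a validation path (agreement is within rounding for all compounds, with
#' small tabulation gaps for Myl, dextrose and PDX in `noh_per_volume`).
#'
#' @return A tibble with one row per compound.
#' @examples
#' default_compounds()
#' @export
default_compounds <- function() {
  read_compounds(system.file("extdata", "compounds_table1.csv",
                             package = "fibredough", mustWork = TRUE))
}

#' Read a compound registry from CSV
#'
#' Expected header:
#' `name,structure_class,mw_g_mol,density_kg_m3,tg_dry_K,noh_s,chi_s` with an
#' optional `noh_per_volume` column (10^-3 mol/cm^3). If absent, sites per
#' molar volume are recomputed from `noh_s`, `mw_g_mol` and `density_kg_m3`.
#'
#' @param path CSV file path.
#' @return A tibble of compounds; empty files yield an empty registry with a
#'   warning.
#' @export
read_compounds <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warn(sprintf("Compound registry '%s' is empty.", path))
    return(tibble::as_tibble(df))
  }
  validate_compounds(df, file = path)
  df <- tibble::as_tibble(df)
  if (!"noh_per_volume" %in% names(df)) {
    df$noh_per_volume <- noh_per_volume(df$noh_s, df$mw_g_mol, df$density_kg_m3)
  }
  dplyr::relocate(df, "noh_per_volume", .after = "noh_s")
}

#' Annotate a compound table with derived quantities
#'
#' Adds molar volume, the site count recomputed from the dry Tg (using the
#' per-class reference polymer Tg) and the recomputed sites-per-volume, so
#' tabulated and model-derived values can be compared side by side.
#'
#' @param compounds A compound tibble, e.g. [default_compounds()].
#' @return The input with columns `v_s_cm3_mol`, `noh_from_tg`,
#'   `noh_per_volume_recomputed` appended.
#' @export
annotate_compounds <- function(compounds) {
  validate_compounds(compounds, "compounds")
  compounds |>
    dplyr::mutate(
      v_s_cm3_mol = molar_volume(.data$mw_g_mol, .data$density_kg_m3),
      noh_from_tg = purrr::map2_dbl(
        .data$tg_dry_K, .data$structure_class,
        function(tg, cls) noh_from_tg(tg, glass_params(cls))
      ),
      noh_per_volume_recomputed =
        noh_per_volume(.data$noh_s, .data$mw_g_mol, .data$density_kg_m3)
    )
}
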