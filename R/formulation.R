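#' Packaged dough recipe set
#'
#' Twelve bread-dough formulations: a reference dough and eleven doughs in
#' which 9% of the flour is replaced by soluble fibres, singly or in pairs,
#' each hydrated to equal consistency (hence differing added-water levels).
#' Long format: one row per ingredient with columns `dough`, `ingredient`,
#' `mass_g` and `role` (`water`, `flour`, `gluten`, `solute` or `excluded`).
#' Salt, yeast and oil carry the `excluded` role: they are recorded but do
#' not enter the solvent-phase volume.
#'
#' @return A tibble of recipe rows.
#' @export
default_recipes <- function() {
  read_recipes(system.file("extdata", "dough_recipes_table2.csv",
                           package = "fibredough", mustWork = TRUE))
}

#' Reference physico-chemical parameters of the packaged doughs
#'
#' The published descriptor block for the twelve packaged recipes
#' (`phi_w_eff`, `chi_eff`, `noh_v_eff`, `phi_flour`), used by
#' [reproduce_tables()] as the comparison fixture.
#'
#' @return A tibble with one row per dough.
#' @export
reference_params <- function() {
  readr::read_csv(system.file("extdata", "dough_reference_params.csv",
                              package = "fibredough", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

recipe_roles <- c("water", "flour", "gluten", "solute", "excluded")

validate_recipes <- function(df, file = "recipes") {
  need <- c("dough", "ingredient", "mass_g", "role")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required columns: %s",
                  file, paste(missing, collapse = ", ")))
  }
  if (any(df$mass_g < 0)) abort("Ingredient masses must be non-negative.")
  bad_role <- setdiff(unique(df$role), recipe_roles)
  if (length(bad_role) > 0) {
    abort(sprintf("Unknown ingredient role(s): %s", paste(bad_role, collapse = ", ")))
  }
  invisible(df)
}

#' Read a dough recipe table from CSV
#'
#' Expected header: `dough,ingredient,mass_g,role` with roles
#' `water|flour|gluten|solute|excluded`. Solute ingredient names must match
#' compound registry names.
#'
#' @param path CSV file path.
#' @return A tibble of recipe rows.
#' @export
read_recipes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_recipes(df, file = path)
  tibble::as_tibble(df)
}

#' Solvent-phase volumes of a dough recipe
#'
#' Maps ingredient masses to component volumes under the fixed convention
#' used throughout the package: the solvent-phase total comprises water
#' (added water plus flour moisture), flour solids, added vital gluten and
#' dissolved solutes; salt, yeast and oil are excluded. Flour solids and
#' gluten use a density of 1500 kg/m^3 and gluten is treated as dry; solute
#' densities come from the compound registry.
#'
#' @param recipes A recipe tibble (see [default_recipes()]), one or more
#'   doughs.
#' @param compounds Compound registry supplying solute densities and
#'   hydrogen-bonding descriptors.
#' @param flour_moisture Flour moisture mass fraction (default 0.155).
#' @param rho_flour Density of flour solids and gluten, kg/m^3.
#' @param rho_w Water density, kg/m^3.
#' @return A tibble with one row per dough component: `dough`, `component`,
#'   `role` and `volume_cm3`.
#' @examples
#' phase_volumes(default_recipes(), default_compounds()) |>
#'   dplyr::count(dough, wt = volume_cm3, name = "V_total_cm3")
#' @export
phase_volumes <- function(recipes, compounds = default_compounds(),
                          flour_moisture = 0.155, rho_flour = 1500,
                          rho_w = 1000) {
  validate_recipes(recipes, "recipes")
  if (flour_moisture < 0 || flour_moisture > 0.3) {
    abort("`flour_moisture` must lie in [0, 0.3].")
  }
  solutes <- dplyr::filter(recipes, .data$role == "solute")
  unknown <- setdiff(unique(solutes$ingredient), compounds$name)
  if (length(unknown) > 0) {
    abort(sprintf("Solute(s) not in the compound registry: %s",
                  paste(unknown, collapse = ", ")))
  }
  rho_of <- stats::setNames(compounds$density_kg_m3, compounds$name)

  recipes |>
    dplyr::group_by(.data$dough) |>
    dplyr::group_modify(function(d, key) {
      m_flour <- sum(d$mass_g[d$role == "flour"])
      m_added_water <- sum(d$mass_g[d$role == "water"])
      m_gluten <- sum(d$mass_g[d$role == "gluten"])
      sol <- d[d$role == "solute", ] |>
        dplyr::count(.data$ingredient, wt = .data$mass_g, name = "mass_g")
      out <- tibble::tibble(
        component = c("water", "flour_solids", "gluten", sol$ingredient),
        role = c("water", "flour", "gluten", rep("solute", nrow(sol))),
        volume_cm3 = c(
          (m_added_water + m_flour * flour_moisture) / (rho_w / 1000),
          m_flour * (1 - flour_moisture) / (rho_flour / 1000),
          m_gluten / (rho_flour / 1000),
          sol$mass_g / (rho_of[sol$ingredient] / 1000)
        )
      )
      dplyr::filter(out, .data$volume_cm3 > 0 | .data$role %in% c("water", "flour"))
    }) |>
    dplyr::ungroup()
}

solute_weighted <- function(volumes, compounds, column) {
  sol <- dplyr::filter(volumes, .data$role == "solute")
  if (nrow(sol) == 0 || sum(sol$volume_cm3) <= 0) {
    abort("No solute volume: the solute-weighted mean is undefined.")
  }
  vals <- stats::setNames(compounds[[column]], compounds$name)[sol$component]
  sum(sol$volume_cm3 * vals) / sum(sol$volume_cm3)
}

params_one <- function(volumes, compounds, v_w = 18, noh_w = 2) {
  v_total <- sum(volumes$volume_cm3)
  if (v_total <= 0) abort("Total solvent-phase volume is zero.")
  phi <- stats::setNames(volumes$volume_cm3 / v_total, volumes$component)
  sol <- dplyr::filter(volumes, .data$role == "solute")
  nohv <- stats::setNames(compounds$noh_per_volume, compounds$name)
  # Eq. for phi_w_eff: each solute contributes its H-bond sites scaled to
  # water-equivalent volume; noh_per_volume is on the 1e-3 mol/cm^3 scale.
  phi_w_eff <- phi[["water"]] +
    sum(phi[sol$component] * nohv[sol$component] * 1e-3 * v_w / noh_w)
  tibble::tibble(
    phi_w = phi[["water"]],
    phi_w_eff = phi_w_eff,
    chi_eff = if (nrow(sol) > 0) solute_weighted(volumes, compounds, "chi_s") else NA_real_,
    noh_v_eff = if (nrow(sol) > 0) solute_weighted(volumes, compounds, "noh_per_volume") else NA_real_,
    phi_flour = sum(volumes$volume_cm3[volumes$role == "flour"]) / v_total,
    v_total_cm3 = v_total
  )
}

#' Effective water volume fraction of a solvent phase
#'
#' The water volume fraction augmented by each dissolved solute's
#' contribution of hydrogen-bonding sites, expressed in water-equivalent
#' volume: `phi_w + sum_i phi_s_i * (N_OH,s/v_s)_i * v_w / N_OH,w`.
#'
#' @param volumes Output of [phase_volumes()] for a single dough.
#' @param compounds Compound registry.
#' @param v_w Water molar volume, cm^3/mol.
#' @param noh_w Hydrogen-bonding sites per water molecule.
#' @return Scalar effective water volume fraction.
#' @export
phi_w_eff <- function(volumes, compounds = default_compounds(),
                      v_w = 18, noh_w = 2) {
  single_dough(volumes)
  params_one(volumes, compounds, v_w, noh_w)$phi_w_eff
}

#' Effective water interaction parameter of a solute mixture
#'
#' Solute-volume-weighted mean of the per-compound Flory-Huggins water
#' interaction parameters; water itself carries no weight.
#'
#' @inheritParams phi_w_eff
#' @return Scalar effective interaction parameter.
#' @export
chi_eff <- function(volumes, compounds = default_compounds()) {
  single_dough(volumes)
  solute_weighted(volumes, compounds, "chi_s")
}

#' Effective hydrogen-bonding sites per molar volume of a solute mixture
#'
#' Solute-volume-weighted mean of the registry `noh_per_volume` values, on
#' the 10^-3 mol/cm^3 reporting scale.
#'
#' @inheritParams phi_w_eff
#' @return Scalar, 10^-3 mol/cm^3.
#' @export
noh_v_eff <- function(volumes, compounds = default_compounds()) {
  single_dough(volumes)
  solute_weighted(volumes, compounds, "noh_per_volume")
}

#' Flour volume fraction of the solvent phase
#'
#' Flour solids over the solvent-phase total; added vital gluten is part of
#' the total but not of the numerator.
#'
#' @inheritParams phi_w_eff
#' @return Scalar volume fraction.
#' @export
phi_flour <- function(volumes) {
  single_dough(volumes)
  sum(volumes$volume_cm3[volumes$role == "flour"]) / sum(volumes$volume_cm3)
}

single_dough <- function(volumes) {
  stopifnot(is.data.frame(volumes), "volume_cm3" %in% names(volumes))
  if ("dough" %in% names(volumes) && dplyr::n_distinct(volumes$dough) > 1) {
    abort("Pass volumes for a single dough; use formulation_params() for batches.")
  }
  invisible(volumes)
}

#' Physico-chemical descriptors for a batch of dough recipes
#'
#' Computes, per dough, the four descriptors that summarise the solvent
#' phase: effective water volume fraction (`phi_w_eff`), effective water
#' interaction parameter (`chi_eff`), effective hydrogen-bonding sites per
#' molar volume (`noh_v_eff`, 10^-3 mol/cm^3) and the flour volume fraction
#' (`phi_flour`), together with the raw water fraction and total volume.
#'
#' @inheritParams phase_volumes
#' @return A tibble with one row per dough.
#' @examples
#' formulation_params(default_recipes())
#' @export
formulation_params <- function(recipes, compounds = default_compounds(),
                               flour_moisture = 0.155, rho_flour = 1500,
                               rho_w = 1000) {
  if (nrow(recipes) == 0) {
    return(tibble::tibble(dough = character(0), phi_w = double(0),
                          phi_w_eff = double(0), chi_eff = double(0),
                          noh_v_eff = double(0), phi_flour = double(0),
                          v_total_cm3 = double(0)))
  }
  vols <- phase_volumes(recipes, compounds, flour_moisture, rho_flour, rho_w)
  vols |>
    dplyr::group_by(.data$dough) |>
    dplyr::group_modify(function(v, key) {
      tryCatch(params_one(v, compounds),
               error = function(e) {
                 abort(sprintf("dough '%s': %s", key$dough, conditionMessage(e)))
               })
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$dough, unique(recipes$dough)))
}
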