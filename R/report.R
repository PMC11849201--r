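#' Recompute every derivable reference-table cell and compare
#'
#' Runs the package end to end on its packaged fixtures and compares each
#' recomputable quantity with its published value: the hydrogen-bonding site
#' counts of the glucan compounds from their dry glass transitions, the
#' sites-per-molar-volume column, the four dough descriptors of the twelve
#' packaged recipes, and the three ratio descriptors of the gluten-network
#' table recomputed from the printed primitive columns.
#'
#' @param tolerances Named list of per-quantity comparison tolerances.
#'   Defaults: `noh_s` 0.01, `noh_per_volume` 0.1 (1.0 for the three
#'   compounds with documented tabulation gaps), `phi_w_eff` 0.002,
#'   `chi_eff` 0.007, `noh_v_eff` 0.3, `phi_flour` 0.002, network rates
#'   1e-4, width 0.03.
#' @return A tibble with one row per compared cell: `table`, `row`,
#'   `quantity`, `reference`, `recomputed`, `tolerance`, `pass`. Known
#'   documented discrepancies (the D_FOS effective site density and its
#'   knock-on effective water fraction, and one network width cell) fail at
#'   tight tolerances by construction; the `pass` column simply reports it.
#' @examples
#' rep <- reproduce_tables()
#' dplyr::count(rep, table, pass)
#' @export
reproduce_tables <- function(tolerances = list()) {
  tol <- utils::modifyList(list(
    noh_s = 0.01, noh_per_volume = 0.1, noh_per_volume_relaxed = 1.0,
    phi_w_eff = 0.002, chi_eff = 0.007, noh_v_eff = 0.3, phi_flour = 0.002,
    branching_rate = 1e-4, endpoint_rate = 1e-4, protein_width_um = 0.03
  ), tolerances)
  comp <- annotate_compounds(default_compounds())

  rows_compounds <- comp |>
    dplyr::filter(.data$structure_class == "glucan") |>
    dplyr::transmute(
      table = "compounds", row = .data$name, quantity = "noh_s",
      reference = .data$noh_s, recomputed = .data$noh_from_tg,
      tolerance = tol$noh_s
    )
  relaxed <- c("Myl", "dextrose", "PDX")
  rows_nohv <- comp |>
    dplyr::transmute(
      table = "compounds", row = .data$name, quantity = "noh_per_volume",
      reference = .data$noh_per_volume,
      recomputed = .data$noh_per_volume_recomputed,
      tolerance = ifelse(.data$name %in% relaxed,
                         tol$noh_per_volume_relaxed, tol$noh_per_volume)
    )

  params <- formulation_params(default_recipes())
  ref <- reference_params()
  rows_params <- c("phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour") |>
    purrr::map(function(q) {
      tibble::tibble(
        table = "formulation", row = ref$dough, quantity = q,
        reference = ref[[q]],
        recomputed = params[[q]][match(ref$dough, params$dough)],
        tolerance = tol[[q]]
      )
    }) |>
    purrr::list_rbind()

  net <- readr::read_csv(
    system.file("extdata", "gluten_network_table4.csv",
                package = "fibredough", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
  rat <- derived_ratios(net$protein_area_um2, net$n_junctions,
                        net$n_endpoints, net$total_length_um)
  rows_net <- c("branching_rate", "endpoint_rate", "protein_width_um") |>
    purrr::map(function(q) {
      tibble::tibble(
        table = "network", row = net$dough, quantity = q,
        reference = net[[q]], recomputed = rat[[q]], tolerance = tol[[q]]
      )
    }) |>
    purrr::list_rbind()

  dplyr::bind_rows(rows_compounds, rows_nohv, rows_params, rows_net) |>
    dplyr::mutate(pass = abs(.data$recomputed - .data$reference) <= .data$tolerance)
}

#' Run the descriptor-to-response pipeline on tabular inputs
#'
#' Chains the formulation stage (recipes to descriptors), optional
#' reduced-variable backward regression of supplied responses on the four
#' descriptors, and the pairwise correlation table. Stages whose inputs are
#' absent are skipped with a message rather than an error.
#'
#' @param recipes Recipe tibble (default: the packaged set).
#' @param compounds Compound registry.
#' @param responses Optional tibble of responses with a `dough` column
#'   matching the recipes plus one numeric column per response.
#' @param alpha Backward-elimination threshold.
#' @return A list with `params`, `reduced`, `fits` (named list of
#'   `backward_lm`, if responses given), `correlations`.
#' @export
run_pipeline <- function(recipes = default_recipes(),
                         compounds = default_compounds(),
                         responses = NULL, alpha = 0.05) {
  params <- formulation_params(recipes, compounds)
  preds <- params[c("dough", "phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour")]
  reduced <- reduce_variables(preds)
  fits <- NULL
  if (is.null(responses)) {
    message("No responses supplied; regression stage skipped.")
  } else {
    stopifnot("dough" %in% names(responses))
    merged <- dplyr::inner_join(reduced, responses, by = "dough")
    resp_cols <- setdiff(names(responses), "dough")
    fits <- purrr::map(
      stats::setNames(resp_cols, resp_cols),
      function(r) fit_backward(merged, r,
                               c("phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour"),
                               alpha = alpha)
    )
  }
  list(
    params = params,
    reduced = reduced,
    fits = fits,
    correlations = pearson_matrix(
      params[c("phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour")]
    )
  )
}
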