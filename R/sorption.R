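#' Water volume fraction from moisture content
#'
#' Converts a gravimetric water content (g water per g dry solid) to the
#' water volume fraction of the solid-water mixture, assuming additive
#' volumes.
#'
#' @param x Water content in g/g dry solid (>= 0).
#' @param rho_s Dry-solid density in kg/m^3.
#' @param rho_w Water density in kg/m^3 (default 1000).
#' @return Volume fraction of water in `[0, 1)`.
#' @examples
#' phi_w_from_x(0, 1550)               # 0
#' phi_w_from_x(1000 / 1550, 1550)     # 0.5 by construction
#' @export
phi_w_from_x <- function(x, rho_s, rho_w = 1000) {
  if (any(x < 0)) abort("Water content `x` must be non-negative.")
  stopifnot(all(rho_s > 0))
  (x / rho_w) / (x / rho_w + 1 / rho_s)
}

#' Moisture content from water volume fraction
#'
#' Inverse of [phi_w_from_x()]; used by the isotherm generator.
#'
#' @param phi_w Water volume fraction in `[0, 1)`.
#' @inheritParams phi_w_from_x
#' @return Water content in g/g dry solid.
#' @export
x_from_phi_w <- function(phi_w, rho_s, rho_w = 1000) {
  stopifnot(all(phi_w >= 0), all(phi_w < 1))
  (phi_w / (1 - phi_w)) * rho_w / rho_s
}

#' Water activity of a rubbery solute-water mixture
#'
#' Flory-Huggins expression for the solvent activity of a plasticized
#' carbohydrate above its mixture glass transition (the rubbery regime,
#' where sorption is governed solely by the interaction parameter):
#' \deqn{\ln a_w = \ln\Phi_w + (1 - v_w/v_s)(1 - \Phi_w) + \chi (1 - \Phi_w)^2}
#'
#' @param phi_w Water volume fraction in `(0, 1]`.
#' @param chi Flory-Huggins water interaction parameter.
#' @param v_s Solute molar volume in cm^3/mol.
#' @param v_w Water molar volume in cm^3/mol (default 18).
#' @return Water activity in `(0, 1]`.
#' @examples
#' aw_rubbery(1, 0.8, 1141)     # pure water: exactly 1
#' aw_rubbery(0.5, 0.84, 1141)
#' @export
aw_rubbery <- function(phi_w, chi, v_s, v_w = 18) {
  if (any(phi_w <= 0)) abort("`phi_w` = 0 gives log(0): water activity is undefined.")
  stopifnot(all(phi_w <= 1), all(v_s > 0))
  exp(log(phi_w) + (1 - v_w / v_s) * (1 - phi_w) + chi * (1 - phi_w)^2)
}

#' Glass transition of a solute-water mixture
#'
#' Couchman-Karasz mixing rule weighted by mass fractions and heat-capacity
#' increments; masses follow from volumes through the component densities.
#' Decreases monotonically from the dry-solute Tg at `phi_w = 0` to the
#' pure-water value (139 K) at `phi_w = 1`. Used to locate the rubbery
#' regime: sorption points with a mixture Tg below the measuring temperature
#' are the ones the Flory-Huggins fit may use.
#'
#' @param phi_w Water volume fraction in `[0, 1]`.
#' @param tg_s Dry-solute glass transition in K.
#' @param rho_s Solute density in kg/m^3.
#' @param dcp_w,dcp_s Heat-capacity increments at Tg for water and solute in
#'   J/(g K); defaults 1.94 and 0.5.
#' @param tg_w Pure-water glass transition in K.
#' @param rho_w Water density in kg/m^3.
#' @return Mixture glass transition in K.
#' @export
tg_mixture <- function(phi_w, tg_s, rho_s, dcp_w = 1.94, dcp_s = 0.5,
                       tg_w = 139, rho_w = 1000) {
  stopifnot(all(phi_w >= 0), all(phi_w <= 1), all(dcp_w > 0), all(dcp_s > 0))
  m_w <- phi_w * rho_w
  m_s <- (1 - phi_w) * rho_s
  (m_w * dcp_w * tg_w + m_s * dcp_s * tg_s) / (m_w * dcp_w + m_s * dcp_s)
}

#' Fit the water interaction parameter to a sorption isotherm
#'
#' Least-squares fit of the Flory-Huggins interaction parameter `chi` in
#' [aw_rubbery()] to measured (water activity, moisture content) pairs.
#' Only points in the rubbery regime are used: those with a water volume
#' fraction above `phi_w_cutoff` (default 0.2, the fraction at which the
#' mixture Tg of common soluble fibres crosses room temperature). The
#' objective is squared error in water-activity space, matching an
#' instrument whose error is uniform in `a_w`; duplicate points therefore
#' weigh in proportionally.
#'
#' @param isotherm A data frame with columns `aw` (water activity, in (0,1))
#'   and `x` (water content, g/g dry solid).
#' @param rho_s Solute density in kg/m^3.
#' @param v_s Solute molar volume in cm^3/mol (see [molar_volume()]).
#' @param phi_w_cutoff Rubbery-regime volume-fraction cutoff (default 0.2).
#' @param chi_bounds Search interval for `chi` (default `c(0, 2)`).
#' @return An object of class `fhfv_fit`: a list with `chi_hat`, `rss`
#'   (residual sum of squares in `a_w`), `n_used`, `phi_w_cutoff`, `v_s`,
#'   `rho_s` and the point table with fitted activities. Supports [tidy()],
#'   [glance()], [augment()] and [autoplot()].
#' @examples
#' iso <- gen_isotherm(chi_true = 0.84, v_s = 1141, rho_s = 1550,
#'                     n_points = 20, sigma_aw = 0, seed = 1)
#' fit_chi(iso, rho_s = 1550, v_s = 1141)$chi_hat  # recovers 0.84
#' @export
fit_chi <- function(isotherm, rho_s, v_s, phi_w_cutoff = 0.2,
                    chi_bounds = c(0, 2)) {
  stopifnot(is.data.frame(isotherm), all(c("aw", "x") %in% names(isotherm)))
  if (any(isotherm$aw <= 0 | isotherm$aw >= 1)) {
    abort("Water activities must lie strictly inside (0, 1).")
  }
  pts <- tibble::as_tibble(isotherm) |>
    dplyr::mutate(phi_w = phi_w_from_x(.data$x, rho_s)) |>
    dplyr::arrange(.data$aw)
  rubbery <- dplyr::filter(pts, .data$phi_w > phi_w_cutoff)
  if (nrow(rubbery) < 3) {
    abort(sprintf(
      "Only %d point(s) above the rubbery cutoff phi_w > %.2f; at least 3 are required.",
      nrow(rubbery), phi_w_cutoff
    ))
  }
  obj <- function(chi) {
    sum((aw_rubbery(rubbery$phi_w, chi, v_s) - rubbery$aw)^2)
  }
  opt <- optimize(obj, interval = chi_bounds, tol = 1e-10)
  pts$aw_fitted <- aw_rubbery(pts$phi_w, opt$minimum, v_s)
  structure(
    list(
      chi_hat = opt$minimum,
      rss = opt$objective,
      n_used = nrow(rubbery),
      phi_w_cutoff = phi_w_cutoff,
      v_s = v_s,
      rho_s = rho_s,
      points = pts
    ),
    class = "fhfv_fit"
  )
}

#' @export
print.fhfv_fit <- function(x, ...) {
  cat("Flory-Huggins sorption fit (rubbery regime)\n")
  cat(sprintf("  chi_hat = %.4f   rss(a_w) = %.3g   points used = %d (phi_w > %.2f)\n",
              x$chi_hat, x$rss, x$n_used, x$phi_w_cutoff))
  invisible(x)
}

#' @export
tidy.fhfv_fit <- function(x, ...) {
  tibble::tibble(term = "chi", estimate = x$chi_hat)
}

#' @export
glance.fhfv_fit <- function(x, ...) {
  tibble::tibble(chi_hat = x$chi_hat, rss = x$rss, n_used = x$n_used,
                 phi_w_cutoff = x$phi_w_cutoff)
}

#' @export
augment.fhfv_fit <- function(x, ...) {
  dplyr::mutate(x$points, .resid = .data$aw - .data$aw_fitted)
}

#' @describeIn fit_chi Plot the isotherm points and fitted sorption curve;
#'   points below the rubbery cutoff are hollow.
#' @param object An `fhfv_fit`.
#' @param ... Ignored.
#' @export
autoplot.fhfv_fit <- function(object, ...) {
  pts <- dplyr::mutate(object$points,
                       used = .data$phi_w > object$phi_w_cutoff)
  grid <- tibble::tibble(phi_w = seq(max(object$phi_w_cutoff, 1e-3), 0.95,
                                     length.out = 200))
  grid$aw <- aw_rubbery(grid$phi_w, object$chi_hat, object$v_s)
  grid$x <- x_from_phi_w(grid$phi_w, object$rho_s)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$aw, y = .data$x)) +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "rubbery") +
    ggplot2::labs(
      x = "water activity",
      y = "water content (g/g dry solid)",
      title = sprintf("FHFV sorption fit: chi = %.3f", object$chi_hat)
    )
}
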