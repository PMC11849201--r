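#' Flory melting-point depression of a polymer by a diluent
#'
#' Melting temperature of a semi-crystalline biopolymer (starch, gluten)
#' plasticized by a low-molar-volume diluent, from Flory's melting-point
#' depression relation:
#' \deqn{1/T_m = 1/T_m^0 + (R/\Delta H_u)(v_u/v_w)(\phi - \chi_p \phi^2)}
#' where `phi` is the diluent (effective water) volume fraction. The default
#' parameters describe a starch-like melting line (dry melting point 515 K,
#' 25.9 kJ/mol per anhydroglucose unit); they are configuration, not fitted
#' values, and any quantitative use should supply system-specific parameters.
#'
#' @param phi Diluent volume fraction in `[0, 1)`; the effective water
#'   fraction of a dough is the natural argument.
#' @param tm0 Melting point of the dry polymer, K.
#' @param dh_u Melting enthalpy per monomer unit, J/mol.
#' @param v_u Monomer molar volume, cm^3/mol.
#' @param v_w Diluent molar volume, cm^3/mol.
#' @param chi_p Polymer-diluent interaction parameter in `[0, 1]`.
#' @return Melting temperature(s) in K; equals `tm0` at `phi = 0` and
#'   decreases with `phi` for `chi_p <= 0.5`.
#' @examples
#' melting_temperature(0)            # 515 K
#' melting_temperature(c(0.2, 0.5))  # depressed melting points
#' @export
melting_temperature <- function(phi, tm0 = 515, dh_u = 25900, v_u = 100,
                                v_w = 18, chi_p = 0.5) {
  stopifnot(all(phi >= 0), tm0 > 0, dh_u > 0, v_u > 0, v_w > 0,
            chi_p >= 0, chi_p <= 1)
  if (any(phi >= 1)) abort("`phi` must be < 1: the pure-diluent limit is outside the melting line.")
  inv <- 1 / tm0 + (8.314 / dh_u) * (v_u / v_w) * (phi - chi_p * phi^2)
  if (any(inv <= 0)) abort("Parameters drive 1/Tm <= 0; no physical melting temperature.")
  1 / inv
}

#' State diagram of dough baking transitions
#'
#' Evaluates configured Flory melting lines (by default a starch
#' gelatinization line and a gluten thermosetting line) over a grid of
#' diluent volume fractions, producing a plot-ready table onto which
#' measured DSC onset/peak temperatures can be placed at each dough's
#' effective water fraction.
#'
#' @param phi Numeric grid of diluent volume fractions in `[0, 1)`.
#' @param lines Named list of parameter lists passed to
#'   [melting_temperature()]; defaults to a starch and a gluten line.
#' @return A tibble with columns `phi`, `line`, `T_K` and `T_C`.
#' @examples
#' state_diagram(seq(0, 0.8, by = 0.1))
#' @export
state_diagram <- function(phi,
                          lines = list(
                            starch = list(tm0 = 515, dh_u = 25900, v_u = 100, chi_p = 0.5),
                            gluten = list(tm0 = 435, dh_u = 19000, v_u = 110, chi_p = 0.5)
                          )) {
  if (length(phi) == 0) {
    return(tibble::tibble(phi = double(0), line = character(0),
                          T_K = double(0), T_C = double(0)))
  }
  purrr::imap(lines, function(p, nm) {
    tk <- do.call(melting_temperature, c(list(phi = phi), p))
    tibble::tibble(phi = phi, line = nm, T_K = tk, T_C = tk - 273.15)
  }) |>
    purrr::list_rbind()
}

#' Plot a dough-baking state diagram
#'
#' @param diagram Output of [state_diagram()].
#' @param points Optional tibble of measured transitions with columns `phi`,
#'   `T_C` and a `label` column, drawn over the melting lines.
#' @return A ggplot object.
#' @export
plot_state_diagram <- function(diagram, points = NULL) {
  p <- ggplot2::ggplot(diagram, ggplot2::aes(x = .data$phi, y = .data$T_C,
                                             colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(phi["w,eff"]), y = "temperature (\u00b0C)",
                  colour = NULL, title = "Baking state diagram")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$phi, y = .data$T_C, shape = .data$label),
      inherit.aes = FALSE
    )
  }
  p
}

validate_curve <- function(curve, xcol = "temperature_C", ycol = "value") {
  stopifnot(is.data.frame(curve), all(c(xcol, ycol) %in% names(curve)))
  if (nrow(curve) < 10) abort("Curves need at least 10 samples.")
  if (any(diff(curve[[xcol]]) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing.", xcol))
  }
  invisible(curve)
}

# Local linear fit of y on x over `window` samples centred (as far as
# possible) on index i; returns c(intercept, slope).
local_tangent <- function(x, y, i, window = 5) {
  half <- window %/% 2
  idx <- max(1, i - half):min(length(x), i + half)
  f <- lm(y[idx] ~ x[idx])
  c(coef(f)[[1]], coef(f)[[2]])
}

tangent_intersection <- function(t1, t2) {
  if (abs(t2[2] - t1[2]) < .Machine$double.eps) return(NA_real_)
  (t1[1] - t2[1]) / (t2[2] - t1[2])
}

#' Onset and peak of a DSC endotherm
#'
#' Locates the dominant endothermic transition in a heat-flow curve. The
#' peak temperature is the extremum of the baseline-subtracted signal (the
#' baseline is a straight line through the curve ends); the onset is the
#' intersection of the pre-peak baseline tangent with the leading-edge
#' tangent at the steepest point, the standard instrument-software
#' construction. If no peak rises above `noise_mult` times the baseline
#' noise, a no-transition sentinel row (`found = FALSE`, temperatures `NA`)
#' is returned rather than an error.
#'
#' @param curve Data frame with columns `temperature_C` and `value` (heat
#'   flow), strictly increasing temperature.
#' @param endo_down If `TRUE` (default) endothermic events point downwards,
#'   the common DSC convention; set `FALSE` for upward endotherms.
#' @param window Samples in each local tangent fit (default 5).
#' @param noise_mult Peak detection threshold as a multiple of the residual
#'   baseline noise (default 5).
#' @return A one-row tibble: `t_onset_C`, `t_peak_C`, `found`.
#' @export
dsc_features <- function(curve, endo_down = TRUE, window = 5, noise_mult = 5) {
  validate_curve(curve)
  tc <- curve$temperature_C
  y <- if (endo_down) -curve$value else curve$value
  n <- length(y)
  base <- y[1] + (y[n] - y[1]) * (tc - tc[1]) / (tc[n] - tc[1])
  dy <- y - base
  noise <- sd(head(dy, max(window, n %/% 10)))
  ipk <- which.max(dy)
  if (dy[ipk] <= noise_mult * max(noise, .Machine$double.eps)) {
    return(tibble::tibble(t_onset_C = NA_real_, t_peak_C = NA_real_,
                          found = FALSE))
  }
  # leading edge: steepest rise between the start and the peak; with a run
  # of equally steep samples (a linear edge) take its middle so the tangent
  # window stays on the segment
  lead <- seq_len(max(ipk - 1, 2))
  slopes <- c(NA, diff(dy)) / c(NA, diff(tc))
  smax <- max(slopes[lead], na.rm = TRUE)
  tied <- lead[which(slopes[lead] >= smax * (1 - 1e-9))]
  istp <- tied[ceiling(length(tied) / 2)]
  # pre-peak baseline tangent: fit over the flat region before the rise
  flat_end <- max(which(dy[seq_len(istp)] < 0.05 * dy[ipk]), window)
  tan_flat <- local_tangent(tc[seq_len(flat_end)], dy[seq_len(flat_end)],
                            flat_end %/% 2, window = flat_end)
  tan_edge <- local_tangent(tc, dy, istp, window)
  tibble::tibble(
    t_onset_C = tangent_intersection(tan_flat, tan_edge),
    t_peak_C = tc[ipk],
    found = TRUE
  )
}

#' Features of DMTA storage-modulus and loss-factor curves
#'
#' Extracts the curve descriptors used to characterise dough structure
#' setting during a temperature sweep with a hold at `hold_end`:
#' values at 28 degC, the structuring onset `t_on_C` (intersection of the
#' pre-rise baseline tangent of G' with the tangent at the steepest rise),
#' values at the onset, the post-onset maximum of G' with its temperature,
#' end-of-hold values, and the ratio of the G' maximum to the pre-rise
#' minimum. A monotone-flat G' curve returns a no-onset sentinel
#' (`found = FALSE`) with `gmax_over_gmin = 1`.
#'
#' @param gprime Data frame `temperature_C,value` with G' in Pa.
#' @param tand Data frame `temperature_C,value` with tan(delta); resampled
#'   onto the G' grid with a warning when grids differ.
#' @param hold_end Temperature of the final hold, degC (default 95).
#' @param window Samples per local tangent fit (default 5).
#' @param rise_mult A rise is declared when G' exceeds `rise_mult` times its
#'   pre-rise minimum (default 2).
#' @return A one-row tibble with `g28_Pa`, `tan28`, `t_on_C`, `g_on_Pa`,
#'   `tan_on`, `g_max_Pa`, `t_gmax_C`, `tan_gmax`, `g95_Pa`, `tan95`,
#'   `gmax_over_gmin`, `found`.
#' @export
dmta_features <- function(gprime, tand, hold_end = 95, window = 5,
                          rise_mult = 2) {
  validate_curve(gprime)
  validate_curve(tand)
  tc <- gprime$temperature_C
  g <- gprime$value
  if (!isTRUE(all.equal(tc, tand$temperature_C))) {
    warn("G' and tan(delta) grids differ; resampling tan(delta) onto the G' grid.")
    tanv <- approx(tand$temperature_C, tand$value, xout = tc, rule = 2)$y
  } else {
    tanv <- tand$value
  }
  at <- function(y, temp) approx(tc, y, xout = temp, rule = 2)$y
  g28 <- at(g, 28); tan28 <- at(tanv, 28)
  g95 <- at(g, hold_end); tan95 <- at(tanv, hold_end)

  # pre-rise minimum and rise detection on G'
  imin <- which.min(g)
  gmin <- g[imin]
  risen <- any(g[imin:length(g)] >= rise_mult * gmin)
  if (!risen) {
    return(tibble::tibble(
      g28_Pa = g28, tan28 = tan28, t_on_C = NA_real_, g_on_Pa = NA_real_,
      tan_on = NA_real_, g_max_Pa = max(g), t_gmax_C = tc[which.max(g)],
      tan_gmax = tanv[which.max(g)], g95_Pa = g95, tan95 = tan95,
      gmax_over_gmin = max(g) / gmin, found = FALSE
    ))
  }
  post <- imin:length(g)
  slopes <- c(NA, diff(g)) / c(NA, diff(tc))
  smax <- max(slopes[post], na.rm = TRUE)
  tied <- post[which(slopes[post] >= smax * (1 - 1e-9))]
  istp <- tied[ceiling(length(tied) / 2)]
  imax <- post[which.max(g[post])]
  # baseline tangent over the flat stretch before the rise (up to where G'
  # first exceeds rise_mult * gmin)
  irise <- post[min(which(g[post] >= rise_mult * gmin))]
  flat <- seq_len(max(irise - 1, window))
  tan_flat <- local_tangent(tc[flat], g[flat], length(flat) %/% 2,
                            window = length(flat))
  tan_edge <- local_tangent(tc, g, istp, window)
  t_on <- tangent_intersection(tan_flat, tan_edge)
  tibble::tibble(
    g28_Pa = g28, tan28 = tan28,
    t_on_C = t_on,
    g_on_Pa = at(g, t_on), tan_on = at(tanv, t_on),
    g_max_Pa = g[imax], t_gmax_C = tc[imax], tan_gmax = tanv[imax],
    g95_Pa = g95, tan95 = tan95,
    gmax_over_gmin = g[imax] / gmin,
    found = TRUE
  )
}

#' Resistance and extensibility from a micro-extension curve
#'
#' Reads a dough-strip extension trace (displacement vs force) and returns
#' the resistance to extension (global maximum force) and the extensibility
#' (displacement at rupture). Rupture is the first point where the force
#' drops by at least `drop_frac` of the running maximum within `drop_window`
#' samples.
#'
#' @param curve Data frame with columns `displacement_mm` and `force_N`,
#'   strictly increasing displacement.
#' @param drop_frac Fractional force drop defining rupture (default 0.5).
#' @param drop_window Samples within which the drop must occur (default 3).
#' @return A one-row tibble: `resistance_N`, `extensibility_mm`.
#' @export
extension_features <- function(curve, drop_frac = 0.5, drop_window = 3) {
  validate_curve(curve, xcol = "displacement_mm", ycol = "force_N")
  d <- curve$displacement_mm
  f <- curve$force_N
  runmax <- cummax(f)
  collapsed <- which(runmax > 0 & f <= (1 - drop_frac) * runmax)
  no_rupture <- function() {
    abort(sprintf(
      "No rupture detected: force never drops by %.0f%% within %d samples of its maximum.",
      100 * drop_frac, drop_window
    ))
  }
  if (length(collapsed) == 0) no_rupture()
  m <- collapsed[1]
  # rupture point: the force maximum immediately preceding the collapse
  pre <- seq_len(m - 1)
  rupture <- pre[which.max(f[pre])]
  if (m - rupture > drop_window) no_rupture()  # gradual decline, not rupture
  tibble::tibble(resistance_N = max(f), extensibility_mm = d[rupture])
}
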