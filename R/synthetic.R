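## Seeded generators with known ground truth for every pipeline stage.
## Each generator sets its own RNG state locally so callers' streams are
## untouched and outputs are byte-identical for a fixed seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic sorption isotherm
#'
#' Samples water volume fractions on a grid over `phi_w_range`, evaluates
#' the rubbery Flory-Huggins activity for a known interaction parameter, and
#' adds Gaussian activity noise (clipped inside (0, 1)). The returned points
#' are (water activity, moisture content) pairs like a sorption balance
#' would produce.
#'
#' @param chi_true True interaction parameter in `[0, 2]`.
#' @param v_s Solute molar volume, cm^3/mol.
#' @param rho_s Solute density, kg/m^3.
#' @param n_points Number of points (>= 3).
#' @param sigma_aw Gaussian noise s.d. in activity units (default 0.005).
#' @param seed Integer seed.
#' @param phi_w_range Volume-fraction grid limits (default `c(0.25, 0.95)`).
#' @return A tibble with columns `aw`, `x`, `phi_w_true`; attributes
#'   `chi_true`, `v_s`, `rho_s` record the ground truth. A warning is issued
#'   if noise breaks monotonicity of `aw` in `x`.
#' @export
gen_isotherm <- function(chi_true, v_s, rho_s, n_points = 20,
                         sigma_aw = 0.005, seed = 1,
                         phi_w_range = c(0.25, 0.95)) {
  stopifnot(chi_true >= 0, chi_true <= 2, v_s > 0, rho_s > 0, sigma_aw >= 0)
  if (n_points < 3) abort("`n_points` must be at least 3.")
  phi <- seq(phi_w_range[1], phi_w_range[2], length.out = n_points)
  aw <- aw_rubbery(phi, chi_true, v_s)
  # keep only the physically sorbing branch: for hygroscopically weak
  # solutes (high chi) the Flory-Huggins activity crosses 1 at mid volume
  # fractions (the demixing region); a sorption balance never sees those
  keep <- aw < 1 - 1e-9
  phi <- phi[keep]
  aw <- aw[keep]
  if (length(aw) < 3) {
    abort("Fewer than 3 physically valid points: lower `phi_w_range` or `chi_true`.")
  }
  if (sigma_aw > 0) {
    aw <- with_seed(seed, aw + rnorm(length(aw), sd = sigma_aw))
    aw <- pmin(pmax(aw, 1e-6), 1 - 1e-6)
  }
  if (any(diff(aw) <= 0)) {
    warn("Noise broke monotonicity of the generated isotherm.")
  }
  out <- tibble::tibble(aw = aw, x = x_from_phi_w(phi, rho_s),
                        phi_w_true = phi)
  attr(out, "chi_true") <- chi_true
  attr(out, "v_s") <- v_s
  attr(out, "rho_s") <- rho_s
  out
}

#' Generate a random dough formulation grid
#'
#' Builds `n_doughs` recipes in the packaged-recipe dialect by drawing one
#' or two fibres and their masses at random from the compound registry,
#' keeping flour, gluten and dextrose at the reference levels and drawing an
#' added-water level in a realistic band. The true descriptors are computed
#' by [formulation_params()] itself, making this a self-consistency harness
#' for downstream statistics.
#'
#' @param n_doughs Number of doughs.
#' @param seed Integer seed.
#' @param compounds Compound registry; fibres are the non-water,
#'   non-dextrose entries.
#' @return A list with `recipes` (tibble) and `params` (tibble of true
#'   descriptors).
#' @export
gen_formulation_grid <- function(n_doughs, seed = 1,
                                 compounds = default_compounds()) {
  if (n_doughs == 0) {
    empty <- tibble::tibble(dough = character(0), ingredient = character(0),
                            mass_g = double(0), role = character(0))
    return(list(recipes = empty, params = formulation_params(empty, compounds)))
  }
  fibres <- setdiff(compounds$name, c("water", "dextrose"))
  recipes <- with_seed(seed, {
    purrr::map(seq_len(n_doughs), function(i) {
      k <- sample(1:2, 1)
      fib <- sample(fibres, k)
      mass <- if (k == 1) 7.8 else {
        m1 <- round(runif(1, 2, 5.8), 1)
        c(m1, 7.8 - m1)
      }
      tibble::tibble(
        dough = sprintf("S_%02d", i),
        ingredient = c("wheat_flour", "gluten", "dextrose", fib, "added_water"),
        mass_g = c(78.8, 2.9, 2.0, mass, round(runif(1, 33, 44), 1)),
        role = c("flour", "gluten", "solute", rep("solute", k), "water")
      )
    }) |>
      purrr::list_rbind()
  })
  list(recipes = recipes,
       params = formulation_params(recipes, compounds))
}

#' Generate a linear response table with known coefficients
#'
#' Builds `y = b0 + sum_k b_k x*_k + N(0, sigma)` on the min-max reduced
#' design of the supplied predictors, the data-generating model assumed by
#' the backward-regression stage.
#'
#' @param predictors Data frame of predictor columns (and optionally
#'   `dough`), reduced internally via [reduce_variables()].
#' @param b_true Numeric vector: intercept followed by one coefficient per
#'   predictor column (length = #predictors + 1).
#' @param sigma Gaussian noise s.d.
#' @param seed Integer seed.
#' @param response_name Name of the generated column (default `"y"`).
#' @return The reduced predictor tibble with the response appended;
#'   attribute `b_true` records the truth.
#' @export
gen_response_table <- function(predictors, b_true, sigma = 0.01, seed = 1,
                               response_name = "y") {
  red <- reduce_variables(predictors)
  num <- setdiff(names(red), "dough")
  if (length(b_true) != length(num) + 1) {
    abort(sprintf("`b_true` must have length %d (intercept + %d predictors).",
                  length(num) + 1, length(num)))
  }
  xmat <- as.matrix(red[num])
  y <- b_true[1] + drop(xmat %*% b_true[-1])
  if (sigma > 0) y <- with_seed(seed, y + rnorm(length(y), sd = sigma))
  red[[response_name]] <- y
  attr(red, "b_true") <- b_true
  red
}

#' Generate a star-shaped binary network image
#'
#' Draws `n_arms` one-pixel-wide straight arms of length `arm_length` from
#' the image centre at evenly spaced angles (plus a seeded random rotation),
#' rasterised with Bresenham stepping. Ground truth: one junction cluster
#' when `n_arms >= 3` (zero for a straight two-arm line) and `n_arms`
#' endpoints. Branch lengths follow the documented decomposition of
#' [skeleton_graph()], whose junction cluster absorbs the centre-adjacent
#' pixel of each arm.
#'
#' @param n_arms Number of arms (>= 2).
#' @param arm_length Arm length in pixels.
#' @param image_size Edge length of the square image.
#' @param seed Integer seed (rotates the star).
#' @param rotate If `FALSE`, arms start at angle 0 (deterministic layout
#'   regardless of seed).
#' @return A list with `img` (logical matrix), `n_junctions_true`,
#'   `n_endpoints_true`.
#' @export
gen_network_image <- function(n_arms, arm_length, image_size = 64, seed = 1,
                              rotate = TRUE) {
  stopifnot(n_arms >= 2, arm_length >= 2)
  centre <- ceiling(image_size / 2)
  if (centre + arm_length + 1 > image_size || centre - arm_length < 1) {
    abort("Arms would overlap the image border; enlarge `image_size`.")
  }
  theta0 <- if (rotate) with_seed(seed, runif(1, 0, 2 * pi / n_arms)) else 0
  img <- matrix(FALSE, image_size, image_size)
  for (k in seq_len(n_arms)) {
    th <- theta0 + 2 * pi * (k - 1) / n_arms
    # Bresenham-style rasterisation of a length-`arm_length` ray
    steps <- max(abs(round(arm_length * cos(th))), abs(round(arm_length * sin(th))))
    for (s in 0:steps) {
      r <- centre + round(s / steps * arm_length * sin(th))
      c <- centre + round(s / steps * arm_length * cos(th))
      img[r, c] <- TRUE
    }
  }
  list(
    img = img,
    n_junctions_true = if (n_arms >= 3) 1L else 0L,
    n_endpoints_true = as.integer(n_arms)
  )
}

#' Generate a synthetic DMTA storage-modulus curve
#'
#' Logistic rise of G' from a baseline plateau to `baseline + amplitude`
#' around an inflection temperature, with optional Gaussian noise, sampled
#' on a 25-95 degC sweep plus a hold. The analytic tangent-intersection
#' onset of a logistic (baseline tangent is flat, steepest tangent has slope
#' `amplitude/(4 width)` through the inflection) is
#' `T_on = T_infl - 2 width`, recorded in the attributes together with the
#' matching tan(delta) trace (a mirrored logistic decay).
#'
#' @param baseline Plateau G' in Pa.
#' @param amplitude Rise height in Pa (0 gives a flat curve).
#' @param t_infl Inflection temperature, degC.
#' @param width Logistic width parameter, degC.
#' @param sigma Multiplicative noise s.d. (lognormal-like, applied as
#'   `G' * exp(N(0, sigma))`).
#' @param seed Integer seed.
#' @param t_range Sweep limits, degC.
#' @param n Samples per curve.
#' @return A list with `gprime` and `tand` tibbles (`temperature_C,value`)
#'   and attributes-in-list `t_on_true` (analytic tangent onset), `t_infl`,
#'   `ratio_true` (`(baseline+amplitude)/baseline`).
#' @export
gen_dmta_curve <- function(baseline = 1e3, amplitude = 99e3, t_infl = 70,
                           width = 2, sigma = 0, seed = 1,
                           t_range = c(25, 95), n = 200) {
  stopifnot(baseline > 0, amplitude >= 0, width > 0)
  tc <- seq(t_range[1], t_range[2], length.out = n)
  g <- baseline + amplitude / (1 + exp(-(tc - t_infl) / width))
  if (sigma > 0) g <- with_seed(seed, g * exp(rnorm(n, sd = sigma)))
  tand <- 0.45 - 0.25 / (1 + exp(-(tc - t_infl) / width))
  list(
    gprime = tibble::tibble(temperature_C = tc, value = g),
    tand = tibble::tibble(temperature_C = tc, value = tand),
    t_on_true = t_infl - 2 * width,
    t_infl = t_infl,
    ratio_true = (baseline + amplitude) / baseline
  )
}

#' Generate a synthetic DSC endotherm
#'
#' A flat (optionally sloped) baseline carrying a single endothermic event.
#' With `shape = "gaussian"` the event is a Gaussian dip centred on
#' `t_peak`; with `shape = "piecewise"` it is a triangular dip whose leading
#' edge is an exact straight line from `t_onset` to the peak, so the
#' tangent-construction onset is known analytically.
#'
#' @param t_onset Onset temperature, degC (piecewise shape).
#' @param t_peak Peak temperature, degC.
#' @param depth Event depth in signal units.
#' @param shape `"gaussian"` or `"piecewise"`.
#' @param sigma Additive Gaussian noise s.d.
#' @param seed Integer seed.
#' @param t_range Scan limits, degC.
#' @param n Samples.
#' @param sd_peak Gaussian peak s.d., degC.
#' @return A tibble `temperature_C,value` (endotherm pointing down) with the
#'   truth in attributes `t_onset_true`, `t_peak_true`.
#' @export
gen_dsc_curve <- function(t_onset = 58, t_peak = 65, depth = 1,
                          shape = c("piecewise", "gaussian"), sigma = 0,
                          seed = 1, t_range = c(30, 110), n = 400,
                          sd_peak = 3) {
  shape <- match.arg(shape)
  stopifnot(t_onset < t_peak, depth >= 0)
  tc <- seq(t_range[1], t_range[2], length.out = n)
  y <- if (shape == "gaussian") {
    -depth * exp(-(tc - t_peak)^2 / (2 * sd_peak^2))
  } else {
    lead <- -depth * (tc - t_onset) / (t_peak - t_onset)
    trail <- -depth * (1 - (tc - t_peak) / (t_peak - t_onset))
    pmin(pmax(pmax(lead, trail), -depth), 0)
  }
  if (sigma > 0) y <- with_seed(seed, y + rnorm(n, sd = sigma))
  out <- tibble::tibble(temperature_C = tc, value = y)
  attr(out, "t_onset_true") <- t_onset
  attr(out, "t_peak_true") <- t_peak
  out
}

#' Generate a synthetic micro-extension curve
#'
#' Force rises with displacement (a softening power law), peaks at the
#' rupture displacement, then collapses to near zero, mimicking a dough
#' strip in a micro-extension rig.
#'
#' @param rupture_mm Displacement at rupture, mm.
#' @param peak_force_N Force at rupture, N.
#' @param sigma Additive Gaussian force noise s.d., N.
#' @param seed Integer seed.
#' @param n Samples before rupture.
#' @return A tibble `displacement_mm,force_N`; attributes `rupture_true_mm`,
#'   `peak_true_N`.
#' @export
gen_extension_curve <- function(rupture_mm = 35, peak_force_N = 0.5,
                                sigma = 0, seed = 1, n = 120) {
  stopifnot(rupture_mm > 0, peak_force_N > 0)
  d_up <- seq(0, rupture_mm, length.out = n)
  f_up <- peak_force_N * (d_up / rupture_mm)^0.7
  d_dn <- rupture_mm + seq(0.2, 2, length.out = 10)
  f_dn <- peak_force_N * 0.02 * exp(-seq(0.2, 2, length.out = 10))
  f <- c(f_up, f_dn)
  if (sigma > 0) {
    f <- with_seed(seed, f + rnorm(length(f), sd = sigma))
    f <- pmax(f, 0)
  }
  out <- tibble::tibble(displacement_mm = c(d_up, d_dn), force_N = f)
  attr(out, "rupture_true_mm") <- rupture_mm
  attr(out, "peak_true_N") <- peak_force_N
  out
}
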