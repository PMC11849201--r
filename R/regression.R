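#' Min-max reduced variables
#'
#' Rescales each predictor column to `[0, 1]` using its own extremes,
#' `x* = (x - min) / (max - min)`, so regression coefficients become
#' comparable across predictors with different natural scales. The ranges
#' used are stored in the `"ranges"` attribute for later back-transformation.
#'
#' @param data A data frame of numeric predictor columns (an identifier
#'   column named `dough` is carried through unscaled).
#' @return A tibble of reduced predictors with attribute `ranges` (a tibble
#'   of `variable`, `min`, `max`).
#' @examples
#' reduce_variables(formulation_params(default_recipes())[
#'   c("dough", "phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour")])
#' @export
reduce_variables <- function(data) {
  stopifnot(is.data.frame(data))
  id <- intersect(names(data), "dough")
  num <- setdiff(names(data), id)
  constant <- num[purrr::map_lgl(data[num], function(x) {
    diff(range(x, na.rm = TRUE)) == 0
  })]
  if (length(constant) > 0) {
    abort(sprintf("Constant column(s) cannot be reduced: %s",
                  paste(constant, collapse = ", ")))
  }
  ranges <- tibble::tibble(
    variable = num,
    min = purrr::map_dbl(data[num], min, na.rm = TRUE),
    max = purrr::map_dbl(data[num], max, na.rm = TRUE)
  )
  out <- data
  for (v in num) {
    r <- ranges[ranges$variable == v, ]
    out[[v]] <- (data[[v]] - r$min) / (r$max - r$min)
  }
  out <- tibble::as_tibble(out)
  attr(out, "ranges") <- ranges
  out
}

#' Backward-selected multilinear regression on reduced variables
#'
#' Ordinary least squares of a dough response on min-max-reduced predictors,
#' followed by backward elimination: while any retained predictor has a
#' coefficient p-value above `alpha`, the predictor with the largest p-value
#' is dropped and the model refitted. Coefficient p-values are two-sided t
#' tests; the model p-value comes from the overall F statistic. The
#' normalized coefficient shares `b_k / sum_j |b_j|` (signs preserved, over
#' retained predictors) quantify each descriptor's relative contribution.
#'
#' @param data A data frame holding the response and predictors (already
#'   reduced, e.g. via [reduce_variables()]; the function does not rescale).
#' @param response Name of the response column (string).
#' @param predictors Character vector of predictor column names.
#' @param alpha Elimination threshold on coefficient p-values (default 0.05).
#' @return An object of class `backward_lm`: list with `fit` (the final
#'   `lm`), `retained`, `dropped` (in elimination order), `shares` (named,
#'   zero for dropped predictors), `r_squared`, `p_model`, `alpha`,
#'   `response`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' df <- tibble::tibble(x1 = runif(12), x2 = runif(12))
#' df$y <- 3 + 2 * df$x1
#' fit_backward(df, "y", c("x1", "x2"))
#' @export
fit_backward <- function(data, response, predictors, alpha = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(predictors %in% names(data)))
  if (nrow(data) < length(predictors) + 2) {
    abort("Too few rows: need at least #predictors + 2 observations.")
  }
  retained <- predictors
  dropped <- character(0)
  fit <- NULL
  repeat {
    form <- stats::reformulate(if (length(retained) > 0) retained else "1",
                               response = response)
    fit <- lm(form, data = data)
    if (length(retained) > 0 && any(is.na(coef(fit)))) {
      abort("Rank-deficient design: predictors are collinear.")
    }
    if (length(retained) == 0) break
    ps <- suppressWarnings(summary(fit))$coefficients[-1, 4]
    # zero residual variance makes t tests NaN: keep predictors that carry a
    # non-zero coefficient in the exact fit, drop the rest
    if (any(is.nan(ps))) {
      bnow <- coef(fit)[-1]
      ps[is.nan(ps)] <- ifelse(abs(bnow[is.nan(ps)]) > 1e-8, 0, 1)
    }
    if (all(ps <= alpha)) break
    worst <- retained[which.max(ps)]
    retained <- setdiff(retained, worst)
    dropped <- c(dropped, worst)
  }
  b <- coef(fit)[retained]
  shares <- stats::setNames(rep(0, length(predictors)), predictors)
  if (length(retained) > 0 && sum(abs(b)) > 0) {
    shares[retained] <- b / sum(abs(b))
  }
  smry <- suppressWarnings(summary(fit))  # exact fits warn in summary.lm
  p_model <- if (length(retained) > 0 && !is.null(smry$fstatistic)) {
    unname(pf(smry$fstatistic[1], smry$fstatistic[2], smry$fstatistic[3],
              lower.tail = FALSE))
  } else {
    NA_real_
  }
  structure(
    list(
      fit = fit, retained = retained, dropped = dropped, shares = shares,
      r_squared = if (length(retained) > 0) smry$r.squared else 0,
      p_model = p_model, alpha = alpha, response = response,
      predictors = predictors
    ),
    class = "backward_lm"
  )
}

#' @export
print.backward_lm <- function(x, ...) {
  cat(sprintf("Backward-selected linear model for '%s'\n", x$response))
  if (length(x$retained) == 0) {
    cat("  intercept-only (no predictor significant at alpha =",
        x$alpha, ")\n")
  } else {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
    cat(sprintf("  R^2 = %.3f, model p = %.3g\n", x$r_squared, x$p_model))
    sh <- x$shares[x$retained]
    cat("  shares:", paste(sprintf("%s = %+.2f", names(sh), sh),
                           collapse = ", "), "\n")
  }
  if (length(x$dropped) > 0) {
    cat("  dropped (in order):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.backward_lm <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    statistic = cf[, 3],
    p_value = cf[, 4],
    share = c(NA_real_, unname(x$shares[x$retained]))[seq_len(nrow(cf))]
  )
}

#' @export
glance.backward_lm <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    p_model = x$p_model,
    n_retained = length(x$retained),
    n_dropped = length(x$dropped),
    alpha = x$alpha
  )
}

#' @describeIn fit_backward Bar chart of the normalized coefficient shares.
#' @param object A `backward_lm`.
#' @param ... Ignored.
#' @export
autoplot.backward_lm <- function(object, ...) {
  df <- tibble::tibble(predictor = names(object$shares),
                       share = unname(object$shares))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(y = "normalized coefficient share", x = NULL,
                  title = sprintf("Contributions to %s", object$response))
}

#' Normalized coefficient shares of a fitted model
#'
#' @param x A `backward_lm` object.
#' @return Named numeric vector of shares over all candidate predictors
#'   (dropped ones are 0); absolute values of retained shares sum to 1.
#' @export
coefficient_shares <- function(x) {
  stopifnot(inherits(x, "backward_lm"))
  if (length(x$retained) == 0 || sum(abs(x$shares)) == 0) {
    abort("No retained non-zero coefficients: shares are undefined.")
  }
  x$shares
}

#' Pairwise Pearson correlation table
#'
#' Pearson correlations with two-sided p-values for every pair of numeric
#' columns, with conventional significance stars (0.05 / 0.01 / 0.001).
#' Pairs with fewer than 3 complete observations yield `NA`.
#'
#' @param data A data frame; non-numeric columns are ignored.
#' @return A tibble with `var1`, `var2`, `r`, `p_value`, `stars`, `n`.
#' @export
pearson_matrix <- function(data) {
  num <- names(data)[purrr::map_lgl(data, is.numeric)]
  pairs <- utils::combn(num, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    x <- data[[p[1]]]; y <- data[[p[2]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(var1 = p[1], var2 = p[2], r = NA_real_,
                            p_value = NA_real_, stars = "", n = n))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok]))
    stars <- dplyr::case_when(
      ct$p.value < 0.001 ~ "***",
      ct$p.value < 0.01 ~ "**",
      ct$p.value < 0.05 ~ "*",
      TRUE ~ ""
    )
    tibble::tibble(var1 = p[1], var2 = p[2], r = unname(ct$estimate),
                   p_value = ct$p.value, stars = stars, n = n)
  }) |>
    purrr::list_rbind()
}
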