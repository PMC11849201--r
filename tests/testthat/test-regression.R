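uniform_design <- function(n = 12, seed = 42) {
  set.seed(seed)
  tibble::tibble(x1 = runif(n), x2 = runif(n), x3 = runif(n), x4 = runif(n))
}

test_that("min-max reduction maps each column onto [0, 1] with its extremes", {
  params <- formulation_params(default_recipes())
  red <- reduce_variables(params[c("dough", "phi_w_eff", "chi_eff",
                                   "noh_v_eff", "phi_flour")])
  for (v in c("phi_w_eff", "chi_eff", "noh_v_eff", "phi_flour")) {
    expect_equal(min(red[[v]]), 0)
    expect_equal(max(red[[v]]), 1)
  }
  # hand value: (0.513 - 0.470) / (0.526 - 0.470) on the printed scale
  refred <- reduce_variables(reference_params()[c("dough", "phi_w_eff")])
  expect_equal(refred$phi_w_eff[refred$dough == "D_TEX"], 0.768, tolerance = 1e-3)
  expect_error(reduce_variables(tibble::tibble(a = rep(1, 5))), "Constant")
})

test_that("backward selection recovers a known sparse linear model", {
  df <- uniform_design()
  rt <- gen_response_table(df, b_true = c(3, 2, -1, 0, 0), sigma = 0.01, seed = 2)
  fit <- fit_backward(rt, "y", c("x1", "x2", "x3", "x4"))
  expect_setequal(fit$retained, c("x1", "x2"))
  b <- coef(fit$fit)
  expect_equal(unname(b["x1"]), 2, tolerance = 0.1 / 2)
  expect_equal(unname(b["x2"]), -1, tolerance = 0.1)
  expect_equal(sum(abs(coefficient_shares(fit))), 1, tolerance = 1e-9)
  # selection is deterministic: identical refit, identical drop order
  fit2 <- fit_backward(rt, "y", c("x1", "x2", "x3", "x4"))
  expect_identical(fit2$dropped, fit$dropped)
  expect_identical(coef(fit2$fit), coef(fit$fit))
})

test_that("degenerate responses give the documented fallbacks", {
  df <- uniform_design()
  df$y <- 5
  fit <- fit_backward(df, "y", c("x1", "x2", "x3", "x4"))
  expect_length(fit$retained, 0)
  expect_identical(fit$r_squared, 0)
  expect_error(coefficient_shares(fit), "undefined")
  # exact linear response: perfect fit, single retained predictor
  df$y2 <- 1 + 4 * df$x1
  fit2 <- fit_backward(df, "y2", c("x1", "x2", "x3", "x4"))
  expect_identical(fit2$retained, "x1")
  expect_equal(fit2$r_squared, 1)
  expect_lt(fit2$p_model, 1e-12)
  # collinear design is refused
  df$x5 <- df$x1 * 2
  expect_error(fit_backward(df, "y2", c("x1", "x5")), "collinear")
})

test_that("shares keep signs, sum to one in magnitude, and are scale-invariant", {
  df <- uniform_design(seed = 9)
  rt <- gen_response_table(df, b_true = c(0, -3, 2, 0, 0), sigma = 0.005, seed = 5)
  fit <- fit_backward(rt, "y", c("x1", "x2", "x3", "x4"))
  sh <- coefficient_shares(fit)
  expect_equal(sum(abs(sh)), 1, tolerance = 1e-9)
  expect_equal(unname(sh["x1"]), -0.6, tolerance = 0.02)
  expect_equal(unname(sh["x2"]), 0.4, tolerance = 0.02)
  rt$y10 <- rt$y * 10
  fit10 <- fit_backward(rt, "y10", c("x1", "x2", "x3", "x4"))
  expect_equal(coefficient_shares(fit10), sh, tolerance = 1e-9)
})

test_that("null predictors are usually all eliminated", {
  df <- uniform_design(seed = 3)
  frac <- mean(purrr::map_lgl(1:200, function(s) {
    rt <- gen_response_table(df, b_true = c(1, 0, 0, 0, 0), sigma = 1, seed = s)
    length(fit_backward(rt, "y", c("x1", "x2", "x3", "x4"))$retained) == 0
  }))
  expect_gte(frac, 0.7)
})

test_that("pearson matrix flags perfect and null correlations", {
  set.seed(11)
  df <- tibble::tibble(a = rnorm(100))
  df$b <- 2 * df$a + 3     # r = 1
  df$c <- -df$a            # r = -1
  df$d <- rnorm(100)       # independent
  pm <- pearson_matrix(df)
  get <- function(v1, v2) pm[pm$var1 == v1 & pm$var2 == v2, ]
  expect_equal(get("a", "b")$r, 1)
  expect_equal(get("a", "c")$r, -1)
  expect_identical(get("a", "b")$stars, "***")
  expect_lt(abs(get("a", "d")$r), 0.25)
  # n < 3 gives NA rather than a spurious estimate
  tiny <- pearson_matrix(tibble::tibble(u = c(1, 2), v = c(2, 1)))
  expect_true(is.na(tiny$r))
})

test_that("backward_lm exposes tidy, glance and autoplot", {
  df <- uniform_design()
  rt <- gen_response_table(df, b_true = c(3, 2, -1, 0, 0), sigma = 0.01, seed = 2)
  fit <- fit_backward(rt, "y", c("x1", "x2", "x3", "x4"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value", "share") %in% names(td)))
  gl <- glance(fit)
  expect_gte(gl$r_squared, 0.99)
  expect_identical(gl$n_retained + gl$n_dropped, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
})
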