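test_that("uncertainty summaries use unbiased estimators and interpolated quantiles", {
  s <- uncertainty_summary(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$variance, 0)

  s2 <- uncertainty_summary(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$variance, 2)

  set.seed(4)
  x <- runif(1e5)
  s3 <- uncertainty_summary(x)
  expect_lt(abs(s3$variance - 1 / 12), 3 * sqrt(1 / 180 / 1e5))
  expect_equal(s3$quantiles$prob, c(0.025, 0.25, 0.5, 0.75, 0.975))
  expect_equal(s3$quantiles$value,
               unname(quantile(x, s3$quantiles$prob, type = 7)))
  expect_error(uncertainty_summary(1), "at least 2")
  expect_error(uncertainty_summary(c(1, NA)), "at least 2")
})

test_that("a single-factor model concentrates all variance on that factor", {
  d <- saltelli_design(3, 512)
  runs <- evaluate_design(d, function(U) U[, 1], vectorized = TRUE)
  res <- sobol_indices(runs, n_boot = 100)
  tol <- 3 * pmax(res$factors$S_se, 0.005)
  expect_true(abs(res$factors$S[1] - 1) < tol[1])
  expect_true(all(abs(res$factors$S[2:3]) < tol[2:3]))
  # dummy factors: total effects near zero
  expect_true(all(res$factors$ST[2:3] < 0.01))
})

test_that("g-function indices match the closed form", {
  a <- c(0, 0.5)
  d <- saltelli_design(2, 2^12)
  runs <- evaluate_design(d, function(U) g_function(U, a),
                          vectorized = TRUE)
  res <- sobol_indices(runs, n_boot = 200)
  truth <- g_function_indices(a)
  expect_equal(res$factors$S, truth$S, tolerance = 0.02)
  expect_equal(res$factors$ST, truth$ST, tolerance = 0.02)
  # interactions exist: ST strictly above S for both factors
  expect_true(all(truth$ST > truth$S))
  expect_true(all(res$factors$ST - res$factors$S >
                    -3 * res$factors$ST_se))
})

test_that("estimates agree with exhaustive enumeration on discrete toys", {
  f <- function(x) x[1] * x[2] + 3 * x[1] + x[3]^2
  levels_list <- list(c(0, 1, 2), c(0, 0.5, 1), c(1, 2, 3, 4, 5))
  truth <- enumerate_indices(f, levels_list)
  runs <- discrete_model_on_design(f, levels_list, N = 2048)
  res <- sobol_indices(runs, n_boot = 300)
  tol_S <- 3 * pmax(res$factors$S_se, 1e-3)
  tol_ST <- 3 * pmax(res$factors$ST_se, 1e-3)
  expect_true(all(abs(res$factors$S - truth$S) < tol_S))
  expect_true(all(abs(res$factors$ST - truth$ST) < tol_ST))

  # purely additive two-factor toy: no interactions, ST ~ S
  g <- function(x) 2 * x[1] - x[2]
  lv2 <- list(c(-1, 0, 1), c(0, 1, 2))
  truth2 <- enumerate_indices(g, lv2)
  runs2 <- discrete_model_on_design(g, lv2, N = 2048)
  res2 <- sobol_indices(runs2, n_boot = 300)
  expect_true(all(abs(res2$factors$S - truth2$S) <
                    3 * pmax(res2$factors$S_se, 1e-3)))
  expect_lt(abs(res2$I), 0.02)
  expect_true(all(abs(res2$factors$ST - res2$factors$S) < 0.02))
})

test_that("indices are invariant to affine rescaling of the output", {
  d <- saltelli_design(3, 256)
  runs <- evaluate_design(d, function(U) U[, 1] + 2 * U[, 2] * U[, 3],
                          vectorized = TRUE)
  res1 <- sobol_indices(runs, n_boot = 0)
  runs$output <- 1000 + 50 * runs$output
  res2 <- sobol_indices(runs, n_boot = 0)
  expect_equal(res1$factors$S, res2$factors$S, tolerance = 1e-12)
  expect_equal(res1$factors$ST, res2$factors$ST, tolerance = 1e-12)
})

test_that("the interaction share is the exact complement of the S sum", {
  expect_equal(interaction_share(c(0.5, 0.4)), 0.1)
  expect_equal(interaction_share(c(0.2, 0.15)), 0.65)
  expect_equal(interaction_share(c(0.6, 0.4)), 0)
  expect_warning(interaction_share(c(0.8, 0.4), tol = 0.1), "negative")

  d <- saltelli_design(2, 128)
  runs <- evaluate_design(d, function(U) U[, 1] * U[, 2],
                          vectorized = TRUE)
  res <- sobol_indices(runs, n_boot = 50)
  expect_identical(res$I, 1 - sum(res$factors$S))
})

test_that("constant output is rejected as undefined", {
  d <- saltelli_design(2, 16)
  runs <- evaluate_design(d, function(u) 3)
  expect_error(sobol_indices(runs), "variance is zero")
})

test_that("factor ranking orders by S with documented tie-breaks and flags", {
  res <- structure(list(factors = tibble::tibble(
    name = c("a", "b", "c", "d"),
    S = c(0.5, 0.3, 0.001, 0.3),
    ST = c(0.6, 0.4, 0.005, 0.5),
    S_se = 0, ST_se = 0, S_lo = 0, S_hi = 0, ST_lo = 0, ST_hi = 0
  )), class = "sensitivity_result")
  r <- rank_factors(res, threshold = 0.01)
  expect_equal(r$name, c("a", "d", "b", "c"))  # ST breaks the S tie
  expect_equal(r$negligible, c(FALSE, FALSE, FALSE, TRUE))
  r2 <- rank_factors(res, threshold = 0)
  expect_false(any(r2$negligible))
})

test_that("tidy, glance and autoplot expose the result", {
  d <- saltelli_design(2, 64)
  runs <- evaluate_design(d, function(U) U[, 1] + U[, 2], vectorized = TRUE)
  res <- sobol_indices(runs, factor_names = c("f1", "f2"), n_boot = 20)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$name, c("f1", "f2"))
  gl <- glance(res)
  expect_equal(gl$runs, 64 * 6)
  expect_identical(gl$interaction, res$I)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
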