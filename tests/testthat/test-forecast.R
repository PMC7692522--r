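test_that("the curve peaks at -c/b with value A + p and clamps at zero", {
  expect_equal(evaluate_curve(curve_params(60, 0.4, -4, 0), 10), 60)
  expect_equal(evaluate_curve(curve_params(60, 0.4, -4, 0.5), 10), 60.5)
  # far in the tail the raw curve is p < 0, clamped to zero
  cp <- curve_params(10, 1, -20, -1)
  expect_lt(10 / cosh(1 * 1 - 20)^2 - 1, 0)
  expect_equal(evaluate_curve(cp, 1), 0)
  expect_true(all(evaluate_curve(cp, 0:30) >= 0))
})

test_that("parameter domains are enforced", {
  expect_error(curve_params(-1, 0.5, -5, 0), "A must be")
  expect_error(curve_params(10, 0, -5, 0), "b must be")
  expect_error(curve_params(10, 0.5, 1, 0), "c must be")
  expect_error(curve_params(10, 0.5, -5, 1.5), "p must lie")
  expect_error(param_bounds(lower = c(A = 1, b = 1, c = -1, p = 0),
                            upper = c(A = 2, b = 0.5, c = 0, p = 1)),
               "strictly below")
})

recovery_sets <- list(
  c(A = 30, b = 0.5, c = -5, p = 0.2),
  c(A = 61.6, b = 0.39, c = -4.3, p = 0.5),
  c(A = 8.6, b = 0.87, c = -5.69, p = 0.12),
  c(A = 27.8, b = 0.57, c = -5.18, p = -0.5),
  c(A = 100, b = 0.25, c = -4, p = 0.9)
)

test_that("noiseless curves are recovered to well under 1% relative error", {
  for (s in recovery_sets) {
    y <- evaluate_curve(do.call(curve_params, as.list(s)), 1:25)
    fit <- fit_curve(y)
    got <- unlist(fit$params[c("A", "b", "c", "p")])
    expect_lt(max(abs(got - s) / abs(s)), 0.01)
    expect_lt(fit$sse, 1e-4)
    # in-sample predictions reproduce the reported sse
    expect_equal(sum((y - evaluate_curve(fit$params, 1:25))^2), fit$sse,
                 tolerance = 1e-8)
  }
})

test_that("fitting is deterministic and respects its box constraints", {
  set.seed(11)
  truth <- curve_params(40, 0.6, -6, 0.3)
  ws <- generate_series(truth, 25, noise = "poisson", institution_id = "x")
  f1 <- fit_curve(ws)
  f2 <- fit_curve(ws)
  expect_identical(f1, f2)
  b <- default_bounds(ws$counts)
  got <- unlist(f1$params[c("A", "b", "c", "p")])
  expect_true(all(got >= b$lower - 1e-12 & got <= b$upper + 1e-12))
})

test_that("degenerate and invalid prefixes are handled", {
  zeros <- weekly_series("z", "s", rep(0, 10))
  fit <- fit_curve(zeros, s = 10)
  expect_true(fit$degenerate)
  expect_equal(fit$params$A, default_bounds(zeros$counts)$lower[["A"]])
  expect_error(fit_curve(1:10, s = 4), "initial five weeks")
  expect_error(fit_curve(1:10, s = 11), "exceeds")
})

test_that("an independent bounded Levenberg-Marquardt fit agrees", {
  truth <- curve_params(30, 0.5, -5, 0.2)
  y <- evaluate_curve(truth, 1:25)
  b <- default_bounds(y)
  resid_fn <- function(par) {
    y - pmax(0, par[1] / cosh(par[2] * (1:25) + par[3])^2 + par[4])
  }
  lm <- minpack.lm::nls.lm(par = c(max(y), 0.6, -5.5, 0),
                           lower = unname(b$lower), upper = unname(b$upper),
                           fn = resid_fn)
  mine <- fit_curve(y, bounds = b)
  expect_equal(unname(unlist(mine$params[c("A", "b", "c", "p")])),
               unname(coef(lm)), tolerance = 1e-2)
  expect_lt(abs(mine$sse - sum(resid_fn(coef(lm))^2)), 1e-3)
})

test_that("rolling forecasts cover exactly the future weeks", {
  truth <- curve_params(30, 0.5, -5, 0.2)
  ws <- generate_series(truth, 12, noise = "none", institution_id = "x")
  fm <- rolling_forecasts(ws)
  expect_equal(rownames(fm), as.character(5:11))
  # row fitted through T-1 has exactly one forecast entry, for week T
  last <- fm[as.character(11), ]
  expect_equal(sum(!is.na(last)), 1L)
  expect_false(is.na(last[12]))
  expect_true(all(fm[!is.na(fm)] >= 0))
  expect_error(rolling_forecasts(ws, first_fit_week = 4), ">= 5")
  expect_error(rolling_forecasts(ws, first_fit_week = 12), "at least one")
})

test_that("forecasts of an all-zero series are zero", {
  ws <- weekly_series("z", "s", rep(0, 10))
  fm <- rolling_forecasts(ws)
  expect_true(all(fm[!is.na(fm)] == 0))
  expect_equal(future_demand(fm, 5), 0)
})

test_that("future demand sums the forecast row and is 0 at season end", {
  mat <- matrix(NA_real_, nrow = 3, ncol = 8,
                dimnames = list(fit_week = 5:7, week = 1:8))
  mat["6", 7:8] <- c(3.2, 1.1)
  mat["5", 6:8] <- 0
  fm <- as_forecast_matrix(mat, 8)
  expect_equal(future_demand(fm, 6), 4.3)
  expect_equal(future_demand(fm, 5), 0)
  expect_equal(future_demand(fm, 8), 0)
  expect_error(future_demand(fm, 4), "no forecasts")
})

test_that("rolling forecast error shrinks once the peak has been observed", {
  for (s in recovery_sets[c(1, 2, 3, 5)]) {
    truth <- do.call(curve_params, as.list(s))
    ws <- generate_series(truth, 25, noise = "none", institution_id = "x")
    fm <- rolling_forecasts(ws)
    errs <- vapply(5:24, function(t) {
      fut <- (t + 1):25
      sum(abs(fm[as.character(t), fut] - ws$counts[fut]))
    }, numeric(1))
    post <- errs[(5:24) >= ceiling(truth$peak_week)]
    # integer-rounded counts allow sub-patient wobble, never a real rebound
    expect_lt(max(diff(post)), 1)
    expect_lt(post[length(post)], 1)
    expect_lt(errs[20], errs[1])
  }
})
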