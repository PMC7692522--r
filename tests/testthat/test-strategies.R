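uniform_toy <- weekly_series("toy", "t", c(0, 0, 0, 0, 10, 10, 10, 10))

test_that("the ideal recursion matches its hand-executed trace", {
  tr <- run_ideal(uniform_toy, W_init = 20)
  expect_equal(unname(tr$W), c(20, 14, 7, 0, 0))
  expect_equal(unname(tr$r), c(2 / 3, 0.7, 0.7, 1))
  expect_equal(unname(tr$used), c(6, 7, 7, 0))
})

test_that("S1 and S2 match their hand-executed traces", {
  s1 <- run_s1(uniform_toy, W_init = 20)
  expect_equal(unname(s1$W), c(20, 10, 5, 3, 2))
  expect_equal(unname(s1$r), c(1.0, 0.5, 0.2, 0.1))
  s2 <- run_s2(uniform_toy, W_init = 20)
  expect_equal(unname(s2$W), c(20, 14, 7, 0, 0))
  expect_equal(unname(s2$used), c(6, 7, 7, 0))
})

test_that("ample stock gives rate one everywhere and a predictable surplus", {
  tr <- run_ideal(uniform_toy, W_init = 60)
  expect_true(all(tr$r == 1))
  expect_equal(unname(tr$W[length(tr$W)]), 60 - 40)
})

test_that("degenerate demands leave the stock untouched", {
  zeros <- weekly_series("z", "s", rep(0, 9))
  expect_true(all(run_ideal(zeros, 15)$W == 15))
  expect_true(all(run_s2(zeros, 15)$W == 15))
  expect_true(all(run_s2(zeros, 15)$r == 0))
  # floor(1/2) = 0: a single kit is never spent by S1
  expect_true(all(run_s1(uniform_toy, 1)$W == 1))
  expect_error(run_ideal(uniform_toy, 0), "W_init")
})

test_that("strategy M reduces to greedy or hoarding at forecast extremes", {
  T_len <- uniform_toy$T
  zero_fm <- as_forecast_matrix(
    matrix(0, nrow = 3, ncol = T_len,
           dimnames = list(fit_week = 5:7, week = 1:T_len)), T_len)
  greedy <- run_main(uniform_toy, zero_fm, 20)
  expect_true(all(greedy$r == 1))
  expect_equal(unname(greedy$W), c(20, 10, 0, 0, 0))

  huge_fm <- as_forecast_matrix(
    matrix(1e9, nrow = 3, ncol = T_len,
           dimnames = list(fit_week = 5:7, week = 1:T_len)), T_len)
  hoard <- run_main(uniform_toy, huge_fm, 20)
  expect_equal(unname(hoard$used[1:3]), c(0, 0, 0))
  # final week has no forecast row: empty future demand gives rate 1
  expect_equal(unname(hoard$r[4]), 1)

  short_fm <- as_forecast_matrix(
    matrix(0, nrow = 2, ncol = T_len,
           dimnames = list(fit_week = 6:7, week = 1:T_len)), T_len)
  expect_error(run_main(uniform_toy, short_fm, 20), "fit week\\(s\\) 5")
})

test_that("exact forecasts make strategy M identical to the ideal", {
  set.seed(42)
  for (i in 1:200) {
    inst <- rand_instance()
    fm <- oracle_forecasts(inst$series)
    m <- run_main(inst$series, fm, inst$W_init)
    i_tr <- run_ideal(inst$series, inst$W_init)
    expect_identical(unname(m$W), unname(i_tr$W))
  }
})

test_that("every strategy conserves kits and never outspends demand", {
  set.seed(99)
  for (i in 1:200) {
    inst <- rand_instance()
    # arbitrary non-negative forecasts: conservation cannot depend on them
    T_len <- inst$series$T
    mat <- matrix(NA_real_, nrow = T_len - 5, ncol = T_len,
                  dimnames = list(fit_week = 5:(T_len - 1), week = 1:T_len))
    for (t in 5:(T_len - 1)) {
      mat[as.character(t), (t + 1):T_len] <-
        runif(T_len - t, 0, 30)
    }
    fm <- as_forecast_matrix(mat, T_len)
    trs <- list(run_ideal(inst$series, inst$W_init),
                run_main(inst$series, fm, inst$W_init),
                run_s1(inst$series, inst$W_init),
                run_s2(inst$series, inst$W_init))
    for (tr in trs) {
      expect_equal(sum(tr$used) + unname(tr$W[length(tr$W)]), tr$W_init)
      expect_true(all(tr$used <= tr$patients))
      expect_true(all(tr$W == floor(tr$W)))
      expect_true(all(diff(tr$W) <= 0))
      expect_true(all(tr$W >= 0 & tr$W <= tr$W_init))
      expect_true(all(tr$r >= 0 & tr$r <= 1))
      expect_equal(unname(tr$W[1]), tr$W_init)
    }
  }
})

test_that("one week of consumption floors the expected usage", {
  expect_equal(apply_week(7, 0.7, 10), list(kits_used = 7, new_stock = 0))
  expect_equal(apply_week(50, 0, 10), list(kits_used = 0, new_stock = 50))
  expect_equal(apply_week(3, 1, 10), list(kits_used = 3, new_stock = 0))
  expect_error(apply_week(3, 1.2, 10), "rate")
})

test_that("stochastic consumption is binomial with the requested rate", {
  set.seed(123)
  draws <- replicate(1e4, apply_week(1e6, 0.3, 100,
                                     mode = "stochastic")$kits_used)
  se <- sqrt(100 * 0.3 * 0.7 / 1e4)
  expect_lt(abs(mean(draws) - 30), 3 * se)
})

test_that("stochastic trajectories conserve kits and match expectation", {
  # exact-floor toy: rates are 2/3 throughout, so expected weekly usage
  # equals the deterministic flooring and the first week is Bin(9, 2/3)
  toy <- weekly_series("x", "s", c(0, 0, 0, 0, 9, 9, 9, 9))
  det <- run_ideal(toy, 18)
  expect_equal(unname(det$used), c(6, 6, 6, 0))
  set.seed(321)
  first_used <- replicate(2000, {
    tr <- run_ideal(toy, 18, mode = "stochastic")
    expect_equal(sum(tr$used) + unname(tr$W[length(tr$W)]), 18)
    unname(tr$used[1])
  })
  se <- sqrt(9 * (2 / 3) * (1 / 3) / 2000)
  expect_lt(abs(mean(first_used) - 6), 3 * se)
})
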