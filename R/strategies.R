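#' Stock trajectory of a rationing strategy
#'
#' Internal constructor shared by the strategy runners. `W[i]` is the stock
#' at the start of week `t0 + i - 1`, so the vector spans weeks
#' `t0 .. T + 1`; the final element is what is left after the season.
#'
#' @noRd
new_stock_trajectory <- function(strategy, series, W, r, used, t0) {
  T_len <- series$T
  weeks <- seq.int(t0, T_len)
  structure(
    list(
      strategy = strategy,
      institution_id = series$institution_id,
      season = series$season,
      W_init = W[1L],
      t0 = t0,
      T = T_len,
      weeks = weeks,
      W = stats::setNames(W, seq.int(t0, T_len + 1L)),
      r = stats::setNames(r, weeks),
      used = stats::setNames(used, weeks),
      patients = stats::setNames(series$counts[weeks], weeks)
    ),
    class = "stock_trajectory"
  )
}

#' @export
print.stock_trajectory <- function(x, ...) {
  cat("<stock_trajectory> strategy ", x$strategy, ", ", x$institution_id,
      "/", x$season, ": W_init = ", x$W_init, ", weeks ", x$t0, "..", x$T,
      ", final stock ", unname(x$W[length(x$W)]), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.stock_trajectory <- function(x, ...) {
  data.frame(
    week = x$weeks,
    stock_start = unname(x$W[as.character(x$weeks)]),
    rate = unname(x$r),
    kits_used = unname(x$used),
    patients = unname(x$patients)
  )
}

#' Stock after one week of rationing
#'
#' Applies the consumption rate for a single week. In the default
#' deterministic mode the number of kits used is the expected value floored
#' to an integer, `min(floor(rate * patients), stock)`. In stochastic mode
#' each suspected patient independently receives a kit with probability
#' `rate`, capped by the available stock; the draw comes from the current R
#' random number generator, so seed it for reproducibility.
#'
#' @param stock Non-negative integer, kits on hand at the start of the week.
#' @param rate Consumption rate in `[0, 1]`.
#' @param patients Non-negative integer, suspected patients this week.
#' @param mode `"deterministic"` (default) or `"stochastic"`.
#' @return List with `kits_used` and `new_stock`.
#' @export
apply_week <- function(stock, rate, patients,
                       mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  stopifnot(stock >= 0, stock == round(stock),
            patients >= 0, patients == round(patients))
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    stop("rate must lie in [0, 1]", call. = FALSE)
  }
  used <- if (mode == "deterministic") {
    floor(rate * patients)
  } else {
    stats::rbinom(1L, size = as.integer(patients), prob = rate)
  }
  used <- min(used, stock)
  list(kits_used = used, new_stock = stock - used)
}

check_run_args <- function(series, W_init, t0) {
  stopifnot(inherits(series, "weekly_series"))
  if (!(W_init >= 1 && W_init == round(W_init))) {
    stop("W_init must be an integer >= 1 (the loss normalises by it)",
         call. = FALSE)
  }
  if (!(t0 >= 1 && t0 <= series$T)) {
    stop("t0 must lie in 1..T", call. = FALSE)
  }
  invisible(NULL)
}

# Shared recursion driver: rate_fn(t, W) returns the target consumption rate
# for week t given current stock W, or NA to signal "spend min(W, P_t)
# directly" (used by S1/S2 whose recursions are floor-based, not rate-based).
run_rate_strategy <- function(strategy, series, W_init, t0, rate_fn,
                              mode = "deterministic") {
  P <- series$counts
  T_len <- series$T
  n <- T_len - t0 + 1L
  W <- numeric(n + 1L)
  r <- numeric(n)
  used <- numeric(n)
  W[1L] <- W_init
  for (i in seq_len(n)) {
    t <- t0 + i - 1L
    r[i] <- rate_fn(t, W[i])
    step <- apply_week(W[i], r[i], P[t], mode = mode)
    used[i] <- step$kits_used
    W[i + 1L] <- step$new_stock
  }
  new_stock_trajectory(strategy, series, W, r, used, t0)
}

#' Strategy I: the hindsight ideal distribution
#'
#' The after-the-fact benchmark: each week's consumption rate is the current
#' stock divided by the *true* number of patients still to come,
#' \deqn{r^I_t = \min\{W^I_t / \textstyle\sum_{s=t+1}^{T} P^R_s,\ 1\},}
#' capped at 1 (and equal to 1 when no patients remain), and the stock
#' updates by \eqn{W^I_{t+1} = \max\{W^I_t - \lfloor r^I_t P^R_t \rfloor, 0\}}.
#' It spreads the stock evenly over the remaining demand, so it needs the
#' full season in hindsight and is only usable as a benchmark.
#'
#' @param series A [weekly_series()] with the full season observed.
#' @param W_init Initial kit stock, integer >= 1.
#' @param t0 Activation week (default 5): `W` at week `t0` equals `W_init`
#'   and the recursion runs for `t = t0..T`.
#' @param mode Consumption mode passed to [apply_week()].
#' @return A `stock_trajectory`.
#' @examples
#' ws <- weekly_series("toy", "t", c(0, 0, 0, 0, 10, 10, 10, 10))
#' run_ideal(ws, W_init = 20)$W  # 20 14 7 0 0
#' @export
run_ideal <- function(series, W_init, t0 = 5, mode = "deterministic") {
  check_run_args(series, W_init, t0)
  P <- series$counts
  T_len <- series$T
  run_rate_strategy("I", series, W_init, t0, function(t, W) {
    future <- if (t < T_len) sum(P[seq.int(t + 1L, T_len)]) else 0
    if (future <= 0) 1 else min(W / future, 1)
  }, mode = mode)
}

#' Strategy M: prediction-based rationing
#'
#' The deployable counterpart of [run_ideal()]: the unknown future demand in
#' the rate is replaced by rolling forecasts,
#' \deqn{r^M_t = \min\{W^M_t / \textstyle\sum_{s=t+1}^{T} \hat P_s(t),\ 1\},}
#' where \eqn{\hat P_s(t)} is the prediction of week `s` from the curve
#' fitted on weeks `1..t`. A zero predicted future demand yields rate 1.
#' When the forecasts are exact (\eqn{\hat P_s(t) = P^R_s}) the trajectory
#' coincides with the ideal one week for week.
#'
#' @param series A [weekly_series()].
#' @param forecasts A `forecast_matrix` from [rolling_forecasts()] covering
#'   fit weeks `t0..T-1`.
#' @inheritParams run_ideal
#' @return A `stock_trajectory`.
#' @export
run_main <- function(series, forecasts, W_init, t0 = 5,
                     mode = "deterministic") {
  check_run_args(series, W_init, t0)
  stopifnot(inherits(forecasts, "forecast_matrix"))
  T_len <- series$T
  if (attr(forecasts, "T") != T_len) {
    stop("forecast matrix covers T = ", attr(forecasts, "T"),
         " weeks but the series has T = ", T_len, call. = FALSE)
  }
  needed <- seq.int(t0, T_len - 1L)
  have <- as.integer(rownames(forecasts))
  if (length(missing <- setdiff(needed, have))) {
    stop("forecast matrix lacks fit week(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  run_rate_strategy("M", series, W_init, t0, function(t, W) {
    demand <- future_demand(forecasts, t)
    if (demand <= 0) 1 else min(W / demand, 1)
  }, mode = mode)
}

#' Strategy S1: spend up to half the stock each week
#'
#' A prediction-free heuristic: each week uses
#' \eqn{\min\{\lfloor W_t / 2 \rfloor, P^R_t\}} kits. The geometric
#' spend-down front-loads consumption, which empties the stock quickly when
#' kits are scarce. The recorded rate is the realised one,
#' `kits_used / patients` (0 on patient-free weeks).
#'
#' @inheritParams run_ideal
#' @return A `stock_trajectory`.
#' @export
run_s1 <- function(series, W_init, t0 = 5) {
  check_run_args(series, W_init, t0)
  run_floor_strategy("S1", series, W_init, t0,
                     function(t, W) floor(W / 2))
}

#' Strategy S2: spread the stock over the remaining weeks
#'
#' A prediction-free heuristic assuming only that the season length `T` is
#' known in advance: week `t < T` uses
#' \eqn{\min\{\lfloor W_t / (T - t) \rfloor, P^R_t\}} kits, and the final
#' week spends whatever demand can absorb, \eqn{\min\{W_T, P^R_T\}}.
#'
#' @inheritParams run_ideal
#' @return A `stock_trajectory`.
#' @export
run_s2 <- function(series, W_init, t0 = 5) {
  check_run_args(series, W_init, t0)
  T_len <- series$T
  run_floor_strategy("S2", series, W_init, t0, function(t, W) {
    if (t < T_len) floor(W / (T_len - t)) else W
  })
}

run_floor_strategy <- function(strategy, series, W_init, t0, target_fn) {
  P <- series$counts
  T_len <- series$T
  n <- T_len - t0 + 1L
  W <- numeric(n + 1L)
  r <- numeric(n)
  used <- numeric(n)
  W[1L] <- W_init
  for (i in seq_len(n)) {
    t <- t0 + i - 1L
    used[i] <- min(target_fn(t, W[i]), P[t])
    W[i + 1L] <- W[i] - used[i]
    r[i] <- if (P[t] == 0) 0 else used[i] / P[t]
  }
  new_stock_trajectory(strategy, series, W, r, used, t0)
}
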