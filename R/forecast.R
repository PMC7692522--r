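#' Parameters of the single-peak incidence curve
#'
#' The weekly incidence model is the classic single-peak epidemic wave
#' \deqn{P(t) = \max\{0,\; A\,\mathrm{sech}^2(b t + c) + p\},}
#' the closed-form incidence shape of the Kermack-McKendrick SIR model near
#' its peak. `A` scales the wave (patients/week), `b` sets how fast it rises
#' and falls (1/week), `c` shifts it so the peak sits at week `-c/b`, and `p`
#' is a small additive baseline in \eqn{[-1, 1]} absorbing off-season
#' sporadic cases. Negative values of the raw curve are clamped to zero
#' before use.
#'
#' @param A Peak scale, > 0 (patients/week).
#' @param b Growth/decay rate, > 0 (1/week).
#' @param c Phase shift, <= 0 (dimensionless; peak week is `-c/b`).
#' @param p Additive baseline in `[-1, 1]` (patients/week).
#'
#' @return A `curve_params` object with fields `A`, `b`, `c`, `p`, the
#'   derived `peak_week`, and `r0_estimate` (reserved; `NA` unless supplied
#'   by an external calculation).
#' @examples
#' cp <- curve_params(A = 60, b = 0.4, c = -4, p = 0)
#' cp$peak_week           # 10
#' evaluate_curve(cp, 10) # 60, the peak value A + p
#' @export
curve_params <- function(A, b, c, p) {
  stopifnot(is.numeric(A), is.numeric(b), is.numeric(c), is.numeric(p))
  if (!(A > 0)) stop("A must be > 0", call. = FALSE)
  if (!(b > 0)) stop("b must be > 0", call. = FALSE)
  if (!(c <= 0)) stop("c must be <= 0", call. = FALSE)
  if (p < -1 || p > 1) stop("p must lie in [-1, 1]", call. = FALSE)
  structure(
    list(A = as.numeric(A), b = as.numeric(b), c = as.numeric(c),
         p = as.numeric(p), peak_week = -c / b, r0_estimate = NA_real_),
    class = "curve_params"
  )
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf(
    "<curve_params> A = %.4g, b = %.4g, c = %.4g, p = %.4g (peak week %.2f)\n",
    x$A, x$b, x$c, x$p, x$peak_week))
  invisible(x)
}

#' Box constraints for curve fitting
#'
#' @param lower,upper Named numeric vectors with entries `A`, `b`, `c`, `p`;
#'   `lower` must be strictly below `upper` componentwise.
#' @return A `param_bounds` object.
#' @seealso [default_bounds()] for data-driven defaults.
#' @export
param_bounds <- function(lower, upper) {
  nm <- c("A", "b", "c", "p")
  lower <- lower[nm]; upper <- upper[nm]
  if (anyNA(lower) || anyNA(upper)) {
    stop("bounds need named entries A, b, c, p", call. = FALSE)
  }
  if (!all(lower < upper)) {
    stop("each lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "param_bounds")
}

#' Default fitting bounds for a count series
#'
#' `A` may range up to three times the largest observed count (so an
#' early-season prefix can still reach a plausible peak), `b` spans slow to
#' very sharp waves, `c` keeps the peak at a non-negative week within the
#' usual season span, and `p` is confined to a one-patient baseline either
#' way.
#'
#' @param counts Numeric vector of observed weekly counts (a prefix is fine).
#' @return A [param_bounds()] object: `A` in `[1e-3, 3 * max(counts, 1)]`,
#'   `b` in `[0.1, 2]`, `c` in `[-10, 0]`, `p` in `[-1, 1]`.
#' @export
default_bounds <- function(counts) {
  top <- max(c(counts, 1), na.rm = TRUE)
  param_bounds(
    lower = c(A = 1e-3, b = 0.1, c = -10, p = -1),
    upper = c(A = 3 * top, b = 2, c = 0, p = 1)
  )
}

sech2 <- function(x) 1 / cosh(x)^2

raw_curve <- function(A, b, c, p, week) A * sech2(b * week + c) + p

#' Evaluate the incidence curve at given weeks
#'
#' @param params A [curve_params()] object.
#' @param week Numeric vector of weeks (>= 0).
#' @return Non-negative predicted patient counts, clamped at zero.
#' @export
evaluate_curve <- function(params, week) {
  stopifnot(inherits(params, "curve_params"))
  if (any(week < 0)) stop("week must be >= 0", call. = FALSE)
  pmax(0, raw_curve(params$A, params$b, params$c, params$p, week))
}

#' Fit the single-peak curve to a prefix of a weekly series
#'
#' Minimises the sum of squared residuals between the observed counts for
#' weeks `1..s` and the clamped curve, subject to box constraints, by
#' bounded quasi-Newton descent (`optim(method = "L-BFGS-B")`) restarted
#' from a fixed coarse grid over `(b, c)`. The multi-start grid is fixed, so
#' repeated calls on the same input give bitwise-identical results.
#'
#' An all-zero prefix carries no signal; the fit then returns the boundary
#' parameters (`A` at its lower bound, curve flat at zero) flagged
#' `degenerate = TRUE`.
#'
#' @param series A [weekly_series()] or a plain numeric vector of weekly
#'   counts (week 1 first). Passing a numeric vector permits fitting
#'   real-valued curves, e.g. when checking parameter recovery on exact
#'   model output.
#' @param s Number of leading weeks to fit on (>= 5); defaults to the full
#'   series.
#' @param bounds A [param_bounds()] object; [default_bounds()] of the fitted
#'   prefix when omitted.
#' @return A `curve_fit` object: `params` ([curve_params()]), `sse`,
#'   `n_weeks_used`, `converged`, `degenerate`.
#' @examples
#' truth <- curve_params(30, 0.5, -5, 0.2)
#' y <- evaluate_curve(truth, 1:25)
#' fit_curve(y)$params
#' @export
fit_curve <- function(series, s = NULL, bounds = NULL) {
  y <- if (inherits(series, "weekly_series")) series$counts else {
    stopifnot(is.numeric(series))
    series
  }
  if (is.null(s)) s <- length(y)
  if (s < 5) {
    stop("fitting requires the data from the initial five weeks (s >= 5)",
         call. = FALSE)
  }
  if (s > length(y)) {
    stop("s = ", s, " exceeds the available ", length(y), " weeks",
         call. = FALSE)
  }
  y <- as.numeric(y[seq_len(s)])
  if (is.null(bounds)) bounds <- default_bounds(y)
  stopifnot(inherits(bounds, "param_bounds"))
  lo <- bounds$lower
  up <- bounds$upper

  if (all(y == 0)) {
    # boundary fit: A at its lower bound and the baseline as low as the box
    # allows, so the clamped curve predicts (near-)zero everywhere
    pars <- clamp_params(c(A = lo[["A"]], b = lo[["b"]], c = up[["c"]],
                           p = lo[["p"]]), lo, up)
    params <- do.call(curve_params, as.list(pars))
    return(new_curve_fit(params, sse_of(pars, y), s,
                         converged = FALSE, degenerate = TRUE))
  }

  weeks <- seq_len(s)
  objective <- function(par) {
    r <- y - pmax(0, raw_curve(par[1L], par[2L], par[3L], par[4L], weeks))
    sum(r * r)
  }
  a0 <- min(max(max(y), lo[["A"]] * 1.01), up[["A"]] * 0.99)
  starts <- expand.grid(
    b = c(0.25, 0.6, 1.2, 1.8),
    c = c(-8, -5.5, -3, -1.2)
  )
  parscale <- pmax(abs(up - lo) / 10, 1e-3)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- clamp_params(c(A = a0, b = starts$b[i], c = starts$c[i], p = 0),
                         lo, up)
    res <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lo, upper = up,
                   control = list(maxit = 300, factr = 1e4,
                                  parscale = parscale)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("curve fit failed from every start", call. = FALSE)
  }
  pars <- clamp_params(stats::setNames(best$par, c("A", "b", "c", "p")),
                       lo, up)
  params <- do.call(curve_params, as.list(pars))
  new_curve_fit(params, best$value, s,
                converged = best$convergence == 0, degenerate = FALSE)
}

clamp_params <- function(par, lo, up) {
  par <- pmin(pmax(par, lo), up)
  # keep the constructor's open constraints satisfied at the box edge
  if (par[["A"]] <= 0) par[["A"]] <- lo[["A"]]
  if (par[["b"]] <= 0) par[["b"]] <- lo[["b"]]
  if (par[["c"]] > 0) par[["c"]] <- 0
  par
}

sse_of <- function(par, y) {
  r <- y - pmax(0, raw_curve(par[["A"]], par[["b"]], par[["c"]], par[["p"]],
                             seq_along(y)))
  sum(r * r)
}

new_curve_fit <- function(params, sse, n_weeks_used, converged, degenerate) {
  structure(
    list(params = params, sse = sse, n_weeks_used = n_weeks_used,
         converged = converged, degenerate = degenerate),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> on %d weeks, sse = %.4g%s\n", x$n_weeks_used,
              x$sse, if (x$degenerate) " (degenerate: no signal)" else ""))
  print(x$params)
  invisible(x)
}

#' Rolling-origin forecasts of a weekly series
#'
#' For each fit week `t = first_fit_week .. T-1`, fits the curve to weeks
#' `1..t` and predicts weeks `t+1..T`. Entry `[t, s]` of the result is
#' \eqn{\hat P_s(t)}, the forecast of week `s` made with data through week
#' `t`; forecasts are clamped at zero.
#'
#' @param series A [weekly_series()].
#' @param bounds Optional [param_bounds()] shared by all fits; defaults to
#'   [default_bounds()] of the full series, so every rolling fit searches
#'   the same box.
#' @param first_fit_week First week whose data prefix is fitted (>= 5;
#'   default 5, the minimum the fit accepts).
#' @return A `forecast_matrix`: numeric matrix with one row per fit week and
#'   one column per season week (`NA` at or before the fit week), carrying
#'   attributes `T`, `first_fit_week` and `sse` (per-fit in-sample error).
#' @export
rolling_forecasts <- function(series, bounds = NULL, first_fit_week = 5) {
  stopifnot(inherits(series, "weekly_series"))
  if (first_fit_week < 5) {
    stop("first_fit_week must be >= 5", call. = FALSE)
  }
  T_len <- series$T
  if (first_fit_week > T_len - 1L) {
    stop("first_fit_week must leave at least one week to forecast",
         call. = FALSE)
  }
  if (is.null(bounds)) bounds <- default_bounds(series$counts)
  fit_weeks <- seq.int(first_fit_week, T_len - 1L)
  mat <- matrix(NA_real_, nrow = length(fit_weeks), ncol = T_len,
                dimnames = list(fit_week = fit_weeks, week = seq_len(T_len)))
  sse <- stats::setNames(numeric(length(fit_weeks)), fit_weeks)
  for (i in seq_along(fit_weeks)) {
    t <- fit_weeks[i]
    fit <- tryCatch(fit_curve(series, s = t, bounds = bounds),
                    error = function(e) {
                      stop("rolling fit failed at week ", t, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    future <- seq.int(t + 1L, T_len)
    mat[i, future] <- evaluate_curve(fit$params, future)
    sse[i] <- fit$sse
  }
  structure(mat, class = c("forecast_matrix", "matrix"),
            T = T_len, first_fit_week = first_fit_week, sse = sse)
}

#' Total predicted future demand after a given week
#'
#' @param fm A `forecast_matrix` from [rolling_forecasts()].
#' @param t Fit week; forecasts fitted on weeks `1..t` are summed over weeks
#'   `t+1..T`. At `t = T` the future is empty and the demand is 0.
#' @return Non-negative real: \eqn{\sum_{s=t+1}^{T} \hat P_s(t)}.
#' @export
future_demand <- function(fm, t) {
  stopifnot(inherits(fm, "forecast_matrix"))
  T_len <- attr(fm, "T")
  if (t == T_len) return(0)
  row <- match(as.character(t), rownames(fm))
  if (is.na(row)) {
    stop("no forecasts fitted through week ", t, call. = FALSE)
  }
  sum(fm[row, seq.int(t + 1L, T_len)])
}
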