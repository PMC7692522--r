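#' Loss of a strategy relative to the ideal distribution
#'
#' Scores a strategy's stock trajectory against the hindsight ideal by the
#' normalised total absolute stock deviation
#' \deqn{E^X = \frac{1}{(T-5)\,W_{\mathrm{init}}}
#'   \sum_{t=6}^{T} |W^X_t - W^I_t|.}
#' The sum starts the week after activation (week 6 for the default
#' `t0 = 5`, the first week on which the strategies can differ); the
#' normaliser keeps the `(T - 5)` of the definition whatever `t0` is. `E` is
#' 0 when the trajectories coincide and grows as the strategy over- or
#' under-spends relative to the ideal; both stocks live in
#' `[0, W_init]`, so `E` is at most 1, and in practice single-peak seasons
#' keep it below 1/2.
#'
#' @param candidate,ideal `stock_trajectory` objects sharing `W_init`, `T`
#'   and `t0`; `ideal` is normally [run_ideal()] output.
#' @return The loss `E`, a non-negative real.
#' @examples
#' ws <- weekly_series("toy", "t", c(0, 0, 0, 0, 10, 10, 10, 10))
#' loss(run_s1(ws, 20), run_ideal(ws, 20))  # 0.15
#' @export
loss <- function(candidate, ideal) {
  stopifnot(inherits(candidate, "stock_trajectory"),
            inherits(ideal, "stock_trajectory"))
  if (candidate$W_init != ideal$W_init) {
    stop("trajectories have different W_init (", candidate$W_init, " vs ",
         ideal$W_init, ")", call. = FALSE)
  }
  if (candidate$T != ideal$T || candidate$t0 != ideal$t0) {
    stop("trajectories cover different weeks (T or t0 mismatch)",
         call. = FALSE)
  }
  T_len <- candidate$T
  t0 <- candidate$t0
  wk <- as.character(seq.int(t0 + 1L, T_len))
  sum(abs(candidate$W[wk] - ideal$W[wk])) / ((T_len - 5) * candidate$W_init)
}

#' Convert a filling rate to an initial stock
#'
#' The filling rate `f = W_init / sum_t P^R_t` measures how severe the kit
#' shortage is: `f = 1` means exactly one kit per suspected patient over the
#' season. This inverts it, rounding to the nearest integer with a floor of
#' one kit.
#'
#' @param f Filling rate, > 0.
#' @param series A [weekly_series()] with positive season total.
#' @return Integer `W_init = max(1, round(f * season_total))`.
#' @export
filling_to_stock <- function(f, series) {
  stopifnot(inherits(series, "weekly_series"))
  if (!(f > 0)) stop("filling rate f must be > 0", call. = FALSE)
  total <- season_total(series)
  if (total == 0) {
    stop("season total is zero for institution ", series$institution_id,
         "; the filling rate is undefined", call. = FALSE)
  }
  max(1L, as.integer(round(f * total)))
}

#' Sweep filling rates across institutions and strategies
#'
#' For every institution and every filling rate in the grid, converts `f` to
#' an initial stock, runs the ideal benchmark plus each requested strategy,
#' and records the loss. Strategy `"M"` triggers one set of rolling
#' forecasts per institution, reused across the whole grid. Failures (e.g. a
#' zero-total institution) are recorded per cell and the sweep continues.
#'
#' @param collection Named list of [weekly_series()].
#' @param strategies Character vector drawn from `"M"`, `"S1"`, `"S2"`,
#'   `"I"` (the last scores the ideal against itself, a zero-loss
#'   self-check).
#' @param f_grid Numeric vector of filling rates (> 0), e.g.
#'   `c(0.4, 0.55, 0.7, 0.85, 1)`.
#' @param t0 Activation week passed to the strategy runners (default 5).
#' @param bounds Optional shared [param_bounds()] for the rolling fits.
#' @param groups Optional named group vector; [assign_groups()] when omitted.
#' @return A `sweep_result` list: `losses` (tibble with one row per
#'   institution x strategy x f: `institution_id`, `season`, `group`,
#'   `strategy`, `f`, `W_init`, `E`, `failed`, `reason`), `summaries`
#'   (per group x strategy x f: n, mean, median, linearly interpolated
#'   quartiles, min, max, and the count of points beyond 1.5 IQR from the
#'   quartiles), plus the grid and strategy list.
#' @export
sweep_filling_rates <- function(collection, strategies = c("M", "S1", "S2"),
                                f_grid, t0 = 5, bounds = NULL,
                                groups = NULL) {
  check_collection(collection)
  strategies <- match.arg(strategies, c("M", "S1", "S2", "I"),
                          several.ok = TRUE)
  if (length(f_grid) == 0L || any(!is.finite(f_grid)) || any(f_grid <= 0)) {
    stop("f_grid must be a non-empty vector of positive filling rates",
         call. = FALSE)
  }
  f_grid <- sort(unique(f_grid))
  if (is.null(groups)) groups <- assign_groups(collection)

  rows <- list()
  for (series in collection) {
    id <- series$institution_id
    group <- unname(groups[[id]])
    fm <- NULL
    fm_error <- NULL
    if ("M" %in% strategies) {
      fm <- tryCatch(rolling_forecasts(series, bounds = bounds,
                                       first_fit_week = t0),
                     error = function(e) {
                       fm_error <<- conditionMessage(e)
                       NULL
                     })
    }
    for (f in f_grid) {
      cell <- function(strategy, E, failed = FALSE, reason = NA_character_,
                       W_init = NA_integer_) {
        tibble::tibble(institution_id = id, season = series$season,
                       group = group, strategy = strategy, f = f,
                       W_init = W_init, E = E, failed = failed,
                       reason = reason)
      }
      W_init <- tryCatch(filling_to_stock(f, series), error = identity)
      if (inherits(W_init, "error")) {
        for (strategy in strategies) {
          rows[[length(rows) + 1L]] <-
            cell(strategy, NA_real_, TRUE, conditionMessage(W_init))
        }
        next
      }
      ideal <- run_ideal(series, W_init, t0 = t0)
      for (strategy in strategies) {
        res <- tryCatch({
          traj <- switch(strategy,
            I = ideal,
            M = {
              if (is.null(fm)) stop(fm_error %||% "no forecasts")
              run_main(series, fm, W_init, t0 = t0)
            },
            S1 = run_s1(series, W_init, t0 = t0),
            S2 = run_s2(series, W_init, t0 = t0)
          )
          cell(strategy, loss(traj, ideal), W_init = W_init)
        }, error = function(e) {
          cell(strategy, NA_real_, TRUE, conditionMessage(e),
               W_init = W_init)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  losses <- dplyr::bind_rows(rows)
  structure(
    list(losses = losses,
         summaries = summarize_sweep(losses),
         f_grid = f_grid,
         strategies = strategies,
         t0 = t0),
    class = "sweep_result"
  )
}

summarize_sweep <- function(losses) {
  ok <- losses[!losses$failed, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(tibble::tibble(group = character(), strategy = character(),
                          f = numeric(), n = integer(), mean = numeric(),
                          median = numeric(), q1 = numeric(), q3 = numeric(),
                          min = numeric(), max = numeric(),
                          n_outliers = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(ok, .data$group, .data$strategy, .data$f),
    n = dplyr::n(),
    mean = mean(.data$E),
    median = stats::median(.data$E),
    q1 = unname(stats::quantile(.data$E, 0.25, type = 7)),
    q3 = unname(stats::quantile(.data$E, 0.75, type = 7)),
    min = min(.data$E),
    max = max(.data$E),
    n_outliers = {
      qq <- unname(stats::quantile(.data$E, c(0.25, 0.75), type = 7))
      iqr <- qq[2L] - qq[1L]
      sum(.data$E < qq[1L] - 1.5 * iqr | .data$E > qq[2L] + 1.5 * iqr)
    },
    .groups = "drop"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(unique(x$losses$institution_id)),
      " institutions x ", length(x$strategies), " strategies x ",
      length(x$f_grid), " filling rates (",
      sum(x$losses$failed), " failed cells)\n", sep = "")
  print(x$summaries)
  invisible(x)
}

#' Filling rate minimising the loss for one institution and strategy
#'
#' Grid argmin of the swept loss. `interior` reports whether the minimiser
#' sits strictly inside the grid range — the signature of a most efficient
#' stock level below "one kit per patient". Ties are resolved to the
#' smallest filling rate and flagged.
#'
#' @param sweep A `sweep_result` from [sweep_filling_rates()].
#' @param institution Institution id present in the sweep.
#' @param strategy Strategy label present in the sweep.
#' @return List with `f_star`, `E_star`, `interior` and `tie`.
#' @export
find_min_loss_fill <- function(sweep, institution, strategy) {
  stopifnot(inherits(sweep, "sweep_result"))
  rows <- sweep$losses[sweep$losses$institution_id == institution &
                         sweep$losses$strategy == strategy &
                         !sweep$losses$failed, , drop = FALSE]
  if (nrow(rows) < 3L) {
    stop("need at least 3 successful grid points for institution ",
         institution, ", strategy ", strategy, " (got ", nrow(rows), ")",
         call. = FALSE)
  }
  rows <- rows[order(rows$f), , drop = FALSE]
  e_min <- min(rows$E)
  at_min <- which(rows$E == e_min)
  f_star <- rows$f[at_min[1L]]
  list(
    f_star = f_star,
    E_star = e_min,
    interior = f_star > min(rows$f) && f_star < max(rows$f),
    tie = length(at_min) > 1L
  )
}
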