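#' Default per-group sampling ranges for synthetic curve parameters
#'
#' Ranges of the single-peak curve parameters `(A, b, c, p)` for
#' high- (A), mid- (B) and low-volume (C) institutions, matching the spread
#' of parameters fitted to a full season of weekly influenza counts across a
#' city's medical institutions. Where a fitted extreme sat exactly on a
#' fitting-box edge (`c = -10`, `b = 2`, `p = +/-1`) the sampling range is
#' pulled slightly interior so that sampled curves never start out
#' degenerate.
#'
#' @return A named list (`A`, `B`, `C`) of lists with `lower`/`upper`
#'   vectors named `A`, `b`, `c`, `p`.
#' @export
default_param_ranges <- function() {
  list(
    A = list(lower = c(A = 22.6, b = 0.20, c = -9.9, p = -0.26),
             upper = c(A = 124.4, b = 0.91, c = -2.07, p = 0.99)),
    B = list(lower = c(A = 13.7, b = 0.21, c = -9.9, p = -0.99),
             upper = c(A = 58.5, b = 1.39, c = -2.58, p = 0.99)),
    C = list(lower = c(A = 1.6, b = 0.18, c = -9.9, p = -0.99),
             upper = c(A = 17.6, b = 1.95, c = -2.23, p = 0.99))
  )
}

#' Configuration for a synthetic incidence ensemble
#'
#' Describes an ensemble of single-peak weekly incidence series emulating
#' one epidemic season of city-wide influenza surveillance: 38 institutions
#' over 25 weeks split 13/13/12 into volume groups by default, with
#' per-group uniform parameter ranges and Poisson observation noise on the
#' weekly counts.
#'
#' @param n_institutions Number of institutions (default 38).
#' @param T Season length in weeks (default 25).
#' @param group_mix Named integer vector of institutions per group, summing
#'   to `n_institutions` (default `c(A = 13, B = 13, C = 12)`).
#' @param param_ranges Per-group ranges as from [default_param_ranges()].
#' @param noise `"poisson"` (default) for Poisson-distributed weekly counts
#'   around the curve, or `"none"` for rounded curve values.
#' @param season Season label stamped on every series.
#' @param seed Integer seed; [generate_ensemble()] is bitwise-reproducible
#'   given the same config.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_institutions = 38, T = 25,
                             group_mix = NULL,
                             param_ranges = default_param_ranges(),
                             noise = c("poisson", "none"),
                             season = "synthetic", seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(group_mix)) {
    n_a <- ceiling(n_institutions / 3)
    n_b <- ceiling((n_institutions - n_a) / 2)
    group_mix <- c(A = n_a, B = n_b, C = n_institutions - n_a - n_b)
  }
  stopifnot(setequal(names(group_mix), c("A", "B", "C")),
            sum(group_mix) == n_institutions,
            T >= 7, seed == round(seed))
  for (g in names(param_ranges)) {
    rg <- param_ranges[[g]]
    if (!all(rg$lower <= rg$upper)) {
      stop("invalid parameter range for group ", g, call. = FALSE)
    }
  }
  structure(
    list(n_institutions = as.integer(n_institutions), T = as.integer(T),
         group_mix = group_mix[c("A", "B", "C")],
         param_ranges = param_ranges, noise = noise,
         season = season, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Draw curve parameters for one synthetic institution
#'
#' Samples `(A, b, c, p)` uniformly within the group's configured range,
#' rejecting draws whose peak week `-c/b` falls outside `[4, T - 4]` so
#' every synthetic season has a single mid-season peak. Uses the current R
#' random number generator state (seed upstream, e.g. via
#' [generate_ensemble()]).
#'
#' @param config A [synthetic_config()].
#' @param group `"A"`, `"B"` or `"C"`.
#' @param max_tries Rejection-sampling cap before erroring (default 1000).
#' @return A [curve_params()] object.
#' @export
sample_params <- function(config, group, max_tries = 1000L) {
  stopifnot(inherits(config, "synthetic_config"))
  rg <- config$param_ranges[[group]]
  if (is.null(rg)) stop("unknown group '", group, "'", call. = FALSE)
  lo <- rg$lower
  up <- rg$upper
  for (i in seq_len(max_tries)) {
    draw <- lo + stats::runif(4L) * (up - lo)
    peak <- -draw[["c"]] / draw[["b"]]
    if (peak >= 4 && peak <= config$T - 4) {
      return(curve_params(draw[["A"]], draw[["b"]], draw[["c"]],
                          draw[["p"]]))
    }
  }
  stop("no feasible single-peak parameters for group ", group,
       " in ", max_tries, " draws; check the configured ranges",
       call. = FALSE)
}

#' Generate one synthetic weekly series from curve parameters
#'
#' Noiseless mode rounds the curve to integer counts; Poisson mode draws
#' each week's count with the curve value as its mean (using the current
#' RNG state). Either way counts are non-negative integers.
#'
#' @param params A [curve_params()].
#' @param T Season length in weeks.
#' @param noise `"none"` or `"poisson"`.
#' @param institution_id,season Labels for the resulting series.
#' @return A [weekly_series()].
#' @export
generate_series <- function(params, T, noise = c("none", "poisson"),
                            institution_id = "synthetic",
                            season = "synthetic") {
  noise <- match.arg(noise)
  mu <- evaluate_curve(params, seq_len(T))
  counts <- switch(noise,
    none = round(mu),
    poisson = stats::rpois(T, lambda = mu)
  )
  weekly_series(institution_id, season, counts)
}

#' Generate a seeded synthetic ensemble of weekly series
#'
#' Draws curve parameters per institution within its group's range and
#' synthesises the weekly counts, restoring the caller's RNG state
#' afterwards. Institution ids encode the generating group
#' (`"A01"`, ..., `"C12"`) so that volume-based grouping can be checked
#' against the truth.
#'
#' @param config A [synthetic_config()].
#' @return Named list of [weekly_series()] with attributes `params` (the
#'   sampled [curve_params()] per institution), `groups` (the generating
#'   group labels) and `config`.
#' @examples
#' ens <- generate_ensemble(synthetic_config(seed = 42))
#' length(ens)       # 38
#' ens[["A01"]]$T    # 25
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  series <- list()
  params <- list()
  groups <- character()
  for (g in c("A", "B", "C")) {
    for (i in seq_len(config$group_mix[[g]])) {
      id <- sprintf("%s%02d", g, i)
      cp <- sample_params(config, g)
      series[[id]] <- generate_series(cp, config$T, noise = config$noise,
                                      institution_id = id,
                                      season = config$season)
      params[[id]] <- cp
      groups[[id]] <- g
    }
  }
  structure(series, params = params, groups = groups, config = config)
}
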