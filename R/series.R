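#' Weekly incidence series for one institution-season
#'
#' A `weekly_series` holds the observed number of newly confirmed suspected
#' patients per week at a single medical institution over one epidemic season:
#' counts \eqn{P^R_t} for weeks \eqn{t = 1, \dots, T}.
#'
#' Seasons must span at least 7 weeks: the rationing strategies activate at
#' week 5 and the loss metric sums deviations from week 6 onward, so shorter
#' series leave no informative weeks.
#'
#' @param institution_id Character scalar identifying the institution.
#' @param season Character scalar labelling the season (e.g. `"2018"`).
#' @param counts Integer vector of non-negative weekly patient counts,
#'   week 1 first.
#'
#' @return An object of class `weekly_series` with fields `institution_id`,
#'   `season`, `counts` and `T` (season length in weeks).
#' @examples
#' ws <- weekly_series("inst01", "2018", c(0, 1, 3, 8, 15, 20, 12, 5, 1, 0))
#' season_total(ws)
#' @export
weekly_series <- function(institution_id, season, counts) {
  stopifnot(is.character(institution_id), length(institution_id) == 1L,
            length(season) == 1L)
  counts <- as.vector(counts)
  if (length(counts) < 7L) {
    stop("a weekly series needs at least 7 weeks (got ", length(counts), ")",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers (institution ",
         institution_id, ")", call. = FALSE)
  }
  structure(
    list(
      institution_id = institution_id,
      season = as.character(season),
      counts = as.integer(round(counts)),
      T = length(counts)
    ),
    class = "weekly_series"
  )
}

#' @export
print.weekly_series <- function(x, ...) {
  cat("<weekly_series> ", x$institution_id, " / season ", x$season,
      " / T = ", x$T, " weeks, ", season_total(x), " patients\n", sep = "")
  invisible(x)
}

#' Season total of a weekly series
#'
#' @param series A [weekly_series()].
#' @return Integer: \eqn{\sum_t P^R_t} over the whole season.
#' @export
season_total <- function(series) {
  stopifnot(inherits(series, "weekly_series"))
  sum(series$counts)
}

#' Read a collection of weekly series from a delimited text file
#'
#' Expects a header row and columns `institution_id`, `season`, `week`,
#' `cases` (comma-separated by default). Each institution must contribute a
#' gapless run of weeks `1..T`. Lines starting with `#` are treated as
#' comments (the command-line tools write provenance headers this way).
#'
#' @param path Path to the input file.
#' @param season Optional season label to select when the file holds several
#'   seasons; if `NULL` the file must contain exactly one season.
#' @param sep Field separator, default comma.
#' @return A named list of [weekly_series()], sorted by institution id.
#' @export
load_series <- function(path, season = NULL, sep = ",") {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, sep = sep, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("institution_id", "season", "week", "cases")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$season <- as.character(df$season)
  if (is.null(season)) {
    seasons <- unique(df$season)
    if (length(seasons) != 1L) {
      stop("file contains seasons [", paste(seasons, collapse = ", "),
           "]; pass `season` to pick one", call. = FALSE)
    }
    season <- seasons
  }
  df <- df[df$season == as.character(season), , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no rows for season '", season, "' in ", path, call. = FALSE)
  }
  bad <- !is.finite(df$cases) | df$cases < 0 | df$cases != round(df$cases)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("invalid cases value ", df$cases[i], " (institution ",
         df$institution_id[i], ", week ", df$week[i],
         "): counts must be non-negative integers", call. = FALSE)
  }
  out <- lapply(split(df, df$institution_id), function(d) {
    d <- d[order(d$week), , drop = FALSE]
    id <- d$institution_id[1L]
    if (anyDuplicated(d$week)) {
      stop("duplicate week ", d$week[anyDuplicated(d$week)],
           " for institution ", id, call. = FALSE)
    }
    expected <- seq_len(nrow(d))
    if (!identical(as.integer(d$week), as.integer(expected))) {
      gap <- setdiff(expected, d$week)
      stop("weeks for institution ", id, " must run 1..T without gaps",
           if (length(gap)) paste0(" (missing week ", gap[1L], ")") else "",
           call. = FALSE)
    }
    weekly_series(id, season, d$cases)
  })
  out[order(names(out))]
}

#' Write a collection of weekly series to a delimited text file
#'
#' Inverse of [load_series()]: `load_series(save_series(x, path))` restores
#' `x` exactly. Institutions are written sorted by id.
#'
#' @param collection Named list of [weekly_series()].
#' @param path Output path.
#' @param sep Field separator, default comma.
#' @param header_lines Optional character vector of provenance lines written
#'   as `#`-prefixed comments before the column header.
#' @return The path, invisibly.
#' @export
save_series <- function(collection, path, sep = ",", header_lines = NULL) {
  check_collection(collection)
  collection <- collection[order(vapply(collection, function(s)
    s$institution_id, character(1)))]
  df <- dplyr::bind_rows(lapply(collection, function(s) {
    tibble::tibble(
      institution_id = s$institution_id,
      season = s$season,
      week = seq_len(s$T),
      cases = s$counts
    )
  }))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_collection <- function(collection) {
  if (!is.list(collection) || length(collection) == 0L ||
      !all(vapply(collection, inherits, logical(1), "weekly_series"))) {
    stop("expected a non-empty list of weekly_series objects", call. = FALSE)
  }
  invisible(collection)
}

#' Rank institutions into groups A, B, C by season volume
#'
#' Institutions are ordered by descending season total; the top
#' `ceiling(N/3)` form group A, the next `ceiling((N - |A|)/2)` group B, and
#' the remainder group C (at N = 38 this yields the 13/13/12 split). Ties in
#' the totals are broken by institution id, lexicographically, so the
#' assignment is deterministic.
#'
#' @param collection Named list of [weekly_series()] (at least 3).
#' @return Named character vector mapping institution id to `"A"`, `"B"` or
#'   `"C"`.
#' @export
assign_groups <- function(collection) {
  check_collection(collection)
  n <- length(collection)
  if (n < 3L) {
    stop("need at least 3 institutions to form groups A/B/C (got ", n, ")",
         call. = FALSE)
  }
  ids <- vapply(collection, function(s) s$institution_id, character(1))
  totals <- vapply(collection, season_total, numeric(1))
  ord <- order(-totals, ids)
  n_a <- ceiling(n / 3)
  n_b <- ceiling((n - n_a) / 2)
  labels <- rep(c("A", "B", "C"), times = c(n_a, n_b, n - n_a - n_b))
  stats::setNames(labels, ids[ord])
}

#' Per-group summaries of season totals
#'
#' Mean, sample standard deviation (denominator n - 1), maximum and minimum
#' of the institutions' season totals, for each group and overall. A group
#' holding a single institution gets `sd = 0` with a warning.
#'
#' @param collection Named list of [weekly_series()].
#' @param groups Named group vector from [assign_groups()]; computed when
#'   omitted.
#' @return A tibble with rows for groups A, B, C and `"Total"` and columns
#'   `group`, `n`, `mean`, `sd`, `max`, `min`.
#' @export
summarize_groups <- function(collection, groups = NULL) {
  check_collection(collection)
  if (is.null(groups)) groups <- assign_groups(collection)
  ids <- vapply(collection, function(s) s$institution_id, character(1))
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids)) {
    stop("no group assignment for institution(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  totals <- vapply(collection, season_total, numeric(1))
  tab <- tibble::tibble(group = unname(groups[ids]), total = totals)
  one <- function(label, x) {
    s <- if (length(x) > 1L) stats::sd(x) else {
      warning("group ", label, " has a single institution; sd reported as 0",
              call. = FALSE)
      0
    }
    tibble::tibble(group = label, n = length(x), mean = mean(x), sd = s,
                   max = max(x), min = min(x))
  }
  per_group <- lapply(sort(unique(tab$group)), function(g) {
    one(g, tab$total[tab$group == g])
  })
  dplyr::bind_rows(c(per_group, list(one("Total", tab$total))))
}
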