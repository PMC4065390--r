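# Calendar bookkeeping: parsing birthdates in declared dialects, aggregating
# to a dense daily count series, and marking weekends/holidays.

DIALECTS <- c("iso", "us", "uk")

#' Calendar configuration
#'
#' Bundles the bookkeeping needed to interpret raw birthdates and to build the
#' weekend/holiday indicator \eqn{I(\cdot)} used by the model: which weekdays
#' count as "weekend", an optional holiday list, and the date dialect raw
#' strings are written in.
#'
#' @param weekend_days Integer ISO weekday numbers (1 = Monday ... 7 = Sunday)
#'   treated as weekend. Default Saturday and Sunday.
#' @param holidays A `Date` vector of public holidays (see [read_holidays()]).
#' @param dialect One of `"iso"` (Y-M-D), `"us"` (M/D/Y), `"uk"` (D/M/Y).
#'   There is deliberately no auto-guessing: silent dialect guessing is itself
#'   a source of the contamination this package detects.
#' @param treat_holidays_as_weekend If `TRUE` (default), listed holidays get
#'   the same indicator as weekends, so a single multiplicative smooth covers
#'   both; births drop on holidays for the same reason they drop on weekends.
#'
#' @return A list of class `calendar_config`.
#' @examples
#' calendar_config(weekend_days = c(6, 7))
#' @export
calendar_config <- function(weekend_days = c(6L, 7L),
                            holidays = as.Date(character()),
                            dialect = "iso",
                            treat_holidays_as_weekend = TRUE) {
  weekend_days <- as.integer(weekend_days)
  if (length(weekend_days) && !all(weekend_days %in% 1:7)) {
    bg_abort("`weekend_days` must be ISO weekday numbers in 1..7.",
             "birthgam_config_error")
  }
  if (!inherits(holidays, "Date")) {
    bg_abort("`holidays` must be a Date vector.", "birthgam_config_error")
  }
  dialect <- match_dialect(dialect)
  structure(
    list(weekend_days = sort(unique(weekend_days)),
         holidays = sort(unique(holidays)),
         dialect = dialect,
         treat_holidays_as_weekend = isTRUE(treat_holidays_as_weekend)),
    class = "calendar_config"
  )
}

match_dialect <- function(dialect) {
  if (length(dialect) != 1 || !dialect %in% DIALECTS) {
    bg_abort(
      paste0("Unknown date dialect ", deparse(dialect),
             "; must be one of ", paste(DIALECTS, collapse = ", "), "."),
      "birthgam_config_error"
    )
  }
  dialect
}

#' ISO weekday number (1 = Monday ... 7 = Sunday)
#'
#' @param date A `Date` vector (proleptic Gregorian, as R's `Date`).
#' @return Integer vector in 1..7.
#' @examples
#' iso_weekday(as.Date("2010-01-02")) # a Saturday -> 6
#' @export
iso_weekday <- function(date) {
  # Date is days since 1970-01-01, a Thursday (ISO weekday 4).
  ((as.integer(unclass(as.Date(date))) + 3L) %% 7L) + 1L
}

#' Parse raw birthdates in a declared dialect
#'
#' Every input maps to exactly one valid date or one rejection entry; nothing
#' is guessed. Accepted dialects are `iso` ("2010-01-02"), `us` ("01/02/2010")
#' and `uk` ("02/01/2010") -- the same string can be a different day in each,
#' which is precisely the format confusion that contaminates databases, so the
#' dialect must be declared explicitly.
#'
#' @param data A data frame of person records, or a character vector of raw
#'   birthdate strings.
#' @param dialect `"iso"`, `"us"` or `"uk"`.
#' @param birthdate_col Column holding the raw birthdate (tidy-eval), default
#'   `birthdate`. Ignored when `data` is a character vector.
#' @param id_col Optional column with a record identifier; default is the row
#'   number.
#' @param date_min,date_max Optional configured plausibility bounds; parsed
#'   dates outside them are rejected with status `"out_of_bounds"`.
#'
#' @return A tibble with one row per input record: `record_id`,
#'   `birthdate_raw`, `date` (`NA` unless accepted) and `status`, one of
#'   `accepted`, `missing`, `unparseable`, `impossible`, `out_of_bounds`.
#' @examples
#' parse_birthdates(c("2010-01-02", "31/02/2010"), dialect = "iso")
#' @export
parse_birthdates <- function(data, dialect,
                             birthdate_col = "birthdate",
                             id_col = NULL,
                             date_min = NULL, date_max = NULL) {
  dialect <- match_dialect(dialect)
  if (is.character(data)) {
    raw <- data
    ids <- as.character(seq_along(raw))
  } else if (is.data.frame(data)) {
    if (!birthdate_col %in% names(data)) {
      bg_abort(paste0("Column `", birthdate_col, "` not found in `data`."),
               "birthgam_config_error")
    }
    raw <- as.character(data[[birthdate_col]])
    ids <- if (is.null(id_col)) as.character(seq_len(nrow(data)))
           else as.character(data[[id_col]])
  } else {
    bg_abort("`data` must be a data frame or character vector.",
             "birthgam_config_error")
  }

  n <- length(raw)
  status <- rep("accepted", n)
  date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")

  missing <- is.na(raw) | !nzchar(trimws(raw))
  status[missing] <- "missing"

  pat <- switch(dialect,
    iso = "^\\s*(\\d{4})-(\\d{1,2})-(\\d{1,2})\\s*$",
    us  = "^\\s*(\\d{1,2})/(\\d{1,2})/(\\d{4})\\s*$",
    uk  = "^\\s*(\\d{1,2})/(\\d{1,2})/(\\d{4})\\s*$"
  )
  todo <- !missing
  m <- regmatches(raw[todo], regexec(pat, raw[todo]))
  ok <- lengths(m) == 4L
  status[todo][!ok] <- "unparseable"

  if (any(ok)) {
    parts_chr <- vapply(m[ok], function(v) v[-1], character(3))
    parts <- matrix(as.integer(parts_chr), ncol = 3, byrow = TRUE)
    ymd <- switch(dialect,
      iso = parts,
      us  = parts[, c(3, 1, 2), drop = FALSE],
      uk  = parts[, c(3, 2, 1), drop = FALSE]
    )
    cand <- as.Date(sprintf("%04d-%02d-%02d", ymd[, 1], ymd[, 2], ymd[, 3]),
                    format = "%Y-%m-%d")
    # as.Date() yields NA for impossible component combinations (e.g. Feb 31)
    bad_comp <- ymd[, 2] < 1 | ymd[, 2] > 12 | ymd[, 3] < 1 | ymd[, 3] > 31 |
      is.na(cand)
    idx <- which(todo)[ok]
    status[idx][bad_comp] <- "impossible"
    good <- idx[!bad_comp]
    date[good] <- cand[!bad_comp]
    if (!is.null(date_min)) {
      oob <- good[date[good] < as.Date(date_min)]
      status[oob] <- "out_of_bounds"; date[oob] <- NA
    }
    if (!is.null(date_max)) {
      oob <- good[!is.na(date[good]) & date[good] > as.Date(date_max)]
      status[oob] <- "out_of_bounds"; date[oob] <- NA
    }
  }

  tibble(record_id = ids, birthdate_raw = raw, date = date,
         status = factor(status, levels = c("accepted", "missing",
                                            "unparseable", "impossible",
                                            "out_of_bounds")))
}

#' Format dates back into a declared dialect
#'
#' Canonical (zero-padded) inverse of [parse_birthdates()]: formatting a
#' parsed date reproduces the normalized input string.
#'
#' @param date A `Date` vector.
#' @param dialect `"iso"`, `"us"` or `"uk"`.
#' @return Character vector.
#' @export
format_birthdates <- function(date, dialect) {
  dialect <- match_dialect(dialect)
  format(as.Date(date),
         switch(dialect, iso = "%Y-%m-%d", us = "%m/%d/%Y", uk = "%d/%m/%Y"))
}

#' Aggregate dates to a dense daily count series
#'
#' Materializes \eqn{N(d)}: the number of records for every calendar day in
#' the covered range, with zero-count days present (the dense grid is the
#' spline covariate, so gaps are not allowed).
#'
#' @param dates A `Date` vector, or a data frame with a `date` column (e.g.
#'   the accepted rows of [parse_birthdates()]; `NA` dates are dropped with a
#'   message).
#' @param range Optional length-2 `Date` (or coercible) vector giving the
#'   series range. Must cover all dates unless `clip = TRUE`.
#' @param clip If `TRUE`, dates outside `range` are dropped (explicitly);
#'   otherwise out-of-range dates are an error.
#'
#' @return A tibble with columns `date`, `count`; `sum(count)` equals the
#'   number of (kept) input dates.
#' @examples
#' aggregate_counts(as.Date(c("1970-01-01", "1970-01-01", "1970-01-03")))
#' @export
aggregate_counts <- function(dates, range = NULL, clip = FALSE) {
  if (is.data.frame(dates)) {
    if (!"date" %in% names(dates)) {
      bg_abort("`dates` data frame must have a `date` column.",
               "birthgam_config_error")
    }
    dates <- dates$date
  }
  dates <- as.Date(dates)
  n_na <- sum(is.na(dates))
  if (n_na > 0) {
    inform(paste0("Dropping ", n_na, " missing/rejected date(s)."))
    dates <- dates[!is.na(dates)]
  }
  if (length(dates) == 0) {
    bg_abort("No valid dates to aggregate.", "birthgam_empty_error")
  }
  if (is.null(range)) {
    range <- range(dates)
  } else {
    range <- as.Date(range)
    if (length(range) != 2 || any(is.na(range)) || range[1] > range[2]) {
      bg_abort("`range` must be two ordered dates.", "birthgam_config_error")
    }
    outside <- dates < range[1] | dates > range[2]
    if (any(outside)) {
      if (!clip) {
        bg_abort(paste0(sum(outside), " date(s) fall outside `range`; pass ",
                        "`clip = TRUE` to drop them explicitly."),
                 "birthgam_config_error")
      }
      dates <- dates[!outside]
      if (length(dates) == 0) {
        bg_abort("All dates clipped away.", "birthgam_empty_error")
      }
    }
  }
  grid <- seq(range[1], range[2], by = "day")
  counts <- tabulate(as.integer(dates - range[1]) + 1L, nbins = length(grid))
  tibble(date = grid, count = as.integer(counts))
}

#' Attach the weekend/holiday indicator to a count series
#'
#' Sets `special = 1` exactly on configured weekend weekdays and (if
#' configured) listed holidays; idempotent.
#'
#' @param series A tibble with `date` and `count` columns (dense, see
#'   [aggregate_counts()]).
#' @param config A [calendar_config()].
#' @return The series with a `special` integer column, classed
#'   `birth_series`.
#' @export
mark_special_days <- function(series, config = calendar_config()) {
  stopifnot(inherits(config, "calendar_config"))
  series <- as_tibble(series)
  special <- iso_weekday(series$date) %in% config$weekend_days
  if (config$treat_holidays_as_weekend && length(config$holidays)) {
    special <- special | (series$date %in% config$holidays)
  }
  series$special <- as.integer(special)
  as_birth_series(series)
}

#' Construct / validate a daily birth count series
#'
#' The modelled object: a gap-free, strictly increasing daily grid of calendar
#' dates with non-negative integer counts and a 0/1 special-day indicator.
#'
#' @param x A data frame with columns `date` (Date), `count` and optionally
#'   `special` (defaults to 0).
#' @return A tibble of subclass `birth_series`.
#' @export
as_birth_series <- function(x) {
  x <- as_tibble(x)
  if (!all(c("date", "count") %in% names(x))) {
    bg_abort("A birth series needs `date` and `count` columns.",
             "birthgam_config_error")
  }
  x$date <- as.Date(x$date)
  if (nrow(x) == 0) bg_abort("Empty series.", "birthgam_empty_error")
  if (anyNA(x$date) || anyNA(x$count)) {
    bg_abort("Series contains missing dates or counts.",
             "birthgam_config_error")
  }
  if (is.unsorted(x$date, strictly = TRUE)) {
    x <- arrange(x, .data$date)
  }
  d <- diff(as.integer(x$date))
  if (nrow(x) > 1 && any(d != 1L)) {
    bg_abort("Series must be dense: consecutive dates must differ by one day.",
             "birthgam_config_error")
  }
  if (any(x$count < 0)) {
    bg_abort("Counts must be non-negative.", "birthgam_config_error")
  }
  x$count <- as.integer(round(x$count))
  if (!"special" %in% names(x)) x$special <- 0L
  x$special <- as.integer(x$special != 0)
  class(x) <- unique(c("birth_series", class(x)))
  x
}

#' Build a marked count series straight from parsed records
#'
#' Convenience composition of [aggregate_counts()] and [mark_special_days()].
#'
#' @inheritParams aggregate_counts
#' @param config A [calendar_config()].
#' @return A `birth_series` tibble (`date`, `count`, `special`).
#' @export
count_birthdates <- function(dates, config = calendar_config(),
                             range = NULL, clip = FALSE) {
  mark_special_days(aggregate_counts(dates, range = range, clip = clip),
                    config)
}

# ---- file readers -----------------------------------------------------------

#' Read a delimited person-record file
#'
#' @param path File path; delimited text with a header row.
#' @param delim Field delimiter, default comma.
#' @return A tibble of raw records.
#' @export
read_person_records <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Read a pre-aggregated daily count file
#'
#' Two columns `date,count`, dates in ISO 8601. The series is validated as
#' dense (see [as_birth_series()]); the `special` indicator still has to be
#' attached with [mark_special_days()].
#'
#' @param path File path.
#' @param delim Field delimiter, default comma.
#' @return A tibble with `date`, `count` (and `special` if present in the
#'   file).
#' @export
read_daily_counts <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!all(c("date", "count") %in% names(x))) {
    bg_abort("Count file must have `date` and `count` columns.",
             "birthgam_config_error")
  }
  x$date <- as.Date(as.character(x$date), format = "%Y-%m-%d")
  if (anyNA(x$date)) {
    bg_abort("Count file has unparseable ISO dates.", "birthgam_config_error")
  }
  x
}

#' Read a holiday list
#'
#' One ISO 8601 date per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return A `Date` vector.
#' @export
read_holidays <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(as.Date(character()))
  out <- as.Date(lines, format = "%Y-%m-%d")
  if (anyNA(out)) {
    bg_abort(paste0("Holiday file has unparseable ISO dates: ",
                    paste(head(lines[is.na(out)], 3), collapse = ", ")),
             "birthgam_config_error")
  }
  sort(unique(out))
}
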