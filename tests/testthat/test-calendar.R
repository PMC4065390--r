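test_that("declared dialects parse correctly and never guess", {
  expect_equal(parse_birthdates("2010-01-02", "iso")$date,
               as.Date("2010-01-02"))
  expect_equal(parse_birthdates("02/01/2010", "uk")$date,
               as.Date("2010-01-02"))
  expect_equal(parse_birthdates("01/02/2010", "us")$date,
               as.Date("2010-01-02"))
  # the same string means different days under different dialects
  expect_equal(parse_birthdates("02/01/2010", "us")$date,
               as.Date("2010-02-01"))
  expect_error(parse_birthdates("2010-01-02", "oracle9i"),
               class = "birthgam_config_error")
})

test_that("rejections are typed: impossible, unparseable, missing, bounds", {
  p <- parse_birthdates(
    c("31/02/2010", "2010-01-02", "02-Jan-10", "", NA, "1700-01-01"),
    dialect = "uk")
  expect_equal(as.character(p$status),
               c("impossible", "unparseable", "unparseable", "missing",
                 "missing", "unparseable"))
  expect_true(all(is.na(p$date)))

  iso <- parse_birthdates(c("2010-02-31", "2010-01-0299", "1700-01-01"),
                          dialect = "iso", date_min = "1850-01-01")
  expect_equal(as.character(iso$status),
               c("impossible", "unparseable", "out_of_bounds"))

  # partition: every record is accepted or rejected, never both or neither
  mixed <- parse_birthdates(c("2000-06-07", "bad", "2000-13-01"), "iso")
  expect_equal(sum(mixed$status == "accepted") +
                 sum(mixed$status != "accepted"), 3)
  expect_true(all(is.na(mixed$date) == (mixed$status != "accepted")))
})

test_that("dialect round-trip reproduces the normalized input", {
  set.seed(11)
  dates <- as.Date("1900-01-01") + sample.int(60000, 300)
  for (dia in c("iso", "us", "uk")) {
    raw <- format_birthdates(dates, dia)
    parsed <- parse_birthdates(raw, dia)
    expect_true(all(parsed$status == "accepted"))
    expect_equal(parsed$date, dates)
    expect_equal(format_birthdates(parsed$date, dia), raw)
  }
})

test_that("aggregation is dense, conserving, and matches a brute tally", {
  s <- aggregate_counts(as.Date(c("1970-01-01", "1970-01-01", "1970-01-01",
                                  "1970-01-03")))
  expect_equal(s$count, c(3L, 0L, 1L))
  expect_equal(aggregate_counts(as.Date("1999-05-05"))$count, 1L)

  set.seed(21)
  dates <- as.Date("2003-01-01") + sample.int(365, 1000, replace = TRUE) - 1
  s <- aggregate_counts(dates)
  # independent hash tally
  tal <- new.env()
  for (d in format(dates)) {
    tal[[d]] <- (tal[[d]] %||% 0L) + 1L
  }
  for (i in seq_len(nrow(s))) {
    expect_identical(s$count[i], tal[[format(s$date[i])]] %||% 0L)
  }
  expect_equal(sum(s$count), 1000L)                       # conservation
  expect_true(all(diff(as.integer(s$date)) == 1L))        # density

  expect_error(aggregate_counts(as.Date(character())),
               class = "birthgam_empty_error")
  expect_error(aggregate_counts(dates, range = c("2003-02-01", "2003-03-01")),
               class = "birthgam_config_error")
  clipped <- aggregate_counts(dates, range = c("2003-02-01", "2003-03-01"),
                              clip = TRUE)
  expect_lt(sum(clipped$count), 1000L)
})

test_that("special-day indicator matches a Zeller day-of-week oracle", {
  cfg <- calendar_config(weekend_days = c(6, 7))
  dates <- seq(as.Date("1899-12-25"), as.Date("1900-01-31"), by = "day")
  s <- mark_special_days(tibble::tibble(date = dates, count = 0L), cfg)
  expect_equal(s$special, as.integer(zeller_iso_weekday(dates) %in% c(6, 7)))
  s2010 <- mark_special_days(
    tibble::tibble(date = as.Date("2010-01-02"), count = 1L), cfg)
  expect_equal(s2010$special, 1L)   # a Saturday

  # a Wednesday holiday becomes special only when configured to
  wed <- as.Date("2001-06-13")
  expect_equal(zeller_iso_weekday(wed), 3L)
  base <- tibble::tibble(date = seq(wed - 2, wed + 2, by = "day"), count = 0L)
  with_hol <- mark_special_days(base, calendar_config(holidays = wed))
  expect_equal(with_hol$special[with_hol$date == wed], 1L)
  no_hol <- mark_special_days(base, calendar_config())
  expect_equal(no_hol$special[no_hol$date == wed], 0L)

  # idempotent
  expect_equal(mark_special_days(with_hol, calendar_config(holidays = wed)),
               with_hol)
})

test_that("series validation enforces density and non-negative counts", {
  good <- tibble::tibble(date = as.Date("2000-01-01") + 0:5, count = 1:6)
  expect_s3_class(as_birth_series(good), "birth_series")
  gap <- good[-3, ]
  expect_error(as_birth_series(gap), class = "birthgam_config_error")
  neg <- good
  neg$count[2] <- -1L
  expect_error(as_birth_series(neg), class = "birthgam_config_error")
})

test_that("file readers handle counts, holidays and person records", {
  tmp <- withr::local_tempdir()
  cf <- file.path(tmp, "counts.csv")
  writeLines(c("date,count", "2000-01-01,3", "2000-01-02,0", "2000-01-03,5"),
             cf)
  x <- read_daily_counts(cf)
  expect_equal(x$count, c(3, 0, 5))

  hf <- file.path(tmp, "holidays.txt")
  writeLines(c("# new year", "2000-01-01", "", "2000-12-25 # xmas"), hf)
  expect_equal(read_holidays(hf), as.Date(c("2000-01-01", "2000-12-25")))

  rf <- file.path(tmp, "records.csv")
  writeLines(c("id,birthdate", "a,1980-05-05", "b,oops"), rf)
  rec <- read_person_records(rf)
  p <- parse_birthdates(rec, "iso", id_col = "id")
  expect_equal(as.character(p$status), c("accepted", "unparseable"))
  expect_equal(p$record_id, c("a", "b"))
})
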