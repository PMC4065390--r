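# The labelled register generator.

test_that("flat specification yields a constant intensity", {
  sp <- intensity_spec(
    start = "2000-01-01", end = "2000-12-31",
    trend = tibble::tibble(date = as.Date(c("2000-01-01", "2000-12-31")),
                           log_level = c(log(10), log(10))),
    seasonal_amplitude = 0,
    weekend = tibble::tibble(date = as.Date(c("2000-01-01", "2000-12-31")),
                             log_ratio = c(0, 0)),
    target_total = NULL)
  tr <- build_true_intensity(sp)
  expect_equal(tr$lambda_true, rep(10, nrow(tr)), tolerance = 1e-9)
})

test_that("a -log(2) weekend ratio halves weekend intensity", {
  sp <- intensity_spec(
    start = "2000-01-01", end = "2000-03-31",
    trend = tibble::tibble(date = as.Date(c("2000-01-01", "2000-03-31")),
                           log_level = c(2, 2)),
    seasonal_amplitude = 0,
    weekend = tibble::tibble(date = as.Date(c("2000-01-01", "2000-03-31")),
                             log_ratio = c(-log(2), -log(2))),
    target_total = NULL)
  tr <- build_true_intensity(sp)
  sat <- tr$lambda_true[tr$special == 1][1]
  mon <- tr$lambda_true[tr$special == 0][1]
  expect_equal(sat / mon, 0.5, tolerance = 1e-12)
})

test_that("the default scenario encodes the depression dip and the boom", {
  tr <- build_true_intensity(intensity_spec())
  yr <- as.POSIXlt(tr$date)$year + 1900
  wk <- tr$special == 0
  dip <- mean(tr$lambda_true[wk & yr %in% 1933:1934])
  before <- mean(tr$lambda_true[wk & yr %in% 1928:1930])
  after <- mean(tr$lambda_true[wk & yr %in% 1938:1940])
  expect_lt(dip, before)
  expect_lt(dip, after)
  boom <- mean(tr$lambda_true[wk & yr %in% 1946:1961])
  expect_gt(boom, mean(tr$lambda_true[wk & yr %in% 1935:1945]))
  expect_gt(boom, mean(tr$lambda_true[wk & yr %in% 1962:1972]))
  # the register's expected size matches the scenario target
  expect_equal(sum(tr$lambda_true), 40000, tolerance = 0.05 * 40000)
})

test_that("count sampling is seeded, Poisson-mean-consistent", {
  lam <- rep(20, 10000)
  a <- sample_counts(lam, seed = 42)
  b <- sample_counts(lam, seed = 42)
  expect_identical(a, b)
  expect_lt(abs(mean(a) - 20), 3 * sqrt(20 / 10000))
})

test_that("per-date dispersion is Poisson over many seeds", {
  sp <- intensity_spec(
    start = "2000-01-01", end = "2000-07-19",
    trend = tibble::tibble(date = as.Date(c("2000-01-01", "2000-07-19")),
                           log_level = c(2, 3)),
    target_total = NULL)
  tr <- build_true_intensity(sp)
  draws <- vapply(1:50, function(s) sample_counts(tr, seed = 500 + s),
                  integer(nrow(tr)))
  disp <- apply(draws, 1, var) / tr$lambda_true
  expect_gt(mean(disp), 0.8)
  expect_lt(mean(disp), 1.2)
})

test_that("injection arithmetic: fills, identity, overlaps, empty spec", {
  clean <- tibble::tibble(
    date = seq(as.Date("1899-12-01"), by = "day", length.out = 120),
    count = rep(2L, 120))
  spec <- contamination_spec(list(
    injection("fill_date", "1899-12-30", magnitude = 120),
    injection("fill_date", "1899-12-30", magnitude = 10),
    injection("identity_duplication", "1900-01-15", magnitude = 5)))
  out <- inject_contamination(clean, spec)
  i <- which(clean$date == as.Date("1899-12-30"))
  expect_equal(out$counts[i], 2L + 120L + 10L)           # overlaps sum
  expect_match(out$labels$kind[out$labels$date == clean$date[i]],
               "fill_date")
  j <- which(clean$date == as.Date("1900-01-15"))
  expect_equal(out$counts[j], 10L)                       # 2 * 5
  # conservation: contaminated - clean equals the ledger exactly
  expect_equal(sum(out$counts) - sum(clean$count), out$total_added)
  expect_equal(sort(out$labels$date),
               sort(clean$date[out$counts != clean$count]))

  empty <- inject_contamination(clean, contamination_spec())
  expect_identical(empty$counts, clean$count)
  expect_equal(nrow(empty$labels), 0)
})

test_that("fraction targeting lands within ten percent", {
  clean <- tibble::tibble(
    date = seq(as.Date("1950-01-01"), by = "day", length.out = 2000),
    count = rpois(2000, 10))
  spec <- contamination_spec(
    list(injection("fill_date", "1950-06-01", magnitude = 500),
         injection("fill_date", "1953-01-01", magnitude = 800)),
    fraction = 0.015)
  out <- inject_contamination(clean, spec, seed = 4)
  achieved <- out$total_added / sum(out$counts)
  expect_lt(abs(achieved - 0.015) / 0.015, 0.10)
})

test_that("generation is reproducible byte-for-byte and fully labelled", {
  sp <- intensity_spec(start = "1995-01-01", end = "1999-12-31",
                       target_total = 8000)
  cs <- contamination_spec(list(
    injection("fill_date", "1995-03-01", magnitude = 60),
    injection("dispensing_block", "1999-01-01", end = "1999-06-30",
              magnitude = 50, n_dates = 5)))
  r1 <- generate_register(sp, cs, seed = 9)
  r2 <- generate_register(sp, cs, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_register(r1, d1); write_register(r2, d2)
  for (f in c("counts.csv", "labels.csv", "spec.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # labels mark exactly the altered dates
  altered <- r1$data$date[r1$data$count != r1$data$clean_count]
  expect_setequal(r1$labels$date, altered)
  expect_true(all(r1$data$count >= r1$data$clean_count))
  # a clean scenario carries no labels
  expect_equal(nrow(generate_register(sp, contamination_spec(),
                                      seed = 9)$labels), 0)
})
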