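# Labelled synthetic birth registers with the statistical structure the
# method assumes: a smooth multi-decade demographic trend (depression dip,
# post-war boom, ageing-out decline), annual seasonality, a secularly
# changing weekend log-ratio, and typed contamination spikes with exact
# ground-truth labels.

#' True-intensity specification for the synthetic register
#'
#' The generative intensity is
#' \eqn{\lambda(d) = s \cdot \exp(\mathrm{trend}(d) + \mathrm{season}(d) +
#' I(d)\, w(d))}, with the trend and the weekend log-ratio `w` interpolated
#' through control points by natural cubic splines on the log scale (twice
#' differentiable, as the additive model assumes), an annual sinusoid, and a
#' global scale `s` chosen so that the expected register size equals
#' `target_total`.
#'
#' The default control points sketch a drug-dispensing register covering
#' 1890--2012 with roughly 40,000 individuals: a dip around 1933--34, an
#' elevated plateau 1946--1961, sparse tails at both range ends, and a
#' weekend ratio drifting from slightly positive before 1920 to about -0.6
#' by 2010. These are scenario choices, not estimates from any real data.
#'
#' @param start,end Date range (inclusive).
#' @param trend Data frame of control points: `date`, `log_level` (relative,
#'   log scale; the overall level is set by `target_total`).
#' @param seasonal_amplitude Amplitude of the annual sinusoid on the log
#'   scale (default 0.05).
#' @param seasonal_peak_doy Day of year at which the seasonal term peaks.
#' @param weekend Data frame of control points: `date`, `log_ratio` for the
#'   weekend multiplicative factor.
#' @param weekend_days ISO weekdays treated as weekend.
#' @param holidays Optional `Date` vector sharing the weekend ratio.
#' @param target_total Expected total number of individuals (`sum(lambda)`);
#'   `NULL` keeps the raw control-point scale.
#' @return A list of class `intensity_spec`.
#' @export
intensity_spec <- function(start = "1890-01-01", end = "2012-12-31",
                           trend = default_trend_points(),
                           seasonal_amplitude = 0.05,
                           seasonal_peak_doy = 105,
                           weekend = default_weekend_points(),
                           weekend_days = c(6L, 7L),
                           holidays = as.Date(character()),
                           target_total = 40000) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    bg_abort("Invalid date range.", "birthgam_config_error")
  }
  stopifnot(is.data.frame(trend), all(c("date", "log_level") %in% names(trend)),
            is.data.frame(weekend),
            all(c("date", "log_ratio") %in% names(weekend)))
  structure(
    list(start = start, end = end,
         trend = mutate(as_tibble(trend), date = as.Date(.data$date)),
         seasonal_amplitude = seasonal_amplitude,
         seasonal_peak_doy = seasonal_peak_doy,
         weekend = mutate(as_tibble(weekend), date = as.Date(.data$date)),
         weekend_days = as.integer(weekend_days),
         holidays = as.Date(holidays),
         target_total = target_total),
    class = "intensity_spec"
  )
}

default_trend_points <- function() {
  tibble(
    date = as.Date(paste0(c(1890, 1910, 1925, 1931, 1933, 1936, 1940, 1946,
                            1953, 1961, 1970, 1980, 1990, 2000, 2008, 2012),
                          "-07-01")),
    log_level = c(-3.9, -1.6, -0.25, -0.35, -0.7, -0.4, 0.0, 1.3,
                  1.55, 1.4, 0.8, 0.25, -0.5, -1.7, -3.0, -3.8)
  )
}

default_weekend_points <- function() {
  tibble(
    date = as.Date(c("1890-01-01", "1920-01-01", "1945-01-01", "1960-01-01",
                     "1990-01-01", "2012-12-31")),
    log_ratio = c(0.05, 0.05, -0.05, -0.25, -0.45, -0.6)
  )
}

#' Evaluate the true intensity of a specification
#'
#' Deterministic given the spec: no randomness is involved.
#'
#' @param spec An [intensity_spec()].
#' @return A tibble `date`, `special`, `lambda_true` with
#'   `sum(lambda_true) == target_total` (when set).
#' @export
build_true_intensity <- function(spec) {
  stopifnot(inherits(spec, "intensity_spec"))
  dates <- seq(spec$start, spec$end, by = "day")
  t_num <- as.numeric(dates)

  trend_f <- splinefun(as.numeric(spec$trend$date), spec$trend$log_level,
                       method = "natural")
  trend <- trend_f(t_num)

  doy <- as.POSIXlt(dates)$yday + 1
  season <- spec$seasonal_amplitude *
    cos(2 * pi * (doy - spec$seasonal_peak_doy) / 365.25)

  special <- as.integer(
    iso_weekday(dates) %in% spec$weekend_days |
      (length(spec$holidays) > 0 & dates %in% spec$holidays)
  )
  if (nrow(spec$weekend) >= 2) {
    w_f <- splinefun(as.numeric(spec$weekend$date), spec$weekend$log_ratio,
                     method = "natural")
    w <- w_f(t_num)
  } else {
    w <- rep(spec$weekend$log_ratio[1] %||% 0, length(dates))
  }

  lam <- exp(trend + season + special * w)
  if (!is.null(spec$target_total)) {
    lam <- lam * (spec$target_total / sum(lam))
  }
  tibble(date = dates, special = special, lambda_true = lam)
}

#' Draw clean daily counts from a true intensity
#'
#' Independent Poisson draws per date, reproducible given the seed.
#'
#' @param lambda_true Positive intensities (vector, or the tibble from
#'   [build_true_intensity()]).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of counts.
#' @export
sample_counts <- function(lambda_true, seed = NULL) {
  if (is.data.frame(lambda_true)) lambda_true <- lambda_true$lambda_true
  if (!is.null(seed)) set.seed(seed)
  rpois(length(lambda_true), lambda_true)
}

#' Contamination specification
#'
#' A list of typed injections plus an optional overall contamination
#' fraction. Each injection is a list with fields `kind` (one of
#' `fill_date`, `newyear_rounding`, `decade_date`, `year_age_confusion`,
#' `dispensing_block`, `identity_duplication`), `date`, and either
#' `magnitude` (added count; for `identity_duplication` the count
#' multiplier) or `times_local` (magnitude as a multiple of the local true
#' intensity, resolved at generation time). `dispensing_block` additionally
#' takes `end` and `n_dates`: the block scatters `n_dates` spikes of mean
#' size `magnitude` uniformly over `[date, end]`.
#'
#' @param injections List of injections; see [injection()].
#' @param fraction Optional target contamination fraction: magnitudes are
#'   rescaled so that added counts are `fraction` of the contaminated total.
#' @return A list of class `contamination_spec`.
#' @export
contamination_spec <- function(injections = list(), fraction = NULL) {
  kinds <- c("fill_date", "newyear_rounding", "decade_date",
             "year_age_confusion", "dispensing_block", "identity_duplication")
  for (inj in injections) {
    if (!inj$kind %in% kinds) {
      bg_abort(paste0("Unknown contamination kind: ", inj$kind),
               "birthgam_config_error")
    }
    if (!is.null(inj$magnitude) && inj$magnitude <= 0) {
      bg_abort("Injection magnitudes must be positive.",
               "birthgam_config_error")
    }
  }
  structure(list(injections = injections, fraction = fraction),
            class = "contamination_spec")
}

#' @rdname contamination_spec
#' @param kind Contamination kind (see above).
#' @param date Target date (block start for `dispensing_block`).
#' @param magnitude Added count / multiplier.
#' @param times_local Magnitude as a multiple of the local true intensity.
#' @param end,n_dates Block extent and number of affected dates
#'   (`dispensing_block` only).
#' @export
injection <- function(kind, date, magnitude = NULL, times_local = NULL,
                      end = NULL, n_dates = NULL) {
  list(kind = kind, date = as.Date(date), magnitude = magnitude,
       times_local = times_local,
       end = if (!is.null(end)) as.Date(end) else NULL,
       n_dates = n_dates)
}

#' The packaged registry-style contamination scenario
#'
#' Emulates the documented mechanisms: software zero dates at the sparse left
#' end of the range (1899-12-30, 1900-01-01, 1901-01-01), a Unix zero date
#' (1970-01-01), year/age confusion (1911-01-01), new-year and decade
#' rounding of self-reported dates, one duplicated identity, and a block of
#' dispensing dates leaking into the birthdate column at the recent end.
#' Magnitudes mix absolute spike sizes (fills, dispensing block) and
#' multiples of the local intensity (roundings at 20x).
#'
#' @return A [contamination_spec()].
#' @export
default_contamination <- function() {
  contamination_spec(list(
    injection("fill_date", "1899-12-30", magnitude = 45),
    injection("fill_date", "1900-01-01", magnitude = 32),
    injection("fill_date", "1901-01-01", magnitude = 38),
    injection("year_age_confusion", "1911-01-01", magnitude = 25),
    injection("fill_date", "1970-01-01", magnitude = 150),
    injection("decade_date", "1950-01-01", times_local = 20),
    injection("decade_date", "1960-01-01", times_local = 20),
    injection("decade_date", "1980-01-01", times_local = 20),
    injection("newyear_rounding", "1979-01-01", times_local = 20),
    injection("fill_date", "1963-02-14", times_local = 20),
    injection("identity_duplication", "1955-03-17", magnitude = 30),
    injection("dispensing_block", "2006-01-01", end = "2007-12-31",
              magnitude = 600, n_dates = 20)
  ))
}

#' Inject typed contamination into clean counts
#'
#' Point kinds add their magnitude to the target date; `dispensing_block`
#' scatters spikes over a contiguous recent block; `identity_duplication`
#' multiplies one date's count. Overlapping injections sum and the label
#' keeps all kinds. Every touched date is labelled; the injected-magnitude
#' ledger is returned so contamination fractions can be audited.
#'
#' @param clean Tibble with `date` and `count` (clean), e.g. from
#'   [sample_counts()] bound to its dates.
#' @param spec A [contamination_spec()].
#' @param lambda_true Optional true intensity per date, required to resolve
#'   `times_local` magnitudes.
#' @param seed Optional seed for block placement and magnitude jitter;
#'   `NULL` uses the current RNG stream.
#' @return A list: `counts` (contaminated integer vector), `labels` (tibble
#'   `date`, `kind`, `added`), `total_added`.
#' @export
inject_contamination <- function(clean, spec, lambda_true = NULL,
                                 seed = NULL) {
  stopifnot(inherits(spec, "contamination_spec"))
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date(clean$date)
  counts <- as.numeric(clean$count)
  added <- numeric(length(counts))
  kind_lab <- vector("list", length(counts))

  resolve_mag <- function(inj, idx) {
    if (!is.null(inj$magnitude)) return(inj$magnitude)
    if (is.null(lambda_true)) {
      bg_abort("`times_local` magnitudes need `lambda_true`.",
               "birthgam_config_error")
    }
    inj$times_local * lambda_true[idx]
  }
  touch <- function(idx, amount, kind) {
    added[idx] <<- added[idx] + amount
    for (i in seq_along(idx)) {
      kind_lab[[idx[i]]] <<- c(kind_lab[[idx[i]]], kind)
    }
  }

  for (inj in spec$injections) {
    if (inj$kind == "dispensing_block") {
      stopifnot(!is.null(inj$end), !is.null(inj$n_dates))
      block <- which(dates >= inj$date & dates <= inj$end)
      if (!length(block)) bg_abort("Dispensing block outside range.",
                                   "birthgam_config_error")
      idx <- sort(sample(block, min(inj$n_dates, length(block))))
      mags <- round(stats::runif(length(idx), 0.6, 1.4) * inj$magnitude)
      touch(idx, mags, inj$kind)
    } else if (inj$kind == "identity_duplication") {
      idx <- match(inj$date, dates)
      if (is.na(idx)) bg_abort("Injection target outside range.",
                               "birthgam_config_error")
      mult <- inj$magnitude %||% inj$times_local
      touch(idx, counts[idx] * (mult - 1), inj$kind)
    } else {
      idx <- match(inj$date, dates)
      if (is.na(idx)) bg_abort("Injection target outside range.",
                               "birthgam_config_error")
      touch(idx, round(resolve_mag(inj, idx)), inj$kind)
    }
  }

  if (!is.null(spec$fraction)) {
    tot_added <- sum(added)
    if (tot_added > 0) {
      target <- spec$fraction / (1 - spec$fraction) * sum(counts)
      added <- round(added * target / tot_added)
    }
  }

  # label exactly the dates whose count was altered (a duplication of a
  # zero count injects nothing and leaves no label)
  touched <- which(added > 0)
  labels <- tibble(
    date = dates[touched],
    kind = vapply(kind_lab[touched],
                  function(k) paste(unique(k), collapse = "+"), character(1)),
    added = added[touched]
  )
  list(counts = as.integer(round(counts + added)), labels = labels,
       total_added = sum(added))
}

#' Generate a labelled synthetic register
#'
#' Composes [build_true_intensity()], [sample_counts()] and
#' [inject_contamination()] under a single seeded RNG stream; fully
#' reproducible from `(intensity, contamination, seed)`.
#'
#' @param intensity An [intensity_spec()].
#' @param contamination A [contamination_spec()] (use
#'   `contamination_spec()` for a clean register).
#' @param seed Integer seed, recorded in the result.
#' @return An object of class `synthetic_register`: a list with `data`
#'   (tibble `date`, `special`, `lambda_true`, `clean_count`, `count`,
#'   `contaminated`, `kind`), `series` (the contaminated `birth_series`),
#'   `labels`, `seed` and the two specs.
#' @export
generate_register <- function(intensity = intensity_spec(),
                              contamination = default_contamination(),
                              seed = 1L) {
  truth <- build_true_intensity(intensity)
  set.seed(seed)
  clean <- rpois(nrow(truth), truth$lambda_true)
  inj <- inject_contamination(
    tibble(date = truth$date, count = clean),
    contamination, lambda_true = truth$lambda_true, seed = NULL
  )
  data <- tibble(
    date = truth$date, special = truth$special,
    lambda_true = truth$lambda_true,
    clean_count = as.integer(clean), count = inj$counts,
    contaminated = truth$date %in% inj$labels$date,
    kind = NA_character_
  )
  data$kind[match(inj$labels$date, data$date)] <- inj$labels$kind
  series <- as_birth_series(
    tibble(date = data$date, count = data$count, special = data$special))
  structure(
    list(data = data, series = series, labels = inj$labels,
         total_added = inj$total_added, seed = as.integer(seed),
         intensity = intensity, contamination = contamination),
    class = "synthetic_register"
  )
}

#' @export
print.synthetic_register <- function(x, ...) {
  cat("Synthetic birth register\n")
  cat(sprintf("  %d days: %s .. %s; %d individuals (%d injected on %d dates)\n",
              nrow(x$data), format(x$data$date[1]),
              format(x$data$date[nrow(x$data)]),
              sum(x$data$count), x$total_added, nrow(x$labels)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Dump / reload a synthetic register as plain text
#'
#' Writes `counts.csv` (`date,count`), `labels.csv` (`date,kind,added`) and a
#' `spec.json` sidecar holding the seed and both specifications.
#'
#' @param register A `synthetic_register`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_register <- function(register, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(
    mutate(select(register$data, "date", "count"), date = format(.data$date)),
    file.path(dir, "counts.csv"))
  readr::write_csv(
    mutate(register$labels, date = format(.data$date)),
    file.path(dir, "labels.csv"))
  side <- list(
    seed = register$seed,
    total_added = register$total_added,
    intensity = serialize_spec(register$intensity),
    contamination = register$contamination
  )
  jsonlite::write_json(side, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(dir)
}

serialize_spec <- function(spec) {
  s <- unclass(spec)
  s$start <- format(s$start); s$end <- format(s$end)
  s$trend$date <- format(s$trend$date)
  s$weekend$date <- format(s$weekend$date)
  s$holidays <- format(s$holidays)
  s
}
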