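# Comparison detectors on the same count series: a seasonal ARIMA with a
# single global residual threshold, and sliding-window median/MAD smoothing.
# Both illustrate what the pointwise Poisson model buys: the SARIMA threshold
# is global (so sparse range ends are mishandled), and the windowed median
# degenerates where most neighbours are zero.

#' Seasonal ARIMA detector specification
#'
#' Defaults echo the high-order model selected on the application data:
#' ARIMA(0,1,5)x(0,0,2) with weekly period 7, flagging one-step residuals
#' above the one-sided normal 99.99th percentile of a single global
#' location/scale estimate.
#'
#' @param order Nonseasonal `(p, n, q)` orders.
#' @param seasonal Seasonal `(P, N, Q)` orders.
#' @param period Seasonal period in days (default 7, the weekly cycle).
#' @param percentile One-sided residual percentile (default 0.9999).
#' @param estimator `"moment"` (mean/sd of the post-warm-up residuals,
#'   mirroring the normality assumption of the residual rule) or `"robust"`
#'   (median/MAD, resistant to the contamination itself).
#' @return A list of class `sarima_spec`.
#' @export
sarima_spec <- function(order = c(0, 1, 5), seasonal = c(0, 0, 2),
                        period = 7, percentile = 0.9999,
                        estimator = c("moment", "robust")) {
  if (any(order < 0) || any(seasonal < 0)) {
    bg_abort("ARIMA orders must be >= 0.", "birthgam_config_error")
  }
  if (period < 1) bg_abort("`period` must be >= 1.", "birthgam_config_error")
  structure(
    list(order = as.integer(order), seasonal = as.integer(seasonal),
         period = as.integer(period), percentile = percentile,
         estimator = match.arg(estimator)),
    class = "sarima_spec"
  )
}

#' Detect outliers by thresholding seasonal ARIMA residuals
#'
#' Fits the SARIMA model with fixed orders by maximum likelihood, takes
#' one-step residuals, and flags dates whose residual exceeds
#' `location + z * scale` where `z` is the one-sided normal quantile of
#' `spec$percentile` and location/scale are estimated from all residuals
#' after the warm-up. This is deliberately a single global threshold with no
#' pointwise adaptation. Only upward excursions are flagged (contamination
#' inflates counts).
#'
#' @param series A `birth_series` tibble.
#' @param spec A [sarima_spec()].
#' @return An `outlier_report`-style tibble with `date`, `count`,
#'   `residual`, `score` (standardized residual), `flagged`, `rank`,
#'   `warm_up` and a `method = "sarima"` column; the fitted `arima` object is
#'   attached as attribute `fit`.
#' @export
detect_sarima <- function(series, spec = sarima_spec()) {
  series <- as_birth_series(series)
  n <- nrow(series)
  if (n < 3 * spec$period) {
    bg_abort("Series shorter than 3 seasonal periods.", "birthgam_data_error")
  }
  fit <- arima(as.numeric(series$count), order = spec$order,
               seasonal = list(order = spec$seasonal, period = spec$period),
               method = "CSS-ML")

  check_arima_roots(fit, spec)

  res <- as.numeric(residuals(fit))
  warm_up <- spec$order[2] + spec$seasonal[2] * spec$period +
    max(spec$order[1] + spec$seasonal[1] * spec$period,
        spec$order[3] + spec$seasonal[3] * spec$period)
  usable <- seq_len(n) > warm_up
  loc <- switch(spec$estimator,
                moment = mean(res[usable]),
                robust = median(res[usable]))
  scl <- switch(spec$estimator,
                moment = sd(res[usable]),
                robust = mad(res[usable]))
  if (!is.finite(scl) || scl <= 0) {
    bg_abort("Degenerate residual scale estimate.", "birthgam_numeric_error")
  }
  z <- qnorm(spec$percentile)
  score <- (res - loc) / scl
  flagged <- usable & score > z
  rep <- tibble(
    date = series$date, count = series$count, special = series$special,
    residual = res, score = score,
    flagged = flagged, rank = NA_integer_,
    warm_up = !usable,
    method = "sarima"
  )
  if (any(flagged)) {
    ord <- order(-rep$score[flagged], rep$date[flagged])
    rep$rank[which(flagged)[ord]] <- seq_len(sum(flagged))
  }
  attr(rep, "fit") <- fit
  attr(rep, "threshold") <- loc + z * scl
  attr(rep, "warm_up") <- warm_up
  rep
}

check_arima_roots <- function(fit, spec, tol = 1e-4) {
  cf <- coef(fit)
  bad <- character(0)
  root_check <- function(coefs, label) {
    if (!length(coefs) || all(coefs == 0)) return(NULL)
    r <- polyroot(c(1, coefs))
    inside <- Mod(r) < 1 - tol
    if (any(inside)) {
      paste0(label, " roots inside the unit circle: ",
             paste(sprintf("%.4f+%.4fi", Re(r[inside]), Im(r[inside])),
                   collapse = ", "))
    }
  }
  ar <- cf[grepl("^ar\\d", names(cf))]
  ma <- cf[grepl("^ma\\d", names(cf))]
  sar <- cf[grepl("^sar\\d", names(cf))]
  sma <- cf[grepl("^sma\\d", names(cf))]
  # AR polynomial is 1 - sum phi_i L^i; MA is 1 + sum theta_i L^i
  bad <- c(bad,
           root_check(-ar, "AR (non-stationary)"),
           root_check(ma, "MA (non-invertible)"),
           root_check(-sar, "seasonal AR (non-stationary)"),
           root_check(sma, "seasonal MA (non-invertible)"))
  if (length(bad)) {
    bg_abort(paste0("SARIMA fit inadmissible: ", paste(bad, collapse = "; ")),
             "birthgam_numeric_error")
  }
  invisible(NULL)
}

#' MAD sliding-window detector specification
#'
#' @param half_width Window half-width in days (default 7); `Inf` uses the
#'   whole sequence as the window.
#' @param multiplier Threshold multiplier on the MAD spread; default the
#'   one-sided normal `z` whose tail matches `1e-4` (`qnorm(1 - 1e-4)`).
#' @return A list of class `mad_spec`.
#' @export
mad_spec <- function(half_width = 7, multiplier = qnorm(1 - 1e-4)) {
  if (half_width < 1) bg_abort("`half_width` must be >= 1.",
                               "birthgam_config_error")
  structure(list(half_width = half_width, multiplier = multiplier),
            class = "mad_spec")
}

#' Detect spikes by sliding-window median / MAD smoothing
#'
#' For each position the underlying signal is estimated by the median of the
#' windowed neighbours (the centre point itself excluded; windows truncate at
#' the edges) and the spread by the median absolute deviation from that
#' median. A point is flagged when `|x - signal| > multiplier * spread`.
#' When the spread degenerates to zero -- as it does near sparse range ends
#' where most neighbours are zero -- any point different from the signal is
#' flagged, which is exactly the failure mode the Poisson model avoids: for
#' `(0, 0, 0, 900, 0, 1, 0)` both the 900 and the single 1 get flagged.
#'
#' @param counts Integer vector (or a `birth_series`, whose `count` column is
#'   used).
#' @param spec A [mad_spec()].
#' @return A tibble `index`, `count`, `signal`, `spread`, `flagged`,
#'   `method = "mad"` (plus `date` when a series was supplied).
#' @export
detect_mad <- function(counts, spec = mad_spec()) {
  dates <- NULL
  if (is.data.frame(counts)) {
    series <- as_birth_series(counts)
    dates <- series$date
    counts <- series$count
  }
  x <- as.numeric(counts)
  n <- length(x)
  if (n == 0) bg_abort("Empty input.", "birthgam_empty_error")
  hw <- spec$half_width
  signal <- spread <- numeric(n)
  for (i in seq_len(n)) {
    win <- if (is.finite(hw)) {
      setdiff(max(1, i - hw):min(n, i + hw), i)
    } else {
      setdiff(seq_len(n), i)
    }
    if (!length(win)) { signal[i] <- x[i]; spread[i] <- 0; next }
    m <- median(x[win])
    signal[i] <- m
    spread[i] <- median(abs(x[win] - m))
  }
  dev <- abs(x - signal)
  flagged <- ifelse(spread > 0, dev > spec$multiplier * spread, dev > 0)
  out <- tibble(index = seq_len(n), count = counts,
                signal = signal, spread = spread,
                score = ifelse(spread > 0, dev / spread,
                               ifelse(dev > 0, Inf, 0)),
                flagged = flagged, method = "mad")
  if (!is.null(dates)) out <- mutate(out, date = dates, .before = 1)
  out
}
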