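# User-facing fit: compose design construction, GCV selection and penalized
# IRLS; decompose the linear predictor into intercept + s1 + I * s2 and expose
# the pointwise intensity lambda_hat.

#' Fit the birthdate Poisson GAM
#'
#' Fits \eqn{\log \lambda(d) = \beta_0 + s_1(d) + I(d) s_2(d)} to a daily
#' count series by penalized IRLS, with smoothing parameters chosen by GCV
#' (unless fixed in `control$sp`). Zero/one observation weights support
#' refitting with previously flagged dates removed (see
#' [detect_birthdate_outliers()]).
#'
#' @param series A [as_birth_series()] tibble (`date`, `count`, `special`).
#' @param control A [gam_control()].
#' @param weights Optional non-negative prior weights, length `nrow(series)`.
#' @return An object of class `birthdate_gam` with elements `lambda_hat`,
#'   `s1_hat`, `s2_hat`, `intercept`, `coefficients`, `sp`, `edf`,
#'   `gcv_score`, `deviance`, `converged`, `gcv_profile`, plus the `design`
#'   and input `series`.
#' @examples
#' set.seed(1)
#' s <- tibble::tibble(
#'   date = seq(as.Date("2000-01-01"), by = "day", length.out = 400),
#'   count = rpois(400, 20)
#' )
#' fit <- fit_birthdate_gam(mark_special_days(s))
#' glance(fit)
#' @export
fit_birthdate_gam <- function(series, control = gam_control(),
                              weights = NULL) {
  series <- as_birth_series(series)
  design <- build_design(series, control)

  if (is.null(control$sp)) {
    sel <- select_smoothing(design, series$count, control, weights)
    sp <- sel$sp
    gcv_profile <- sel$profile
  } else {
    sp <- normalize_sp(design, control$sp)
    gcv_profile <- NULL
  }

  fit <- fit_pirls(design, series$count, sp, weights, control)
  if (!fit$converged) {
    warning("IRLS did not converge within `max_iter` iterations.")
  }

  beta <- fit$coefficients
  b1 <- beta[design$idx$s1]
  s1_hat <- as.numeric(design$Xs[, design$idx$s1 - 1L, drop = FALSE] %*% b1) -
    sum(design$u[design$idx$s1 - 1L] * b1)
  if (design$has_s2) {
    b2 <- beta[design$idx$s2]
    # s2 reported on all dates (its value only enters the fit on special days)
    s2_hat <- as.numeric(eval_basis(design$basis2, design$x) %*% b2)
  } else {
    s2_hat <- numeric(design$n)
  }

  structure(
    list(series = series, design = design, control = control,
         weights = weights,
         coefficients = beta, intercept = beta[1],
         s1_hat = s1_hat, s2_hat = s2_hat,
         lambda_hat = fit$mu, eta = fit$eta,
         sp = sp, edf = fit$edf, edf_total = fit$edf_total,
         gcv_score = gcv_score(fit), gcv_profile = gcv_profile,
         deviance = fit$deviance, n_eff = fit$n_eff,
         converged = fit$converged, iter = fit$iter),
    class = "birthdate_gam"
  )
}

#' @export
print.birthdate_gam <- function(x, ...) {
  cat("Birthdate Poisson GAM (", x$design$basis1$kind, " basis)\n", sep = "")
  cat(sprintf("  %d days: %s .. %s\n", x$design$n,
              format(x$series$date[1]), format(x$series$date[x$design$n])))
  cat(sprintf("  ranks: s1 = %d, s2 = %d; edf: s1 = %.2f, s2 = %.2f, total = %.2f\n",
              x$design$rank[["s1"]], x$design$rank[["s2"]],
              x$edf[["s1"]], x$edf[["s2"]], x$edf_total))
  cat(sprintf("  smoothing: s1 = %.4g%s; GCV = %.5g; deviance = %.5g\n",
              x$sp[["s1"]],
              if (x$design$has_s2) sprintf(", s2 = %.4g", x$sp[["s2"]]) else "",
              x$gcv_score, x$deviance))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' Predict pointwise intensity from a fitted birthdate GAM
#'
#' On the fitting dates this reproduces `fit$lambda_hat` exactly. For other
#' dates the smooths are evaluated at the corresponding normalized day index;
#' dates outside the fitted range are an error unless `extrapolate = TRUE`,
#' in which case the smooths are held constant at the range ends.
#'
#' @param fit A `birthdate_gam` (or a reloaded [read_gam_json()] model).
#' @param newdata A data frame with columns `date` and `special`, or a `Date`
#'   vector (then `special` is derived from `config`).
#' @param config A [calendar_config()] used to derive `special` when
#'   `newdata` has none.
#' @param extrapolate Allow dates outside the fitted range.
#' @return A tibble `date`, `special`, `lambda_hat`.
#' @export
predict_intensity <- function(fit, newdata, config = calendar_config(),
                              extrapolate = FALSE) {
  if (inherits(newdata, "Date")) {
    newdata <- tibble(date = newdata)
  }
  newdata <- as_tibble(newdata)
  newdata$date <- as.Date(newdata$date)
  if (!"special" %in% names(newdata)) {
    wd <- iso_weekday(newdata$date) %in% config$weekend_days
    hol <- config$treat_holidays_as_weekend & newdata$date %in% config$holidays
    newdata$special <- as.integer(wd | hol)
  }
  n_fit <- fit$design$n
  x <- as.numeric(newdata$date - fit$design$date0) / (n_fit - 1)
  out <- x < 0 | x > 1
  if (any(out)) {
    if (!extrapolate) {
      bg_abort("Dates outside the fitted range; pass `extrapolate = TRUE` to
               evaluate with the smooths held constant at the range ends.",
               "birthgam_config_error")
    }
    x <- pmin(pmax(x, 0), 1)
  }
  d <- fit$design
  beta <- fit$coefficients
  X1 <- eval_basis(d$basis1, x)[, d$keep1, drop = FALSE]
  i1 <- d$idx$s1
  s1 <- as.numeric(X1 %*% beta[i1]) - sum(d$u[i1 - 1L] * beta[i1])
  s2 <- if (d$has_s2) {
    as.numeric(eval_basis(d$basis2, x) %*% beta[d$idx$s2])
  } else 0
  lam <- exp(beta[1] + s1 + newdata$special * s2)
  tibble(date = newdata$date, special = newdata$special, lambda_hat = lam)
}

#' @describeIn fit_birthdate_gam Per-date tidy view: `date`, `count`,
#'   `special`, `lambda_hat`, `s1`, `s2`, and the working weight.
#' @param x A `birthdate_gam`.
#' @param ... Unused.
#' @export
tidy.birthdate_gam <- function(x, ...) {
  tibble(
    date = x$series$date,
    count = x$series$count,
    special = x$series$special,
    lambda_hat = x$lambda_hat,
    s1 = x$s1_hat,
    s2 = x$s2_hat,
    weight = (x$weights %||% rep(1, x$design$n))
  )
}

#' @describeIn fit_birthdate_gam One-row model summary.
#' @export
glance.birthdate_gam <- function(x, ...) {
  tibble(
    n = x$design$n, n_eff = x$n_eff,
    rank_s1 = x$design$rank[["s1"]], rank_s2 = x$design$rank[["s2"]],
    edf_s1 = x$edf[["s1"]], edf_s2 = x$edf[["s2"]],
    edf_total = x$edf_total,
    sp_s1 = x$sp[["s1"]],
    sp_s2 = if (x$design$has_s2) x$sp[["s2"]] else NA_real_,
    gcv = x$gcv_score, deviance = x$deviance,
    converged = x$converged
  )
}

# ---- model dump -------------------------------------------------------------

#' Save / reload a fitted model as JSON
#'
#' The dump carries the basis definition, constraint bookkeeping,
#' coefficients, smoothing parameters, edf and GCV score at full double
#' precision: reloading reproduces `lambda_hat` bit-for-bit through
#' [predict_intensity()].
#'
#' @param fit A `birthdate_gam`.
#' @param path Output (input) file path.
#' @return `write_gam_json()` returns `path` invisibly; `read_gam_json()`
#'   returns a lightweight object usable with [predict_intensity()].
#' @export
write_gam_json <- function(fit, path) {
  d <- fit$design
  b1 <- d$basis1
  dump <- list(
    package = "birthgam", version = as.character(packageVersion("birthgam")),
    basis_kind = b1$kind,
    rank = as.list(d$rank),
    n = d$n, date0 = format(d$date0),
    keep1 = d$keep1, u = d$u,
    basis1 = serialize_basis(b1),
    basis2 = if (d$has_s2) serialize_basis(d$basis2) else NULL,
    has_s2 = d$has_s2,
    idx = d$idx,
    coefficients = fit$coefficients,
    sp = as.list(fit$sp),
    edf = as.list(fit$edf), edf_total = fit$edf_total,
    gcv = fit$gcv_score, deviance = fit$deviance,
    converged = fit$converged
  )
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

serialize_basis <- function(b) {
  out <- list(kind = b$kind, q = b$q, const_col = b$const_col)
  if (b$kind == "cubic_ps") out$knots <- b$knots
  else { out$centers <- b$centers; out$M <- b$M }
  out
}

deserialize_basis <- function(x) {
  b <- list(kind = x$kind, q = x$q,
            const_col = if (is.null(x$const_col)) NA_integer_ else x$const_col)
  if (x$kind == "cubic_ps") {
    b$knots <- as.numeric(x$knots)
  } else {
    b$centers <- as.numeric(x$centers)
    b$M <- if (is.matrix(x$M)) x$M else do.call(rbind, lapply(x$M, as.numeric))
  }
  structure(b, class = "birthgam_basis")
}

#' @rdname write_gam_json
#' @export
read_gam_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- list(
    n = x$n, date0 = as.Date(x$date0),
    basis1 = deserialize_basis(as.list(x$basis1)),
    basis2 = if (isTRUE(x$has_s2)) deserialize_basis(as.list(x$basis2)) else NULL,
    keep1 = as.integer(x$keep1), u = as.numeric(x$u),
    has_s2 = isTRUE(x$has_s2),
    idx = lapply(x$idx, as.integer),
    rank = unlist(x$rank)
  )
  structure(
    list(design = design, coefficients = as.numeric(x$coefficients),
         intercept = as.numeric(x$coefficients)[1],
         sp = unlist(x$sp), edf = unlist(x$edf), edf_total = x$edf_total,
         gcv_score = x$gcv, deviance = x$deviance, converged = x$converged),
    class = c("birthdate_gam_dump", "birthdate_gam")
  )
}
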