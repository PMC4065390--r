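# Shared scenario builders, plus memoized heavy simulation panels that
# several acceptance checks draw on (computed once per test run).

# A small dense series with known smooth log-intensity and constant weekend
# log-ratio; lambda ranges over roughly [5, 50] on weekdays.
recovery_series <- function(n_days = 2200, weekend_ratio = -0.5,
                            start = as.Date("1990-01-01")) {
  dates <- seq(start, by = "day", length.out = n_days)
  x <- (seq_len(n_days) - 1) / (n_days - 1)
  special <- as.integer(iso_weekday(dates) %in% c(6L, 7L))
  eta <- log(15) + 1.1 * sin(2 * pi * x) + 0.55 * x
  lam <- exp(eta + special * weekend_ratio)
  list(dates = dates, x = x, special = special,
       eta_weekday = eta, lambda_true = lam)
}

sample_recovery_series <- function(sc, seed) {
  set.seed(seed)
  as_birth_series(tibble::tibble(
    date = sc$dates, count = rpois(length(sc$lambda_true), sc$lambda_true),
    special = sc$special))
}

.bg_cache <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (is.null(.bg_cache[[key]])) .bg_cache[[key]] <- fn()
  .bg_cache[[key]]
}

# 20 detections on clean full-scale registers: flag counts and the
# mean-identity residual of each converged fit.
clean_register_panel <- function(n_seeds = 20) {
  memoize("clean_panel", function() {
    lapply(seq_len(n_seeds), function(seed) {
      reg <- generate_register(intensity_spec(), contamination_spec(),
                               seed = 1000 + seed)
      rep <- detect_birthdate_outliers(reg$series)
      fit <- attr(rep, "fit")
      w <- fit$weights %||% rep(1, nrow(reg$data))
      hist <- attr(rep, "history")
      stable <- length(hist) == 1 ||
        identical(hist[[1]], hist[[length(hist)]])
      list(n_days = nrow(reg$data), n_flagged = sum(rep$flagged),
           mean_identity = abs(sum(w * fit$lambda_hat) -
                                 sum(w * reg$series$count)) /
             sum(w * reg$series$count),
           refit_stable = stable,
           converged = fit$converged)
    })
  })
}

# 20 runs on the standard contaminated scenario: GAM (with one refit) and
# SARIMA on the same series, plus the ground truth needed for power/AUC
# checks.
contaminated_panel <- function(n_seeds = 20) {
  memoize("contaminated_panel", function() {
    lapply(seq_len(n_seeds), function(seed) {
      reg <- generate_register(seed = 2000 + seed)
      gam_rep <- detect_birthdate_outliers(reg$series)
      sar_rep <- detect_sarima(reg$series)
      truth <- reg$data$contaminated
      lam <- reg$data$lambda_true
      labels <- reg$labels
      labels$lambda_true <- lam[match(labels$date, reg$data$date)]
      fit <- attr(gam_rep, "fit")
      w <- fit$weights %||% rep(1, nrow(reg$data))
      list(
        labels = labels,
        gam_flag = gam_rep$flagged, gam_score = gam_rep$score,
        sar_flag = sar_rep$flagged, sar_score = sar_rep$score,
        truth = truth, dates = reg$data$date,
        auc_gam = roc_auc(gam_rep$score, truth)$auc,
        auc_sarima = roc_auc(sar_rep$score, truth)$auc,
        mean_identity = abs(sum(w * fit$lambda_hat) -
                              sum(w * reg$series$count)) /
          sum(w * reg$series$count)
      )
    })
  })
}
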