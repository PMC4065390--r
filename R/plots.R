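# ggplot2 views of the main result types. Plotting is a convenience layer;
# nothing downstream depends on it.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_step labs
#'   scale_colour_manual theme_minimal geom_vline
NULL

#' Plot a fitted birthdate GAM
#'
#' Counts, the fitted intensity \eqn{\hat\lambda(d)}, and the pointwise
#' upper Poisson percentile envelope.
#'
#' @param object A `birthdate_gam`.
#' @param percentile Envelope percentile (default 0.9999).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.birthdate_gam <- function(object, percentile = 0.9999, ...) {
  d <- tidy(object)
  d$upper <- poisson_quantile(percentile, d$lambda_hat)
  ggplot(d, aes(x = .data$date)) +
    geom_point(aes(y = .data$count), size = 0.3, alpha = 0.3) +
    geom_line(aes(y = .data$lambda_hat, colour = "fitted intensity")) +
    geom_line(aes(y = .data$upper, colour = "pointwise percentile"),
              linetype = "dashed") +
    scale_colour_manual(values = c("fitted intensity" = "#2166ac",
                                   "pointwise percentile" = "#1b7837")) +
    labs(x = NULL, y = "births per day", colour = NULL,
         title = "Birthdate counts and fitted Poisson intensity") +
    theme_minimal()
}

#' Plot an outlier report
#'
#' Counts with flagged dates highlighted.
#'
#' @param object An `outlier_report` (from [detect_birthdate_outliers()] or
#'   [flag_outliers()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.outlier_report <- function(object, ...) {
  ggplot(object, aes(x = .data$date, y = .data$count)) +
    geom_point(size = 0.3, alpha = 0.3) +
    geom_point(data = dplyr::filter(object, .data$flagged),
               colour = "#b2182b", shape = 4, size = 2) +
    geom_line(aes(y = .data$expected), colour = "#2166ac") +
    labs(x = NULL, y = "births per day",
         title = "Flagged birthdates",
         subtitle = sprintf("%d of %d dates flagged",
                            sum(object$flagged), nrow(object))) +
    theme_minimal()
}

#' Plot the weekend smooth of a fitted model
#'
#' The fitted weekend log-ratio \eqn{\hat s_2(d)} over time; values below
#' zero mean fewer weekend than weekday births.
#'
#' @param fit A `birthdate_gam`.
#' @return A ggplot.
#' @export
plot_weekend_effect <- function(fit) {
  d <- tidy(fit)
  ggplot(d, aes(x = .data$date, y = .data$s2)) +
    geom_line(colour = "#2166ac") +
    geom_line(aes(y = 0), linetype = "dotted") +
    labs(x = NULL, y = expression(hat(s)[2](d)),
         title = "Weekend birth log-ratio over time") +
    theme_minimal()
}

#' Plot an ROC curve
#'
#' @param roc The list returned by [roc_auc()].
#' @return A ggplot.
#' @export
plot_roc <- function(roc) {
  ggplot(roc$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_line(data = tibble(fpr = c(0, 1), tpr = c(0, 1)),
              linetype = "dotted", colour = "grey50") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", roc$auc)) +
    theme_minimal()
}
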