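# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_vline labs theme_minimal facet_wrap
NULL

#' Plot an elbow scan
#'
#' Within-cluster sum of squares against k, with the chosen elbow marked.
#'
#' @param object An `elbow_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.elbow_scan <- function(object, ...) {
  ggplot(object$wss_curve, aes(x = .data$k, y = .data$wss)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    labs(x = "number of clusters k", y = "within-cluster sum of squares",
         title = sprintf("Elbow scan (chosen k = %d%s)", object$chosen_k,
                         if (object$no_clear_elbow) ", no clear elbow" else "")) +
    theme_minimal()
}

#' Plot a robust PCA biplot
#'
#' Subject scores on the first two components, optionally coloured by
#' cluster label.
#'
#' @param object A `robust_pca`.
#' @param labels Optional per-subject grouping (e.g. K-means labels).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.robust_pca <- function(object, labels = NULL, ...) {
  d <- tibble::tibble(PC1 = object$scores[, 1], PC2 = object$scores[, 2])
  ef <- 100 * object$explained_fraction[1:2]
  p <- if (is.null(labels)) {
    ggplot(d, aes(x = .data$PC1, y = .data$PC2)) + geom_point(alpha = 0.5)
  } else {
    d$cluster <- factor(labels)
    ggplot(d, aes(x = .data$PC1, y = .data$PC2, colour = .data$cluster)) +
      geom_point(alpha = 0.5)
  }
  p + labs(x = sprintf("PC1 (%.1f%%)", ef[1]),
           y = sprintf("PC2 (%.1f%%)", ef[2])) +
    theme_minimal()
}

#' Plot back-transformed composition trend curves
#'
#' Mean percent-abundance curves with 95% bands against age, faceted by
#' peak and coloured by sex.
#'
#' @param curves Output of [predict_composition_curve()] (both sexes may be
#'   bound together).
#' @param peaks Which peaks to show (default the first 12).
#' @return A ggplot.
#' @export
plot_trend_curves <- function(curves, peaks = paste0("GP", 1:12)) {
  d <- dplyr::filter(curves, .data$peak %in% peaks)
  d$peak <- factor(d$peak, levels = gp_names())
  ggplot(d, aes(x = .data$age, y = .data$mean, colour = .data$sex,
                fill = .data$sex)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95),
                alpha = 0.2, colour = NA) +
    geom_line() +
    facet_wrap(~peak, scales = "free_y") +
    labs(x = "age (years)", y = "relative abundance (%)") +
    theme_minimal()
}

#' Plot a fitted smooth
#'
#' @param object A `psmooth_fit` or `beta_smooth`.
#' @param age_grid Evaluation grid (default 100 points over the fitted
#'   range).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.psmooth_fit <- function(object, age_grid = NULL, ...) {
  g <- age_grid %||% seq(object$x_range[1], object$x_range[2], length.out = 100)
  d <- predict(object, g)
  ggplot(d, aes(x = .data$x, y = .data$fit)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95), alpha = 0.2) +
    geom_line() + labs(x = "x", y = "fitted smooth") + theme_minimal()
}

#' @rdname autoplot.psmooth_fit
#' @exportS3Method ggplot2::autoplot
autoplot.beta_smooth <- function(object, age_grid = NULL, ...) {
  g <- age_grid %||% seq(object$x_range[1], object$x_range[2], length.out = 100)
  d <- predict(object, g)
  ggplot(d, aes(x = .data$x, y = .data$mu)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95), alpha = 0.2) +
    geom_line() + labs(x = "x", y = "fitted mean (0-1 scale)") +
    theme_minimal()
}
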