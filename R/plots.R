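#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_abline geom_pointrange
#'   labs theme_minimal autoplot
#' @importFrom rlang .data
NULL

#' Observed versus inferred gradient values for a calibration model
#'
#' @param object A `wa_model` or `wapls_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.wa_model <- function(object, ...) {
  df <- tibble::tibble(observed = object$x, inferred = object$fitted)
  ggplot(df, aes(.data$observed, .data$inferred)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    labs(x = "Observed", y = "Inferred (apparent)") +
    theme_minimal()
}

#' @rdname autoplot.wa_model
#' @exportS3Method ggplot2::autoplot
autoplot.wapls_model <- autoplot.wa_model

#' Deletion curves of an RNE analysis
#'
#' Cross-validated r2 against deletion radius for the random, neighbour and
#' environment schemes; a neighbour curve falling well below the random curve
#' signals spatially inflated skill.
#'
#' @param object An `rne_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rne_result <- function(object, ...) {
  ggplot(object, aes(.data$radius, .data$r2,
                     colour = .data$scheme, shape = .data$scheme)) +
    geom_line() + geom_point(size = 2) +
    labs(x = "Deletion radius (km)", y = expression(r^2~(jackknife)),
         colour = "Scheme", shape = "Scheme") +
    theme_minimal()
}

#' Taxon optima and tolerances along the gradient
#'
#' @param responses Tibble from [estimate_responses()].
#' @param min_n2 Hide taxa with fewer effective occurrences than this.
#' @return A ggplot (point = optimum, bar = +/- one tolerance).
#' @export
plot_optima <- function(responses, min_n2 = 0) {
  df <- dplyr::filter(responses, .data$n2 >= min_n2) |>
    dplyr::arrange(.data$optimum) |>
    dplyr::mutate(taxon = factor(.data$taxon, levels = .data$taxon))
  ggplot(df, aes(x = .data$optimum, y = .data$taxon)) +
    geom_pointrange(aes(xmin = .data$optimum - .data$tolerance,
                        xmax = .data$optimum + .data$tolerance),
                    linewidth = 0.3, size = 0.2) +
    labs(x = "Optimum ± tolerance", y = NULL) +
    theme_minimal()
}

#' Model-selection grid as a dot plot
#'
#' @param grid A `model_selection` tibble.
#' @return A ggplot of RMSEP by model and transform.
#' @export
plot_model_grid <- function(grid) {
  ggplot(grid, aes(.data$rmsep, .data$model, colour = .data$transform)) +
    geom_point(size = 2) +
    labs(x = "RMSEP", y = NULL, colour = "Transform") +
    theme_minimal()
}
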