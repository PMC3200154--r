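#' Contact-map plot
#'
#' Draws a contact map as points on the (i, j) grid. With a `truth` map the
#' plot uses the conventional split view: true contacts in the lower
#' triangle, predictions in the upper triangle, so predicted interaction
#' regions can be compared with the native ones at a glance.
#'
#' @param object A `contact_map`, `contact_consensus` or
#'   `contact_prediction`.
#' @param truth Optional `contact_map` of true contacts for the lower
#'   triangle.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, truth = NULL, ...) {
  plot_contact_map(object, truth = truth)
}

#' @rdname autoplot.contact_map
#' @method autoplot contact_consensus
#' @export
autoplot.contact_consensus <- function(object, truth = NULL, ...) {
  plot_contact_map(object, truth = truth)
}

#' @rdname autoplot.contact_map
#' @method autoplot contact_prediction
#' @export
autoplot.contact_prediction <- function(object, truth = NULL, ...) {
  plot_contact_map(object, truth = truth)
}

#' @rdname autoplot.contact_map
#' @param contacts As `object`.
#' @export
plot_contact_map <- function(contacts, truth = NULL, ...) {
  upper <- tibble::tibble(
    x = pmin(contacts$i, contacts$j),
    y = pmax(contacts$i, contacts$j),
    set = "predicted"
  )
  df <- upper
  if (!is.null(truth)) {
    lower <- tibble::tibble(
      x = pmax(truth$i, truth$j),
      y = pmin(truth$i, truth$j),
      set = "true"
    )
    df <- dplyr::bind_rows(upper, lower)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$set)) +
    ggplot2::geom_point(shape = 15, size = 1.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(predicted = "#2166ac", true = "#b2182b")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "residue index", y = "residue index", colour = NULL,
      title = if (is.null(truth)) {
        "Contact map"
      } else {
        "Contact map (upper: predicted, lower: true)"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Coverage histogram plot
#'
#' Bar chart of the fraction of ensemble models covering each number of
#' contact clusters.
#'
#' @param object A `coverage_report` (see [cluster_coverage()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  ggplot2::ggplot(
    object$histogram,
    ggplot2::aes(x = .data$covered, y = .data$fraction)
  ) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = "clusters covered by a model",
      y = "fraction of models",
      title = sprintf("Cluster coverage (%d clusters)", object$n_clusters)
    ) +
    ggplot2::theme_minimal()
}
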