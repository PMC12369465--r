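# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an association analysis
#'
#' Lollipop display of the normalized mutual information per feature,
#' one panel per association kind, significant features emphasised.
#'
#' @param object A [ctg_association()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctg_assoc <- function(object, ...) {
  d <- tidy(object)
  d$feature <- stats::reorder(d$feature, d$statistic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$statistic,
                                  colour = .data$reject)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~kind, nrow = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey55"),
                                 name = "significant") +
    ggplot2::labs(x = NULL, y = "normalized mutual information") +
    ggplot2::theme_minimal()
}

#' Plot a time-resolved KS result
#'
#' Per-epoch KS discriminability versus time to delivery, with the pooled
#' time-invariant value as a horizontal reference and significant epochs
#' marked.
#'
#' @param object A [time_resolved_ks()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctg_ks <- function(object, ...) {
  tv <- tibble::as_tibble(object[object$scope != "TI" & object$available, ])
  ti <- object[object$scope == "TI", ]
  ggplot2::ggplot(tv, ggplot2::aes(x = .data$ttd_epoch, y = .data$d_ks)) +
    ggplot2::geom_hline(yintercept = ti$d_ks, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_point(data = tv[tv$significant, ], colour = "black",
                        size = 1.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "epochs to delivery",
                  y = expression(d[KS]),
                  title = attr(object, "feature"),
                  subtitle = "dashed: pooled time-invariant value; dots: significant epochs") +
    ggplot2::theme_minimal()
}

#' Plot epoch availability by outcome class
#'
#' The proportion of infants in each class contributing an epoch at each
#' time to delivery.
#'
#' @param tbl A feature table (or a [summarize_availability()] result).
#' @return A ggplot object.
#' @export
plot_availability <- function(tbl) {
  av <- if (all(c("prop", "ttd_epoch", "class") %in% names(tbl))) tbl
        else summarize_availability(tbl)
  ggplot2::ggplot(av, ggplot2::aes(x = .data$ttd_epoch, y = .data$prop,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "epochs to delivery", y = "proportion with data",
                  colour = "outcome") +
    ggplot2::theme_minimal()
}
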