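# ggplot2 autoplot methods for the main result objects.

#' Plot a Procrustes superimposition
#'
#' Aligned landmark coordinates (points) overlaid with the consensus shape
#' (larger labelled points), the standard diagnostic for a GPA fit.
#'
#' @param object A [gpa()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gpa
#' @export
autoplot.gpa <- function(object, ...) {
  al <- array_to_landmarks(object$aligned)
  cons <- tibble::tibble(
    landmark = seq_len(nrow(object$consensus)),
    x = object$consensus[, 1], y = object$consensus[, 2]
  )
  ggplot2::ggplot(al, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "black", size = 2) +
    ggplot2::geom_text(
      data = cons, ggplot2::aes(label = .data$landmark),
      nudge_y = 0.015, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Generalized Procrustes superimposition",
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot relative warp scores
#'
#' Ordination of specimens on two relative warps, with variance fractions
#' in the axis labels.
#'
#' @param object A [warp_scores()] result.
#' @param axes Which two relative warps to plot.
#' @param group Optional vector (recycled to specimens, in score order)
#'   used to colour points, e.g. strain.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot warp_scores
#' @export
autoplot.warp_scores <- function(object, axes = c(1, 2), group = NULL, ...) {
  df <- object$relative
  df$.group <- if (is.null(group)) "all" else as.character(group)
  ax <- paste0("rw", axes)
  lab <- sprintf(
    "RW%d (%.1f%%)", axes,
    100 * object$variance_fraction[axes]
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]],
    colour = .data$.group
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(group)) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot animal-model variance components
#'
#' Proportions of phenotypic variance per component.
#'
#' @param object An [animal_model()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot animal_model
#' @export
autoplot.animal_model <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$term, y = .data$proportion
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      data = td[!is.na(td$se), ],
      ggplot2::aes(
        ymin = pmax(0, .data$proportion - .data$se),
        ymax = pmin(1, .data$proportion + .data$se)
      ),
      width = 0.2
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("Variance components: %s", object$trait),
      x = NULL, y = "proportion of phenotypic variance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a discriminant reclassification matrix
#'
#' Heatmap of leave-one-out reclassification percentages.
#'
#' @param object A [dfa_loo()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dfa_loo
#' @export
autoplot.dfa_loo <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$classified, y = .data$original, fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Leave-one-out reclassification (%.1f%% overall)", object$accuracy),
      x = "classified as", y = "original group"
    ) +
    ggplot2::theme_minimal()
}
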