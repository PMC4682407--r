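# ggplot2 visualisations of scorecards, tracks and class comparisons.

#' Heat map of a scorecard's dipeptide propensity scores
#'
#' Rows are the first residue of the dipeptide, columns the second, in
#' canonical alphabet order; fill is the propensity score on \[0, 1000\]
#' with low scores blue and high scores red, the conventional colouring for
#' propensity surfaces.
#'
#' @param object A `scorecard`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scorecard <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$second,
    y = factor(.data$first, levels = rev(AA_ALPHABET)),
    fill = .data$score
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      midpoint = 500, limits = c(0, 1000), name = "score"
    ) +
    ggplot2::labs(x = "second residue", y = "first residue",
                  title = "Dipeptide propensity scores") +
    ggplot2::theme_minimal()
}

#' Plot a per-residue propensity track
#'
#' One line per sequence, faceted; the dashed reference line marks the
#' neutral mid-scale score of 500.
#'
#' @param object A `residue_track` tibble from [residue_track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.residue_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 500, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::facet_wrap(~sequence_id, scales = "free_x") +
    ggplot2::labs(x = "residue position", y = "propensity score") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window propensity profile
#'
#' The smoothed analogue of a hydropathy plot: window means against window
#' centre positions, one panel per sequence.
#'
#' @param object An `scm_profile` tibble from [sliding_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scm_profile <- function(object, ...) {
  w <- attr(object, "window")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 500, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::facet_wrap(~sequence_id, scales = "free_x") +
    ggplot2::labs(
      x = "window centre position", y = "mean propensity score",
      title = if (!is.null(w)) sprintf("Sliding-window profile (window = %d)", w) else NULL
    ) +
    ggplot2::theme_minimal()
}
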