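# ggplot2 views of the result objects

#' @describeIn scenario_choice Bar chart of classification votes.
#' @param object An `msat_choice`.
#' @exportS3Method ggplot2::autoplot
autoplot.msat_choice <- function(object, ...) {
  if (is.null(object$votes))
    abort_msat("no votes to plot: scenario_choice() was run without an observed dataset")
  ggplot2::ggplot(object$votes,
                  ggplot2::aes(x = .data$scenario, y = .data$votes)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "scenario", y = sprintf("votes (of %d trees)", object$n_trees),
      title = sprintf("Scenario choice: %s selected%s", object$selected,
                      if (!is.null(object$posterior_prob))
                        sprintf(" (PP = %.2f)", object$posterior_prob) else "")
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_parameters Point estimates with 90% intervals.
#' @param object An `msat_estimates`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.msat_estimates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q05, ymax = .data$q95)) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(y = "posterior median and 90% interval", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Project the reference table and an observed dataset on the LDA plane
#'
#' Scatter of the first two linear-discriminant scores of the simulated
#' reference table, coloured by scenario, with the observed dataset
#' overlaid -- the usual visual check that the observed data fall within
#' the cloud spanned by the candidate scenarios and priors.
#'
#' @param table An `msat_reftable` with LDA axes (see [append_lda_axes()]).
#' @param observed Optional one-row tibble from [summarize_dataset()].
#' @param max_points Subsample size for plotting large tables.
#' @return A ggplot object.
#' @export
plot_lda_projection <- function(table, observed = NULL, max_points = 5000) {
  if (!"LD1" %in% names(table))
    abort_msat("table has no LDA axes; run append_lda_axes() first")
  df <- table
  if (nrow(df) > max_points) df <- df[seq(1, nrow(df), length.out = max_points), ]
  y2 <- if ("LD2" %in% names(df)) "LD2" else "LD1"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data[[y2]],
                                        colour = .data$scenario)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::labs(colour = "scenario") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    ob <- project_lda(table, observed)
    p <- p + ggplot2::geom_point(
      data = ob, ggplot2::aes(x = .data$LD1, y = .data[[y2]]),
      inherit.aes = FALSE, shape = 8, size = 4, colour = "black"
    )
  }
  p
}

#' @describeIn fst_ena Tile map of pairwise corrected F_ST.
#' @param object An `msat_fst_ena`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.msat_fst_ena <- function(object, ...) {
  ggplot2::ggplot(object$pairwise,
                  ggplot2::aes(x = .data$pop_a, y = .data$pop_b,
                               fill = .data$Fst_ena)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$Fst_ena)),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "F_ST*") +
    ggplot2::theme_minimal()
}
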