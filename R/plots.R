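# Sweep figures: per-replicate points with a line through across-replicate
# means, optionally split by group (solid majority / dashed minority).

#' Plot a sweep outcome against a varied parameter
#'
#' Draws one circle per replicate and a line connecting the across-replicate
#' means, the standard presentation for this family of models. With
#' `by_group = TRUE` the two groups are drawn separately, the majority as a
#' solid line and the minority dashed (at equal group sizes both are solid).
#'
#' @param result A `sweep_result` from [run_sweep()].
#' @param x Name of a varied parameter column (e.g. `"sigma"`).
#' @param y Name of an outcome column (e.g. `"mean_reliance"`).
#' @param colour Optional name of a second varied parameter mapped to colour.
#' @param facet Optional name of a column to facet by.
#' @param by_group Split curves by group instead of averaging over groups.
#' @param file Optional output path; if supplied the figure is saved there
#'   with [ggplot2::ggsave()] (format from the file extension).
#' @param width,height Figure size in inches when saving.
#' @return The ggplot object, invisibly if `file` is given.
#' @examples
#' spec <- sweep_spec(model_params(N = 60, generations = 10),
#'                    grid = list(sigma = c(0.1, 0.5)), n_reps = 2)
#' plot_sweep(run_sweep(spec, quiet = TRUE), x = "sigma", y = "mean_reliance")
#' @export
plot_sweep <- function(result, x, y, colour = NULL, facet = NULL,
                       by_group = FALSE, file = NULL, width = 6, height = 4) {
  stopifnot(is.data.frame(result))
  for (col in c(x, y, colour, facet))
    if (!col %in% names(result))
      stop(sprintf("column `%s` not found in the sweep result", col),
           call. = FALSE)

  df <- as.data.frame(result)
  group_cols <- c(x, colour, facet)
  if (by_group) {
    df$majority <- ifelse(
      df$group_size >= stats::ave(df$group_size, df$combo, df$replicate,
                                  FUN = max),
      "majority", "minority")
    df$group_label <- factor(paste("group", df$group))
    group_cols <- c(group_cols, "group_label", "majority")
  } else {
    # average the two group rows of each run into one population-level point
    agg <- stats::aggregate(df[[y]],
                            by = df[c(group_cols, "combo", "replicate")],
                            FUN = mean)
    names(agg)[ncol(agg)] <- y
    df <- agg
  }

  aes_pt <- ggplot2::aes(x = .data[[x]], y = .data[[y]])
  pl <- ggplot2::ggplot(df, aes_pt)
  if (by_group) {
    pl <- pl + ggplot2::geom_point(
      ggplot2::aes(shape = .data$majority), alpha = 0.4) +
      ggplot2::stat_summary(
        ggplot2::aes(linetype = .data$majority, group = interaction(
          .data$majority, .data$group_label,
          if (!is.null(colour)) .data[[colour]] else 1)),
        fun = mean, geom = "line") +
      ggplot2::scale_linetype_manual(
        values = c(majority = "solid", minority = "dashed"))
  } else {
    pl <- pl + ggplot2::geom_point(alpha = 0.4, shape = 1) +
      ggplot2::stat_summary(
        ggplot2::aes(group = if (!is.null(colour)) .data[[colour]] else 1),
        fun = mean, geom = "line")
  }
  if (!is.null(colour))
    pl <- pl + ggplot2::aes(colour = factor(.data[[colour]])) +
      ggplot2::labs(colour = colour)
  if (!is.null(facet))
    pl <- pl + ggplot2::facet_wrap(stats::as.formula(paste("~", facet)),
                                   labeller = ggplot2::label_both)
  pl <- pl + ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, pl, width = width, height = height, dpi = 150)
    return(invisible(pl))
  }
  pl
}
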