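# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   facet_wrap labs theme_minimal scale_colour_brewer
NULL

#' Plot a module catalog
#'
#' Entropy against module size, coloured by the number of networks the
#' module spans; significant modules (when scored) are filled.
#'
#' @param object An `mdm_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdm_catalog <- function(object, ...) {
  df <- as_tibble(object) %>% mutate(level = factor(.data$level))
  p <- ggplot(df, aes(x = .data$n_genes, y = .data$H, colour = .data$level))
  if ("significant" %in% names(df)) {
    p <- p + geom_point(aes(shape = .data$significant), size = 2)
  } else {
    p <- p + geom_point(size = 2)
  }
  p + labs(x = "module size", y = "graph entropy H(C)", colour = "level") +
    theme_minimal()
}

#' Plot dynamics scores
#'
#' @param object An `mcds_table` (ideally after [mcds_significance()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcds_table <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = stats::reorder(.data$module_id, .data$mcds), y = .data$mcds))
  if ("dynamic" %in% names(df)) {
    p <- p + geom_col(aes(fill = .data$dynamic))
  } else {
    p <- p + geom_col()
  }
  p + labs(x = NULL, y = "connectivity dynamics score") +
    ggplot2::coord_flip() + theme_minimal()
}

#' Plot module activity profiles
#'
#' @param activity Tibble (condition, time, activity), optionally with a
#'   `module_id` column for facetting.
#' @return A ggplot.
#' @export
plot_module_activity <- function(activity) {
  p <- ggplot(activity, aes(x = .data$time, y = .data$activity,
                            colour = .data$condition, group = .data$condition)) +
    geom_line() + geom_point() +
    labs(x = "time point", y = "mean z-scored expression", colour = "condition") +
    theme_minimal()
  if ("module_id" %in% names(activity)) p <- p + facet_wrap(~module_id)
  p
}
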