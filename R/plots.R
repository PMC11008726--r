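#' Plot microstate templates
#'
#' Channel-by-template heatmap of the topographies. With no electrode
#' geometry available the channel index is used as the spatial axis; the
#' plot is meant for quick inspection of template structure and polarity.
#'
#' @param object A [microstate_templates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microstate_templates <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(t(object$templates)))
  names(df) <- object$labels
  df$channel <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -"channel", names_to = "template",
                              values_to = "potential")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$template, y = .data$channel,
                                     fill = .data$potential)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = "Microstate", y = "Channel",
                  fill = "Potential\n(a.u.)",
                  title = sprintf("%s-level microstate templates", object$level)) +
    ggplot2::theme_minimal()
}

#' Plot a regressor set at TR rate
#'
#' Line plot of selected TR-rate regressors after HRF convolution and
#' standardization.
#'
#' @param object A [regressor_set()].
#' @param names Regressor names to show (default the first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regressor_set <- function(object, names = NULL, ...) {
  tab <- object$tr_rate
  if (is.null(names)) names <- colnames(tab)[seq_len(min(4, ncol(tab)))]
  tab$tr <- seq_len(nrow(tab))
  long <- tidyr::pivot_longer(tab[, c("tr", names)], -"tr",
                              names_to = "regressor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tr, y = .data$value,
                                     colour = .data$regressor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "TR", y = "Standardized amplitude",
                  colour = "Regressor") +
    ggplot2::theme_minimal()
}

#' Plot a group t map with cluster annotations
#'
#' Unit-wise group t statistics with the voxel-level threshold and
#' significant clusters shaded.
#'
#' @param object A `cluster_map` from [permutation_cluster_correction()].
#' @param tstat Optional per-unit t vector (taken from the map attributes
#'   if available via `group_stat`).
#' @param group_stat Optional `group_stat` providing the t map.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_map <- function(object, tstat = NULL, group_stat = NULL, ...) {
  if (is.null(tstat) && !is.null(group_stat)) tstat <- group_stat$tstat
  thr <- attr(object, "t_threshold")
  sig_units <- unlist(object$units[object$significant])
  df <- tibble::tibble(unit = seq_along(tstat), tstat = tstat,
                       significant = seq_along(tstat) %in% sig_units)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$tstat)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "Unit", y = "Group t",
                  fill = "In significant\ncluster") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation correlations
#'
#' Per-output pooled Pearson correlations by horizon (and experiment,
#' when the table carries an `experiment` column).
#'
#' @param object A `cv_result` tibble (possibly with an `experiment`
#'   column from [run_four_experiments()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$horizon <- factor(df$horizon)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$output, y = .data$r,
                                        fill = .data$horizon)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Output", y = "Pooled Pearson r", fill = "Horizon (TR)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("experiment" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~experiment, scales = "free_x")
  }
  p
}
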