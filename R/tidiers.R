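#' Tidy a group statistic table
#'
#' @param x A `group_stat` from [group_ttest()].
#' @param ... Unused.
#' @return A tibble with one row per unit: `unit`, `mean_beta`, `tstat`, `p`.
#' @export
tidy.group_stat <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a group statistic table
#'
#' @param x A `group_stat` from [group_ttest()].
#' @param ... Unused.
#' @return Tibble with `n_units`, `dof`, `n_flagged`, `min_p`, `max_abs_t`.
#' @export
glance.group_stat <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x),
    dof = attr(x, "dof"),
    n_flagged = sum(attr(x, "flagged")),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    max_abs_t = suppressWarnings(max(abs(x$tstat), na.rm = TRUE))
  )
}

#' Tidy a cluster map
#'
#' @param x A `cluster_map` from [permutation_cluster_correction()].
#' @param ... Unused.
#' @return Tibble with one row per cluster (without the unit list-column).
#' @export
tidy.cluster_map <- function(x, ...) {
  dplyr::select(tibble::as_tibble(unclass(x)), -"units")
}

#' One-row summary of a cluster map
#'
#' @param x A `cluster_map`.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_significant`, `min_extent`,
#'   `t_threshold`, `dof`.
#' @export
glance.cluster_map <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    n_significant = sum(x$significant),
    min_extent = attr(x, "min_extent"),
    t_threshold = attr(x, "t_threshold"),
    dof = attr(x, "dof")
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [expanding_window_cv()].
#' @param ... Unused.
#' @return The result as a plain tibble (`output`, `horizon`, `r`, `n_test`).
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with mean pooled correlation per horizon.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |>
    dplyr::group_by(.data$horizon) |>
    dplyr::summarise(mean_r = mean(.data$r, na.rm = TRUE),
                     n_outputs = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "horizon", values_from = c("mean_r"),
                       names_prefix = "mean_r_h") |>
    dplyr::mutate(n_outputs = length(unique(x$output)))
}
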