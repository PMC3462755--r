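#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.siseq_cutoff_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_clusters)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_clusters)) +
    ggplot2::geom_vline(xintercept = object$chosen, linetype = 2) +
    ggplot2::labs(x = "clustering identity cutoff", y = "clusters",
                  title = sprintf("Cutoff calibration (chosen %.2f)",
                                  object$chosen)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.siseq_otu_table <- function(object, ...) {
  cols <- setdiff(names(object), c("otu", "rep_centroid", "taxonomy"))
  df <- tidyr::pivot_longer(tibble::as_tibble(object)[c("otu", cols)],
                            -"otu", names_to = "sample_id",
                            values_to = "count") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$rel,
                                   fill = .data$otu)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot a rarefaction curve
#'
#' @param curve a [rarefaction_curve()] tibble.
#' @return a ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sequences sampled", y = "richness") +
    ggplot2::theme_minimal()
}

#' Plot species accumulation curves
#'
#' @param curves one or more row-bound [species_accumulation()] tibbles.
#' @return a ggplot object.
#' @export
plot_accumulation <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$k, y = .data$mean,
                                       linetype = .data$filtered)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "samples drawn", y = "cumulative OTUs") +
    ggplot2::theme_minimal()
}
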