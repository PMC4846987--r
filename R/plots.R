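# ggplot2 diagnostics for the result tables.

#' Boxplot of pairwise GTV Dice: humans versus virtual raters
#'
#' @param experiment result of [vr_agreement_experiment()] (or its `dice`
#'   tibble).
#' @return a ggplot object.
#' @export
plot_agreement <- function(experiment) {
  d <- if (is.data.frame(experiment)) experiment else experiment$dice
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kind, y = .data$dice,
                                  fill = .data$kind)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = 1) +
    ggplot2::scale_x_discrete(labels = c(human = "human raters",
                                         vr = "virtual raters")) +
    ggplot2::labs(x = NULL, y = "pairwise GTV Dice",
                  title = "Inter-rater agreement, humans vs virtual raters") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Longitudinal relative GTV change (dGTV) per patient
#'
#' Lines of percent GTV change versus baseline with the response cutoffs as
#' dashed horizontal guides (+25% progression, -50% partial response).
#'
#' @param gtv tibble with columns `patient`, `timepoint`, `rater`,
#'   `gtv_mm3` (e.g. the `gtv` table of [vr_agreement_experiment()]).
#' @param thresholds a [response_thresholds()].
#' @return a ggplot object.
#' @export
plot_dgtv <- function(gtv, thresholds = response_thresholds()) {
  d <- gtv |>
    dplyr::group_by(.data$patient, .data$rater) |>
    dplyr::arrange(.data$timepoint, .by_group = TRUE) |>
    dplyr::mutate(dgtv = relative_change_series(.data$gtv_mm3)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$dgtv,
                                  colour = .data$rater, group = .data$rater)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = thresholds$progression_increase_pct,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -thresholds$response_decrease_pct,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~patient) +
    ggplot2::labs(x = "timepoint", y = "dGTV vs baseline [%]") +
    ggplot2::theme_minimal()
}

#' Axial slice of a label volume
#'
#' @param object a [label_volume()].
#' @param slice 0-based axial slice (default: middle).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.label_volume <- function(object, slice = NULL, ...) {
  d <- dim(object$labels)
  if (is.null(slice)) slice <- d[3] %/% 2L
  sl <- object$labels[, , slice + 1L]
  # expand.grid varies the first factor fastest, matching column-major arrays
  df <- tibble::as_tibble(expand.grid(x = seq_len(d[1]), y = seq_len(d[2])))
  df$class <- factor(class_names(object$scheme)[as.vector(sl) + 1L],
                     levels = class_names(object$scheme))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("axial slice z=", slice)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
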