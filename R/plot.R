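#' Plot longitudinal tissuetype volume trajectories
#'
#' Volume-versus-time curves per tissuetype, faceted by patient, in the
#' conventional tissuetype colors (CE red-toned yellow, Fluid blue,
#' Edema1 brown, Edema2 cyan, High FLAIR light blue).
#'
#' @param records A [scan_records()] table.
#' @param tissues Which volume columns to draw.
#' @return A ggplot object.
#' @export
plot_volume_trajectories <- function(records,
                                     tissues = c("ce_cm3", "fluid_cm3",
                                                 "edema1_cm3", "edema2_cm3",
                                                 "high_flair_cm3")) {
  records <- scan_records(records)
  long <- tidyr::pivot_longer(records, dplyr::all_of(tissues),
                              names_to = "tissue", values_to = "volume_cm3")
  cols <- c(ce_cm3 = "#D4B000", fluid_cm3 = "#0000FF",
            edema1_cm3 = "#8B4513", edema2_cm3 = "#00AEAE",
            high_flair_cm3 = "#7EB6FF")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_C1D1, .data$volume_cm3,
                                     color = .data$tissue)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::facet_wrap(~patient_id, scales = "free_y") +
    ggplot2::labs(x = "days since treatment C1D1",
                  y = expression(volume ~ (cm^3)), color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed versus predicted TTP for a fitted model
#'
#' @param object A [ttp_model()] with an underlying fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ttp_model
#' @export
autoplot.ttp_model <- function(object, ...) {
  if (is.null(object$fit))
    stop("model carries no fitted data; use select_model()")
  df <- tibble::tibble(observed = object$fit$model$ttp_days,
                       predicted = stats::fitted(object$fit))
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed TTP (days)", y = "predicted TTP (days)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
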