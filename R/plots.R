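#' Heatmap of a temporal generalization matrix
#'
#' @param object A `tgm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tgm <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$time_test_ms, .data$time_train_ms,
                                 fill = .data$correlation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Time (ms)", y = "Time (ms)",
      fill = paste0(object$metric, "\nr"),
      title = sprintf("Temporal generalization (%s pairs)", object$subset)
    )
}

#' Heatmap of a TGM case contrast with significance outline
#'
#' Cells significant at the contrast's alpha are outlined.
#'
#' @param object A `tgm_contrast`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tgm_contrast <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_test_ms, .data$time_train_ms)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Time (ms)", y = "Time (ms)", fill = sprintf("t(%d)", object$df),
      title = sprintf("Case vs controls TGM contrast (p < %g, %s)",
                      object$alpha, object$correction)
    )
  sig <- dplyr::filter(df, .data$significant)
  if (nrow(sig)) {
    p <- p + ggplot2::geom_tile(data = sig, fill = NA, colour = "black",
                                linewidth = 0.2)
  }
  p
}

#' Brain-model correlation timecourse plot
#'
#' @param object A `model_timecourse` (or a plain tibble binding several).
#' @param ... Unused.
#' @return A ggplot of rho over time, one line per subject.
#' @export
autoplot.model_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$rho,
                                       group = .data$subject)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (ms)", y = "partial Spearman ρ",
                  title = unique(object$model))
}

#' Patient-versus-controls timecourse figure
#'
#' Control mean with a standard-error band, the patient's curve, and dots
#' marking timepoints with a significant case-control contrast.
#'
#' @param patient A `model_timecourse` for the patient.
#' @param controls List of `model_timecourse` objects for the controls.
#' @param contrast Output of [timecourse_case_contrast()] for the same
#'   timecourses.
#' @return A ggplot.
#' @export
plot_timecourse_contrast <- function(patient, controls, contrast) {
  cmat <- vapply(controls, `[[`, numeric(nrow(patient)), "rho")
  band <- tibble::tibble(
    time_ms = patient$time_ms,
    mean = rowMeans(cmat),
    se = apply(cmat, 1, stats::sd) / sqrt(ncol(cmat))
  )
  sig <- dplyr::filter(contrast, .data$significant)
  ggplot2::ggplot(band, ggplot2::aes(.data$time_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "grey30") +
    ggplot2::geom_line(data = patient,
                       ggplot2::aes(y = .data$rho), colour = "deeppink") +
    ggplot2::geom_point(data = sig,
                        ggplot2::aes(y = min(band$mean - band$se) - 0.02),
                        shape = 16, size = 1) +
    ggplot2::labs(x = "Time (ms)", y = "partial Spearman ρ",
                  title = unique(patient$model),
                  subtitle = "pink: patient; grey: control mean ± SE; dots: significant contrast")
}
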