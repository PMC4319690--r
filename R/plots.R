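# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_vline
#'   geom_raster labs scale_fill_viridis_c coord_equal theme_minimal
#'   geom_point geom_errorbar geom_hline
NULL

#' @export
ggplot2::autoplot

#' Plot a phase-stability profile
#'
#' Smoothed PSI against reference frequency, with the raw profile underneath
#' and the profile maximum marked.
#'
#' @param object a [stability_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stability_profile <- function(object, ...) {
  mx <- block_metrics(object)
  ggplot(object, aes(x = .data$freq)) +
    geom_line(aes(y = .data$psi_raw), colour = "grey70", linewidth = 0.3) +
    geom_line(aes(y = .data$psi), colour = "#2c6fbb", linewidth = 0.7) +
    geom_vline(xintercept = mx$argmax_freq, linetype = 2, colour = "#b03a2e") +
    labs(x = "Reference frequency (Hz)", y = "PSI",
         title = sprintf("Phase-stability profile (max %.3f at %.1f Hz)",
                         mx$max_psi, mx$argmax_freq)) +
    theme_minimal()
}

#' Plot a multitaper spectral estimate
#'
#' @param object a `spectral_estimate` from [multitaper_psd()].
#' @param max_freq upper frequency limit for display (Hz).
#' @param ... unused.
#' @return a ggplot (log10 power).
#' @export
autoplot.spectral_estimate <- function(object, max_freq = 30, ...) {
  df <- filter(as_tibble(object), .data$freq <= max_freq, .data$power > 0)
  ggplot(df, aes(x = .data$freq, y = .data$power)) +
    geom_line(colour = "#2c6fbb") +
    ggplot2::scale_y_log10() +
    labs(x = "Frequency (Hz)", y = "Power spectral density") +
    theme_minimal()
}

#' Plot a phase-difference likelihood histogram
#'
#' @param object a [phase_histogram()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phase_histogram <- function(object, ...) {
  ggplot(object, aes(x = .data$center, y = .data$prob)) +
    geom_col(width = diff(object$lower[1:2]) * 0.95, fill = "#2c6fbb") +
    labs(x = "Phase difference (rad)", y = "Likelihood") +
    theme_minimal()
}

#' Plot a slice of the current-density magnitude
#'
#' @param object a `field_solution`.
#' @param axis slicing axis (1, 2 or 3).
#' @param index slice index; defaults to the grid midplane.
#' @param what `"Jmag"` or `"phi"`.
#' @param ... unused.
#' @return a ggplot raster.
#' @export
autoplot.field_solution <- function(object, axis = 2, index = NULL,
                                    what = c("Jmag", "phi"), ...) {
  what <- match.arg(what)
  vol <- if (what == "Jmag") object$Jmag else object$phi
  dims <- dim(vol)
  index <- index %||% ceiling(dims[axis] / 2)
  sl <- switch(axis, vol[index, , ], vol[, index, ], vol[, , index])
  h <- object$model$voxel_size_mm
  df <- expand.grid(u = (seq_len(nrow(sl)) - 0.5) * h,
                    v = (seq_len(ncol(sl)) - 0.5) * h)
  df$value <- as.vector(sl)
  ggplot(df, aes(x = .data$u, y = .data$v, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (what == "Jmag") "|J| (A/m²)" else "φ (V)") +
    coord_equal() +
    labs(x = "mm", y = "mm") +
    theme_minimal()
}

#' Bar chart of sham-baselined percent change per condition
#'
#' For multi-subject summaries the bars show group means with +/- 1 SEM.
#'
#' @param summaries a [condition_summary()] tibble (possibly stacked over
#'   subjects).
#' @return a ggplot.
#' @export
plot_condition_summary <- function(summaries) {
  df <- summaries |>
    filter(!.data$condition %in% c("sham", "initial")) |>
    group_by(.data$condition) |>
    summarise(mean = mean(.data$pct_change),
              sem = sd(.data$pct_change) / sqrt(n()), .groups = "drop")
  ggplot(df, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "#2c6fbb") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "Change in phase stability vs sham (%)") +
    theme_minimal()
}
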