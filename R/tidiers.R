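# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stability profile
#'
#' @param x a [stability_profile()].
#' @param ... unused.
#' @return tibble with `freq`, `psi`, `psi_raw`.
#' @export
tidy.stability_profile <- function(x, ...) {
  tibble(freq = x$freq, psi = x$psi, psi_raw = x$psi_raw)
}

#' @rdname tidy.stability_profile
#' @export
glance.stability_profile <- function(x, ...) {
  m <- block_metrics(x)
  tibble(max_psi = m$max_psi, argmax_freq = m$argmax_freq,
         n_freqs = nrow(x), smoothing_width = attr(x, "smoothing_width"))
}

#' Tidy a Box-Cox result
#'
#' @param x a [boxcox_stabilize()] result.
#' @param ... unused.
#' @return one-row tibble with `lambda`, `shift`, `n`.
#' @export
tidy.boxcox_result <- function(x, ...) {
  tibble(lambda = x$lambda, shift = x$shift, n = length(x$transformed))
}

#' Summaries of a field solution
#'
#' `tidy()` reports mean and peak current-density magnitude per tissue;
#' `glance()` gives the one-row solver summary.
#'
#' @param x a `field_solution`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.field_solution <- function(x, ...) {
  lab <- as.vector(x$model$labels)
  jm <- as.vector(x$Jmag)
  tibble(label = lab, jmag = jm) |>
    group_by(.data$label) |>
    summarise(n_voxels = n(), mean_jmag = mean(.data$jmag),
              max_jmag = max(.data$jmag), .groups = "drop") |>
    left_join(x$model$tissues, by = "label") |>
    select("tissue", "sigma", "n_voxels", "mean_jmag", "max_jmag")
}

#' @rdname tidy.field_solution
#' @export
glance.field_solution <- function(x, ...) {
  tibble(injected_current_mA = x$injected_current * 1e3,
         iterations = x$iterations, residual = x$residual,
         n_voxels = length(x$phi),
         voxel_size_mm = x$model$voxel_size_mm)
}

#' Tidy a pc projection
#'
#' @param x a [first_principal_component()] result.
#' @param ... unused.
#' @return tibble of channel loadings.
#' @export
tidy.pc_projection <- function(x, ...) {
  tibble(channel = names(x$loading), loading = unname(x$loading),
         var_explained = x$var_explained)
}
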