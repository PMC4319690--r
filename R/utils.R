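# Internal helpers shared across modules.

stop_tremor <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("tremorlock_error_", class), "tremorlock_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_tremor(sprintf("`%s` must be a number, not NULL.", name), "validation")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_tremor(sprintf("`%s` must be a single finite number.", name), "validation")
  }
  if (x < lower || x > upper) {
    stop_tremor(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x),
                "validation")
  }
  invisible(x)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector with every element in `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3.5))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

# Linear index helpers for 3-D arrays.
lin_index <- function(i, j, k, dims) {
  i + dims[1L] * ((j - 1L) + dims[2L] * (k - 1L))
}
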