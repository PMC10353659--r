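# broom-style tidiers for the package's result objects.

#' Tidy confusion proportions
#'
#' @param x A [confusion_counts()].
#' @param ... Unused.
#' @return One row per error class with its pixel proportion.
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble(
    class = c("TP", "TN", "FP", "FN"),
    proportion = c(x$tp, x$tn, x$fp, x$fn)
  )
}

#' One-row summary of confusion proportions
#'
#' @inheritParams tidy.confusion_counts
#' @return A tibble with `accuracy`, `f1`, `n_pixels`.
#' @export
glance.confusion_counts <- function(x, ...) {
  dplyr::bind_cols(pixel_metrics(x), tibble(n_pixels = x$n_pixels))
}

#' Tidy a kernel density estimate
#'
#' @param x A [class_density()] result.
#' @param ... Unused.
#' @export
tidy.density_estimate <- function(x, ...) {
  tibble(class = attr(x, "class_label"), grid = x$grid, density = x$density)
}

#' One-row summary of a density estimate
#' @inheritParams tidy.density_estimate
#' @export
glance.density_estimate <- function(x, ...) {
  tibble(
    class = attr(x, "class_label"),
    bandwidth = attr(x, "bandwidth"),
    n_samples = attr(x, "n_samples"),
    absent = attr(x, "absent")
  )
}

#' One-row summary of a green-fraction series
#'
#' @param x A [gf_series()].
#' @param ... Unused.
#' @export
glance.gf_series <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_gf = mean(x$green_fraction),
    min_gf = min(x$green_fraction),
    max_gf = max(x$green_fraction)
  )
}
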