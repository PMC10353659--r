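#' Pixel confusion proportions
#'
#' Counts TP/TN/FP/FN pixels between a predicted and a reference
#' binary mask, with green vegetation as the positive class, and
#' reports them as proportions of all evaluated pixels (so
#' `tp + tn + fp + fn = 1`). Counts are poolable across images by
#' pixel-weighted averaging — see [pool_confusion()].
#'
#' @param pred,truth Binary masks of equal dimensions (logical, 0/1 or
#'   0/255).
#' @return A `confusion_counts` object (fields `tp`, `tn`, `fp`, `fn`,
#'   `n_pixels`).
#' @examples
#' truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, byrow = TRUE)
#' pred  <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, byrow = TRUE)
#' confusion_counts(pred, truth)
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_mask(pred, warn_nonbinary = FALSE)
  truth <- as_mask(truth, warn_nonbinary = FALSE)
  if (!identical(dim(pred), dim(truth))) {
    abort("`pred` and `truth` must have identical dimensions")
  }
  n <- length(pred)
  if (n == 0L) abort("empty masks")
  new_confusion(
    tp = sum(pred & truth) / n,
    tn = sum(!pred & !truth) / n,
    fp = sum(pred & !truth) / n,
    fn = sum(!pred & truth) / n,
    n_pixels = n
  )
}

new_confusion <- function(tp, tn, fp, fn, n_pixels) {
  vals <- c(tp, tn, fp, fn)
  if (any(vals < -1e-12 | vals > 1 + 1e-12)) {
    abort("confusion proportions must lie in [0, 1]")
  }
  if (abs(sum(vals) - 1) > 1e-9) {
    abort("confusion proportions must sum to 1")
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n_pixels = as.numeric(n_pixels)),
            class = "confusion_counts")
}

#' Construct confusion proportions directly
#'
#' For working from published confusion tables rather than masks.
#' Proportions must sum to 1 (up to numerical noise).
#'
#' @param tp,tn,fp,fn Proportions in `[0, 1]`.
#' @param n_pixels Pixel count behind the proportions (defaults to 1).
#' @return A `confusion_counts`.
#' @examples
#' as_confusion_counts(tp = 0.46, tn = 0.48, fp = 0.0354, fn = 0.0246)
#' @export
as_confusion_counts <- function(tp, tn, fp, fn, n_pixels = 1) {
  new_confusion(tp, tn, fp, fn, n_pixels)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: tp %.4f  tn %.4f  fp %.4f  fn %.4f  (n = %s)>\n",
              x$tp, x$tn, x$fp, x$fn, format(x$n_pixels, big.mark = ",")))
  invisible(x)
}

#' Pool confusion counts across images
#'
#' Pixel-weighted average, equivalent to computing the confusion on
#' the concatenation of all images.
#'
#' @param ... `confusion_counts` objects, or a single list of them.
#' @return A pooled `confusion_counts`.
#' @export
pool_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  stopifnot(length(xs) > 0, all(vapply(xs, inherits, logical(1), "confusion_counts")))
  w <- vapply(xs, `[[`, numeric(1), "n_pixels")
  agg <- function(f) sum(vapply(xs, `[[`, numeric(1), f) * w) / sum(w)
  new_confusion(agg("tp"), agg("tn"), agg("fp"), agg("fn"), sum(w))
}

#' Accuracy and F1 from confusion proportions
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`; F1 is defined as 0 when its
#' denominator vanishes (no green pixels predicted or present).
#'
#' @param confusion A [confusion_counts()].
#' @return A tibble with `accuracy` and `f1`.
#' @examples
#' pixel_metrics(as_confusion_counts(0.46, 0.48, 0.0354, 0.0246))
#' @export
pixel_metrics <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_counts"))
  tot <- confusion$tp + confusion$tn + confusion$fp + confusion$fn
  denom <- 2 * confusion$tp + confusion$fp + confusion$fn
  tibble(
    accuracy = (confusion$tp + confusion$tn) / tot,
    f1 = if (denom == 0) 0 else 2 * confusion$tp / denom
  )
}

#' Green fraction of a mask
#'
#' Number of green pixels divided by the total number of pixels.
#'
#' @param mask A binary mask.
#' @return A fraction in `[0, 1]`.
#' @export
green_fraction <- function(mask) {
  mask <- as_mask(mask, warn_nonbinary = FALSE)
  if (length(mask) == 0L) abort("empty mask")
  sum(mask) / length(mask)
}

#' Image-scale regression metrics
#'
#' Agreement between predicted and reference green fractions:
#' `RMSE = sqrt(mean((f - y)^2))` and the coefficient of determination
#' `R^2 = 1 - sum((f - y)^2) / sum((y - mean(y))^2)`. A constant
#' reference leaves R^2 undefined and it is reported as `NA`.
#'
#' @param predicted,reference Equal-length numeric vectors (n >= 2).
#' @return A tibble with `r_squared`, `rmse`, `n`.
#' @examples
#' regression_metrics(c(0.1, 0.2, 0.6), c(0.1, 0.2, 0.3))
#' @export
regression_metrics <- function(predicted, reference) {
  if (length(predicted) != length(reference)) {
    abort("`predicted` and `reference` must have the same length")
  }
  n <- length(reference)
  if (n < 2L) abort("need at least two observations")
  ss_res <- sum((predicted - reference)^2)
  ss_tot <- sum((reference - mean(reference))^2)
  tibble(
    r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(mean((predicted - reference)^2)),
    n = n
  )
}

#' Normalized Euclidean distance between two images
#'
#' Root-mean-square difference of 8-bit digital numbers scaled to
#' `[0, 1]`: `sqrt(mean(((x - y) / 255)^2))` over all channels, so
#' identical images score 0 and an all-black vs all-white pair scores
#' 1. The raw sum-of-squares form is unbounded and grows with image
#' size; this dimension-free normalization makes values comparable
#' across resolutions.
#'
#' @param img_x,img_y Images of identical dimensions.
#' @return A distance in `[0, 1]`.
#' @export
euclidean_image_distance <- function(img_x, img_y) {
  x <- as_dn(img_x)
  y <- as_dn(img_y)
  if (!identical(dim(x), dim(y))) abort("images must have identical dimensions")
  sqrt(mean(((as.numeric(x) - as.numeric(y)) / 255)^2))
}

#' Domain gap between two image collections
#'
#' Mean normalized Euclidean distance over seeded random cross-set
#' pairs. The pairing is oriented canonically (larger set first; when
#' the sets have equal size each sampled pair is evaluated in both
#' directions), so the estimate is exactly symmetric in its arguments
#' under the same seed.
#'
#' @param set_a,set_b Non-empty lists of images with common
#'   dimensions.
#' @param n_pairs Number of sampled cross-set pairs.
#' @param seed Integer seed.
#' @return A tibble with `mean_distance`, `se`, `n_pairs`.
#' @export
domain_gap <- function(set_a, set_b, n_pairs = 200L, seed = 1L) {
  if (!length(set_a) || !length(set_b)) abort("both sets must be non-empty")
  dims <- unique(lapply(c(set_a, set_b), dim))
  if (length(dims) != 1L) abort("all images must share the same dimensions")
  if (length(set_b) > length(set_a)) {
    tmp <- set_a; set_a <- set_b; set_b <- tmp
  }
  na <- length(set_a)
  nb <- length(set_b)
  idx <- with_seed(seed, list(
    i = sample.int(na, n_pairs, replace = TRUE),
    j = sample.int(nb, n_pairs, replace = TRUE)
  ))
  d <- vapply(seq_len(n_pairs), function(k) {
    euclidean_image_distance(set_a[[idx$i[k]]], set_b[[idx$j[k]]])
  }, numeric(1))
  if (na == nb) {
    d2 <- vapply(seq_len(n_pairs), function(k) {
      euclidean_image_distance(set_a[[idx$j[k]]], set_b[[idx$i[k]]])
    }, numeric(1))
    d <- c(d, d2)
  }
  tibble(
    mean_distance = mean(d),
    se = stats::sd(d) / sqrt(length(d)),
    n_pairs = length(d)
  )
}

#' Green-fraction time series
#'
#' Computes the GF of each dated mask, orders by time and averages
#' duplicate timestamps, yielding the canopy-cover dynamic curve.
#'
#' @param samples A data frame with a `timestamp` column and a `mask`
#'   list column, or a list of `list(timestamp =, mask =)` entries.
#' @return A tibble of class `gf_series` with strictly increasing
#'   timestamps: `timestamp`, `green_fraction`, `n_images`.
#' @export
gf_series <- function(samples) {
  if (!is.data.frame(samples)) {
    if (!length(samples)) abort("need at least one sample")
    samples <- tibble(
      # do.call(c, ...) keeps Date/POSIXct classes
      timestamp = do.call(c, lapply(samples, `[[`, "timestamp")),
      mask = lapply(samples, `[[`, "mask")
    )
  }
  if (!nrow(samples)) abort("need at least one sample")
  if (!all(c("timestamp", "mask") %in% names(samples))) {
    abort("`samples` needs `timestamp` and `mask` columns")
  }
  gf <- vapply(samples$mask, green_fraction, numeric(1))
  out <- tibble(timestamp = samples$timestamp, gf = gf) |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(green_fraction = mean(.data$gf),
                     n_images = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$timestamp)
  structure(out, class = c("gf_series", class(out)))
}
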