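#' Otsu threshold of a scalar collection
#'
#' Returns the threshold maximizing the between-class variance of the
#' two classes `values <= t` (background) and `values > t`
#' (foreground), searching the `bins - 1` interior bin edges of the
#' data range. Class statistics are computed from the raw values (not
#' bin midpoints), so the result agrees exactly with an exhaustive
#' search over the same candidate edges. Ties are broken towards the
#' smallest threshold.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return The selected threshold (a bin edge).
#' @examples
#' otsu_threshold(c(rnorm(100, 60, 5), rnorm(100, 200, 5)))
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort("need at least two values")
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) abort("constant input: no threshold separates a single value")
  if (bins < 2 || bins != round(bins)) abort("`bins` must be an integer >= 2")
  edges <- seq(lo, hi, length.out = bins + 1L)
  cand <- edges[2:bins]
  xs <- sort(values)
  cs <- cumsum(xs)
  n <- length(xs)
  tot <- cs[n]
  n1 <- findInterval(cand, xs)          # count of values <= candidate
  valid <- n1 > 0L & n1 < n
  if (!any(valid)) {
    # all mass in one extreme bin; the data still has >= 2 distinct
    # values, so split at the first edge above the minimum
    return(cand[which(cand > lo)[1]])
  }
  w1 <- n1 / n
  m1 <- cs[pmax(n1, 1L)] / n1
  m2 <- (tot - cs[pmax(n1, 1L)]) / (n - n1)
  bc <- ifelse(valid, w1 * (1 - w1) * (m1 - m2)^2, -Inf)
  cand[which.max(bc)]                    # which.max takes the first tie
}

#' Excess-green + Otsu baseline segmenter
#'
#' Classical desk-scale baseline: computes the per-pixel excess-green
#' index `ExG = 2G - R - B` on raw digital numbers via [exg_map()],
#' finds an Otsu threshold over the ExG values, and labels pixels with
#' `ExG > threshold` as green vegetation. A constant-colour image has
#' no contrast to threshold and falls back to an all-background mask
#' with a warning.
#'
#' @param rgb An 8-bit RGB array (`H x W x 3`; 0--255 integers or
#'   \code{[0, 1]} doubles).
#' @param bins Histogram bins passed to [otsu_threshold()].
#' @return A logical `H x W` mask (`TRUE` = green vegetation).
#' @examples
#' img <- array(0L, c(8, 8, 3))
#' img[, 1:4, 2] <- 255L   # left half pure green
#' img[, 5:8, 1] <- 255L   # right half pure red
#' mean(segment_exg_otsu(img))  # 0.5
#' @export
segment_exg_otsu <- function(rgb, bins = 256L) {
  exg <- exg_map(rgb)
  if (min(exg) == max(exg)) {
    warn("constant-colour image: returning an all-background mask")
    return(matrix(FALSE, nrow(exg), ncol(exg)))
  }
  t <- otsu_threshold(as.vector(exg), bins = bins)
  exg > t
}

#' Wrap a segmentation function as a segmenter
#'
#' A segmenter is the contract every model must satisfy to be
#' evaluated by this toolkit: a named function mapping an RGB image to
#' a binary mask of identical height/width. [run_segmenter()] applies
#' it and enforces the contract.
#'
#' @param name Display name.
#' @param fn Function `rgb -> mask`.
#' @return An object of class `segmenter`.
#' @export
new_segmenter <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn), class = "segmenter")
}

#' @rdname new_segmenter
#' @param segmenter A `segmenter`.
#' @param rgb RGB image.
#' @export
run_segmenter <- function(segmenter, rgb) {
  stopifnot(inherits(segmenter, "segmenter"))
  out <- segmenter$fn(rgb)
  out <- as_mask(out, warn_nonbinary = FALSE)
  d <- dim(rgb)
  if (!identical(dim(out), d[1:2])) {
    abort(sprintf("segmenter '%s' returned a %s mask for a %d x %d image",
                  segmenter$name, paste(dim(out), collapse = " x "),
                  d[1], d[2]))
  }
  out
}

#' The bundled excess-green baseline as a segmenter
#' @return A `segmenter` wrapping [segment_exg_otsu()].
#' @export
exg_otsu_segmenter <- function() new_segmenter("exg-otsu", segment_exg_otsu)

#' Run an external segmenter over a manifest
#'
#' Bridges deep models (or any executable) into the toolkit. The
#' adapter contract: an executable invoked as
#' `adapter <rgb.png> <out_mask.png>` that writes a binary mask PNG of
#' the same height/width. Malformed outputs (missing file, wrong
#' dimensions, non-two-valued) are rejected per image; the run
#' continues and every failure is recorded.
#'
#' @param adapter_cmd Path to the executable adapter.
#' @param manifest A [build_manifest()] manifest (or any data frame
#'   with a `tile` column of RGB paths).
#' @param out_dir Directory the predicted masks are written to.
#' @return A tibble with one row per image: `tile`, `pred`, `ok`,
#'   `message`.
#' @export
run_external <- function(adapter_cmd, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(manifest$tile, function(tile) {
    pred <- file.path(out_dir, sub("_rgb\\.png$", "_pred.png", basename(tile)))
    msg <- tryCatch({
      status <- suppressWarnings(system2(adapter_cmd, c(tile, pred),
                                         stdout = FALSE, stderr = FALSE))
      if (status != 0) stop(sprintf("adapter exited with status %d", status))
      if (!file.exists(pred)) stop("adapter produced no output file")
      m <- png::readPNG(pred)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      src <- dim(read_rgb_png(tile))
      if (!identical(dim(m), src[1:2])) {
        stop(sprintf("mask dims %s do not match image dims %s",
                     paste(dim(m), collapse = "x"),
                     paste(src[1:2], collapse = "x")))
      }
      if (length(unique(as.vector(m))) > 2L) stop("mask is not two-valued")
      ""
    }, error = function(e) conditionMessage(e))
    tibble(tile = tile, pred = pred, ok = msg == "", message = msg)
  })
  dplyr::bind_rows(rows)
}
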