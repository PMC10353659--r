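#' Per-pixel excess-green index
#'
#' `ExG = 2G - R - B` on raw 8-bit digital numbers (not chromaticity),
#' so values range over `[-510, 510]`: pure green scores 510,
#' achromatic pixels 0, pure red -255. ExG is the package's greenness
#' axis, used both by the baseline segmenter and the error-class
#' density analysis.
#'
#' @param rgb An RGB array (`H x W x 3`).
#' @return A numeric `H x W` matrix.
#' @examples
#' exg_map(array(c(0, 255, 0), c(1, 1, 3)))  # 510
#' @export
exg_map <- function(rgb) {
  x <- as_dn(rgb)
  if (length(dim(x)) != 3L || dim(x)[3] < 3L) abort("`rgb` must be H x W x 3")
  out <- 2 * x[, , 2] - x[, , 1] - x[, , 3]
  matrix(as.numeric(out), dim(x)[1], dim(x)[2])
}

#' Per-pixel CIELAB lightness
#'
#' L* in `[0, 100]` under the sRGB/D65 standard: channels are
#' linearized with the piecewise sRGB transfer curve, combined to
#' relative luminance Y (Rec. 709/sRGB primaries), and mapped through
#' the CIE L* cube-root curve. Reference white scores 100, black 0,
#' pure sRGB red about 53.24.
#'
#' @inheritParams exg_map
#' @return A numeric `H x W` matrix of L* values.
#' @export
lightness_map <- function(rgb) {
  x <- as_dn(rgb)
  if (length(dim(x)) != 3L || dim(x)[3] < 3L) abort("`rgb` must be H x W x 3")
  lin <- function(c) {
    v <- c / 255
    ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  }
  y <- 0.2126729 * lin(x[, , 1]) + 0.7151522 * lin(x[, , 2]) +
    0.0721750 * lin(x[, , 3])
  eps <- (6 / 29)^3
  fy <- ifelse(y > eps, y^(1 / 3), y / (3 * (6 / 29)^2) + 4 / 29)
  matrix(116 * fy - 16, dim(x)[1], dim(x)[2])
}

#' Per-pixel error classes
#'
#' Assigns every pixel of a (prediction, truth) pair to TP, FP, FN or
#' TN (green vegetation positive). Class counts divided by the pixel
#' total equal [confusion_counts()] exactly.
#'
#' @param pred,truth Binary masks of equal dimensions.
#' @return A `pixel_error_map`: integer matrix with levels
#'   `c("TP", "FP", "FN", "TN")`.
#' @export
error_map <- function(pred, truth) {
  pred <- as_mask(pred, warn_nonbinary = FALSE)
  truth <- as_mask(truth, warn_nonbinary = FALSE)
  if (!identical(dim(pred), dim(truth))) {
    abort("`pred` and `truth` must have identical dimensions")
  }
  # 1 TP, 2 FP, 3 FN, 4 TN
  code <- ifelse(pred & truth, 1L,
          ifelse(pred & !truth, 2L,
          ifelse(!pred & truth, 3L, 4L)))
  structure(matrix(code, nrow(pred), ncol(pred)),
            levels = c("TP", "FP", "FN", "TN"),
            class = "pixel_error_map")
}

#' @export
print.pixel_error_map <- function(x, ...) {
  tab <- error_class_counts(x)
  cat("<pixel_error_map>\n")
  print(tab)
  invisible(x)
}

#' Class counts of an error map
#' @param emap A [error_map()].
#' @return Named integer vector over TP/FP/FN/TN.
#' @export
error_class_counts <- function(emap) {
  stopifnot(inherits(emap, "pixel_error_map"))
  lv <- attr(emap, "levels")
  counts <- tabulate(unclass(emap), nbins = length(lv))
  setNames(counts, lv)
}

#' Kernel density of a pixel feature within one error class
#'
#' Gaussian kernel density estimate of a per-pixel feature (ExG or
#' CIELAB L*) over the pixels of one error class, with Scott's-rule
#' bandwidth, evaluated on a uniform grid spanning
#' `[min - 3 bw, max + 3 bw]`. An absent class yields an explicit
#' absent result rather than an error.
#'
#' @param values Numeric matrix of per-pixel feature values (from
#'   [exg_map()] or [lightness_map()]).
#' @param emap A [error_map()] aligned with `values`.
#' @param cls One of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @param grid_size Number of grid points (default 256).
#' @return A `density_estimate`: tibble with `grid` and `density`
#'   columns and attributes `bandwidth`, `n_samples`, `class`,
#'   `absent`.
#' @export
class_density <- function(values, emap, cls, grid_size = 256L) {
  stopifnot(inherits(emap, "pixel_error_map"))
  lv <- attr(emap, "levels")
  cls <- match.arg(cls, lv)
  if (!identical(dim(values), dim(unclass(emap)))) {
    abort("`values` and `emap` must have identical dimensions")
  }
  v <- values[unclass(emap) == match(cls, lv)]
  if (length(v) < 2L) {
    return(structure(tibble(grid = numeric(), density = numeric()),
                     bandwidth = NA_real_, n_samples = length(v),
                     class_label = cls, absent = TRUE,
                     class = c("density_estimate", class(tibble()))))
  }
  bw <- tryCatch(stats::bw.nrd(v), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) {
    bw <- 1.06 * max(stats::sd(v), 1e-9) * length(v)^(-1 / 5)
  }
  den <- stats::density(v, bw = bw, kernel = "gaussian",
                        from = min(v) - 3 * bw, to = max(v) + 3 * bw,
                        n = grid_size)
  structure(tibble(grid = den$x, density = den$y),
            bandwidth = bw, n_samples = length(v), class_label = cls,
            absent = FALSE,
            class = c("density_estimate", class(tibble())))
}

#' Densities of a feature for all four error classes
#'
#' Convenience wrapper over [class_density()] returning one long
#' tibble ready for plotting/export, with absent classes dropped.
#'
#' @inheritParams class_density
#' @return A tibble with `class`, `grid`, `density`, `bandwidth`,
#'   `n_samples`.
#' @export
class_densities <- function(values, emap, grid_size = 256L) {
  lv <- attr(emap, "levels")
  rows <- lapply(lv, function(cl) {
    d <- class_density(values, emap, cl, grid_size)
    if (attr(d, "absent")) return(NULL)
    tibble(class = cl, grid = d$grid, density = d$density,
           bandwidth = attr(d, "bandwidth"),
           n_samples = attr(d, "n_samples"))
  })
  dplyr::bind_rows(rows)
}

default_error_palette <- function() {
  c(TP = "#2E7D32", FP = "#2196F3", FN = "#F44336", TN = "#616161")
}

#' Colour-coded error-pixel visualization
#'
#' Maps the four error classes to a bijective palette, yielding an RGB
#' overlay image; [decode_error_overlay()] inverts it exactly.
#' [write_error_overlay()] writes the PNG plus a sidecar JSON legend.
#'
#' @param emap A [error_map()].
#' @param palette Named vector of four distinct colours over
#'   TP/FP/FN/TN.
#' @return An 8-bit RGB array.
#' @export
render_error_overlay <- function(emap, palette = default_error_palette()) {
  stopifnot(inherits(emap, "pixel_error_map"))
  lv <- attr(emap, "levels")
  if (!all(lv %in% names(palette))) abort("palette must name all four classes")
  cols <- grDevices::col2rgb(palette[lv])   # 3 x 4
  if (anyDuplicated(t(cols))) abort("palette colours must be distinct (bijective)")
  code <- as.vector(unclass(emap))
  out <- array(0L, c(nrow(emap), ncol(emap), 3L))
  for (ch in 1:3) out[, , ch] <- matrix(cols[ch, code], nrow(emap), ncol(emap))
  storage.mode(out) <- "integer"
  out
}

#' @rdname render_error_overlay
#' @param overlay An overlay produced by [render_error_overlay()].
#' @export
decode_error_overlay <- function(overlay, palette = default_error_palette()) {
  x <- as_dn(overlay)
  lv <- c("TP", "FP", "FN", "TN")
  cols <- grDevices::col2rgb(palette[lv])
  key <- as.numeric(x[, , 1]) * 65536 + as.numeric(x[, , 2]) * 256 +
    as.numeric(x[, , 3])
  ckey <- cols[1, ] * 65536 + cols[2, ] * 256 + cols[3, ]
  code <- match(key, ckey)
  if (anyNA(code)) abort("overlay contains colours outside the palette")
  structure(matrix(code, dim(x)[1], dim(x)[2]),
            levels = lv, class = "pixel_error_map")
}

#' @rdname render_error_overlay
#' @param path PNG output path; the legend sidecar is written next to
#'   it as `<path>.legend.json`.
#' @export
write_error_overlay <- function(emap, path, palette = default_error_palette()) {
  overlay <- render_error_overlay(emap, palette)
  write_rgb_png(overlay, path)
  jsonlite::write_json(as.list(palette), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
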