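# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb the
# user's session RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Coerce an image to 8-bit digital numbers
#'
#' Accepts an integer array already on the 0--255 scale or a double
#' array on \code{[0, 1]} (as returned by [png::readPNG()]) and returns
#' an integer array of digital numbers (DN) on 0--255.
#'
#' @param x An RGB array (`H x W x 3`) or single-channel matrix.
#' @return An integer array with the same dimensions.
#' @keywords internal
as_dn <- function(x) {
  if (is.integer(x)) return(x)
  v <- as.numeric(x)
  if (length(v) && max(v, na.rm = TRUE) <= 1 + 1e-9) {
    out <- as.integer(round(v * 255))
  } else {
    out <- as.integer(round(v))
  }
  if (any(out < 0L | out > 255L)) {
    abort("image values outside the 8-bit range 0..255")
  }
  dim(out) <- dim(x)
  out
}

# Coerce a mask-like input (logical matrix, 0/1, or 0/255 PNG channel)
# to a logical matrix. Any nonzero value is treated as green; a warning
# is raised when values other than {0, max} are present.
as_mask <- function(mask, warn_nonbinary = TRUE) {
  if (is.logical(mask)) {
    if (is.null(dim(mask))) abort("mask must be a matrix")
    return(mask)
  }
  d <- dim(mask)
  if (length(d) == 3L) {
    mask <- mask[, , 1L]
    d <- dim(mask)
  }
  if (is.null(d) || length(d) != 2L) abort("mask must be a 2-d matrix")
  v <- as.numeric(mask)
  u <- sort(unique(v))
  if (warn_nonbinary && length(u) > 2L) {
    warn("mask contains values other than 0 and its maximum; treating any nonzero value as green")
  }
  out <- v != 0
  dim(out) <- d
  out
}

# Read / write helpers around the png package ------------------------

read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  as_dn(img[, , 1:3, drop = FALSE])
}

write_rgb_png <- function(rgb, path) {
  rgb <- as_dn(rgb)
  png::writePNG(rgb / 255, target = path)
  invisible(path)
}

read_mask_png <- function(path) {
  as_mask(png::readPNG(path))
}

write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}
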