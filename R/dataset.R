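#' Tile an image (and its mask) into fixed-size squares
#'
#' Centre-crops the source to the largest multiple of `tile_size` in
#' each dimension, then cuts a non-overlapping grid. The mask, when
#' present, is tiled identically, so a 1,024 x 1,024 rendered sample
#' yields four 512 x 512 tiles and the tiles reassemble the centre crop
#' exactly.
#'
#' @param rgb An `H x W x 3` image, or a `rendered_sample` (its mask is
#'   then tiled too).
#' @param mask Optional aligned binary mask.
#' @param tile_size Tile side in pixels (default 512).
#' @return A tibble with one row per tile: `tile_id`, `row_off`,
#'   `col_off` (pixel origin of the tile in the source), and list
#'   columns `rgb` and `mask` (the latter `NULL`-filled when no mask
#'   was supplied). The centre-crop origin is attached as attribute
#'   `crop_origin`.
#' @examples
#' img <- array(0L, c(64, 64, 3))
#' nrow(tile_sample(img, tile_size = 32))  # 4 tiles
#' @export
tile_sample <- function(rgb, mask = NULL, tile_size = 512L) {
  if (inherits(rgb, "rendered_sample")) {
    mask <- mask %||% rgb$mask
    rgb <- rgb$rgb
  }
  d <- dim(rgb)
  if (length(d) != 3L || d[3] < 3L) abort("`rgb` must be an H x W x 3 array")
  if (tile_size < 1 || tile_size != round(tile_size)) {
    abort("`tile_size` must be a positive integer")
  }
  if (d[1] < tile_size || d[2] < tile_size) {
    abort(sprintf("image (%d x %d) is smaller than tile_size = %d",
                  d[1], d[2], tile_size))
  }
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    if (!identical(dim(mask), d[1:2])) abort("mask dimensions must match the image")
  }
  kh <- d[1] %/% tile_size
  kw <- d[2] %/% tile_size
  r0 <- (d[1] - kh * tile_size) %/% 2
  c0 <- (d[2] - kw * tile_size) %/% 2

  grid <- expand.grid(i = seq_len(kh), j = seq_len(kw))
  grid <- grid[order(grid$i, grid$j), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    i <- grid$i[k]; j <- grid$j[k]
    rs <- r0 + (i - 1L) * tile_size
    cs <- c0 + (j - 1L) * tile_size
    ri <- rs + seq_len(tile_size)
    ci <- cs + seq_len(tile_size)
    list(
      row_off = rs, col_off = cs,
      rgb = rgb[ri, ci, , drop = FALSE],
      mask = if (is.null(mask)) NULL else mask[ri, ci, drop = FALSE]
    )
  })
  out <- tibble(
    tile_id = seq_along(rows),
    row_off = vapply(rows, `[[`, numeric(1), "row_off"),
    col_off = vapply(rows, `[[`, numeric(1), "col_off"),
    rgb = lapply(rows, `[[`, "rgb"),
    mask = lapply(rows, `[[`, "mask")
  )
  attr(out, "crop_origin") <- c(r0, c0)
  attr(out, "tile_size") <- as.integer(tile_size)
  out
}

#' Write tiles as paired PNG files
#'
#' Files are named `<source_id>_t<k>_rgb.png` / `<source_id>_t<k>_mask.png`
#' so that [build_manifest()] can group tiles by source image.
#'
#' @param tiles Output of [tile_sample()].
#' @param dir Output directory.
#' @param source_id Identifier of the source image.
#' @return Invisibly, the written RGB paths.
#' @export
write_tiles <- function(tiles, dir, source_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(tiles))
  for (k in seq_len(nrow(tiles))) {
    stem <- file.path(dir, sprintf("%s_t%d", source_id, tiles$tile_id[k]))
    write_rgb_png(tiles$rgb[[k]], paste0(stem, "_rgb.png"))
    if (!is.null(tiles$mask[[k]])) {
      write_mask_png(tiles$mask[[k]], paste0(stem, "_mask.png"))
    }
    paths[k] <- paste0(stem, "_rgb.png")
  }
  invisible(paths)
}

#' Build a train/val/test manifest over a directory of tiles
#'
#' Scans `dir` for `*_rgb.png` / `*_mask.png` pairs, groups tiles by
#' their source image (the stem before the `_t<k>` suffix) and assigns
#' whole sources to splits, so tiles of one image never straddle a
#' split (no spatial leakage). The split is deterministic given `seed`.
#' Unpaired files are an error and are listed in the message.
#'
#' @param dir Directory of tiles written by [write_tiles()].
#' @param split_fractions Named numeric vector over
#'   `c(train, val, test)` (any subset), summing to 1.
#' @param seed Integer seed for the source shuffle.
#' @param tag Optional site/scenario tag recorded per entry.
#' @return A tibble of class `dataset_manifest` with columns `tile`,
#'   `mask`, `source_id`, `tag`, `split`; split counts in
#'   `attr(, "counts")`.
#' @export
build_manifest <- function(dir, split_fractions = c(train = 0.8, val = 0.1, test = 0.1),
                           seed = 1L, tag = NA_character_) {
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    abort("`split_fractions` must sum to 1")
  }
  if (is.null(names(split_fractions)) || any(names(split_fractions) == "")) {
    abort("`split_fractions` must be named (train/val/test)")
  }
  rgbs <- sort(list.files(dir, pattern = "_rgb\\.png$", full.names = TRUE))
  masks <- sort(list.files(dir, pattern = "_mask\\.png$", full.names = TRUE))
  stem <- function(p, suf) sub(suf, "", basename(p))
  rs <- stem(rgbs, "_rgb\\.png$")
  ms <- stem(masks, "_mask\\.png$")
  orphans <- c(paste0(setdiff(rs, ms), "_rgb.png", recycle0 = TRUE),
               paste0(setdiff(ms, rs), "_mask.png", recycle0 = TRUE))
  if (length(orphans)) {
    abort(c("unpaired tile files found:", setNames(orphans, rep("x", length(orphans)))))
  }
  if (!length(rgbs)) abort(sprintf("no tiles found under %s", dir))
  source_id <- sub("_t\\d+$", "", rs)
  sources <- unique(source_id)
  shuffled <- with_seed(seed, sample(sources))
  n <- length(shuffled)
  # largest-remainder apportionment of sources to splits
  quota <- split_fractions * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  split_of <- rep(names(split_fractions), times = base)
  names(split_of) <- shuffled
  out <- tibble(
    tile = rgbs,
    mask = file.path(dir, paste0(rs, "_mask.png")),
    source_id = source_id,
    tag = tag,
    split = unname(split_of[source_id])
  )
  counts <- table(factor(out$split, levels = names(split_fractions)))
  structure(out, counts = counts,
            class = c("dataset_manifest", class(out)))
}

#' Write / read a manifest
#'
#' JSON carries the entries and split counts; `.csv` writes the flat
#' entry table.
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output path (`.json` or `.csv`).
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(entries = df, counts = as.list(attr(manifest, "counts"))),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    counts <- table(df$split)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as_tibble(obj$entries)
    counts <- unlist(obj$counts)
  }
  structure(df, counts = counts, class = c("dataset_manifest", class(df)))
}

#' Export unpaired image folders for domain-adaptation tools
#'
#' Writes `trainA/` and `trainB/` folders of `n_each` RGB tiles each
#' (no masks), subsampled with `seed` — the standard unpaired
#' image-translation layout consumed by CycleGAN-style tools. The
#' translation model itself is outside this package's scope.
#'
#' @param manifest_a,manifest_b Manifests of the two domains.
#' @param out_dir Output directory; must be empty unless
#'   `overwrite = TRUE`.
#' @param n_each Number of images per folder (0 allowed).
#' @param seed Integer seed for the subsample.
#' @param overwrite Allow writing into a non-empty `out_dir`.
#' @return Invisibly, `out_dir`.
#' @export
export_unpaired <- function(manifest_a, manifest_b, out_dir, n_each,
                            seed = 1L, overwrite = FALSE) {
  if (!nrow(manifest_a) || !nrow(manifest_b)) {
    abort("both manifests must be non-empty")
  }
  if (n_each < 0 || n_each != round(n_each)) abort("`n_each` must be >= 0")
  if (n_each > nrow(manifest_a) || n_each > nrow(manifest_b)) {
    abort(sprintf("n_each = %d exceeds availability (%d / %d tiles)",
                  n_each, nrow(manifest_a), nrow(manifest_b)))
  }
  if (dir.exists(out_dir) && length(list.files(out_dir, recursive = TRUE)) &&
      !overwrite) {
    abort(sprintf("`%s` is not empty; use overwrite = TRUE to force", out_dir))
  }
  dir.create(file.path(out_dir, "trainA"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trainB"), recursive = TRUE, showWarnings = FALSE)
  pick <- function(m, sub_seed) {
    if (n_each == 0) return(character(0))
    with_seed(sub_seed, sample(m$tile, n_each))
  }
  fa <- pick(manifest_a, derive_seed(seed, 1L))
  fb <- pick(manifest_b, derive_seed(seed, 2L))
  file.copy(fa, file.path(out_dir, "trainA", basename(fa)), overwrite = TRUE)
  file.copy(fb, file.path(out_dir, "trainB", basename(fb)), overwrite = TRUE)
  invisible(out_dir)
}
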