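#' Reproducible run configuration
#'
#' Bundles everything a simulation run needs — crop, sample count,
#' growth stages, camera, light, tile size, output root and a single
#' global seed — so a run is reproducible from its persisted config.
#' The global seed fans out to per-stage seeds through a fixed affine
#' scheme ([stage_seed()]), so stages can be rerun independently.
#'
#' @param crop `"rice"` or `"wheat"`.
#' @param n_samples Latin-hypercube sample count.
#' @param n_stages Growth stages per sample.
#' @param camera A [camera_config()].
#' @param light A [light_config()].
#' @param tile_size Tile side in pixels.
#' @param out_dir Output root directory.
#' @param seed Global integer seed.
#' @param fidelity `"standard"` or `"low"` (fewer leaf segments, no
#'   shadow pass — faster batch rendering at slightly coarser
#'   geometry).
#' @param space Optional [parameter_space()] override.
#' @return A `run_config`.
#' @export
run_config <- function(crop = c("rice", "wheat"), n_samples = 500L,
                       n_stages = 4L, camera = camera_config(),
                       light = light_config(), tile_size = 512L,
                       out_dir = "greensim-run", seed = 1L,
                       fidelity = c("standard", "low"), space = NULL) {
  crop <- match.arg(crop)
  fidelity <- match.arg(fidelity)
  structure(list(
    crop = crop, n_samples = as.integer(n_samples),
    n_stages = as.integer(n_stages), camera = camera, light = light,
    tile_size = as.integer(tile_size), out_dir = out_dir,
    seed = as.integer(seed), fidelity = fidelity,
    space = space %||% parameter_space(crop, n_stages = n_stages)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML config path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cam <- do.call(camera_config, cfg$camera %||% list())
  lgt <- do.call(light_config, cfg$light %||% list())
  space <- if (!is.null(cfg$parameter_space_file)) {
    read_parameter_space(cfg$parameter_space_file)
  } else NULL
  run_config(
    crop = cfg$crop %||% "rice",
    n_samples = cfg$n_samples %||% 500L,
    n_stages = cfg$n_stages %||% 4L,
    camera = cam, light = lgt,
    tile_size = cfg$tile_size %||% 512L,
    out_dir = cfg$out_dir %||% "greensim-run",
    seed = cfg$seed %||% 1L,
    fidelity = cfg$fidelity %||% "standard",
    space = space
  )
}

#' Per-stage seed fan-out
#'
#' Deterministic map from the global seed and a named stage to a
#' 32-bit seed, so each stage has an independent but reproducible
#' stream.
#'
#' @param seed Global seed.
#' @param stage One of `"sample"`, `"render"`, `"tile"`, `"split"`,
#'   `"export"`, `"segment"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage = c("sample", "render", "tile", "split",
                                       "export", "segment")) {
  stage <- match.arg(stage)
  derive_seed(seed, match(stage, c("sample", "render", "tile", "split",
                                   "export", "segment")) * 7L)
}

run_log <- function(dir, stage, info) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info$stage <- stage
  info$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  info$package_version <- as.character(utils::packageVersion("greensim"))
  jsonlite::write_json(info, file.path(dir, paste0("log_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(info)
}

#' Simulate a rendered dataset
#'
#' Samples the parameter space, pairs every point with each growth
#' stage, builds and renders every scene, and (optionally) writes the
#' paired image/mask/metadata files under `out_dir/images`. With
#' `callback` supplied the rendered samples are streamed to it instead
#' of being kept, so full-scale runs need constant memory.
#'
#' @param config A [run_config()].
#' @param write Write PNG/JSON artefacts to disk.
#' @param callback Optional `function(sample, spec)` applied to each
#'   rendered sample.
#' @return A tibble of scene specifications with an `id` column (one
#'   row per rendered sample).
#' @export
simulate_dataset <- function(config, write = TRUE, callback = NULL) {
  stopifnot(inherits(config, "run_config"))
  pts <- sample_parameter_space(config$space, config$n_samples,
                                seed = stage_seed(config$seed, "sample"))
  specs <- with_growth_stages(pts, config$n_stages,
                              base_seed = stage_seed(config$seed, "render"))
  if (nrow(specs)) {
    specs$id <- sprintf("%s_s%04d_g%d", config$crop, specs$sample_id,
                        specs$growth_stage)
  } else {
    specs$id <- character(0)
  }
  detail <- if (config$fidelity == "low") 8L else 12L
  shadows <- config$fidelity != "low"
  img_dir <- file.path(config$out_dir, "images")
  guard <- config$camera$resolution < config$tile_size
  for (k in seq_len(nrow(specs))) {
    scene <- build_canopy(specs[k, ], detail = detail)
    sample <- render_sample(scene, config$camera, config$light,
                            seed = specs$seed[k], shadows = shadows)
    if (write) write_sample(sample, img_dir, specs$id[k])
    if (!is.null(callback)) callback(sample, specs[k, ])
  }
  if (write) {
    run_log(config$out_dir, "simulate", list(
      crop = config$crop, n_samples = config$n_samples,
      n_stages = config$n_stages, n_rendered = nrow(specs),
      resolution = config$camera$resolution, seed = config$seed,
      tile_size_guard = guard
    ))
  }
  if (guard) {
    warn(sprintf("rendered resolution %d is below tile_size %d: tiling will produce 0 tiles",
                 config$camera$resolution, config$tile_size))
  }
  specs
}

#' Tile every rendered sample of a run
#'
#' @param config A [run_config()] whose `out_dir/images` holds
#'   rendered samples.
#' @return Number of tiles written (invisibly `0` with a warning when
#'   the source images are smaller than the tile size).
#' @export
tile_dataset <- function(config) {
  stopifnot(inherits(config, "run_config"))
  img_dir <- file.path(config$out_dir, "images")
  tile_dir <- file.path(config$out_dir, "tiles")
  ids <- sub("_rgb\\.png$", "",
             list.files(img_dir, pattern = "_rgb\\.png$"))
  n_tiles <- 0L
  for (id in ids) {
    s <- read_sample(img_dir, id)
    if (nrow(s$mask) < config$tile_size || ncol(s$mask) < config$tile_size) next
    tiles <- tile_sample(s$rgb, s$mask, config$tile_size)
    write_tiles(tiles, tile_dir, id)
    n_tiles <- n_tiles + nrow(tiles)
  }
  if (n_tiles == 0L && length(ids)) {
    warn("no tiles produced: source images are smaller than the tile size")
  }
  run_log(config$out_dir, "tile", list(
    n_sources = length(ids), n_tiles = n_tiles,
    tile_size = config$tile_size, seed = config$seed
  ))
  n_tiles
}

#' Run the full simulate / tile / split pipeline
#'
#' Chains [simulate_dataset()], [tile_dataset()] and
#' [build_manifest()] under one config and seed; every stage writes a
#' machine-readable JSON log under `out_dir`.
#'
#' @param config A [run_config()].
#' @param split_fractions Passed to [build_manifest()].
#' @return The dataset manifest (or `NULL` when no tiles were
#'   produced).
#' @export
run_pipeline <- function(config,
                         split_fractions = c(train = 0.8, val = 0.1, test = 0.1)) {
  simulate_dataset(config, write = TRUE)
  n_tiles <- tile_dataset(config)
  if (n_tiles == 0L) return(invisible(NULL))
  manifest <- build_manifest(file.path(config$out_dir, "tiles"),
                             split_fractions,
                             seed = stage_seed(config$seed, "split"),
                             tag = config$crop)
  write_manifest(manifest, file.path(config$out_dir, "manifest.json"))
  run_log(config$out_dir, "split", list(
    counts = as.list(attr(manifest, "counts")), seed = config$seed
  ))
  manifest
}
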