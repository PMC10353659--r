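#' Camera configuration
#'
#' Pinhole camera above the background plane `z = 0`. The default
#' matches the simulated capture regime: 1.5 m above the plane, 85
#' degree horizontal field of view, inclined 45 degrees from nadir,
#' 1,024 x 1,024 pixels. The camera is positioned so its optical axis
#' passes through the plot centre at the stated zenith angle.
#'
#' @param height Height above the background plane (m, > 0).
#' @param fov Horizontal field of view (degrees, 0 < fov < 180).
#' @param inclination Zenith angle of the optical axis (degrees,
#'   0 = straight down, up to 90).
#' @param resolution Square image side in pixels (>= 16).
#' @param azimuth Horizontal heading of the view direction (degrees).
#' @return A `camera_config`.
#' @examples
#' cam <- camera_config()
#' ground_sample_distance(camera_config(inclination = 0))
#' @export
camera_config <- function(height = 1.5, fov = 85, inclination = 45,
                          resolution = 1024L, azimuth = 0) {
  stopifnot_scalar_number(height, "height", lower = 1e-6)
  stopifnot_scalar_number(fov, "fov", lower = 1e-6, upper = 180 - 1e-6)
  stopifnot_scalar_number(inclination, "inclination", lower = 0, upper = 90)
  stopifnot_scalar_number(azimuth, "azimuth")
  if (resolution < 16 || resolution != round(resolution)) {
    abort("`resolution` must be an integer >= 16.")
  }
  structure(list(height = height, fov = fov, inclination = inclination,
                 resolution = as.integer(resolution), azimuth = azimuth),
            class = "camera_config")
}

#' @export
print.camera_config <- function(x, ...) {
  cat(sprintf("<camera: %.2f m, fov %.0f deg, inclined %.0f deg, %d px>\n",
              x$height, x$fov, x$inclination, x$resolution))
  invisible(x)
}

#' Illumination configuration
#'
#' Sunny conditions combine a directional sun beam (casting hard
#' shadows) with a small diffuse sky term; cloudy conditions are
#' dominated by the diffuse term. The diffuse fraction is constrained
#' accordingly: below 0.5 when sunny, at least 0.8 when cloudy.
#'
#' @param condition `"sunny"` or `"cloudy"`.
#' @param sun_elevation Sun elevation above the horizon (degrees).
#' @param sun_azimuth Sun azimuth (degrees).
#' @param diffuse_fraction Fraction of irradiance that is diffuse sky
#'   light; defaults to 0.25 (sunny) or 0.9 (cloudy).
#' @return A `light_config`.
#' @export
light_config <- function(condition = c("sunny", "cloudy"),
                         sun_elevation = 50, sun_azimuth = 135,
                         diffuse_fraction = NULL) {
  condition <- match.arg(condition)
  diffuse_fraction <- diffuse_fraction %||%
    if (condition == "sunny") 0.25 else 0.9
  stopifnot_scalar_number(sun_elevation, "sun_elevation", lower = 0, upper = 90)
  stopifnot_scalar_number(sun_azimuth, "sun_azimuth")
  stopifnot_scalar_number(diffuse_fraction, "diffuse_fraction", 0, 1)
  if (condition == "sunny" && diffuse_fraction >= 0.5) {
    abort("sunny conditions require diffuse_fraction < 0.5")
  }
  if (condition == "cloudy" && diffuse_fraction < 0.8) {
    abort("cloudy conditions require diffuse_fraction >= 0.8")
  }
  structure(list(condition = condition, sun_elevation = sun_elevation,
                 sun_azimuth = sun_azimuth,
                 diffuse_fraction = diffuse_fraction),
            class = "light_config")
}

# Orthonormal camera frame; optical axis through `target` on z = 0.
camera_basis <- function(camera, target = c(0, 0, 0)) {
  i <- camera$inclination * pi / 180
  a <- camera$azimuth * pi / 180
  fwd <- c(sin(i) * cos(a), sin(i) * sin(a), -cos(i))
  pos <- c(target[1], target[2], 0) - fwd * (camera$height / cos(i))
  right <- c(-sin(a), cos(a), 0)
  up <- c(cos(a) * cos(i), sin(a) * cos(i), sin(i))
  focal <- (camera$resolution / 2) / tan(camera$fov * pi / 360)
  list(pos = pos, fwd = fwd, right = right, up = up, focal = focal)
}

#' Pinhole projection of world points
#'
#' Projects 3D world points (metres, background plane at `z = 0`)
#' through the camera to continuous pixel coordinates. Pixel `(0, 0)`
#' is top-left and pixel centres sit at half-integer coordinates, so a
#' point on the optical axis maps to `(resolution/2, resolution/2)`.
#' Points at or behind the camera plane are flagged `behind`; points
#' outside the frustum map outside `[0, resolution)`.
#'
#' @param points Length-3 vector or `n x 3` matrix of world points.
#' @param camera A [camera_config()].
#' @param target Point on `z = 0` the optical axis passes through.
#' @return A tibble with columns `u`, `v` (pixels), `depth` (m along
#'   the optical axis) and `behind`.
#' @export
project <- function(points, camera, target = c(0, 0, 0)) {
  stopifnot(inherits(camera, "camera_config"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (ncol(points) != 3) abort("`points` must have 3 columns")
  b <- camera_basis(camera, target)
  d <- sweep(points, 2, b$pos)
  if (any(rowSums(d^2) < 1e-18)) abort("point coincides with the camera origin")
  z <- as.vector(d %*% b$fwd)
  x <- as.vector(d %*% b$right)
  y <- as.vector(d %*% b$up)
  half <- camera$resolution / 2
  behind <- z <= 1e-9
  zz <- ifelse(behind, NA_real_, z)
  tibble(
    u = half + b$focal * x / zz,
    v = half - b$focal * y / zz,
    depth = z,
    behind = behind
  )
}

#' Ground sample distance at the image centre
#'
#' Physical footprint of one pixel where the optical axis meets the
#' background plane, in mm/pixel:
#' `1000 * 2 * (height / cos(inclination)) * tan(fov / 2) / resolution`.
#'
#' @inheritParams project
#' @return GSD in mm/pixel.
#' @examples
#' ground_sample_distance(camera_config(inclination = 0))  # ~2.68
#' @export
ground_sample_distance <- function(camera) {
  stopifnot(inherits(camera, "camera_config"))
  if (camera$inclination >= 90 - 1e-9) {
    abort("grazing geometry: inclination must be < 90 degrees")
  }
  i <- camera$inclination * pi / 180
  1000 * 2 * (camera$height / cos(i)) * tan(camera$fov * pi / 360) /
    camera$resolution
}

#' Render a canopy scene to an RGB image and its green mask
#'
#' Deterministic z-buffered rasterization with Lambertian shading (plus
#' a hard shadow term under sunny skies) and a supersampled label pass:
#' a pixel is labelled green when the majority of a 4 x 4 subpixel grid
#' is covered by a green-vegetation primitive (ties go to background).
#' Image and mask come from the same projected geometry, so they are
#' aligned by construction, and the mask depends only on geometry —
#' changing the illumination changes the image but never the mask.
#'
#' @param scene A [build_canopy()] scene.
#' @param camera A [camera_config()].
#' @param light A [light_config()].
#' @param seed Integer seed for the deterministic background texture.
#' @param shadows Render hard sun shadows when sunny.
#' @param subsamples Side of the subpixel label grid.
#' @return A `rendered_sample`: `rgb` (8-bit integer `H x W x 3`),
#'   `mask` (logical `H x W`), and `meta` (parameters, camera, light,
#'   seed, ground sample distance).
#' @examples
#' p <- list(crop = "wheat", plant_density = 60, row_spacing = 0.15,
#'           tillers_per_plant = 2, leaves_per_tiller = 3,
#'           leaf_length = 0.15, leaf_max_width = 0.008,
#'           leaf_inclination = 55, leaf_curvature = 1,
#'           plant_height = 0.3, growth_stage = 4, n_stages = 4, seed = 7)
#' s <- render_sample(build_canopy(p), camera_config(resolution = 64),
#'                    light_config("cloudy"), seed = 1)
#' green_fraction(s$mask)
#' @export
render_sample <- function(scene, camera = camera_config(),
                          light = light_config(), seed = 1L,
                          shadows = TRUE, subsamples = 4L) {
  stopifnot(inherits(scene, "canopy_scene"))
  stopifnot(inherits(camera, "camera_config"))
  stopifnot(inherits(light, "light_config"))
  b <- camera_basis(camera)
  el <- light$sun_elevation * pi / 180
  az <- light$sun_azimuth * pi / 180
  sun <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  bg <- scene$background
  if (bg$type == "soil") {
    bg_type <- 1L
    bg_params <- c(bg$albedo, bg$noise_scales)
  } else {
    bg_type <- 2L
    bg_params <- c(bg$base_gray, bg$specular_strength, bg$shininess, 0, 0)
  }
  sunny <- light$condition == "sunny"
  out <- raster_scene_cpp(
    scene$primitives, scene$colors,
    b$pos, b$fwd, b$right, b$up, b$focal, camera$resolution,
    bg_type, bg_params,
    as.integer(sunny && shadows), sun, light$diffuse_fraction,
    as.integer(subsamples), as.integer(seed)
  )
  structure(list(
    rgb = out$rgb,
    mask = out$mask,
    meta = list(
      params = scene$params,
      camera = unclass(camera),
      light = unclass(light),
      seed = as.integer(seed),
      gsd_mm_per_pixel = ground_sample_distance(camera)
    )
  ), class = "rendered_sample")
}

#' @export
print.rendered_sample <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<rendered_sample: %d x %d, green fraction %.3f>\n",
              d[1], d[2], mean(x$mask)))
  invisible(x)
}

#' Write / read a rendered sample
#'
#' Persists the paired artefacts `<id>_rgb.png`, `<id>_mask.png`
#' (0/255) and `<id>_meta.json`; `read_sample()` round-trips them.
#'
#' @param sample A `rendered_sample`.
#' @param dir Output directory (created if missing).
#' @param id Sample identifier used as the file stem.
#' @return `write_sample()` returns the three paths invisibly;
#'   `read_sample()` returns a `rendered_sample`.
#' @export
write_sample <- function(sample, dir, id) {
  stopifnot(inherits(sample, "rendered_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(id, c("_rgb.png", "_mask.png", "_meta.json")))
  write_rgb_png(sample$rgb, paths[1])
  write_mask_png(sample$mask, paths[2])
  jsonlite::write_json(sample$meta, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir, id) {
  paths <- file.path(dir, paste0(id, c("_rgb.png", "_mask.png", "_meta.json")))
  structure(list(
    rgb = read_rgb_png(paths[1]),
    mask = read_mask_png(paths[2]),
    meta = jsonlite::read_json(paths[3], simplifyVector = TRUE)
  ), class = "rendered_sample")
}
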