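# Shared fixtures, all built in code.

wheat_params <- function(seed = 7L, growth_stage = 4L, ...) {
  utils::modifyList(list(
    crop = "wheat", plant_density = 60, row_spacing = 0.15,
    plant_jitter = 0.01, tillers_per_plant = 2, leaves_per_tiller = 3,
    leaf_length = 0.18, leaf_max_width = 0.008, leaf_inclination = 55,
    leaf_curvature = 1.0, plant_height = 0.35, green_hue = 0.5,
    green_sat = 0.6, growth_stage = growth_stage, n_stages = 4L,
    seed = seed
  ), list(...))
}

rice_params <- function(seed = 7L, growth_stage = 4L, ...) {
  utils::modifyList(wheat_params(seed, growth_stage,
    crop = "rice", plant_density = 24, row_spacing = 0.25,
    tillers_per_plant = 6, leaf_length = 0.4, leaf_curvature = 1.8,
    plant_height = 0.7
  ), list(...))
}

small_camera <- function(resolution = 96L, inclination = 45, ...) {
  camera_config(resolution = resolution, inclination = inclination, ...)
}

# Scene made of explicit triangles (all green vegetation).
raw_scene <- function(triangles, background = "soil", colors = NULL) {
  tri <- matrix(as.numeric(triangles), ncol = 9)
  if (is.null(colors)) {
    colors <- matrix(rep(c(0.25, 0.55, 0.15), each = nrow(tri)), ncol = 3)
  }
  bg <- if (background == "water") {
    list(type = "water", base_gray = 0.72, specular_strength = 0.55,
         shininess = 120)
  } else {
    list(type = "soil", albedo = c(0.46, 0.34, 0.21), noise_scales = c(30, 140))
  }
  structure(list(
    primitives = tri, colors = colors,
    organ_class = rep("green_vegetation", nrow(tri)),
    background = bg, plot_extent = c(2, 2), params = list(seed = 1L)
  ), class = "canopy_scene")
}

# Axis-aligned horizontal square [x0,x1] x [y0,y1] at height z.
square_tris <- function(x0, x1, y0, y1, z) {
  rbind(
    c(x0, y0, z, x1, y0, z, x1, y1, z),
    c(x0, y0, z, x1, y1, z, x0, y1, z)
  )
}

rand_mask <- function(n = 16L, p = 0.5) {
  matrix(stats::runif(n * n) < p, n, n)
}

# A small clean rendered sample for reuse across tests.
clean_sample <- function(seed = 3L, resolution = 128L, crop = "wheat",
                         sunny = FALSE) {
  p <- if (crop == "wheat") wheat_params(seed) else rice_params(seed)
  scene <- build_canopy(p, detail = 8L)
  light <- if (sunny) light_config("sunny") else light_config("cloudy")
  render_sample(scene, small_camera(resolution), light, seed = seed,
                shadows = sunny)
}
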