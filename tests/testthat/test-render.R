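test_that("pinhole projection matches the closed form", {
  res <- 1024L
  cam <- camera_config(height = 1.5, fov = 85, inclination = 0,
                       resolution = res)
  # optical axis -> image centre
  ctr <- project(c(0, 0, 0), cam)
  expect_equal(c(ctr$u, ctr$v), c(res / 2, res / 2))

  # view angle = fov/2 -> frame edge (image-right is +y at azimuth 0)
  edge_x <- 1.5 * tan(42.5 * pi / 180)
  e <- project(c(0, edge_x, 0), cam)
  expect_equal(e$u, res, tolerance = 1e-9)
  e2 <- project(c(0, -edge_x, 0), cam)
  expect_equal(e2$u, 0, tolerance = 1e-9)

  # independently computed closed-form offset for a 0.5 m off-axis point
  off <- project(c(0, 0.5, 0), cam)
  oracle <- res / 2 + (res / 2) * (0.5 / 1.5) / tan(42.5 * pi / 180)
  expect_equal(off$u, oracle, tolerance = 1e-9)

  # behind-camera points are flagged
  b <- project(c(0, 0, 3), cam)
  expect_true(b$behind)
  expect_error(project(c(0, 0, 1.5), cam), "origin")
})

test_that("ground sample distance follows the stated geometry", {
  gsd <- function(h, fov, incl, res) {
    1000 * 2 * (h / cos(incl * pi / 180)) * tan(fov * pi / 360) / res
  }
  cam0 <- camera_config(1.5, 85, 0, 1024)
  expect_equal(ground_sample_distance(cam0), gsd(1.5, 85, 0, 1024))
  expect_equal(ground_sample_distance(cam0), 2.68, tolerance = 0.01)
  # doubling resolution halves GSD
  expect_equal(ground_sample_distance(camera_config(1.5, 85, 0, 2048)),
               ground_sample_distance(cam0) / 2)
  # 60 degrees doubles the slant range and hence the GSD
  expect_equal(ground_sample_distance(camera_config(1.5, 85, 60, 1024)),
               2 * ground_sample_distance(cam0))
})

test_that("camera and light configs validate their invariants", {
  expect_error(camera_config(fov = 180), "fov")
  expect_error(camera_config(resolution = 8), "resolution")
  expect_error(light_config("sunny", diffuse_fraction = 0.7), "< 0.5")
  expect_error(light_config("cloudy", diffuse_fraction = 0.5), ">= 0.8")
  expect_equal(light_config("cloudy")$diffuse_fraction, 0.9)
})

test_that("an empty scene renders to an all-background mask", {
  sc <- build_canopy(wheat_params(plant_density = 0))
  s <- render_sample(sc, small_camera(64), light_config("cloudy"), seed = 1)
  expect_false(any(s$mask))
  expect_equal(green_fraction(s$mask), 0)
})

test_that("a leaf filling the frustum gives an all-green mask", {
  sc <- raw_scene(square_tris(-60, 60, -60, 60, 0.4))
  s <- render_sample(sc, small_camera(64, inclination = 0),
                     light_config("cloudy"), seed = 1)
  expect_true(all(s$mask))
  expect_equal(green_fraction(s$mask), 1)
})

test_that("mask coverage matches a point-in-polygon oracle for a unit square", {
  res <- 64L
  cam <- camera_config(height = 1.5, fov = 85, inclination = 0,
                       resolution = res)
  sc <- raw_scene(square_tris(-0.5, 0.5, -0.5, 0.5, 0.2))
  s <- render_sample(sc, cam, light_config("cloudy"), seed = 1)

  # oracle: project pixel centres to the z = 0.2 plane and test the square
  half <- res / 2
  focal <- half / tan(cam$fov * pi / 360)
  centers <- expand.grid(px = seq_len(res) - 0.5, py = seq_len(res) - 0.5)
  # nadir camera at (0,0,1.5): fwd (0,0,-1), right (0,1,0), up (1,0,0)
  xr <- (centers$px - half) / focal    # along right = +y
  yu <- -(centers$py - half) / focal   # along up = +x
  zf <- 1.5 - 0.2
  wx <- yu * zf
  wy <- xr * zf
  inside <- abs(wx) <= 0.5 & abs(wy) <= 0.5
  oracle_count <- sum(inside)
  perimeter_px <- 4 * (1 / (zf * tan(cam$fov * pi / 360) * 2 / res)) / 1
  expect_lt(abs(sum(s$mask) - oracle_count), perimeter_px + 4)
})

test_that("rendering is bit-identical for identical inputs", {
  sc <- build_canopy(wheat_params(seed = 5), detail = 8L)
  a <- render_sample(sc, small_camera(96), light_config("sunny"), seed = 9)
  b <- render_sample(sc, small_camera(96), light_config("sunny"), seed = 9)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$mask, b$mask)
})

test_that("illumination changes the image but never the mask", {
  sc <- build_canopy(wheat_params(seed = 11), detail = 8L)
  cam <- small_camera(96)
  sunny <- render_sample(sc, cam, light_config("sunny"), seed = 2)
  cloudy <- render_sample(sc, cam, light_config("cloudy"), seed = 2)
  dusk <- render_sample(sc, cam, light_config("sunny", sun_elevation = 15),
                        seed = 2)
  expect_identical(sunny$mask, cloudy$mask)
  expect_identical(sunny$mask, dusk$mask)
  expect_false(identical(sunny$rgb, cloudy$rgb))
})

test_that("adding a green triangle never turns green pixels to background", {
  sc <- build_canopy(wheat_params(seed = 13, plant_density = 20), detail = 8L)
  cam <- small_camera(96)
  base <- render_sample(sc, cam, light_config("cloudy"), seed = 1)
  sc2 <- sc
  sc2$primitives <- rbind(sc$primitives, square_tris(-0.3, 0.1, -0.2, 0.2, 0.25))
  sc2$colors <- rbind(sc$colors, matrix(rep(c(0.2, 0.5, 0.1), each = 2), ncol = 3))
  more <- render_sample(sc2, cam, light_config("cloudy"), seed = 1)
  expect_true(all(more$mask[base$mask]))
})

test_that("mask green fraction is conserved exactly against pixel counts", {
  for (seed in 1:3) {
    s <- clean_sample(seed, resolution = 96)
    expect_identical(green_fraction(s$mask), sum(s$mask) / length(s$mask))
  }
})

test_that("rendered samples round-trip through PNG + JSON files", {
  s <- clean_sample(2, resolution = 64)
  dir <- withr::local_tempdir()
  write_sample(s, dir, "demo")
  r <- read_sample(dir, "demo")
  expect_identical(r$rgb, s$rgb)
  expect_identical(r$mask, s$mask)
  expect_equal(r$meta$camera$resolution, 64)
  expect_equal(r$meta$gsd_mm_per_pixel, s$meta$gsd_mm_per_pixel)
})
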