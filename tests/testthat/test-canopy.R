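test_that("leaf count equals rows x plants-per-row from the placement rule", {
  # density 100 m^-2 on a 1 x 1 m plot with one leaf per plant
  p <- wheat_params(plant_density = 100, row_spacing = 0.2,
                    plant_jitter = 0, tillers_per_plant = 1,
                    leaves_per_tiller = 1, leaf_curvature = 0.2,
                    growth_stage = 4)
  sc <- build_canopy(p, plot_extent = c(1, 1), detail = 12L)
  n_seg <- nrow(sc$primitives) / (2 * 100)
  expect_equal(n_seg, round(n_seg))  # uniform segments per leaf
  expect_equal(nrow(sc$primitives) / (2 * n_seg), 100)

  # independent count oracle: rows x per-row occupancy
  n_rows <- floor(1 / 0.2)
  expect_equal(sum(rep(100 %/% n_rows, n_rows)) + 100 %% n_rows, 100)
})

test_that("zero density gives a legal empty scene", {
  sc <- build_canopy(wheat_params(plant_density = 0))
  expect_equal(nrow(sc$primitives), 0)
  expect_equal(scene_leaf_area(sc), 0)
  expect_equal(sc$background$type, "soil")
})

test_that("background follows the crop and can be overridden", {
  expect_equal(build_canopy(rice_params())$background$type, "water")
  expect_equal(build_canopy(wheat_params())$background$type, "soil")
  expect_equal(build_canopy(rice_params(), background = "soil")$background$type,
               "soil")
})

test_that("straight-leaf limits are exact", {
  # vertical planar strip: tip height = base height + length
  tri <- leaf_surface(0.3, 0.01, inclination = 90, curvature = 0)
  z <- tri[, c(3, 6, 9)]
  expect_equal(max(z), 0.3, tolerance = 1e-12)
  # horizontal strip: all z equal; nadir-projected area = mesh area
  tri <- leaf_surface(0.3, 0.01, inclination = 0, curvature = 0)
  expect_equal(max(abs(tri[, c(3, 6, 9)])), 0, tolerance = 1e-12)

  # zero curvature leaves the midrib collinear at any inclination
  tri <- leaf_surface(0.3, 0.01, inclination = 40, curvature = 0)
  x <- as.vector(tri[, c(1, 4, 7)])
  z <- as.vector(tri[, c(3, 6, 9)])
  expect_lt(max(abs(z - x * tan(40 * pi / 180))), 1e-12)
})

test_that("drooping midrib follows the tangent-angle law (numeric ODE oracle)", {
  len <- 0.4; incl <- 60; curv <- 4
  # oracle: integrate dz/ds = sin(theta0 - curv * s / len) by fine Riemann sum
  s <- seq(0, len, length.out = 20001)
  th <- incl * pi / 180 - curv * s / len
  tip_z_oracle <- sum(sin(th[-1]) + sin(th[-length(th)])) / 2 * (s[2] - s[1])
  tip_x_oracle <- sum(cos(th[-1]) + cos(th[-length(th)])) / 2 * (s[2] - s[1])

  tri <- leaf_surface(len, 0.02, inclination = incl, curvature = curv,
                      n_seg = 64)
  # the tip ring is degenerate (width 0): take the farthest vertex arc-wise
  tip_z <- tri[nrow(tri), 9]
  tip_x <- tri[nrow(tri), 7]
  expect_equal(tip_z, tip_z_oracle, tolerance = 1e-4)
  expect_equal(tip_x, tip_x_oracle, tolerance = 1e-4)
  expect_lt(tip_z, 0)  # strong droop carries the tip below the base
})

test_that("mesh area stays within 5% of the analytic strip area", {
  cases <- expand.grid(incl = c(0, 30, 60, 85), curv = c(0, 0.8, 2.5))
  for (k in seq_len(nrow(cases))) {
    tri <- leaf_surface(0.35, 0.012, cases$incl[k], cases$curv[k])
    ux <- tri[, 4] - tri[, 1]; uy <- tri[, 5] - tri[, 2]; uz <- tri[, 6] - tri[, 3]
    vx <- tri[, 7] - tri[, 1]; vy <- tri[, 8] - tri[, 2]; vz <- tri[, 9] - tri[, 3]
    area <- sum(sqrt((uy * vz - uz * vy)^2 + (uz * vx - ux * vz)^2 +
                     (ux * vy - uy * vx)^2)) / 2
    expect_equal(area, 0.5 * 0.012 * 0.35, tolerance = 0.05)
  }
})

test_that("identical parameters give identical scenes", {
  a <- build_canopy(wheat_params(seed = 42))
  b <- build_canopy(wheat_params(seed = 42))
  expect_identical(a$primitives, b$primitives)
  expect_identical(a$colors, b$colors)
  c <- build_canopy(wheat_params(seed = 43))
  expect_false(identical(a$primitives, c$primitives))
})

test_that("doubling plant density never decreases total leaf area", {
  for (seed in 1:5) {
    base <- wheat_params(seed = seed, plant_density = 30 + 10 * seed)
    lo <- scene_leaf_area(build_canopy(base))
    hi <- scene_leaf_area(build_canopy(
      utils::modifyList(base, list(plant_density = base$plant_density * 2))))
    expect_gte(hi, lo)
  }
})

test_that("scene leaf area is non-decreasing in growth stage", {
  for (seed in 1:5) {
    areas <- vapply(1:4, function(g) {
      scene_leaf_area(build_canopy(wheat_params(seed = seed, growth_stage = g)))
    }, numeric(1))
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("invalid canopy parameters are rejected", {
  expect_error(build_canopy(wheat_params(leaf_length = -1)), ">= 0")
  expect_error(build_canopy(wheat_params(leaf_inclination = 120)), "0, 90")
  expect_error(build_canopy(wheat_params(leaf_curvature = -0.1)), ">= 0")
  expect_error(build_canopy(wheat_params(growth_stage = 9)), "n_stages")
})

test_that("scenes round-trip through the JSON mesh format", {
  sc <- build_canopy(rice_params(plant_density = 6), detail = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_json(sc, path)
  sc2 <- read_scene_json(path)
  expect_equal(sc2$primitives, sc$primitives, tolerance = 1e-12)
  expect_equal(sc2$background$type, "water")
  expect_equal(sc2$organ_class, sc$organ_class)
})
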