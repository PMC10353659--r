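test_that("excess green follows 2G - R - B on raw digital numbers", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(exg_map(px(0, 255, 0))[1, 1], 510)
  expect_equal(exg_map(px(128, 128, 128))[1, 1], 0)
  expect_equal(exg_map(px(255, 0, 0))[1, 1], -255)
  expect_equal(exg_map(px(0, 0, 255))[1, 1], -255)
  # pure per-pixel map: permuting pixels permutes outputs identically
  set.seed(1)
  img <- array(sample.int(256, 8 * 8 * 3, TRUE) - 1L, c(8, 8, 3))
  perm <- sample(64)
  permuted <- array(0L, c(8, 8, 3))
  for (ch in 1:3) permuted[, , ch] <- matrix(img[, , ch][perm], 8, 8)
  expect_identical(matrix(exg_map(img)[perm], 8, 8), exg_map(permuted))
})

test_that("CIELAB lightness matches an independent reference conversion", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(lightness_map(px(255, 255, 255))[1, 1], 100, tolerance = 1e-6)
  expect_equal(lightness_map(px(0, 0, 0))[1, 1], 0, tolerance = 1e-9)
  expect_equal(lightness_map(px(255, 0, 0))[1, 1], 53.24, tolerance = 1e-3)
  # farver as the independent oracle across random colours
  set.seed(2)
  img <- array(sample.int(256, 5 * 5 * 3, TRUE) - 1L, c(5, 5, 3))
  ours <- lightness_map(img)
  ref <- farver::convert_colour(
    cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3])),
    "rgb", "lab")[, 1]
  expect_equal(as.vector(ours), ref, tolerance = 1e-4)
})

test_that("error maps agree exactly with confusion counts and a per-pixel oracle", {
  set.seed(3)
  for (trial in 1:25) {
    pred <- rand_mask(8)
    truth <- rand_mask(8)
    em <- error_map(pred, truth)
    counts <- error_class_counts(em)
    cc <- confusion_counts(pred, truth)
    expect_identical(unname(counts / 64),
                     c(cc$tp, cc$fp, cc$fn, cc$tn))
    # exhaustive per-pixel oracle
    oracle <- matrix(NA_character_, 8, 8)
    for (k in 1:64) {
      oracle[k] <- if (pred[k] && truth[k]) "TP"
        else if (pred[k] && !truth[k]) "FP"
        else if (!pred[k] && truth[k]) "FN" else "TN"
    }
    expect_identical(attr(em, "levels")[unclass(em)], as.vector(oracle))
  }
  m <- rand_mask(6)
  expect_setequal(attr(error_map(m, m), "levels")[unique(as.vector(unclass(error_map(m, m))))],
                  c("TP", "TN"))
  all_fp <- error_map(matrix(TRUE, 4, 4), matrix(FALSE, 4, 4))
  expect_true(all(attr(all_fp, "levels")[unclass(all_fp)] == "FP"))
})

test_that("class densities integrate to one and recover the normal density", {
  set.seed(4)
  # N(0,1) oracle: density at 0 within 10% of 1/sqrt(2*pi)
  v <- matrix(rnorm(10000), 100, 100)
  em <- error_map(matrix(TRUE, 100, 100), matrix(TRUE, 100, 100))  # all TP
  d <- class_density(v, em, "TP")
  expect_false(attr(d, "absent"))
  integral <- sum(diff(d$grid) * (head(d$density, -1) + d$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 0.02)
  at0 <- d$density[which.min(abs(d$grid))]
  expect_equal(at0, 1 / sqrt(2 * pi), tolerance = 0.1)

  # near-constant values give a unimodal peak at that value
  v2 <- matrix(50 + rnorm(10000, 0, 1e-3), 100, 100)
  d2 <- class_density(v2, em, "TP")
  expect_equal(d2$grid[which.max(d2$density)], 50, tolerance = 1e-2)

  # absent class -> explicit absent result, not an error
  d3 <- class_density(v, em, "FN")
  expect_true(attr(d3, "absent"))
  expect_equal(nrow(d3), 0)
})

test_that("class_densities pools the present classes for plotting", {
  set.seed(5)
  pred <- rand_mask(24); truth <- rand_mask(24)
  em <- error_map(pred, truth)
  vals <- matrix(rnorm(576), 24, 24)
  dens <- class_densities(vals, em)
  expect_true(all(dens$class %in% c("TP", "FP", "FN", "TN")))
  for (cl in unique(dens$class)) {
    sub <- dens[dens$class == cl, ]
    integral <- sum(diff(sub$grid) * (head(sub$density, -1) + sub$density[-1]) / 2)
    expect_equal(integral, 1, tolerance = 0.02)
  }
  expect_s3_class(plot_class_densities(dens), "ggplot")
})

test_that("error overlays are bijective and round-trip the class map", {
  set.seed(6)
  em <- error_map(rand_mask(16), rand_mask(16))
  overlay <- render_error_overlay(em)
  decoded <- decode_error_overlay(overlay)
  expect_identical(unclass(decoded), unclass(em))
  # all-TN map -> a single uniform colour
  tn <- error_map(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4))
  otn <- render_error_overlay(tn)
  expect_equal(length(unique(matrix(otn, 16, 3, byrow = FALSE))), 3)
  # checkerboard TP/FP -> exactly two colours
  truth <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)
  cb <- error_map(matrix(TRUE, 4, 4), truth)
  ocb <- render_error_overlay(cb)
  keys <- unique(as.vector(ocb[, , 1]) * 65536 +
                 as.vector(ocb[, , 2]) * 256 + as.vector(ocb[, , 3]))
  expect_length(keys, 2)
  # file round trip with the sidecar legend
  path <- withr::local_tempfile(fileext = ".png")
  write_error_overlay(em, path)
  expect_true(file.exists(paste0(path, ".legend.json")))
  back <- decode_error_overlay(png::readPNG(path))
  expect_identical(unclass(back), unclass(em))
  expect_s3_class(autoplot(em), "ggplot")
})

test_that("green pixels render brighter than the background on shadowed scenes", {
  # seeded fixture property: mean L* of TP exceeds mean L* of TN when the
  # baseline segments a sunny, shadow-casting render
  for (seed in c(21, 22)) {
    s <- clean_sample(seed, resolution = 128, crop = "wheat", sunny = TRUE)
    pred <- segment_exg_otsu(s$rgb)
    em <- error_map(pred, s$mask)
    L <- lightness_map(s$rgb)
    lv <- attr(em, "levels")
    mean_tp <- mean(L[unclass(em) == match("TP", lv)])
    mean_tn <- mean(L[unclass(em) == match("TN", lv)])
    expect_gt(mean_tp, mean_tn)
  }
})
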