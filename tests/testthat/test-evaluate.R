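test_that("confusion proportions match brute-force counting on random mask pairs", {
  set.seed(42)
  for (trial in seq_len(1000)) {
    pred <- rand_mask(16)
    truth <- rand_mask(16)
    cc <- confusion_counts(pred, truth)
    # brute force: loop-free but element-wise reference count
    n <- 256
    ref <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (k in seq_len(n)) {
      ref[if (pred[k] && truth[k]) "tp"
          else if (!pred[k] && !truth[k]) "tn"
          else if (pred[k]) "fp" else "fn"] <-
        ref[if (pred[k] && truth[k]) "tp"
            else if (!pred[k] && !truth[k]) "tn"
            else if (pred[k]) "fp" else "fn"] + 1
    }
    expect_identical(c(cc$tp, cc$tn, cc$fp, cc$fn), unname(ref) / n)
    m <- pixel_metrics(cc)
    expect_identical(m$accuracy, (ref[["tp"]] + ref[["tn"]]) / n)
    denom <- 2 * ref[["tp"]] + ref[["fp"]] + ref[["fn"]]
    expect_identical(m$f1, if (denom == 0) 0 else 2 * ref[["tp"]] / denom)
  }
})

test_that("confusion identities hold at the extremes", {
  m <- rand_mask(8)
  perfect <- confusion_counts(m, m)
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_equal(perfect$tp + perfect$tn, 1)
  worst <- confusion_counts(!m, m)
  expect_equal(worst$tp + worst$tn, 0)
  # 2x2 worked example: one pixel per class
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, byrow = TRUE)
  pred <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, byrow = TRUE)
  cc <- confusion_counts(pred, truth)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), rep(0.25, 4))
  expect_error(confusion_counts(rand_mask(4), rand_mask(8)), "dimensions")
})

test_that("metrics pool across images exactly like concatenation", {
  set.seed(9)
  a_pred <- rand_mask(12); a_truth <- rand_mask(12)
  b_pred <- rand_mask(20, 0.3); b_truth <- rand_mask(20, 0.7)
  pooled <- pool_confusion(confusion_counts(a_pred, a_truth),
                           confusion_counts(b_pred, b_truth))
  concat <- confusion_counts(rbind(matrix(a_pred, 144), matrix(b_pred, 400)),
                             rbind(matrix(a_truth, 144), matrix(b_truth, 400)))
  expect_equal(c(pooled$tp, pooled$tn, pooled$fp, pooled$fn),
               c(concat$tp, concat$tn, concat$fp, concat$fn))
  expect_equal(pooled$n_pixels, 544)
})

test_that("green fraction is the exact pixel count ratio", {
  m <- matrix(FALSE, 512, 512)
  expect_equal(green_fraction(m), 0)
  m[seq_len(131072)] <- TRUE
  expect_equal(green_fraction(m), 0.5)
  expect_error(green_fraction(matrix(logical(0), 0, 0)), "empty")
})

test_that("regression metrics follow their formulas", {
  expect_equal(regression_metrics(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9)),
               tibble::tibble(r_squared = 1, rmse = 0, n = 3L))
  off <- regression_metrics(c(0.2, 0.5, 0.9) + 0.1, c(0.2, 0.5, 0.9))
  expect_equal(off$rmse, 0.1)
  # hand-evaluated example
  ex <- regression_metrics(c(0.1, 0.2, 0.6), c(0.1, 0.2, 0.3))
  expect_equal(ex$rmse, sqrt(0.09 / 3))
  expect_equal(ex$r_squared, 1 - 0.09 / 0.02)
  # constant reference: R^2 undefined, reported as NA
  const <- regression_metrics(c(0.1, 0.2), c(0.5, 0.5))
  expect_true(is.na(const$r_squared))
  expect_equal(const$rmse, sqrt(mean(c(0.4, 0.3)^2)))
  # R^2 <= 1 always; 1 iff perfect
  set.seed(3)
  for (i in 1:20) {
    y <- runif(10); f <- y + rnorm(10, 0, 0.1)
    r2 <- regression_metrics(f, y)$r_squared
    expect_lte(r2, 1)
    if (!isTRUE(all.equal(f, y))) expect_lt(r2, 1)
  }
})

test_that("normalized euclidean distance satisfies its axioms and worked examples", {
  set.seed(5)
  x <- array(sample.int(256, 48, TRUE) - 1L, c(4, 4, 3))
  y <- array(sample.int(256, 48, TRUE) - 1L, c(4, 4, 3))
  expect_equal(euclidean_image_distance(x, x), 0)
  expect_equal(euclidean_image_distance(x, y), euclidean_image_distance(y, x))
  black <- array(0L, c(8, 8, 3)); white <- array(255L, c(8, 8, 3))
  expect_equal(euclidean_image_distance(black, white), 1)
  # 1x1 pixel (0,0,0) vs (255,0,0): sqrt(1/3)
  a <- array(0L, c(1, 1, 3)); b <- array(c(255L, 0L, 0L), c(1, 1, 3))
  expect_equal(euclidean_image_distance(a, b), sqrt(1 / 3))
  expect_error(euclidean_image_distance(black, array(0L, c(4, 4, 3))),
               "dimensions")
})

test_that("domain gap is symmetric under the seed-derived pairing and matches the
           uniform-noise expectation", {
  set.seed(11)
  mk <- function() array(runif(32 * 32 * 3), c(32, 32, 3))
  A <- replicate(6, mk(), simplify = FALSE)
  B <- replicate(6, mk(), simplify = FALSE)
  gab <- domain_gap(A, B, n_pairs = 50, seed = 4)
  gba <- domain_gap(B, A, n_pairs = 50, seed = 4)
  expect_equal(gab$mean_distance, gba$mean_distance)
  # unequal sizes: canonical orientation keeps it symmetric too
  expect_equal(domain_gap(A, B[1:3], n_pairs = 40, seed = 2)$mean_distance,
               domain_gap(B[1:3], A, n_pairs = 40, seed = 2)$mean_distance)
  # single identical image in both sets -> zero gap
  expect_equal(domain_gap(A[1], A[1], n_pairs = 5, seed = 1)$mean_distance, 0)

  # Monte-Carlo oracle: for u, v ~ U(0,1), E[(u-v)^2] = 1/6
  bigA <- replicate(12, mk(), simplify = FALSE)
  bigB <- replicate(12, mk(), simplify = FALSE)
  g <- domain_gap(bigA, bigB, n_pairs = 1000, seed = 8)
  expect_equal(g$mean_distance, sqrt(1 / 6), tolerance = 0.01)
  expect_error(domain_gap(A, list(array(0, c(4, 4, 3)))), "dimensions")
})

test_that("GF series are ordered, averaged over duplicate dates, and monotone when
           green counts are", {
  m0 <- matrix(FALSE, 8, 8)
  gfm <- function(k) { m <- m0; if (k > 0) m[seq_len(k)] <- TRUE; m }
  dates <- as.Date("2022-03-01") + c(10, 0, 5, 5)
  s <- gf_series(tibble::tibble(timestamp = dates,
                                mask = list(gfm(40), gfm(0), gfm(8), gfm(16))))
  expect_equal(nrow(s), 3)
  expect_true(all(diff(as.numeric(s$timestamp)) > 0))
  expect_equal(s$green_fraction, c(0, mean(c(8, 16) / 64), 40 / 64))
  expect_equal(s$n_images, c(1L, 2L, 1L))
  # flat zero series
  flat <- gf_series(tibble::tibble(timestamp = 1:5,
                                   mask = replicate(5, m0, simplify = FALSE)))
  expect_true(all(flat$green_fraction == 0))
  # single sample
  one <- gf_series(list(list(timestamp = 1, mask = gfm(3))))
  expect_equal(nrow(one), 1)
  # monotone counts give a monotone series
  mono <- gf_series(tibble::tibble(timestamp = 1:6,
                                   mask = lapply(c(0, 4, 9, 20, 33, 64), gfm)))
  expect_true(all(diff(mono$green_fraction) >= 0))
  expect_s3_class(autoplot(mono), "ggplot")
})

test_that("tidiers expose confusion counts in broom style", {
  cc <- as_confusion_counts(0.4, 0.4, 0.1, 0.1, n_pixels = 100)
  td <- tidy(cc)
  expect_equal(td$proportion, c(0.4, 0.4, 0.1, 0.1))
  gl <- glance(cc)
  expect_equal(gl$accuracy, 0.8)
  expect_equal(gl$f1, 0.8)
  expect_error(as_confusion_counts(0.5, 0.5, 0.2, 0.1), "sum to 1")
})
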