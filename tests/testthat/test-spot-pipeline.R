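test_that("illumination correction handles the degenerate cases exactly", {
  ny <- 32; nx <- 32
  dark <- image_stack(array(100, dim = c(ny, nx, 50)))
  flat <- image_stack(array(600, dim = c(ny, nx, 5)))
  sample <- image_stack(array(rep(100 + 1:nx, each = ny), dim = c(ny, nx, 1)))
  # uniform flat field: correction reduces to dark subtraction
  out <- correct_illumination(sample, dark, flat)
  expect_equal(out$frames[, , 1],
               sample$frames[, , 1] - 100, tolerance = 1e-12)
  # sample identical to dark: all-zero output
  out0 <- correct_illumination(dark, dark, flat)
  expect_true(all(abs(out0$frames) < 1e-12))
  expect_error(correct_illumination(sample, dark,
                                    image_stack(array(50, dim = c(ny, nx, 5)))),
               "brighter")
  expect_warning(
    correct_illumination(sample,
                         image_stack(array(100, dim = c(ny, nx, 10))), flat),
    "dark frames")
})

test_that("a synthetic vignette is flattened to sub-percent RMS", {
  ny <- 128; nx <- 128
  field <- vignette_field(ny, nx, strength = 0.5)
  truth <- 400
  set.seed(31)
  mk <- function(base, n, noise = 1) {
    fr <- array(0, dim = c(ny, nx, n))
    for (i in seq_len(n)) fr[, , i] <- base + rnorm(ny * nx, sd = noise)
    image_stack(fr)
  }
  sample <- mk(100 + truth * field, 20)
  dark <- mk(matrix(100, ny, nx), 50)
  flat <- mk(100 + 1000 * field, 20)
  out <- correct_illumination(sample, dark, flat)
  avg <- rowMeans(out$frames, dims = 2)
  expect_lt(sd(avg) / mean(avg), 0.005)
  expect_equal(mean(avg), truth, tolerance = 0.01)
})

test_that("LoG detection finds isolated spots and nothing in noise", {
  set.seed(32)
  blank <- matrix(rnorm(256 * 256, sd = 6), 256, 256)
  expect_identical(nrow(detect_spots(blank)), 0L)
  # 50 well-separated bright spots, peak SNR >= 5
  tab <- data.frame(spot_id = 1:50, n_subunits = 1L, n_bright = 1L,
                    intensity = 600, detected = TRUE)
  sim <- simulate_image_stack(tab, camera_spec(read_noise_sd = 6),
                              frame_shape = c(512L, 512L),
                              spots_per_frame = 50L, n_dark = 50L,
                              seed = 33)
  fr <- sim$sample$frames[, , 1] - 100
  spots <- detect_spots(fr)
  spots$frame <- 1
  st <- match_detections(spots, sim$truth)
  expect_gte(st["recall"], 48 / 50)
  expect_identical(unname(st["fp_rate"]), 0)
  # localization: every detection within 1 px of a true spot (checked by
  # match_detections), and sub-pixel on average much closer
  d2 <- outer(spots$x_px, sim$truth$x_px, "-")^2 +
        outer(spots$y_px, sim$truth$y_px, "-")^2
  expect_lt(mean(sqrt(apply(d2, 1, min))), 0.5)
})

test_that("detection is translation-equivariant for integer shifts", {
  set.seed(34)
  fr <- matrix(rnorm(200 * 200, sd = 2), 200, 200)
  for (pos in list(c(60, 80), c(101, 41))) {
    g <- outer(dnorm(1:200, pos[2], 1.5), dnorm(1:200, pos[1], 1.5))
    fr <- fr + 4000 * g
  }
  shift <- 7L
  fr_shift <- rbind(fr[(shift + 1):200, ], matrix(0, shift, 200))
  a <- detect_spots(fr); b <- detect_spots(fr_shift)
  a <- a[order(a$x_px), ]; b <- b[order(b$x_px), ]
  expect_equal(nrow(a), nrow(b))
  expect_equal(b$y_px, a$y_px - shift, tolerance = 1e-6)
  expect_equal(b$x_px, a$x_px, tolerance = 1e-6)
})

test_that("close spot pairs are merged into a single detection", {
  fr <- matrix(0, 128, 128)
  for (x0 in c(64, 68)) # separated by < 1 diameter
    fr <- fr + 3000 * outer(dnorm(1:128, 64, 1.5), dnorm(1:128, x0, 1.5))
  spots <- detect_spots(fr)
  expect_identical(nrow(spots), 1L)
})

test_that("ROI filter keeps the centered window with the right area", {
  shape <- c(512L, 512L)
  center <- data.frame(x_px = 256, y_px = 256, frame = 1)
  corner <- data.frame(x_px = 2, y_px = 509, frame = 1)
  expect_identical(nrow(roi_filter(center, shape)), 1L)
  expect_identical(nrow(roi_filter(corner, shape)), 0L)
  expect_error(roi_filter(center, c(256L, 256L), width = 400, height = 400),
               "larger than the frame")
  set.seed(35)
  unif <- data.frame(x_px = runif(20000, 0, 512), y_px = runif(20000, 0, 512))
  frac <- nrow(roi_filter(unif, shape)) / 20000
  p <- (400 / 512)^2
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("intensity measurement subtracts flat and sloped backgrounds", {
  # flat background B plus a spot of known mass: corrected ~ aperture share
  B <- 50
  fr <- matrix(B, 101, 101) + 4000 * outer(dnorm(1:101, 51, 1.5),
                                           dnorm(1:101, 51, 1.5))
  spot <- data.frame(x_px = 50, y_px = 50)
  m <- measure_intensity(fr, spot)
  aperture <- 1 - exp(-(3^2) / (2 * 1.5^2))   # disk r = 3 on sigma = 1.5
  expect_equal(m$corrected_intensity, 4000 * aperture, tolerance = 0.02 * 4000)
  # adding a constant is absorbed by the background term exactly
  m2 <- measure_intensity(fr + 123, spot)
  expect_equal(m2$corrected_intensity, m$corrected_intensity,
               tolerance = 1e-9)
  # zero image measures zero
  z <- measure_intensity(matrix(0, 64, 64), data.frame(x_px = 30, y_px = 30))
  expect_identical(z$corrected_intensity, 0)
  # sloped background: bias stays below 2%
  slope <- outer(rep(1, 101), seq(0, 20, length.out = 101))
  m3 <- measure_intensity(fr + slope, spot)
  expect_lt(abs(m3$corrected_intensity / m$corrected_intensity - 1), 0.02)
})

test_that("bleach traces are extracted and classified by step count", {
  expect_identical(as.character(classify_steps(c(rep(100, 40), rep(0, 40)))),
                   "single")
  expect_identical(
    as.character(classify_steps(c(rep(200, 30), rep(100, 30), rep(0, 30)))),
    "double")
  expect_identical(
    as.character(classify_steps(c(rep(300, 25), rep(200, 25), rep(100, 25),
                                  rep(0, 25)))),
    "multi")
  expect_error(classify_steps(rep(1, 10)), "at least 20")
  set.seed(36)
  never <- 100 + rnorm(80, sd = 3)
  cls <- classify_steps(never)
  expect_identical(as.character(cls), "multi")
  expect_true(attr(cls, "never_bleached"))
})

test_that("step classification stays accurate at step SNR 5", {
  correct <- vapply(c(1L, 2L, 12L), function(n) {
    hits <- vapply(1:120, function(i) {
      tr <- simulate_bleach_trace(n, nu = 0, unit_intensity = 100,
                                  noise_sd = 20, seed = 7000 * n + i)
      truth <- attr(tr, "true_steps")
      expected <- if (truth == 1) "single" else if (truth == 2) "double"
                  else "multi"
      as.character(classify_steps(tr)) == expected
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(correct >= 0.9))
})

test_that("extract_trace reads the spot maximum through the stack", {
  frames <- array(0, dim = c(32, 32, 25))
  for (f in 1:25)
    frames[, , f] <- (if (f <= 12) 500 else 0) *
      outer(dnorm(1:32, 17, 1.5), dnorm(1:32, 17, 1.5)) * 2 * pi * 1.5^2
  tr <- extract_trace(image_stack(frames), data.frame(x_px = 16, y_px = 16))
  expect_length(tr$values, 25)
  expect_identical(as.character(classify_steps(tr)), "single")
})
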