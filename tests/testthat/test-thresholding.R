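# A profile with four plateaus joined by linear ramps of distinct
# steepness, then mirrored: the synthetic analogue of a center line
# through background, edge, intermediate, and core zones. The designed
# cutoffs are the ramp midpoint intensities.
plateau_profile <- function(levels = c(230, 140, 90, 40),
                            plateau_len = 40L,
                            ramp_lens = c(10L, 14L, 20L)) {
  x <- rep(levels[1L], plateau_len)
  for (k in 1:3) {
    ramp <- seq(levels[k], levels[k + 1L], length.out = ramp_lens[k] + 2L)
    x <- c(x, ramp[-c(1L, length(ramp))], rep(levels[k + 1L], plateau_len))
  }
  c(x, rev(x))
}

test_that("extract_profile averages perpendicular to the bar", {
  m <- micrograph(matrix(200, 20, 30))
  p <- extract_profile(m, bar_width = 5)
  expect_length(p, 30L)
  expect_true(all(p$intensities == 200))

  ramp <- micrograph(matrix(rep(0:29, each = 20), 20, 30))
  p2 <- extract_profile(ramp, bar_width = 3)
  expect_equal(p2$intensities, as.numeric(0:29))

  stripe <- matrix(230, 20, 40)
  stripe[, 15:18] <- 50
  p3 <- extract_profile(micrograph(stripe), orientation = "horizontal")
  expect_true(all(p3$intensities[15:18] == 50))
  expect_true(all(p3$intensities[-(15:18)] == 230))

  vert <- extract_profile(micrograph(t(stripe)), orientation = "vertical")
  expect_equal(vert$intensities, p3$intensities)

  expect_error(extract_profile(m, center = c(25, 5)), "outside",
               class = "spheroquant_validation_error")
})

test_that("smoothing is a truncated centered moving average", {
  p <- line_profile(c(0, 0, 0, 0, 100, 100, 100, 100))
  expect_equal(smooth_profile(p, 1)$intensities, p$intensities)
  expect_equal(smooth_profile(p, 4)$intensities[2:6],
               c(0, 25, 50, 75, 100))

  const <- line_profile(rep(130, 50))
  expect_true(all(smooth_profile(const, 20)$intensities == 130))

  expect_error(smooth_profile(p, 0), class = "spheroquant_validation_error")
  expect_error(smooth_profile(p, 9), class = "spheroquant_validation_error")
})

test_that("smoothing never widens the intensity range", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(60, 0, 255)
    w <- sample(1:30, 1)
    s <- smooth_profile(line_profile(x), w)$intensities
    expect_gte(min(s), min(x))
    expect_lte(max(s), max(x))
    expect_equal(s, brute_moving_average(x, w))
  }
})

test_that("first derivative is exact on lines and zero on constants", {
  expect_true(all(first_derivative(line_profile(rep(77, 10))) == 0))
  ramp <- seq(250, 250 - 2 * 19, by = -2)
  d <- first_derivative(line_profile(ramp))
  expect_true(all(d[2:19] == -2))
  expect_error(first_derivative(1:2), class = "spheroquant_validation_error")
})

test_that("three-level detection recovers ramp midpoint intensities", {
  p <- line_profile(plateau_profile())
  t <- detect_thresholds(p, window = 10)
  # midpoints of 230->140, 140->90, 90->40
  expect_equal(t$t_all, 185, tolerance = 0.02)
  expect_equal(t$t_intermediate, 115, tolerance = 0.02)
  expect_equal(t$t_core, 65, tolerance = 0.03)
  expect_true(t$t_core < t$t_intermediate && t$t_intermediate < t$t_all)
  expect_true(all(diff(t$provenance$positions) > 0))
})

test_that("single-step profiles fail at 3 levels but work at 1", {
  step <- c(rep(230, 60), seq(230, 40, length.out = 12), rep(40, 60))
  p <- line_profile(step)
  expect_error(detect_thresholds(p, window = 10),
               "found 1 of 3", class = "spheroquant_detection_error")
  cut1 <- detect_thresholds(p, window = 10, n_levels = 1)
  expect_equal(as.numeric(cut1), 135, tolerance = 0.05)
})

test_that("left- and right-side detection agree on mirrored profiles", {
  p <- line_profile(plateau_profile())
  tl <- detect_thresholds(p, window = 10)
  tr <- detect_thresholds(p, window = 10, side = "right")
  for (f in c("t_all", "t_intermediate", "t_core"))
    expect_equal(tl[[f]], tr[[f]], tolerance = 1e-8)

  # and on a noisy phantom, within the intensity span of one window
  ph <- generate_phantom(phantom_spec(noise_sigma = 2, seed = 9))
  prof <- extract_profile(ph$micrograph)
  tl2 <- detect_thresholds(prof)
  tr2 <- detect_thresholds(prof, side = "right")
  sm <- smooth_profile(prof)$intensities
  for (k in 1:3) {
    f <- c("t_all", "t_intermediate", "t_core")[k]
    pos <- round(tl2$provenance$positions[k])
    span <- diff(range(sm[max(1, pos - 10):min(length(sm), pos + 10)]))
    expect_lte(abs(tl2[[f]] - tr2[[f]]), span)
  }
})

test_that("cutoffs shift equivariantly with a constant intensity offset", {
  base <- plateau_profile(levels = c(215, 130, 85, 40))
  t0 <- detect_thresholds(line_profile(base), window = 10)
  for (b in c(-20, 15)) {
    tb <- detect_thresholds(line_profile(base + b), window = 10)
    expect_equal(tb$t_all, t0$t_all + b, tolerance = 1e-6)
    expect_equal(tb$t_intermediate, t0$t_intermediate + b, tolerance = 1e-6)
    expect_equal(tb$t_core, t0$t_core + b, tolerance = 1e-6)
  }
})

test_that("suspension threshold sits a margin below the background minimum", {
  obj <- c(rep(230, 20), rep(60, 60), rep(230, 20))
  expect_equal(suspension_threshold(line_profile(obj), margin = 5), 225)

  asym <- c(rep(230, 20), rep(60, 60), rep(228, 20))
  expect_equal(suspension_threshold(line_profile(asym), margin = 5), 223)

  expect_error(suspension_threshold(line_profile(rep(40, 50))),
               class = "spheroquant_validation_error")
  expect_error(suspension_threshold(line_profile(obj), margin = 231),
               class = "spheroquant_validation_error")
})

test_that("threshold sets validate ordering and serialize to JSON", {
  expect_error(threshold_set(100, 150, 50),
               class = "spheroquant_validation_error")
  expect_error(threshold_set(200, 110, 110),
               class = "spheroquant_validation_error")
  t <- detect_thresholds(line_profile(plateau_profile()), window = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_thresholds(t, f)
  t2 <- read_thresholds(f)
  expect_equal(t2$t_all, t$t_all)
  expect_equal(t2$t_core, t$t_core)
  expect_equal(t2$provenance$side, "left")
})
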