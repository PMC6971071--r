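test_that("invasion indices follow the subarea decomposition", {
  m <- micrograph_with_areas(area_core = 50, area_intermediate = 30,
                             area_edge = 20, size = 10L)
  s <- segment(m, default_thresholds(), min_area = 0)
  expect_identical(c(s$area_core, s$area_intermediate_region, s$area_edge),
                   c(50L, 30L, 20L))
  idx <- invasion_indices(s)
  expect_equal(idx$index_A, 20)
  expect_equal(idx$index_B, 50)

  pure_core <- segment(micrograph(matrix(30, 10, 10)), default_thresholds(),
                       min_area = 0)
  expect_equal(invasion_indices(pure_core), list(index_A = 0, index_B = 0))

  dispersed <- segment(micrograph(matrix(150, 10, 10)), default_thresholds(),
                       min_area = 0)
  expect_equal(invasion_indices(dispersed), list(index_A = 100, index_B = 100))
})

test_that("index bounds and the B - A identity hold for fuzzed inputs", {
  set.seed(61)
  for (i in 1:30) {
    m <- micrograph(matrix(sample(0:255, 18 * 18, TRUE), 18, 18))
    v <- sort(sample(1:254, 3))
    s <- tryCatch(segment(m, threshold_set(v[3], v[2], v[1]), min_area = 0),
                  error = function(e) NULL)
    if (is.null(s)) next
    idx <- invasion_indices(s)
    expect_gte(idx$index_A, 0)
    expect_lte(idx$index_A, idx$index_B)
    expect_lte(idx$index_B, 100)
    expect_equal(idx$index_B - idx$index_A,
                 100 * s$area_intermediate_region / s$area_all)
  }
})

test_that("volume from area assumes a sphere", {
  for (r in c(1, 2, 5, 10))
    expect_equal(volume_from_area(pi * r^2), (4 / 3) * pi * r^3)
  a <- 137.5
  expect_equal(volume_from_area(2 * a) / volume_from_area(a), 2^1.5)
  # calibration: area in px^2 with s um/px scales volume by s^3
  expect_equal(volume_from_area(100, pixel_size = 2),
               volume_from_area(100) * 8)
  expect_error(volume_from_area(0), class = "spheroquant_validation_error")
})

test_that("relative metrics are plain ratios with a guarded reference", {
  expect_equal(relative_metric(5, 5), 1)
  expect_equal(relative_metric(0, 4), 0)
  expect_equal(relative_metric(3, 2), 1.5)
  expect_error(relative_metric(3, 0), class = "spheroquant_validation_error")
})

test_that("max invasion length measures beyond the reference disk", {
  t <- default_thresholds()
  img <- matrix(240, 111, 111)
  img[disk_mask(111, 20)] <- 30
  ref <- segment(micrograph(img), t, min_area = 0)
  expect_lt(max_invasion_length(ref, ref), 1)

  img2 <- img
  img2[56, 56 + 50] <- 30  # single pixel 50 px right of center
  s_t <- segment(micrograph(img2), t, min_area = 0)
  expect_equal(max_invasion_length(s_t, ref), 30, tolerance = 0.02)

  set.seed(19)
  for (i in 1:5) {
    a <- matrix(sample(c(30, 240), 25 * 25, TRUE, prob = c(0.3, 0.7)), 25, 25)
    b <- matrix(sample(c(30, 240), 25 * 25, TRUE, prob = c(0.3, 0.7)), 25, 25)
    sa <- segment(micrograph(a), t, min_area = 0)
    sb <- segment(micrograph(b), t, min_area = 0)
    expect_equal(max_invasion_length(sa, sb),
                 brute_max_invasion_length(sa$mask_all, sb$centroid,
                                           sb$area_all))
  }
})

test_that("skeleton end points count sprouts", {
  line <- matrix(FALSE, 9, 30); line[5, 6:25] <- TRUE
  expect_equal(count_endpoint_voxels(line), 2L)

  plus <- matrix(FALSE, 21, 21)
  plus[11, 4:18] <- TRUE; plus[4:18, 11] <- TRUE
  expect_equal(count_endpoint_voxels(plus), 4L)

  expect_error(count_endpoint_voxels(matrix(FALSE, 3, 3)),
               class = "spheroquant_validation_error")
})

test_that("end-point count grows with phantom protrusions", {
  counts <- vapply(c(2, 4, 6, 8), function(k) {
    ph <- generate_phantom(phantom_spec(n_protrusions = k,
                                        protrusion_length = 35, seed = 5))
    s <- segment(ph$micrograph,
                 detect_thresholds(extract_profile(ph$micrograph)))
    count_endpoint_voxels(s$mask_all)
  }, numeric(1))
  expect_true(all(counts >= c(2, 4, 6, 8)))
  expect_true(all(diff(counts) >= 0))
})

test_that("detached cells are components beyond the body", {
  blob <- matrix(FALSE, 30, 30); blob[10:20, 10:20] <- TRUE
  expect_equal(count_detached_cells(blob), 0L)

  mask <- blob
  mask[2:4, 2:4] <- TRUE; mask[25:27, 5:7] <- TRUE; mask[2:4, 25:27] <- TRUE
  mask[28, 28] <- TRUE; mask[1, 15] <- TRUE  # sub-threshold specks
  expect_equal(count_detached_cells(mask, min_size = 5), 3L)

  set.seed(27)
  for (i in 1:10) {
    m <- rand_mask(24, 24, runif(1, 0.2, 0.5))
    if (!any(m)) next
    ms <- sample(1:6, 1)
    expect_equal(count_detached_cells(m, ms), brute_detached(m, ms))
  }
})

test_that("shape descriptors match analytic shapes", {
  d30 <- disk_mask(101, 30)
  sd_ <- shape_descriptors(d30)
  expect_gte(sd_$roundness, 0.95)
  expect_lte(sd_$roundness, 1)
  expect_equal(sd_$equivalent_diameter, 60, tolerance = 1 / 60)

  rect <- matrix(FALSE, 50, 20)
  rect[6:45, 6:15] <- TRUE  # 40 x 10 rectangle
  r <- shape_descriptors(rect)
  expect_lt(r$roundness, 0.5)
  # closed form: major axis 4*sqrt((40^2-1)/12), area 400
  expect_equal(r$roundness, 4 * 400 / (pi * (4 * sqrt((40^2 - 1) / 12))^2),
               tolerance = 1e-8)

  single <- matrix(FALSE, 5, 5); single[2, 3] <- TRUE
  expect_equal(shape_descriptors(single)$roundness, 1)

  small <- disk_mask(41, 12); big <- disk_mask(81, 24)
  expect_equal(shape_descriptors(big)$equivalent_diameter,
               2 * shape_descriptors(small)$equivalent_diameter,
               tolerance = 1 / 24)
})
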