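test_that("nucleus detection finds rendered nuclei near their true centroids", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_nuclei(blank)$centroids), 0L)
  expect_error(detect_nuclei(array(0, c(4, 4, 2))), "2-D")

  f <- simulate_cell_field(50, frac_myo = 0.5, dim = c(320, 320), seed = 23)
  det <- detect_nuclei(f$image[, , 1])
  expect_equal(nrow(det$centroids), 50L)
  ## match each detection to the nearest true centroid: within 3 px
  d <- vapply(seq_len(nrow(det$centroids)), function(i) {
    sqrt(min((f$truth$x - det$centroids$x[i])^2 +
               (f$truth$y - det$centroids$y[i])^2))
  }, numeric(1))
  expect_true(all(d <= 3))
})

test_that("two nuclei separated by twice their radius resolve separately", {
  img <- matrix(0, 96, 96)
  paint <- function(cy, cx, r, v) {
    for (i in (cy - r):(cy + r)) for (j in (cx - r):(cx + r)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <<- v
    }
  }
  paint(40, 40, 4, 20000)
  paint(40, 60, 4, 20000)  # centers 20 px apart, radius 4
  det <- detect_nuclei(img)
  expect_equal(nrow(det$centroids), 2L)
})

test_that("seeded segmentation yields one disjoint region per nucleus", {
  ## one seed, one bright blob -> one region covering the blob
  img <- matrix(0, 64, 64); img[20:40, 20:40] <- 8000
  seeds <- matrix(0L, 64, 64); seeds[30, 30] <- 1L
  seg <- segment_cells(img, seeds)
  expect_equal(max(seg), 1L)
  expect_true(all(seg[25:35, 25:35] == 1L))
  expect_error(segment_cells(img, matrix(0L, 64, 64)), "seeds")

  f <- simulate_cell_field(35, frac_myo = 0.5, dim = c(256, 256), seed = 31)
  det <- detect_nuclei(f$image[, , 1])
  cells <- segment_cells(f$image[, , 4], det$labels)
  ## region count equals seed count; every region holds exactly one seed
  expect_equal(max(cells), max(det$labels))
  for (i in seq_len(max(det$labels))) {
    expect_equal(unique(cells[det$labels == i]), i)
  }
  ## mean intersection-over-union against the generator's masks
  iou <- vapply(seq_len(nrow(f$truth)), function(i) {
    lab <- cells[round(f$truth$y[i]) + 1, round(f$truth$x[i]) + 1]
    if (lab == 0) return(0)
    gt <- f$cell_mask == i; dt <- cells == lab
    sum(gt & dt) / sum(gt | dt)
  }, numeric(1))
  expect_gte(mean(iou), 0.7)
})

test_that("granularity spectra are bounded and localize object size", {
  ## constant image: openings change nothing
  expect_equal(unname(granularity_spectrum(matrix(500, 32, 32), 1:4)),
               rep(0, 4))
  ## all-zero region: zero vector, not an error
  expect_equal(sum(granularity_spectrum(matrix(0, 16, 16), 1:3)), 0)
  ## disks of radius 3: signal removed at scales 3-4, as the brute-force
  ## opening-series oracle predicts
  img <- matrix(0, 48, 48)
  for (ctr in list(c(12, 12), c(12, 36), c(36, 12), c(36, 36))) {
    for (i in -3:3) for (j in -3:3) {
      if (i^2 + j^2 <= 9) img[ctr[1] + i, ctr[2] + j] <- 1000
    }
  }
  g <- granularity_spectrum(img, 1:6)
  o <- oracle_granularity(img, 1:6)
  expect_true(unname(which.max(g)) %in% 3:4)
  expect_true(which.max(o) %in% 3:4)
  expect_equal(unname(which.max(g)), which.max(o))
  ## bounds on arbitrary inputs
  set.seed(13)
  for (k in 1:5) {
    m <- matrix(runif(64 * 64, 0, 65535), 64, 64)
    g <- granularity_spectrum(m, c(1, 2, 4, 6))
    expect_true(all(g >= 0))
    expect_lte(sum(g), 100 + 1e-9)
  }
  expect_error(granularity_spectrum(matrix(1, 8, 8), c(2, 1)), "increasing")
})

test_that("feature extraction is complete, finite and deterministic", {
  f <- simulate_cell_field(30, frac_myo = 0.5, dim = c(224, 224), seed = 41)
  det <- detect_nuclei(f$image[, , 1])
  cells <- segment_cells(f$image[, , 4], det$labels)
  feat <- extract_cell_features(f$image, cells, det$labels, well = "B02")
  ## one record per nucleus, >= 40 features per marker channel
  expect_equal(nrow(feat), max(det$labels))
  expect_gte(sum(startsWith(names(feat), "asma_")), 40L)
  expect_gte(sum(startsWith(names(feat), "fn_")), 40L)
  num <- vapply(feat, is.numeric, logical(1))
  expect_true(all(vapply(feat[num], function(v) all(is.finite(v)),
                         logical(1))))
  ## no hidden randomness
  feat2 <- extract_cell_features(f$image, cells, det$labels, well = "B02")
  expect_identical(feat, feat2)
  expect_error(extract_cell_features(f$image, cells[1:100, 1:100],
                                     det$labels), "shape")
})

test_that("solidity of a convex elliptical mask is ~1 and 1-px cells survive", {
  H <- 64; W <- 64
  cells <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W) {
    if (((i - 32) / 14)^2 + ((j - 32) / 8)^2 <= 1) cells[i, j] <- 1L
  }
  nuclei <- matrix(0L, H, W); nuclei[30:34, 30:34] <- 1L
  img <- array(500, c(H, W, 4))
  feat <- extract_cell_features(img, cells, nuclei)
  expect_gt(feat$shape_solidity, 0.92)
  expect_lte(feat$shape_solidity, 1)
  ## degenerate but valid: a single-pixel cell
  cells1 <- matrix(0L, 32, 32); cells1[16, 16] <- 1L
  set.seed(3)
  img1 <- array(runif(32 * 32 * 4, 0, 1000), c(32, 32, 4))
  feat1 <- extract_cell_features(img1, cells1, cells1)
  num <- vapply(feat1, is.numeric, logical(1))
  expect_true(all(vapply(feat1[num], function(v) all(is.finite(v)),
                         logical(1))))
})

test_that("alpha-SMA granularity separates the classes strongly", {
  plate <- small_control_plate()
  feat <- plate$features
  roles <- setNames(plate$layout$role, plate$layout$well)
  lab <- roles[feat$well]  # control wells are near-pure populations
  gran_cols <- grep("^asma_gran_", names(feat), value = TRUE)
  smd <- vapply(gran_cols, function(cn) {
    a <- feat[[cn]][lab == "neg_control"]
    b <- feat[[cn]][lab == "pos_control"]
    abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_gt(max(smd), 1)
})
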