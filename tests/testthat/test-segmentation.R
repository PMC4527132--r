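test_that("connected components use 8-connectivity and raster-order labels", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal touch
  lm <- connected_components(m)
  expect_equal(max(lm), 1L)
  expect_equal(max(connected_components(matrix(0L, 3, 3))), 0L)
  # raster order: first pixel of label 1 precedes label 2's in row-major scan
  m2 <- matrix(0L, 5, 5); m2[1, 4] <- 1L; m2[3, 1] <- 1L
  lm2 <- connected_components(m2)
  expect_equal(lm2[1, 4], 1L)
  expect_equal(lm2[3, 1], 2L)
})

test_that("component counts agree with the flood-fill oracle on random masks", {
  set.seed(51)
  for (i in 1:20) {
    m <- matrix(as.integer(runif(15 * 15) < 0.35), 15, 15)
    expect_equal(max(connected_components(m)), oracle_component_count(m))
  }
})

test_that("median_equivalent_radius matches its definition", {
  disc <- render_discs(20, cbind(10, 10), 5)  # area 81 -> r 5.08
  lm <- connected_components(disc)
  expect_equal(median_equivalent_radius(lm), sqrt(sum(disc) / pi),
               tolerance = 1e-12)
  # two objects with areas ~pi and ~9*pi -> radii ~1 and ~3, median 2
  m <- matrix(0L, 30, 30)
  m[2:3, 2:3] <- 1L                      # area 4, r 1.13
  m[10:15, 10:15] <- 1L                  # area 36, r 3.39
  expect_equal(median_equivalent_radius(connected_components(m)),
               mean(sqrt(c(4, 36) / pi)), tolerance = 1e-12)
  expect_error(median_equivalent_radius(matrix(0L, 3, 3)), "no objects",
               class = "srseg_error_degenerate")
  # sort-based oracle on a random label map
  set.seed(52)
  lm3 <- connected_components(matrix(as.integer(runif(400) < 0.3), 20, 20))
  areas <- sort(tabulate(lm3[lm3 > 0]))
  expect_equal(median_equivalent_radius(lm3),
               stats::median(sqrt(areas / pi)))
})

test_that("shape declumping splits fused discs at the neck", {
  mask <- render_discs(40, rbind(c(20, 16), c(20, 25)), 6)
  expect_equal(oracle_component_count(mask), 1L)  # rendered as one component
  lm <- declump_shape(mask, suppression_distance_px = 4)
  expect_equal(max(lm), 2L)
  expect_false(lm[20, 16] == lm[20, 25])  # disc centres carry distinct labels
  expect_true(all((lm > 0L) == (mask > 0L)))  # exact foreground partition
})

test_that("a single disc is not split and fully covered", {
  mask <- render_discs(30, cbind(15, 15), 7)
  lm <- declump_shape(mask, 3)
  expect_equal(max(lm), 1L)
  expect_true(all((lm > 0L) == (mask > 0L)))
})

test_that("intensity declumping separates peaks subject to suppression", {
  peaks <- rbind(c(15, 10, 100), c(15, 22, 100))  # 12 px apart
  img <- render_gaussians(30, peaks, sigma = 3) + 1
  mask <- matrix(as.integer(img > 5), 30, 30)
  expect_equal(oracle_component_count(mask), 1L)
  lm5 <- declump_intensity(mask, sr_image(img), 5)
  expect_equal(max(lm5), 2L)
  expect_false(lm5[15, 10] == lm5[15, 22])
  # suppression beyond the separation keeps one object
  lm20 <- declump_intensity(mask, sr_image(img), 20)
  expect_equal(max(lm20), 1L)
  # flat component: single surviving maximum
  flat <- matrix(0L, 10, 10); flat[3:7, 3:7] <- 1L
  expect_equal(max(declump_intensity(flat, sr_image(matrix(1, 10, 10)), 2)), 1L)
})

test_that("declump output always tiles the foreground and never loses objects", {
  set.seed(53)
  for (i in 1:10) {
    spots <- cbind(runif(4, 8, 40), runif(4, 8, 40), runif(4, 50, 150))
    img <- render_gaussians(48, spots, sigma = 3) + 2
    mask <- matrix(as.integer(img > 6), 48, 48)
    ncomp <- oracle_component_count(mask)
    for (lm in list(declump_shape(mask, 3),
                    declump_intensity(mask, sr_image(img), 3))) {
      expect_true(all((lm > 0L) == (mask > 0L)))
      expect_gte(max(lm), ncomp)
      if (max(lm) > 0) expect_setequal(unique(lm[lm > 0]), seq_len(max(lm)))
    }
  }
})

test_that("suppression distance is monotone in object count", {
  mask <- render_discs(60, rbind(c(30, 15), c(30, 24), c(30, 33), c(22, 24)), 6)
  counts <- vapply(c(1, 2, 4, 6, 9, 14, 25),
                   function(s) max(declump_shape(mask, s)), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("declumping is deterministic", {
  set.seed(54)
  img <- render_gaussians(40, cbind(runif(5, 5, 35), runif(5, 5, 35),
                                    runif(5, 60, 120)), 2.5) + 3
  mask <- matrix(as.integer(img > 8), 40, 40)
  a <- declump_intensity(mask, sr_image(img), 2)
  b <- declump_intensity(mask, sr_image(img), 2)
  expect_identical(a, b)
})

test_that("filter_objects removes by size and border and relabels", {
  m <- matrix(0L, 20, 20)
  m[2, 2] <- 1L              # diameter ~1.1: below min
  m[5:10, 5:10] <- 1L        # diameter ~6.8: kept
  m[18:20, 14:17] <- 1L      # touches border
  lm <- connected_components(m)
  p <- segmentation_params(declump_method = "none", min_diameter_px = 5,
                           max_diameter_px = 15, discard_border = TRUE)
  out <- filter_objects(lm, p)
  expect_equal(max(out), 1L)
  expect_true(all(out[5:10, 5:10] == 1L))
  # brute-force re-measurement: every survivor is in range and off-border
  surv <- measure_objects(out, matrix(1, 20, 20))
  expect_true(all(surv$equivalent_diameter_px >= 5 &
                  surv$equivalent_diameter_px <= 15))
})

test_that("measure_objects reports 0-based centroids and exact areas", {
  m <- matrix(0L, 10, 10)
  m[3:4, 5:6] <- 1L
  img <- matrix(1, 10, 10); img[3, 5] <- 9
  tab <- measure_objects(connected_components(m), img)
  expect_equal(tab$area_px, 4L)
  expect_equal(tab$centroid_row, 2.5)   # rows 3,4 -> 0-based 2,3
  expect_equal(tab$centroid_col, 4.5)
  expect_equal(tab$max_intensity, 9)
  expect_equal(tab$mean_intensity, 3)
  expect_equal(tab$equivalent_diameter_px, 2 * sqrt(4 / pi))
})

test_that("identify_primary_objects finds well-separated discs near truth", {
  set.seed(55)
  centers <- cbind(c(12, 12, 32, 50, 50), c(12, 50, 31, 12, 50))
  img <- render_gaussians(64, cbind(centers, rep(120, 5)), sigma = 3) + 2
  seg <- identify_primary_objects(sr_image(img), segmentation_params(
    declump_method = "none", min_diameter_px = 3, max_diameter_px = 30))
  expect_equal(nrow(seg$objects), 5L)
  got <- as.matrix(seg$objects[, c("centroid_row", "centroid_col")]) + 1
  d <- sqrt(rowSums((got[order(got[, 1]), ] - centers[order(centers[, 1]), ])^2))
  expect_true(all(d <= 1))
})

test_that("declump method changes fused-blob object count as designed", {
  # two overlapping discs rendered as one bright blob: the neck is a shape
  # cue, so shape declumping splits it while "none" keeps one object
  blob <- render_discs(40, rbind(c(20, 14), c(20, 23)), 6)
  img <- sr_image(blob * 100 + 1)
  p_shape <- segmentation_params(declump_method = "shape",
                                 suppression_distance_px = 3,
                                 min_diameter_px = 2, max_diameter_px = 30)
  p_none <- segmentation_params(declump_method = "none",
                                min_diameter_px = 2, max_diameter_px = 30)
  expect_equal(nrow(identify_primary_objects(img, p_shape)$objects), 2L)
  expect_equal(nrow(identify_primary_objects(img, p_none)$objects), 1L)
})

test_that("structure-free speckle noise is emptied by the size filter", {
  # isolated hot pixels with no real structure: the threshold keeps them
  # but every component is far below the minimum diameter
  set.seed(56)
  img <- matrix(0.1, 96, 96)
  img[cbind(sample(5:92, 30), sample(5:92, 30))] <- runif(30, 50, 120)
  seg <- identify_primary_objects(sr_image(img), segmentation_params(
    declump_method = "none", min_diameter_px = 5, max_diameter_px = 40))
  expect_equal(nrow(seg$objects), 0L)
  expect_equal(max(seg$labels), 0L)
  expect_error(identify_primary_objects(sr_image(matrix(1, 8, 8))),
               class = "srseg_error_degenerate")
})
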