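test_that("a clean single pore shows one local maximum per subunit", {
  p <- npc_simulation_params(image_size_px = 96, n_pores = 1,
                             subunits_per_pore = 8, angular_jitter_deg = 0,
                             poisson_noise = FALSE, read_noise_sd = 0,
                             subunit_intensity_range = c(150, 150), seed = 7)
  sim <- simulate_npc_field(p)
  red <- extract_channel(sim$image, "red")$pixels
  n_max <- oracle_count_maxima_2d(red, floor_value = p$background_level + 1)
  expect_equal(n_max, 8L)
  # unresolvable PSF regime: everything fuses into one blob
  p_wide <- npc_simulation_params(image_size_px = 192, n_pores = 1,
                                  subunits_per_pore = 8, angular_jitter_deg = 0,
                                  poisson_noise = FALSE, read_noise_sd = 0,
                                  psf_fwhm_nm = 300,
                                  subunit_intensity_range = c(150, 150),
                                  seed = 7)
  wide <- extract_channel(simulate_npc_field(p_wide)$image, "red")$pixels
  expect_equal(oracle_count_maxima_2d(wide, floor_value = p$background_level + 1),
               1L)
})

test_that("simulation is reproducible under a seed and varies across seeds", {
  a <- simulate_npc_field(npc_simulation_params(n_pores = 10, seed = 3))
  b <- simulate_npc_field(npc_simulation_params(n_pores = 10, seed = 3))
  c <- simulate_npc_field(npc_simulation_params(n_pores = 10, seed = 4))
  expect_identical(extract_channel(a$image, "red")$pixels,
                   extract_channel(b$image, "red")$pixels)
  expect_identical(a$truth$pore_centers_px, b$truth$pore_centers_px)
  expect_false(identical(a$truth$pore_centers_px, c$truth$pore_centers_px))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_npc_field(npc_simulation_params(n_pores = 5)))
  expect_identical(runif(3), before)
})

test_that("ground truth is consistent: counts, separations, green spots", {
  p <- npc_simulation_params(image_size_px = 320, n_pores = 25,
                             subunits_per_pore = 6, seed = 8)
  sim <- simulate_npc_field(p)
  expect_equal(nrow(sim$truth$pore_centers_px), 25L)
  expect_true(all(vapply(sim$truth$subunit_positions_px, nrow, 0L) == 6L))
  expect_equal(sim$truth$true_counts, rep(6L, 25L))
  d <- as.matrix(stats::dist(sim$truth$pore_centers_px))
  diag(d) <- Inf
  expect_gte(min(d), p$min_pore_separation_nm / p$pixel_size_nm)
  # green channel: exactly one spot per pore
  pg <- npc_simulation_params(image_size_px = 256, n_pores = 12,
                              poisson_noise = FALSE, read_noise_sd = 0, seed = 9)
  green <- extract_channel(simulate_npc_field(pg)$image, "green")$pixels
  expect_equal(oracle_count_maxima_2d(green, floor_value = pg$background_level + 1),
               12L)
})

test_that("noise-free images are bounded by background plus peak sums", {
  p <- npc_simulation_params(n_pores = 8, poisson_noise = FALSE,
                             read_noise_sd = 0, seed = 10)
  red <- extract_channel(simulate_npc_field(p)$image, "red")$pixels
  expect_true(all(red >= 0))
  expect_lte(max(red), p$background_level +
               p$subunits_per_pore * p$subunit_intensity_range[2L])
})

test_that("infeasible placement raises a placement error", {
  expect_error(
    simulate_npc_field(npc_simulation_params(image_size_px = 64, n_pores = 500)),
    class = "srseg_error_placement")
})

test_that("active zone simulator books the right ground truth and maxima", {
  p <- az_simulation_params(n_zones = 2, clusters_per_zone = 5, seed = 2)
  sim <- simulate_active_zones(p)
  expect_equal(length(sim$truth$cluster_positions_px), 2L)
  expect_true(all(vapply(sim$truth$cluster_positions_px, nrow, 0L) == 5L))
  n_max <- oracle_count_maxima_2d(sim$image$pixels,
                                  floor_value = p$background_level + 2)
  expect_equal(n_max, 10L)
  again <- simulate_active_zones(p)
  expect_identical(sim$image$pixels, again$image$pixels)
})
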