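test_that("fixture pixel counts match their closed forms", {
  expect_equal(sum(generate_fixture("line", 64)), 64)
  expect_equal(sum(generate_fixture("filled_square", 32)), 32^2)
  expect_equal(sum(generate_fixture("single_pixel", 16)), 1)
  # depth-8 gasket: closed form 3^8, cross-checked against a brute-force
  # construction of Pascal's triangle mod 2
  expect_equal(sum(generate_fixture("sierpinski", 256, depth = 8)), 3^8)
  expect_equal(brute_pascal_mod2_count(8), 3^8)
  expect_error(generate_fixture("sierpinski", 100, depth = 8),
               class = "fdretina_config_error")
})

test_that("vessel-tree generation is seeded, bounded and connected-ish", {
  p <- vessel_tree_params(size_px = 128)
  a <- generate_vessel_tree(p, seed = 11)
  b <- generate_vessel_tree(p, seed = 11)
  expect_identical(a, b)
  expect_true(min(a) >= 0 && max(a) <= 1)
  expect_false(identical(a, generate_vessel_tree(p, seed = 12)))
  # planar curve bounds on the skeleton dimension
  fd <- estimate_fd(generate_vessel_tree(seed = 3))$fd
  expect_gt(fd, 1.0)
  expect_lt(fd, 2.0)
})

test_that("parameter validation catches degenerate generator configs", {
  expect_error(vessel_tree_params(width_decay = 0),
               class = "fdretina_config_error")
  expect_error(vessel_tree_params(min_segment_px = 10, max_segment_px = 5),
               class = "fdretina_config_error")
  expect_error(scan_perturbation(gamma = 0),
               class = "fdretina_config_error")
  expect_error(variance_components_params(n_subjects = 1),
               class = "fdretina_config_error")
  expect_error(variance_components_params(sigma_error = -1),
               class = "fdretina_config_error")
})

test_that("identity perturbation is the identity function on images", {
  img <- generate_vessel_tree(seed = 5)
  expect_identical(perturb_scan(img, scan_perturbation(), seed = 9), img)
})

test_that("pure sub-pixel shift approximately preserves mean intensity", {
  img <- generate_vessel_tree(seed = 2)
  out <- perturb_scan(img, scan_perturbation(shift_px = c(0.5, 0)), seed = 1)
  expect_identical(dim(out), dim(img))
  expect_lt(abs(mean(out) - mean(img)) / mean(img), 0.02)
})

test_that("small perturbations move the estimated FD by less than 0.05", {
  p <- scan_perturbation(shift_px = c(0.7, 0.7), noise_reseed = TRUE,
                         extra_noise_sd = 0.02)  # |shift| < 1 px
  for (s in 1:10) {
    img <- generate_vessel_tree(seed = s)
    fd0 <- estimate_fd(img)$fd
    fd1 <- estimate_fd(perturb_scan(img, p, seed = 100 + s))$fd
    expect_lt(abs(fd1 - fd0), 0.05)
  }
})

test_that("measurement-table simulator recovers the implied ICC", {
  # zero within-subject variance -> ICC exactly 1
  tab <- simulate_measurement_table(
    variance_components_params(sigma_observer = 0, sigma_error = 0,
                               n_subjects = 20, seed = 4))
  expect_equal(icc(tab)$estimate, 1)
  # no subject variance -> ICC near 0 at large n
  tab0 <- simulate_measurement_table(
    variance_components_params(sigma_subject = 0, sigma_error = 1,
                               n_subjects = 500, seed = 5))
  expect_lt(abs(icc(tab0)$estimate), 0.1)
  # convergence to the variance-ratio truth at n = 1000
  tab7 <- simulate_measurement_table(
    variance_components_params(sigma_subject = sqrt(7), sigma_error = sqrt(3),
                               n_subjects = 1000, seed = 6))
  expect_lt(abs(icc(tab7)$estimate - 0.7), 0.03)
})

test_that("cohort generator reproduces the study's acquisition structure", {
  ch <- generate_cohort(n_participants = 3, seed = 2)
  expect_length(ch$images, 3 * 3 * 2)
  m <- ch$metadata
  expect_setequal(m$observer_id[m$scan_index == 1], 1L)
  expect_setequal(m$observer_id[m$scan_index %in% 2:3], 2L)
  expect_setequal(unique(m$plexus), c("SCP", "DCP"))
  expect_true(all(m$eye[m$birth_year %% 2 == 0] == "right"))
  expect_true(all(m$eye[m$birth_year %% 2 == 1] == "left"))
  ch2 <- generate_cohort(n_participants = 3, seed = 2)
  expect_identical(ch, ch2)
})
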