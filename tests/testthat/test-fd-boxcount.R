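test_that("mesh_schedule follows the dyadic rule", {
  expect_equal(mesh_schedule(256, 256), c(128, 64, 32, 16, 8, 4, 2))
  expect_equal(mesh_schedule(300, 256), c(128, 64, 32, 16, 8, 4, 2))
  expect_equal(mesh_schedule(16, 16), c(8, 4, 2))  # too few scales for a fit
  expect_error(fit_fd(box_count_curve(generate_fixture("line", 16))),
               class = "fdretina_input_error")
  expect_error(mesh_schedule(15, 300), class = "fdretina_input_error")
})

test_that("box counts match closed forms on simple shapes", {
  sq <- generate_fixture("filled_square", 8)
  expect_equal(box_count_curve(sq, c(4, 2))$counts, c(4, 16))
  px <- generate_fixture("single_pixel", 64)
  expect_equal(box_count_curve(px)$counts, rep(1L, 5))
  # dyadic-aligned gasket: count at size 2^k is exactly 3^(8-k)
  si <- generate_fixture("sierpinski", 256, depth = 8)
  expect_equal(box_count_curve(si)$counts, 3^(1:7))
  expect_error(box_count_curve(matrix(0L, 8, 8)),
               class = "fdretina_input_error")
})

test_that("counts agree exactly with the brute-force cell scan", {
  sizes <- mesh_schedule(64, 64)
  for (s in 1:25) {
    mat <- with(list(), {
      set.seed(s)
      matrix(as.integer(runif(64 * 64) < runif(1, 0.02, 0.5)), 64, 64)
    })
    if (sum(mat) == 0) next
    counts <- box_count_curve(mat, sizes)$counts
    expect_identical(counts, vapply(sizes, function(z)
      brute_box_count(mat, z), integer(1)))
  }
})

test_that("fit_fd recovers exact slopes from perfect dyadic scaling", {
  curve2 <- structure(list(sizes_px = c(8L, 4L, 2L, 1L),
                           counts = c(1L, 4L, 16L, 64L)),
                      class = "box_count_curve")
  f2 <- fit_fd(curve2)
  expect_equal(f2$fd, 2.0)
  expect_equal(f2$r_squared, 1.0)
  curve1 <- structure(list(sizes_px = c(8L, 4L, 2L, 1L),
                           counts = c(1L, 2L, 4L, 8L)),
                      class = "box_count_curve")
  expect_equal(fit_fd(curve1)$fd, 1.0)
  flat <- structure(list(sizes_px = c(8L, 4L, 2L, 1L),
                         counts = rep(3L, 4)),
                    class = "box_count_curve")
  expect_equal(fit_fd(flat)$fd, 0.0)
  short <- structure(list(sizes_px = c(4L, 2L), counts = c(1L, 2L)),
                     class = "box_count_curve")
  expect_error(fit_fd(short), class = "fdretina_input_error")
})

test_that("estimate_fd equals the stage-by-stage composition", {
  img <- generate_vessel_tree(seed = 8)
  res <- estimate_fd(img, threshold = 0.5)
  bin <- binarise(img, 0.5)
  sk <- skeletonise(bin)
  expect_true(verify_continuity(bin, sk)$passed)
  manual <- fit_fd(box_count_curve(sk))
  expect_identical(res$fd, manual$fd)
  expect_identical(attr(res, "curve")$counts,
                   box_count_curve(sk)$counts)
  # same composition holds on an area-like fixture
  fs <- generate_fixture("filled_square", 64) + 0
  resq <- estimate_fd(fs, 0.5)
  manq <- fit_fd(box_count_curve(skeletonise(binarise(fs, 0.5))))
  expect_identical(resq$fd, manq$fd)
})

test_that("known-dimension fixtures and strict ordering", {
  fd_line <- estimate_fd(generate_fixture("line", 64) + 0)$fd
  expect_lt(abs(fd_line - 1.0), 0.05)
  fd_sier <- estimate_fd(generate_fixture("sierpinski", 256, depth = 8) + 0,
                         skeletonise = FALSE)$fd
  expect_lt(abs(fd_sier - log(3) / log(2)), 0.05)
  fd_fill <- estimate_fd(generate_fixture("filled_square", 256) + 0,
                         skeletonise = FALSE)$fd
  expect_lt(fd_line, fd_sier)
  expect_lt(fd_sier, fd_fill)
})

test_that("counts are invariant to whole-mesh translations", {
  base <- matrix(0L, 256, 256)
  base[40:60, 30:55] <- generate_fixture("sierpinski", 16, depth = 4)[
    rep(1:16, length.out = 21), rep(1:16, length.out = 26)]
  shifted <- matrix(0L, 256, 256)
  shifted[(40:60) + 128, (30:55) + 128] <- base[40:60, 30:55]
  expect_identical(box_count_curve(base)$counts,
                   box_count_curve(shifted)$counts)
})
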