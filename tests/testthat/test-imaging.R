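# Stack rendering, restoration and focus detection.

small_optics <- function(...) optics_params(field_um = 4.16, ...)

test_that("optics invariants are enforced", {
  expect_error(optics_params(n_slices = 10, voxel_z_um = 0.2, depth_um = 4),
               "depth")
  expect_error(optics_params(blur_lateral_um = 0), "positive")
  o <- optics_params()
  expect_equal(o$n_slices * o$voxel_z_um, 4)
})

test_that("a noise-only stack yields no detections", {
  set.seed(60)
  stack <- render_stack(as_foci_table(matrix(numeric(0), ncol = 3)),
                        small_optics())
  expect_identical(nrow(detect_foci(stack)), 0L)
})

test_that("a single isolated focus is recovered as one spot", {
  set.seed(61)
  stack <- render_stack(as_foci_table(matrix(c(0.3, -0.2, 0), 1)),
                        small_optics())
  found <- detect_foci(stack)
  expect_identical(nrow(found), 1L)
  err <- sqrt((found$x_um - 0.3)^2 + (found$y_um + 0.2)^2 + found$z_um^2)
  expect_lt(err, 0.15)
  # detection is deterministic on a fixed stack
  expect_identical(found, detect_foci(stack))
})

test_that("ten isolated foci are recovered with sub-voxel accuracy", {
  set.seed(62)
  gt <- as_foci_table(cbind(rep(seq(-1.5, 1.5, length.out = 5), 2),
                            rep(c(-0.8, 0.8), each = 5),
                            rep(c(-0.4, 0.4), 5)))
  stack <- render_stack(gt, small_optics())
  found <- detect_foci(stack)
  expect_gte(nrow(found), 9L)
  expect_lte(nrow(found), 11L)
  # every ground-truth focus has a detection within 0.15 um
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((found$x_um - gt$x_um[i])^2 + (found$y_um - gt$y_um[i])^2 +
                (found$z_um - gt$z_um[i])^2)
    expect_lt(min(d), 0.15)
  }
})

test_that("two sub-resolution foci merge without restoration", {
  set.seed(63)
  gt <- as_foci_table(rbind(c(-0.1, 0, 0), c(0.1, 0, 0)))
  stack <- render_stack(gt, small_optics())
  raw <- detect_foci(stack, detection_params(restore_iterations = 0))
  expect_identical(nrow(raw), 1L)
})

test_that("restoration resolves clustered foci that merge in the raw image", {
  set.seed(1)
  # five cluster members on a ~0.25 um ring: a single diffuse blob before
  # deconvolution, countable members after
  ang <- 2 * pi * (1:5) / 5
  gt <- as_foci_table(cbind(0.24 * cos(ang), 0.24 * sin(ang), 0))
  gt$sigma_um <- 0.10
  gt$intensity <- 300
  stack <- render_stack(gt, small_optics())
  raw <- detect_foci(stack, detection_params(restore_iterations = 0,
                                             smooth_um = 0.05))
  rest <- detect_foci(stack, detection_params(restore_iterations = 30,
                                              smooth_um = 0.05))
  expect_lte(nrow(raw), 3L)
  expect_gte(nrow(rest), 4L)
})

test_that("integrated intensity is linear in spot amplitude", {
  o <- small_optics()
  gt1 <- as_foci_table(matrix(c(0, 0, 0), 1))
  gt1$intensity <- 100
  gt2 <- data.table::copy(gt1)
  gt2$intensity <- 200
  s1 <- render_stack(gt1, o, noise = FALSE)
  s2 <- render_stack(gt2, o, noise = FALSE)
  i1 <- sum(s1$data - o$background)
  i2 <- sum(s2$data - o$background)
  expect_equal(i2 / i1, 2, tolerance = 0.01)
})

test_that("measured widths recover the rendered spot width", {
  set.seed(65)
  gt <- as_foci_table(matrix(c(0, 0, 0), 1))
  gt$sigma_um <- 0.6 / (2 * sqrt(2 * log(2)))  # true lateral FWHM 0.6 um
  gt$intensity <- 400
  stack <- render_stack(gt, small_optics())
  found <- detect_foci(stack)
  expect_identical(nrow(found), 1L)
  expect_equal(found$width_um, 0.6, tolerance = 0.1)
})

test_that("wide-mode spots measure wider than narrow-mode spots", {
  set.seed(66)
  o <- small_optics()
  mk <- function(scale) {
    gt <- as_foci_table(matrix(c(0, 0, 0), 1))
    gt$sigma_um <- o$spot_sigma_um * scale
    gt$intensity <- 400
    w <- detect_foci(render_stack(gt, o))
    w$width_um[1]
  }
  ratio <- mk(3.5) / mk(1)
  expect_gt(ratio, 2)
})

test_that("degenerate spots are flagged rather than measured", {
  o <- small_optics()
  stack <- render_stack(as_foci_table(matrix(numeric(0), ncol = 3)), o,
                        noise = FALSE)
  stack$data[32, 32, 10] <- 1e4  # single hot voxel
  found <- detect_foci(stack, detection_params(restore_iterations = 0))
  expect_identical(nrow(found), 1L)
  expect_false(found$fit_ok)
  expect_true(is.na(found$width_um))
})

test_that("stacks round-trip through TIFF with calibration", {
  set.seed(67)
  gt <- as_foci_table(matrix(c(0.2, 0.1, 0.2), 1))
  stack <- render_stack(gt, small_optics())
  f <- tempfile(fileext = ".tif")
  write_stack(stack, f)
  back <- read_stack(f)
  expect_equal(dim(back$data), dim(stack$data))
  expect_equal(back$optics$voxel_xy_um, stack$optics$voxel_xy_um)
  expect_equal(back$data, stack$data, tolerance = 0.05)
  expect_identical(nrow(back$ground_truth), 1L)
  # a stack without sidecar metadata is rejected
  f2 <- tempfile(fileext = ".tif")
  file.copy(f, f2)
  expect_error(read_stack(f2), "metadata")
  unlink(c(f, f2, paste0(f, c(".meta.yaml", ".truth.tsv"))))
})

test_that("max projection and component labelling behave", {
  set.seed(68)
  gt <- as_foci_table(rbind(c(-1, 0, 0), c(1, 0, 0)))
  stack <- render_stack(gt, small_optics(), noise = FALSE)
  proj <- max_projection(stack)
  expect_identical(dim(proj), dim(stack$data)[1:2])
  lab <- label_components(stack$data > stack$optics$background + 5)
  expect_identical(max(lab), 2L)
})
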