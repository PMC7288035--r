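test_that("segmentation yields floor(duration/window) windows, remainder dropped", {
  mk <- function(n) make_recording(matrix(rnorm(16 * n), 16))
  expect_length(segment_recording(mk(7680)), 120)   # 60 s
  expect_length(segment_recording(mk(128)), 2)      # 1 s
  expect_length(segment_recording(mk(96)), 1)       # 0.75 s
  segs <- segment_recording(mk(7680))
  expect_equal(ncol(segs[[1]]$samples), 64)
  expect_equal(segs[[3]]$start_s, 1.0)
  expect_error(segment_recording(mk(32)), "longer than the recording")
  expect_error(segment_recording(mk(128), window_s = 1 / 3), "integer")
})

test_that("channel summaries reduce each channel in montage order", {
  seg <- segment_recording(make_recording(matrix(0, 16, 128)))[[1]]
  expect_equal(unname(channel_summary(seg)), rep(0, 16))

  x <- matrix(0, 16, 128)
  x[4, ] <- 3
  seg2 <- segment_recording(make_recording(x))[[1]]
  s <- channel_summary(seg2)
  expect_equal(unname(s[MONTAGE$channel[4]]), 3)

  x[4, ] <- rep(c(1, -1), 64)
  seg3 <- segment_recording(make_recording(x))[[1]]
  expect_equal(unname(channel_summary(seg3, "mean")[4]), 0)
  expect_equal(unname(channel_summary(seg3, "rms")[4]), 1)
})

test_that("scalp interpolation is exact at the electrodes", {
  pts <- as.matrix(MONTAGE[, c("x", "y")])
  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(16)
    f <- scalp_interpolant(v)
    expect_lt(max(abs(f(pts) - v)), 1e-6)
  }
})

test_that("a constant value vector interpolates to a constant field", {
  field <- interpolate_scalp_field(rep(4.2, 16), grid_n = 60)
  expect_equal(range(field, na.rm = TRUE), c(4.2, 4.2), tolerance = 1e-9)
})

test_that("a unit bump at Cz decays away from Cz", {
  v <- as.numeric(MONTAGE$channel == "Cz")
  f <- scalp_interpolant(v)
  expect_equal(f(matrix(c(0, 0), 1)), 1, tolerance = 1e-9)
  radii <- c(0.05, 0.15, 0.25)
  vals <- f(cbind(radii, 0))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 1)
})

test_that("interpolated grid masks pixels outside the head disk", {
  field <- interpolate_scalp_field(rnorm(16), grid_n = 50)
  g <- seq(-1, 1, length.out = 50)
  outside <- outer(g^2, g^2, "+") > 1
  expect_true(all(is.na(field[outside])))
  expect_true(all(!is.na(field[!outside])))
})

test_that("rendering maps the extremes to the jet endpoints deterministically", {
  field <- interpolate_scalp_field(c(10, rep(0, 15)), grid_n = 60)
  img <- render_topomap(field)
  expect_equal(dim(unclass(img)), c(60, 60, 3))
  # the field maximum renders dark red (high r, zero g/b), minimum dark blue
  imax <- which(field == max(field, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(img[imax[1], imax[2], ]), c(128, 0, 0))
  imin <- which(field == min(field, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(img[imin[1], imin[2], ]), c(0, 0, 128))
  expect_identical(render_topomap(field), img)
})

test_that("a constant field renders as the uniform colormap midpoint", {
  img <- render_topomap(interpolate_scalp_field(rep(1, 16), grid_n = 40))
  g <- seq(-1, 1, length.out = 40)
  inside <- outer(g^2, g^2, "+") <= 1
  mid <- 255 * jet_colormap(0.5)
  for (k in 1:3) {
    plane <- img[, , k][inside]
    expect_true(all(plane == round(mid[k])))
  }
})

test_that("background pixels outside the disk are uniform white", {
  img <- render_topomap(interpolate_scalp_field(rnorm(16), grid_n = 40))
  g <- seq(-1, 1, length.out = 40)
  outside <- outer(g^2, g^2, "+") > 1
  for (k in 1:3) expect_true(all(img[, , k][outside] == 255L))
})

test_that("per-image scaling makes images invariant to joint affine changes", {
  seg <- segment_recording(small_study()$recordings[[1]])[[1]]
  img1 <- topomap_image(seg, grid_n = 40)
  seg2 <- seg
  seg2$samples <- 3.7 * seg$samples + 11
  img2 <- topomap_image(seg2, grid_n = 40)
  expect_identical(unclass(img1)[, , ], unclass(img2)[, , ])
})

test_that("study_images renders 120 segments per 60 s recording with labels", {
  st <- small_study()  # 8 s recordings -> 16 segments each
  iml <- study_images(st, grid_n = 30)
  expect_equal(dim(iml$images), c(30, 30, 3, 2 * 4 * 16))
  expect_equal(nrow(iml$meta), 128)
  expect_setequal(unique(iml$meta$category), CATS)
  expect_true(all(range(iml$images) >= 0 & range(iml$images) <= 1))
})

test_that("write_topomaps writes PNGs named by labels plus a manifest", {
  st <- generate_study(n_pairs = 1, seed = 5, duration_s = 1)
  st <- preprocess_study(st)
  dir <- withr::local_tempdir()
  mf <- write_topomaps(st, dir, grid_n = 24)
  expect_equal(nrow(mf), 4 * 2)
  expect_true(all(file.exists(file.path(dir, mf$filename))))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_match(mf$filename[1], "^P01_(HKT|BSC)_(process_owner|leader)_\\d+\\.png$")
  back <- read_topomaps(dir)
  expect_equal(dim(back$images), c(24, 24, 3, 8))
})
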