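test_that("afm_image validates its inputs and round-trips as text raster", {
  expect_error(afm_image(matrix(c(1, NA), 1), 2), "finite")
  expect_error(afm_image(matrix(0, 4, 4), 0), "pixel_size")
  img <- afm_image(matrix(stats::rnorm(64), 8, 8), 1.95, frame_time = 37)
  tmp <- tempfile(fileext = ".txt")
  write_afm_raster(img, tmp)
  back <- read_afm_raster(tmp)
  expect_equal(back$heights, img$heights, tolerance = 1e-6)
  expect_equal(back$pixel_size, 1.95)
  expect_equal(back$frame_time, 37)
})

test_that("line flattening removes polynomial background exactly", {
  x <- 1:96
  bg <- t(sapply(1:64, function(r) 0.01 * r + 0.002 * x +
                   1e-4 * (x - 48)^2))
  fl <- flatten(afm_image(bg, 2), 2)
  expect_lt(max(abs(fl$heights)), 1e-9)
  # idempotence
  fl2 <- flatten(fl, 2)
  expect_equal(fl2$heights, fl$heights, tolerance = 1e-9)
  expect_error(flatten(afm_image(bg, 2), 4), "order")
})

test_that("flattening preserves the height of molecules crossing lines", {
  x <- 1:96
  bg <- t(sapply(1:64, function(r) 0.01 * r + 0.002 * x +
                   1e-4 * (x - 48)^2))
  rod <- matrix(0, 64, 96)
  rod[10:50, 40:42] <- 1.0
  fl <- flatten(afm_image(bg + rod, 2), 2)
  expect_equal(max(fl$heights), 1.0, tolerance = 0.02)
})

test_that("rod skeletons recover length within tolerance across angles", {
  errs <- c()
  for (seed in 1:12) {
    set.seed(seed)
    ang <- stats::runif(1, 0, pi)
    L <- stats::runif(1, 100, 350)
    img <- render_rod(L, ang, noise_sd = 0.3, seed = seed)
    trs <- skeletonize_molecule(img, flatten_first = FALSE)
    expect_length(trs, 1)
    errs <- c(errs, abs(trs[[1]]$contour_length - L) / L)
  }
  expect_lt(max(errs), 0.05)
  expect_lt(stats::median(errs), 0.03)
})

test_that("bp length is contour length over 0.36 by construction", {
  img <- render_rod(200, 0.4, seed = 3)
  tr <- skeletonize_molecule(img, flatten_first = FALSE)[[1]]
  expect_equal(tr$bp_length * 0.36, tr$contour_length, tolerance = 1e-12)
  rs <- resample_trace(tr)
  # chords between per-bp resampled points track the 0.36 nm arc spacing
  expect_equal(mean(sqrt(rowSums(diff(rs$path)^2))), 0.36,
               tolerance = 1e-3)
})

test_that("disjoint molecules give separate traces; blank noise gives none", {
  p1 <- cbind(seq(40, 160, length.out = 300), rep(60, 300))
  p2 <- cbind(seq(40, 160, length.out = 300), rep(180, 300))
  img <- render_afm_image(image_design(128, 2,
    list(list(path = p1, height = 1), list(path = p2, height = 1)),
    noise_sd = 0.25, seed = 3))
  expect_length(skeletonize_molecule(img, flatten_first = FALSE), 2)
  blank <- render_afm_image(image_design(128, 2, list(),
                                         noise_sd = 0.3, seed = 5))
  expect_length(skeletonize_molecule(blank, flatten_first = FALSE), 0)
})

test_that("thinning reduces thick strokes to unit-width connected paths", {
  m <- matrix(0L, 40, 40)
  m[18:21, 5:35] <- 1L          # 4-px thick horizontal bar
  sk <- thin_binary(m)
  deg <- curvafm:::skel_degree(sk)
  expect_true(all(deg[sk == 1] <= 2))
  expect_identical(sum(sk == 1 & deg == 1), 2L)
  # diagonal strip: no junction artifacts
  d <- matrix(0L, 40, 40)
  for (k in 5:30) d[k + (0:1), k + (0:1)] <- 1L
  skd <- thin_binary(d)
  degd <- curvafm:::skel_degree(skd)
  expect_true(all(degd[skd == 1] <= 2))
})

test_that("rendered noiseless rod has the designed crest height", {
  img <- render_rod(120, 0.9, noise_sd = 0, seed = 1, height = 1.0)
  expect_equal(max(img$heights), 1.0, tolerance = 0.01)
  expect_error(render_afm_image(image_design(64, 2,
    list(list(path = cbind(c(-5, 300), c(0, 0)), height = 1)))),
    "frame")
})
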