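test_that("Ends ratio closed forms: straight line and semicircle", {
  straight <- cbind(0.34 * (0:299), 0, 0)
  prof <- ends_ratio(straight, 1, 150)
  expect_true(all(prof$value == 1))
  # semicircular arc spanning exactly one window: arc/chord = pi/2
  th <- seq(0, pi, length.out = 151)
  semi <- cbind(cos(th), sin(th))
  v <- ends_ratio(semi, 1, 150)$value
  expect_equal(v, pi / 2, tolerance = 1e-4)
})

test_that("Ends ratio equals brute-force recomputation on random windows", {
  s <- gen_control_sequence(600, seed = 21)
  P <- build_trajectory(s)$points
  prof <- ends_ratio(P, 1, 150)
  set.seed(22)
  for (i in sample(nrow(prof), 100, replace = TRUE)) {
    expect_equal(prof$value[i], brute_ends_ratio(P, i, 150),
                 tolerance = 1e-9)
  }
})

test_that("Ends ratio is invariant under rigid motion and uniform scaling", {
  s <- gen_control_sequence(400, seed = 23)
  P <- build_trajectory(s)$points
  v0 <- ends_ratio(P, 1, 150)$value
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  P2 <- sweep(P %*% R, 2, c(10, -4, 2), "+")
  expect_equal(ends_ratio(P2, 1, 150)$value, v0, tolerance = 1e-12)
  expect_equal(ends_ratio(3.7 * P, 1, 150)$value, v0, tolerance = 1e-12)
})

test_that("window growth never lowers the arc/chord ratio on a circle", {
  th <- seq(0, 1.8 * pi, length.out = 400)
  circ <- cbind(cos(th), sin(th))
  vals <- vapply(c(50, 100, 200, 300), function(w)
    max(ends_ratio(circ, 1, w)$value), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("degenerate windows are rejected gracefully", {
  short <- cbind(0:50 * 0.34, 0, 0)
  expect_warning(prof <- ends_ratio(short, 1, 150), "longer than")
  expect_identical(nrow(prof), 0L)
})

test_that("curvature map at the native pitch row matches the direct profile", {
  s <- gen_control_sequence(400, seed = 31)
  native <- helical_repeat(default_step_table())
  m <- curvature_map(s, pitches = c(8, native, 13))
  direct <- seq_ends_ratio(s)
  expect_equal(m$values[, 2], direct$value, tolerance = 1e-12)
  expect_identical(m$centers, direct$center)
})

test_that("phased tracts put the map maximum at the phasing pitch", {
  s <- gen_phased_sequence(400, 8, tract_len = 5,
                           tract_region = c(120, 280), seed = 7)
  m <- curvature_map(s)
  peak <- arrayInd(which.max(m$values), dim(m$values))
  expect_lte(m$pitches[peak[2]], 9)
  gt <- attr(s, "ground_truth")
  expect_gte(m$centers[peak[1]], gt$region[1] - 75)
  expect_lte(m$centers[peak[1]], gt$region[2] + 75)
})

test_that("supercoil calls recover handedness from the phasing period", {
  for (cfg in list(list(period = 8, hand = "left"),
                   list(period = 13, hand = "right"))) {
    s <- gen_phased_sequence(400, cfg$period, tract_len = 5,
                             tract_region = c(120, 280), seed = 7)
    calls <- call_supercoils(curvature_map(s))
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$handedness, cfg$hand)
    expect_equal(calls$peak_pitch, cfg$period, tolerance = 0.5)
  }
  # canonical-period phasing is planar curvature, not a supercoil
  s <- gen_phased_sequence(400, 10.5, tract_len = 5,
                           tract_region = c(120, 280), seed = 7)
  expect_identical(nrow(call_supercoils(curvature_map(s))), 0L)
  # and a straight-ish pure-GC sequence yields no call at all
  expect_identical(nrow(call_supercoils(curvature_map(
    gen_control_sequence(400, gc = 1, seed = 1)))), 0L)
})

test_that("random control sequences rarely trigger supercoil calls", {
  fp <- vapply(1:40, function(seed) {
    nrow(call_supercoils(curvature_map(
      gen_control_sequence(976, 0.5, seed = seed)))) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.10)
})

test_that("apex position takes the global maximum, ties toward 3'", {
  prof <- structure(data.frame(center = c(-60, -50, -40, -30),
                               value = c(1.1, 1.2, 1.5, 1.2)),
                    class = c("ends_ratio_profile", "data.frame"))
  expect_identical(apex_position(prof), -40)
  flat <- prof
  flat$value <- rep(1, 4)
  expect_identical(apex_position(flat), -30)
})

test_that("map export and wig export round-trip the values", {
  s <- gen_control_sequence(300, seed = 41)
  m <- curvature_map(s, pitches = c(7, 10.5, 13), window_len = 150)
  tmp <- tempfile(fileext = ".tsv")
  write_curvature_map_tsv(m, tmp)
  back <- utils::read.table(tmp, header = TRUE)
  expect_identical(nrow(back), length(m$centers) * 3L)
  expect_equal(matrix(back$value, ncol = 3), unname(m$values))
})
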