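test_that("default step table is complete and complement-symmetric", {
  tab <- default_step_table()
  expect_identical(nrow(tab), 16L)
  expect_true(all(tab$twist > 0 & tab$twist < 90))
  expect_gt(helical_repeat(tab), 9)
  expect_lt(helical_repeat(tab), 12)
  rc <- function(d) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(d, "")[[1]]), collapse = ""))
  for (d in rownames(tab)) {
    e <- rc(d)
    expect_equal(tab[d, "roll"], tab[e, "roll"])
    expect_equal(tab[d, "tilt"], -tab[e, "tilt"])
    expect_equal(tab[d, "twist"], tab[e, "twist"])
  }
})

test_that("twist rescaling hits the target repeat and is identity at native", {
  tab <- default_step_table()
  native <- helical_repeat(tab)
  expect_equal(rescale_twist(tab, native)$twist, tab$twist)
  expect_equal(mean(rescale_twist(tab, 7.5)$twist), 48)
  expect_equal(mean(rescale_twist(tab, 13.5)$twist), 360 / 13.5,
               tolerance = 1e-12)
  expect_equal(helical_repeat(rescale_twist(tab, 8.25)), 8.25)
})

test_that("contour length is exact and pure twist cannot bend the axis", {
  s <- genomic_sequence(random_bases(200, 1))
  traj <- build_trajectory(s)
  seg <- sqrt(rowSums(diff(traj$points)^2))
  expect_equal(seg, rep(0.34, 199), tolerance = 1e-12)
  expect_equal(contour_length(traj), 199 * 0.34, tolerance = 1e-9)
  # roll = tilt = 0: collinear points, end-to-end = (n-1) * rise
  tab0 <- default_step_table()
  tab0$roll[] <- 0
  tab0$tilt[] <- 0
  t0 <- build_trajectory(s, tab0)
  e2e <- sqrt(sum((t0$points[200, ] - t0$points[1, ])^2))
  expect_equal(e2e, 199 * 0.34, tolerance = 1e-9)
})

test_that("pitch override at the native repeat reproduces the trajectory", {
  s <- genomic_sequence(random_bases(300, 2))
  tab <- default_step_table()
  t1 <- build_trajectory(s, tab)
  t2 <- build_trajectory(s, tab, pitch = helical_repeat(tab))
  expect_equal(t1$points, t2$points, tolerance = 1e-12)
  expect_error(build_trajectory(s, tab, pitch = 3), "pitch")
})

test_that("reverse-complement trajectory superimposes on the reversed one", {
  for (seed in 1:3) {
    s <- gen_control_sequence(250, gc = 0.5, seed = seed)
    A <- build_trajectory(s)$points
    B <- build_trajectory(reverse_complement(s))$points
    expect_lt(kabsch_rmsd(A, B[nrow(B):1, ]), 1e-6)
  }
})

test_that("phased A-tracts at the canonical period give a near-planar arc", {
  s <- gen_phased_sequence(105, 10.5, tract_len = 5, gc = 1, seed = 1)
  P <- build_trajectory(s)$points
  C <- sweep(P, 2, colMeans(P))
  sv <- svd(C)
  out_of_plane <- C %*% sv$v[, 3]
  proj <- C %*% sv$v[, 1:2]
  # least-squares circle through the in-plane projection
  sol <- qr.solve(cbind(2 * proj, 1), rowSums(proj^2))
  radius <- sqrt(sol[3] + sum(sol[1:2]^2))
  # phased tracts curve the axis in one plane: the residual out-of-plane
  # deviation stays a small fraction of the turn radius, while a random
  # sequence of the same length is strongly three-dimensional
  expect_lt(max(abs(out_of_plane)) / radius, 0.25)
  # the in-phase tracts bend the axis into a tight arc: far more curvature
  # than a random sequence of the same length
  er_phased <- max(ends_ratio(P, 1, 100)$value)
  r <- gen_control_sequence(105, gc = 0.5, seed = 4)
  er_random <- max(ends_ratio(build_trajectory(r)$points, 1, 100)$value)
  expect_gt(er_phased, 2)
  expect_lt(er_random, 1.5)
})

test_that("step table reader validates completeness and twist range", {
  tab <- default_step_table()
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(tab[tab$step != "GT", ],
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_step_table(tmp), "16 dinucleotides")
  bad <- tab
  bad$twist[1] <- 95
  utils::write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_step_table(tmp), "twist")
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_step_table(tmp)$twist, tab$twist)
})

test_that("model height profile is per-base, standardized and seeded", {
  p <- synthetic_promoter()
  m <- model_height_profile(p)
  expect_length(m, length(p))
  expect_equal(mean(m), 0, tolerance = 1e-9)
  expect_equal(stats::sd(m), 1, tolerance = 1e-9)
})
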