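test_that("dyad arithmetic follows the arm-length formula", {
  call <- map_nucleosome(898, 500, 250)
  expect_equal(call$extra, 148)          # Lc = L - (L+ + L-)
  expect_equal(call$position, 574)       # L+ + Lc/2
  # symmetric arms put the dyad at the fragment center
  expect_equal(map_nucleosome(898, 375.5, 375.5)$position, 449)
  expect_error(map_nucleosome(898, 500, 398), "wrapped")
  expect_error(map_nucleosome(898, 200, 300), "L_plus")
  # consistency identity: both arm-side computations agree
  for (k in 1:20) {
    set.seed(k)
    L <- sample(500:1500, 1)
    Lc <- sample(100:160, 1)
    Lp <- stats::runif(1, (L - Lc) / 2, L - Lc)
    Lm <- L - Lc - Lp
    call <- map_nucleosome(L, Lp, Lm)
    expect_equal(Lp + call$extra / 2 + (Lm + call$extra / 2), L)
  }
})

test_that("rendered nucleosomes map back to the planned dyad", {
  errs <- vapply(1:8, function(seed) {
    set.seed(seed)
    dyad <- stats::runif(1, 300, 600)
    img <- make_nucleosome_image(dyad, seed = seed)
    if (is.null(img)) return(NA_real_)
    trs <- skeletonize_molecule(img, flatten_first = FALSE)
    if (length(trs) != 1) return(NA_real_)
    call <- measure_nucleosome(trs[[1]], 898)
    if (is.null(call)) return(NA_real_)
    mirror_err(call$position, dyad, 898)
  }, numeric(1))
  expect_gte(sum(!is.na(errs)), 6)
  expect_lte(stats::median(errs, na.rm = TRUE), 10)
})

test_that("protein bumps are called at the planned position", {
  w <- sample_wlc_2d(563, 120, seed = 9, start = c(150, 150),
                     heading = 1.0)
  img <- render_afm_image(image_design(256, 2,
    list(list(path = w, height = 1.0)),
    particles = list(list(molecule = 1, position_bp = 430, height = 1.7,
                          width_nm = 3)),
    noise_sd = 0.3, seed = 21))
  tr <- skeletonize_molecule(img, flatten_first = FALSE)[[1]]
  call <- map_protein(tr)
  expect_identical(call$kind, "protein")
  expect_lte(mirror_err(call$position, 430, 563), 15)
  # bare DNA: no call
  bare <- render_afm_image(image_design(256, 2,
    list(list(path = w, height = 1.0)), noise_sd = 0.3, seed = 22))
  trb <- skeletonize_molecule(bare, flatten_first = FALSE)[[1]]
  expect_identical(nrow(map_protein(trb)), 0L)
})

test_that("with two bumps the more prominent wins, verbose returns both", {
  w <- sample_wlc_2d(700, 200, seed = 12, start = c(140, 160),
                     heading = 0.6)
  img <- render_afm_image(image_design(256, 2,
    list(list(path = w, height = 1.0)),
    particles = list(
      list(molecule = 1, position_bp = 200, height = 1.8, width_nm = 4),
      list(molecule = 1, position_bp = 500, height = 2.2, width_nm = 4)),
    noise_sd = 0.25, seed = 31))
  tr <- skeletonize_molecule(img, flatten_first = FALSE)[[1]]
  best <- map_protein(tr)
  all_calls <- map_protein(tr, verbose = TRUE)
  expect_gte(nrow(all_calls), 2)
  expect_lte(mirror_err(best$position, 500, 700), 20)
})

test_that("loops are detected with length, midpoint and over-strand", {
  lp <- gen_loop_path(total_bp = 898, loop_mid_bp = 450, loop_len_bp = 260,
                      seed = 3)
  path <- sweep(lp$path, 2, apply(lp$path, 2, min)) + 60
  img <- render_afm_image(image_design(256, 2,
    list(list(path = path, height = 1.0)), noise_sd = 0.3, seed = 11))
  tr <- skeletonize_molecule(img, flatten_first = FALSE)[[1]]
  res <- detect_loop(tr, img)
  expect_false(is.null(res))
  expect_lt(abs(res$placement$extra - 260) / 260, 0.10)
  expect_lte(mirror_err(res$placement$position, 450, 898), 20)
  # crossing summit stands above the single-helix height
  expect_gte(res$crossing$summit_height, 1.3)
  # a bent but non-crossing molecule gives no call
  w <- sample_wlc_2d(500, 120, seed = 5, start = c(150, 150), heading = 0)
  img2 <- render_afm_image(image_design(256, 2,
    list(list(path = w, height = 1.0)), noise_sd = 0.25, seed = 12))
  tr2 <- skeletonize_molecule(img2, flatten_first = FALSE)[[1]]
  expect_null(detect_loop(tr2, img2))
})

test_that("crossing summits render in the capped range and pick the over-strand", {
  # two straight strands crossing at right angles, one 0.5 nm higher
  pa <- cbind(seq(40, 200, length.out = 500), rep(120, 500))
  pb <- cbind(rep(120, 500), seq(40, 200, length.out = 500))
  img <- render_afm_image(image_design(128, 2,
    list(list(path = pa, height = 1.0), list(path = pb, height = 1.0)),
    noise_sd = 0, seed = 1))
  ctr <- img$heights[55:67, 55:67]
  expect_gte(max(ctr), 1.5)
  expect_lte(max(ctr), 1.6)
})

test_that("orientation by height profile is exact on clean model signals", {
  p <- synthetic_promoter()
  model <- model_height_profile(p)
  path <- cbind(seq(0, by = 0.36, length.out = length(model)), 0)
  tr_f <- molecule_trace(path, model, 2)
  o_f <- orient_molecule(tr_f, model)
  expect_identical(o_f$orientation, "forward")
  expect_equal(o_f$r_forward, 1.0, tolerance = 1e-6)
  tr_r <- molecule_trace(path, rev(model), 2)
  o_r <- orient_molecule(tr_r, model)
  expect_identical(o_r$orientation, "reverse")
  expect_equal(o_r$r_reverse, 1.0, tolerance = 1e-6)
  # the returned trace is flipped so heights run 5' to 3'
  expect_equal(o_r$trace$heights, model, tolerance = 1e-9)
  # length mismatch refuses orientation with a reason
  short <- molecule_trace(path[1:500, ], model[1:500], 2)
  o_s <- orient_molecule(short, model)
  expect_false(o_s$oriented)
  expect_match(o_s$reason, "length mismatch")
})

test_that("noisy molecules orient correctly in most replicates", {
  p <- synthetic_promoter()
  model <- model_height_profile(p)
  n <- length(model)
  path <- cbind(seq(0, by = 0.36, length.out = n), 0)
  succ <- vapply(1:60, function(s) {
    set.seed(s)
    fwd <- s %% 2 == 0
    prof <- 1 + 0.15 * (if (fwd) model else rev(model)) +
      stats::rnorm(n, 0, 0.3)
    o <- orient_molecule(molecule_trace(path, prof, 2), model)
    o$oriented && o$orientation == (if (fwd) "forward" else "reverse")
  }, logical(1))
  expect_gte(mean(succ), 0.8)
})

test_that("apex tracking recovers a moving bend and reports frame times", {
  mk_frame <- function(shift, t) {
    n <- 500
    th <- 1.2 * exp(-((1:n) - (200 + shift))^2 / (2 * 25^2))
    theta <- cumsum(th) * 0.04
    x <- c(0, cumsum(0.36 * cos(theta)))
    y <- c(0, cumsum(0.36 * sin(theta)))
    tr <- molecule_trace(cbind(x, y), rep(1, n + 1), 2, frame_time = t)
    tr$oriented <- TRUE
    tr
  }
  frames <- lapply(0:3, function(k) mk_frame(30 * k, 37 * k))
  res <- track_apex(frames)
  expect_equal(res$time, c(0, 37, 74, 111))
  expect_equal(attr(res, "net_displacement_bp"), 90, tolerance = 15)
  # identical frames: zero displacement
  same <- lapply(0:2, function(k) mk_frame(0, 37 * k))
  expect_equal(attr(track_apex(same), "net_displacement_bp"), 0)
  # unoriented frames are dropped with a warning
  bad <- frames
  bad[[2]]$oriented <- FALSE
  expect_warning(track_apex(bad), "unoriented")
})
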