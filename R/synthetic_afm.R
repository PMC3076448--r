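#' Sample a 2D-equilibrated worm-like chain
#'
#' Discrete worm-like chain in the plane: per segment of length l the
#' tangent angle picks up an independent Gaussian increment of variance
#' l / persistence (the 2D-equilibrated convention, under which the
#' tangent autocorrelation decays as exp(-s / (2 * persistence))). This is
#' the conformational model for DNA molecules equilibrated on a mica
#' surface before capture; it is not a projected 3D chain.
#'
#' @param length_bp chain length in base pairs (0.36 nm/bp).
#' @param persistence_nm persistence length in nm (~50 for B-DNA);
#'   `Inf` gives a straight path.
#' @param seed RNG seed.
#' @param segment_bp discretization in bp per segment (default 1).
#' @param start,heading starting point (nm) and initial tangent angle
#'   (radians).
#' @return (n+1) x 2 matrix of positions in nm.
#' @export
sample_wlc_2d <- function(length_bp, persistence_nm = 50, seed = 1,
                          segment_bp = 1, start = c(0, 0), heading = 0) {
  withr_seed(seed)
  nseg <- max(1L, ceiling(length_bp / segment_bp) - 1L)  # L bp -> L points
  l <- segment_bp * NM_PER_BP
  dtheta <- if (is.infinite(persistence_nm)) rep(0, nseg - 1)
            else stats::rnorm(nseg - 1, 0, sqrt(l / persistence_nm))
  theta <- heading + c(0, cumsum(dtheta))
  x <- start[1] + c(0, cumsum(l * cos(theta)))
  y <- start[2] + c(0, cumsum(l * sin(theta)))
  cbind(x = x, y = y)
}

#' Estimate the persistence length of 2D chains from tangent correlations
#'
#' For 2D-equilibrated chains the tangent autocorrelation is
#' <t(s+ds) . t(s)> = exp(-ds / (2 Lp)); Lp is recovered from a zero-
#' intercept log-linear fit over a set of contour lags.
#'
#' @param paths list of n x 2 path matrices (nm).
#' @param lags_nm contour lags at which the correlation is evaluated.
#' @return estimated persistence length in nm.
#' @export
estimate_persistence_2d <- function(paths, lags_nm = seq(5, 30, by = 5)) {
  corsum <- numeric(length(lags_nm))
  l <- mean(sqrt(rowSums(diff(paths[[1]])^2)))
  for (P in paths) {
    th <- atan2(diff(P[, 2]), diff(P[, 1]))
    for (k in seq_along(lags_nm)) {
      lag <- max(1L, round(lags_nm[k] / l))
      i <- seq_len(length(th) - lag)
      corsum[k] <- corsum[k] + mean(cos(th[i + lag] - th[i]))
    }
  }
  cc <- corsum / length(paths)
  fit <- stats::lm.fit(matrix(lags_nm, ncol = 1), log(cc))
  unname(-1 / (2 * fit$coefficients))
}

#' Designed molecule path containing one loop
#'
#' Deterministic geometry for ground-truth loop studies: a straight-ish
#' incoming arm, a 270-degree circular arc whose exit strand crosses the
#' incoming arm at right angles (a teardrop loop), and an outgoing arm.
#' The loop contour (between the two crossing passages) has the requested
#' length; mild WLC wiggle can be added to the arms.
#'
#' @param total_bp total molecule length in bp.
#' @param loop_mid_bp planned contour position of the loop middle point.
#' @param loop_len_bp planned loop contour length in bp.
#' @param wiggle_persistence_nm persistence for the arm wiggle (large =
#'   nearly straight); `Inf` disables it.
#' @param seed RNG seed for the wiggle.
#' @return list: `path` (n x 2 nm, one point per bp), `crossing_bp` (the
#'   two passage positions), `loop_mid_bp`, `loop_len_bp`.
#' @export
gen_loop_path <- function(total_bp, loop_mid_bp, loop_len_bp,
                          wiggle_persistence_nm = 2000, seed = 1) {
  # teardrop: the incoming arm overshoots the crossing by R, turns left
  # through a 270-degree arc, and exits perpendicularly back across the
  # arm; loop contour = R + 1.5*pi*R + R, which sets R
  Lloop <- loop_len_bp * NM_PER_BP
  R <- Lloop / (2 + 1.5 * pi)
  s1 <- loop_mid_bp - loop_len_bp / 2        # first passage (bp)
  s2 <- loop_mid_bp + loop_len_bp / 2
  if (s1 < 5 || s2 > total_bp - 5)
    stop("loop does not fit inside the molecule")
  arc_start_bp <- s1 + R / NM_PER_BP          # arm continues R nm past s1
  n_arc <- round(1.5 * pi * R / NM_PER_BP)
  withr_seed(seed)
  l <- NM_PER_BP
  # tangent angles per bp step
  n_arm1 <- round(arc_start_bp)
  th1 <- cumsum(c(0, stats::rnorm(n_arm1 - 1, 0,
                                  sqrt(l / wiggle_persistence_nm))))
  th_arc <- th1[n_arm1] + 1.5 * pi * seq_len(n_arc) / n_arc
  n_arm2 <- total_bp - n_arm1 - n_arc
  th2 <- th_arc[n_arc] + cumsum(stats::rnorm(n_arm2, 0,
                                 sqrt(l / wiggle_persistence_nm)))
  theta <- c(th1, th_arc, th2)
  x <- c(0, cumsum(l * cos(theta)))
  y <- c(0, cumsum(l * sin(theta)))
  list(path = cbind(x = x, y = y),
       crossing_bp = c(s1, s2), loop_mid_bp = loop_mid_bp,
       loop_len_bp = loop_len_bp)
}

#' Design for a synthetic AFM image
#'
#' @param size_px image size (pixels, square).
#' @param pixel_size nm per pixel.
#' @param molecules list of molecule specs: each a list with `path`
#'   (n x 2 nm), `height` (ridge height nm), optional `width_nm` (ridge
#'   Gaussian sigma, default 2).
#' @param particles list of particle specs: each a list with `molecule`
#'   (index), `position_bp`, `height` (absolute nm), `width_nm` (Gaussian
#'   sigma).
#' @param noise_sd additive Gaussian noise SD in nm.
#' @param tip_sigma_nm Gaussian tip-broadening sigma (0 disables).
#' @param crossing_cap height cap where ridges overlap (nm); crossing
#'   summits render in the 1.5-1.6 nm range for 1 nm ridges with the
#'   default 1.6 cap.
#' @param frame_time optional frame time (s).
#' @param seed RNG seed for the noise.
#' @export
image_design <- function(size_px = 256, pixel_size = 2, molecules = list(),
                         particles = list(), noise_sd = 0.3,
                         tip_sigma_nm = 0, crossing_cap = 1.6,
                         frame_time = NULL, seed = 1) {
  stopifnot(noise_sd >= 0, pixel_size > 0)
  list(size_px = size_px, pixel_size = pixel_size, molecules = molecules,
       particles = particles, noise_sd = noise_sd,
       tip_sigma_nm = tip_sigma_nm, crossing_cap = crossing_cap,
       frame_time = frame_time, seed = seed)
}

#' Render a synthetic AFM height image with ground truth
#'
#' Molecule paths are rasterized as Gaussian-profile ridges of the given
#' crest height; where two strands overlap (a crossing) their
#' contributions add and are clipped at `crossing_cap`, reproducing the
#' observed summit range without modelling tip physics. Particles are
#' Gaussian bumps anchored at a contour position of their molecule.
#' Optional Gaussian tip broadening, then additive Gaussian noise.
#'
#' @param design an [image_design()].
#' @return an [afm_image()] with attribute `ground_truth` (the design plus
#'   derived particle positions in nm).
#' @export
render_afm_image <- function(design) {
  npx <- design$size_px
  px <- design$pixel_size
  H <- matrix(0, npx, npx)
  cap <- design$crossing_cap
  for (mol in design$molecules) {
    P <- as.matrix(mol$path)
    lim <- (npx - 1) * px
    if (any(P < 0) || any(P > lim))
      stop("molecule exceeds the image frame")
    sigma <- if (is.null(mol$width_nm)) 2 else mol$width_nm
    # `height` may be a per-path-point vector (e.g. sequence-dependent
    # height modulation along the molecule)
    H <- pmin(H + raster_ridge(P, mol$height, sigma, npx, px), cap)
  }
  gt_particles <- list()
  for (pt in design$particles) {
    mol <- design$molecules[[pt$molecule]]
    P <- as.matrix(mol$path)
    cs <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    s <- pt$position_bp * NM_PER_BP
    cx <- stats::approx(cs, P[, 1], xout = s)$y
    cy <- stats::approx(cs, P[, 2], xout = s)$y
    H <- pmax(H, gauss_bump(cx, cy, pt$height, pt$width_nm, npx, px))
    gt_particles[[length(gt_particles) + 1]] <-
      c(x = cx, y = cy, position_bp = pt$position_bp)
  }
  if (design$tip_sigma_nm > 0)
    H <- as.matrix(gaussian_blur(H, design$tip_sigma_nm / px))
  withr_seed(design$seed)
  if (design$noise_sd > 0)
    H <- H + matrix(stats::rnorm(npx * npx, 0, design$noise_sd), npx, npx)
  img <- afm_image(H, px, design$frame_time)
  attr(img, "ground_truth") <- c(design, list(particle_xy = gt_particles))
  img
}

# max-envelope ridge rasterization; same-passage stamps combine by max,
# contour-distant passages (> 30 bp apart) by summation, so self-crossings
# add up like two independent strands
raster_ridge <- function(P, height, sigma, npx, px, passage_gap_bp = 30) {
  best1 <- matrix(0, npx, npx); pos1 <- matrix(-Inf, npx, npx)
  best2 <- matrix(0, npx, npx)
  hw <- ceiling(3 * sigma / px)
  # resample the path to ~half-pixel spacing for a smooth envelope
  cs <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  s <- seq(0, cs[length(cs)], by = px / 2)
  xs <- stats::approx(cs, P[, 1], xout = s)$y
  ys <- stats::approx(cs, P[, 2], xout = s)$y
  hvec <- if (length(height) == 1) rep(height, length(s))
          else stats::approx(cs, rep_len(height, nrow(P)), xout = s)$y
  sbp <- s / NM_PER_BP
  for (k in seq_along(s)) {
    cc <- round(xs[k] / px) + 1
    rr <- round(ys[k] / px) + 1
    r0 <- max(1, rr - hw); r1 <- min(npx, rr + hw)
    c0 <- max(1, cc - hw); c1 <- min(npx, cc + hw)
    gx <- ((c0:c1) - 1) * px - xs[k]
    gy <- ((r0:r1) - 1) * px - ys[k]
    g <- hvec[k] * exp(-(outer(gy^2, gx^2, "+")) / (2 * sigma^2))
    b1 <- best1[r0:r1, c0:c1]; p1 <- pos1[r0:r1, c0:c1]
    b2 <- best2[r0:r1, c0:c1]
    same <- abs(p1 - sbp[k]) < passage_gap_bp | !is.finite(p1)
    upd1 <- same & g > b1
    promote <- !same & g > b1        # new passage beats the current best
    b2[promote] <- pmax(b2[promote], b1[promote])
    b1[upd1 | promote] <- g[upd1 | promote]
    p1[upd1 | promote] <- sbp[k]
    b2[!same & !promote] <- pmax(b2[!same & !promote], g[!same & !promote])
    best1[r0:r1, c0:c1] <- b1; pos1[r0:r1, c0:c1] <- p1
    best2[r0:r1, c0:c1] <- b2
  }
  best1 + best2
}

gauss_bump <- function(cx, cy, height, sigma, npx, px) {
  gx <- ((1:npx) - 1) * px - cx
  gy <- ((1:npx) - 1) * px - cy
  height * exp(-outer(gy^2, gx^2, "+") / (2 * sigma^2))
}
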