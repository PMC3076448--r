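# Shared helpers: independent oracles and small constructors used across
# test files. The oracles are deliberately naive (explicit loops, no shared
# code with the implementation).

# rigid-body superposition residual (Kabsch, proper rotations only)
kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((B - A %*% t(R))^2)))
}

# brute-force Ends ratio of the window starting at point i (1-based),
# covering m segments
brute_ends_ratio <- function(points, i, m) {
  arc <- 0
  for (k in i:(i + m - 1)) {
    arc <- arc + sqrt(sum((points[k + 1, ] - points[k, ])^2))
  }
  chord <- sqrt(sum((points[i + m, ] - points[i, ])^2))
  arc / chord
}

# brute-force nearest-neighbor window dG: explicit step enumeration
brute_window_dG <- function(bases, dg16) {
  tot <- 0
  for (k in 1:(nchar(bases) - 1)) {
    tot <- tot + dg16[[substr(bases, k, k + 1)]]
  }
  tot / (nchar(bases) - 1)
}

random_bases <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# nucleosome-loaded molecule: two worm-like-chain arms joined at the
# particle, rendered with the particle bump at the junction
make_nucleosome_image <- function(dyad_bp, L_bp = 898, seed = 1,
                                  noise_sd = 0.3) {
  wrap <- 147
  arm1_bp <- dyad_bp - wrap / 2
  arm2_bp <- L_bp - dyad_bp - wrap / 2
  w1 <- sample_wlc_2d(round(arm1_bp), 150, seed = seed,
                      start = c(200, 150), heading = 0.3)
  endp <- w1[nrow(w1), ]
  hd <- atan2(endp[2] - w1[nrow(w1) - 5, 2], endp[1] - w1[nrow(w1) - 5, 1])
  w2 <- sample_wlc_2d(round(arm2_bp), 150, seed = seed + 5000,
                      start = endp, heading = hd + 0.9)
  path <- rbind(w1, w2[-1, ])
  # chains that wander out of the frame yield NULL (caller skips the seed)
  tryCatch(render_afm_image(image_design(300, 2,
    list(list(path = path, height = 1.0)),
    particles = list(list(molecule = 1, position_bp = arm1_bp,
                          height = 2.6, width_nm = 4.5)),
    noise_sd = noise_sd, seed = seed + 9000)),
    error = function(e) NULL)
}

mirror_err <- function(est, truth, L) min(abs(est - truth),
                                          abs((L - est) - truth))

# straight-rod AFM image with known length, angle and noise
render_rod <- function(length_nm, angle, noise_sd = 0.3, seed = 1,
                       size_px = 256, pixel_size = 2, height = 1.0) {
  n <- round(length_nm / 0.36)
  t <- seq(-length_nm / 2, length_nm / 2, length.out = n)
  ctr <- (size_px - 1) * pixel_size / 2
  path <- cbind(ctr + cos(angle) * t, ctr + sin(angle) * t)
  render_afm_image(image_design(size_px, pixel_size,
                                list(list(path = path, height = height)),
                                noise_sd = noise_sd, seed = seed))
}
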