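#' Single-molecule trace on an AFM image
#'
#' Ordered sub-pixel path along the axis of one imaged molecule, with the
#' measured height at every point. Contour length is the sum of consecutive
#' segment lengths; bp length is contour/0.36 nm per bp (the image
#' calibration constant, global and not per-molecule).
#'
#' @param path n x 2 matrix of (x, y) positions in nm.
#' @param heights height in nm per path point.
#' @param pixel_size nm per pixel of the source image.
#' @param frame_time optional frame time in seconds.
#' @export
molecule_trace <- function(path, heights, pixel_size, frame_time = NULL) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) == length(heights))
  cl <- contour_length(path)
  structure(list(path = path, heights = as.numeric(heights),
                 contour_length = cl, bp_length = cl / NM_PER_BP,
                 pixel_size = pixel_size, frame_time = frame_time,
                 oriented = FALSE, origin_end = "unknown"),
            class = "molecule_trace")
}

NM_PER_BP <- 0.36

#' @export
print.molecule_trace <- function(x, ...) {
  cat(sprintf("<molecule_trace> %d pts, %.1f nm (%.0f bp)%s%s\n",
              nrow(x$path), x$contour_length, x$bp_length,
              if (x$oriented) sprintf(", oriented (5' at %s end)",
                                      x$origin_end) else ", unoriented",
              if (is.null(x$frame_time)) ""
              else sprintf(", t = %gs", x$frame_time)))
  invisible(x)
}

# --- binary morphology -----------------------------------------------------

shift_mat <- function(m, dr, dc) {
  n <- matrix(0L, nrow(m), ncol(m))
  rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
  cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
  n[rs, cs] <- m[rs - dr, cs - dc]
  n
}

#' Morphological thinning (Guo-Hall) of a binary mask
#'
#' Reduces a thresholded molecule mask to one-pixel-wide 8-connected
#' center lines, preserving endpoints and connectivity. The Guo-Hall
#' two-subiteration scheme is used because it does not leave the two-pixel
#' diagonal staircases that simpler schemes retain.
#'
#' @param mask logical or 0/1 matrix.
#' @return 0/1 integer matrix of the same size.
#' @export
thin_binary <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north (row - 1)
      p2 <- shift_mat(m, -1, 0);  p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);   p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);   p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1);  p9 <- shift_mat(m, -1, -1)
      C <- (1 - p2) * (p3 | p4) + (1 - p4) * (p5 | p6) +
           (1 - p6) * (p7 | p8) + (1 - p8) * (p9 | p2)
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      O <- if (pass == 1) (p6 | p7 | (1 - p9)) * p8
           else (p2 | p3 | (1 - p5)) * p4
      cond <- m == 1 & C == 1 & N >= 2 & N <= 3 & O == 0
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

neighbor_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

skel_degree <- function(m) {
  d <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(nrow(neighbor_offsets)))
    d <- d + shift_mat(m, neighbor_offsets[k, 1], neighbor_offsets[k, 2])
  d * m
}

# Remove short side branches. Each branch is walked from its endpoint to
# the first junction; branches of at most prune_px pixels are candidates.
# At a junction that still has >= 2 non-candidate continuations the
# candidates are plain noise spurs and all are removed; at a junction that
# terminates the main path (a spur right at a molecule end splits the true
# tail into a second short branch) the longest candidate is the tail and
# is kept.
prune_spurs <- function(m, prune_px) {
  repeat {
    deg <- skel_degree(m)
    ep <- which(m == 1 & deg == 1, arr.ind = TRUE)
    if (nrow(ep) == 0) break
    cand <- list()
    for (k in seq_len(nrow(ep))) {
      r <- ep[k, 1]; c <- ep[k, 2]
      branch <- list()
      prev <- c(NA, NA)
      for (s in seq_len(prune_px + 1)) {
        if (deg[r, c] >= 3) break        # reached a junction
        branch[[length(branch) + 1]] <- c(r, c)
        nb <- find_neighbors(m, r, c)
        if (!is.na(prev[1]))
          nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                   drop = FALSE]
        if (nrow(nb) == 0) { branch <- list(); break }  # isolated segment
        prev <- c(r, c)
        r <- nb[1, 1]; c <- nb[1, 2]
      }
      if (length(branch) > 0 && length(branch) <= prune_px &&
          deg[r, c] >= 3) {
        cand[[length(cand) + 1]] <- list(branch = branch,
                                         junction = c(r, c))
      }
    }
    if (length(cand) == 0) break
    # junctions at a thick node thin to a small cluster of adjacent
    # junction pixels; branches meeting the same cluster are one group
    jpx <- t(vapply(cand, function(b) b$junction, numeric(2)))
    grp_id <- seq_len(nrow(jpx))
    for (a in seq_len(nrow(jpx))) for (b in seq_len(nrow(jpx))) {
      if (max(abs(jpx[a, ] - jpx[b, ])) <= 2)
        grp_id[grp_id == grp_id[b]] <- grp_id[a]
    }
    removed <- FALSE
    for (g in unique(grp_id)) {
      grp <- cand[grp_id == g]
      # continuations leaving the junction cluster that are not one of the
      # candidate branches
      cluster <- unique(do.call(rbind, lapply(grp, function(b)
        b$junction)))
      nbrs <- unique(do.call(rbind, lapply(seq_len(nrow(cluster)),
        function(i) find_neighbors(m, cluster[i, 1], cluster[i, 2]))))
      in_cluster <- apply(nbrs, 1, function(p)
        any(p[1] == cluster[, 1] & p[2] == cluster[, 2]))
      branch_tips <- do.call(rbind, lapply(grp, function(b)
        b$branch[[length(b$branch)]]))
      in_branch <- apply(nbrs, 1, function(p)
        any(p[1] == branch_tips[, 1] & p[2] == branch_tips[, 2]))
      rest <- nbrs[!in_cluster & !in_branch, , drop = FALSE]
      # adjacent continuation pixels belong to one and the same path
      n_long <- n_pixel_groups(rest)
      drop <- grp
      if (n_long <= 1) {
        keep <- which.max(vapply(grp, function(b) length(b$branch),
                                 integer(1)))
        drop <- grp[-keep]
      }
      for (b in drop) {
        for (p in b$branch) m[p[1], p[2]] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# number of 8-connected groups among a small set of pixels
n_pixel_groups <- function(px) {
  n <- nrow(px)
  if (n == 0) return(0L)
  id <- seq_len(n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (max(abs(px[a, ] - px[b, ])) <= 1)
      id[id == id[b]] <- id[a]
  }
  length(unique(id))
}

find_neighbors <- function(m, r, c) {
  rr <- r + neighbor_offsets[, 1]
  cc <- c + neighbor_offsets[, 2]
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  rr <- rr[ok]; cc <- cc[ok]
  on <- m[cbind(rr, cc)] == 1
  cbind(rr[on], cc[on])
}

# Order skeleton pixels into a path. At junction pixels (crossings thin to
# 3/4-degree nodes) the walk continues in the direction of minimal turning
# angle; every pixel-to-pixel edge is used at most once, so both passes of
# a crossing are traversed.
trace_skeleton_path <- function(m) {
  deg <- skel_degree(m)
  ep <- which(m == 1 & deg == 1, arr.ind = TRUE)
  if (nrow(ep) == 0) return(NULL)       # closed loop or empty: not traced
  start <- ep[1, ]
  used <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste(a[1], a[2], b[1], b[2])
  cur <- start
  dir <- c(0, 0)
  path <- matrix(cur, 1, 2)
  for (s in seq_len(10 * sum(m) + 10)) {
    nb <- find_neighbors(m, cur[1], cur[2])
    if (nrow(nb) == 0) break
    cand <- nb[!vapply(seq_len(nrow(nb)), function(k)
      exists(edge_key(cur, nb[k, ]), envir = used), logical(1)), ,
      drop = FALSE]
    if (nrow(cand) == 0) break
    if (nrow(cand) > 1 && any(dir != 0)) {
      v <- sweep(cand, 2, cur)
      ang <- acos(pmin(1, pmax(-1,
        (v %*% dir) / (sqrt(rowSums(v^2)) * sqrt(sum(dir^2))))))
      cand <- cand[order(ang), , drop = FALSE]
    }
    nxt <- cand[1, ]
    assign(edge_key(cur, nxt), TRUE, envir = used)
    assign(edge_key(nxt, cur), TRUE, envir = used)
    path <- rbind(path, nxt)
    dir <- 0.5 * dir + (nxt - cur)      # smoothed heading
    cur <- nxt
    if (deg[cur[1], cur[2]] == 1 && s > 1) break
  }
  path
}

bilinear <- function(h, x, y) {
  # x = column, y = row, 1-based continuous coordinates
  x <- pmin(pmax(x, 1), ncol(h)); y <- pmin(pmax(y, 1), nrow(h))
  x0 <- pmin(floor(x), ncol(h) - 1); y0 <- pmin(floor(y), nrow(h) - 1)
  fx <- x - x0; fy <- y - y0
  h[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    h[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    h[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    h[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# height-weighted centroid refinement perpendicular to the local path
refine_subpixel <- function(path_px, hfield, halfwidth = 2) {
  n <- nrow(path_px)
  if (n < 5) return(path_px)
  out <- path_px
  offs <- seq(-halfwidth, halfwidth, by = 0.5)
  for (i in seq_len(n)) {
    a <- max(1, i - 2); b <- min(n, i + 2)
    tg <- path_px[b, ] - path_px[a, ]
    nt <- sqrt(sum(tg^2)); if (nt < 1e-9) next
    nrm <- c(-tg[2], tg[1]) / nt
    xs <- path_px[i, 2] + offs * nrm[2]   # column
    ys <- path_px[i, 1] + offs * nrm[1]   # row
    w <- pmax(bilinear(hfield, xs, ys), 0)
    if (sum(w) < 1e-9) next
    d <- sum(w * offs) / sum(w)
    out[i, ] <- path_px[i, ] + d * nrm
  }
  out
}

# moving-average smoothing of path coordinates, ends kept
smooth_path <- function(p, k = 5) {
  if (nrow(p) < k + 2) return(p)
  f <- rep(1 / k, k)
  sm <- apply(p, 2, function(v) {
    s <- stats::filter(v, f, sides = 2)
    s[is.na(s)] <- v[is.na(s)]
    as.numeric(s)
  })
  sm[1, ] <- p[1, ]; sm[nrow(p), ] <- p[nrow(p), ]
  sm
}

# place both path ends at the half-crest point: a Gaussian-blurred ridge
# end falls to half its crest height exactly over the true molecule end,
# so ends are first trimmed back above that level, then extended out to it
adjust_ends <- function(path_px, hfield, max_px = 12, step = 0.25) {
  n <- nrow(path_px)
  if (n < 10) return(path_px)
  mid <- path_px[round(n * 0.25):round(n * 0.75), , drop = FALSE]
  crest <- stats::median(bilinear(hfield, mid[, 2], mid[, 1]))
  # a blurred max-envelope ridge stays near 0.8 of crest directly over the
  # molecule end (measured on noiseless renders); 0.75 trades a fraction
  # of a pixel of systematic overshoot for robustness to noise dips
  level <- 0.75 * crest
  for (side in 1:2) {
    if (side == 2) path_px <- path_px[rev(seq_len(nrow(path_px))), ,
                                      drop = FALSE]
    # trim points below the half-crest level
    v <- bilinear(hfield, path_px[, 2], path_px[, 1])
    k <- which(v >= level)[1]
    if (is.na(k)) k <- 1
    if (k > 1) path_px <- path_px[k:nrow(path_px), , drop = FALSE]
    # extend outward to the half-crest boundary
    m <- nrow(path_px)
    tg <- path_px[1, ] - path_px[min(5, m), ]
    nt <- sqrt(sum(tg^2))
    if (nt > 1e-9) {
      tg <- tg / nt
      added <- NULL
      for (s in seq(step, max_px, by = step)) {
        q <- path_px[1, ] + s * tg
        if (q[1] < 1 || q[2] < 1 || q[1] > nrow(hfield) ||
            q[2] > ncol(hfield)) break
        if (bilinear(hfield, q[2], q[1]) < level) break
        added <- rbind(q, added)
      }
      if (!is.null(added)) path_px <- rbind(added, path_px)
    }
    if (side == 2) path_px <- path_px[rev(seq_len(nrow(path_px))), ,
                                      drop = FALSE]
  }
  path_px
}

#' Trace all molecules on an AFM image
#'
#' The image is background-flattened (line-by-line, second order), lightly
#' Gaussian-smoothed for geometric stability, thresholded, and each
#' connected molecule is morphologically thinned to a one-pixel path.
#' Short side branches are pruned, crossings are traversed by direction
#' continuity (minimal turning angle), the path is refined to sub-pixel
#' accuracy by height-weighted centroids perpendicular to the local axis,
#' its ends are extended to the height boundary, and heights are read off
#' the flattened image along the path.
#'
#' @param image an [afm_image()].
#' @param height_threshold nm above the flattened background separating
#'   molecule from noise (default 0.5: between a noise SD of ~0.3 nm and
#'   the 0.8-1.2 nm double-helix height).
#' @param min_contour_nm traces shorter than this are discarded.
#' @param prune_px side branches up to this many pixels are pruned.
#' @param flatten_first set `FALSE` if the image is already flattened.
#' @return list of [molecule_trace()] objects (possibly empty).
#' @export
skeletonize_molecule <- function(image, height_threshold = 0.5,
                                 min_contour_nm = 30, prune_px = 6,
                                 flatten_first = TRUE) {
  flat <- if (flatten_first) flatten(image, 2, height_threshold) else image
  h <- flat$heights
  hb <- gaussian_blur(h, sigma_px = 1)
  # blur lowers ridge crests and the threshold must stay several blurred-
  # noise SDs below the crest, or correlated noise dips sever the ridge
  mask <- hb >= height_threshold * 0.6
  # bridge single-pixel dropouts along the ridge and fill small enclosed
  # holes (a hole thins to a ring, which has no traceable endpoints);
  # large enclosed regions are genuine loop interiors and are kept
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, "box"))
  mask <- fill_small_holes(mask, max_px_area = 25)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab)
  traces <- list()
  for (id in which(sizes >= 5)) {
    comp <- lab == id
    sk <- thin_binary(comp)
    sk <- prune_spurs(sk, prune_px)
    if (sum(sk) < 4) next
    p <- trace_skeleton_path(sk)
    if (is.null(p) || nrow(p) < 5) next
    p <- refine_subpixel(p, hb)
    p <- smooth_path(p, 5)
    p <- adjust_ends(p, hb)
    hts <- bilinear(h, p[, 2], p[, 1])
    path_nm <- cbind(x = (p[, 2] - 1) * image$pixel_size,
                     y = (p[, 1] - 1) * image$pixel_size)
    tr <- molecule_trace(path_nm, hts, image$pixel_size, image$frame_time)
    if (tr$contour_length >= min_contour_nm)
      traces[[length(traces) + 1]] <- tr
  }
  traces
}

fill_small_holes <- function(mask, max_px_area = 25) {
  inv <- EBImage::bwlabel(!mask)
  sizes <- tabulate(inv)
  border_ids <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1],
                         inv[, ncol(inv)]))
  fill_ids <- setdiff(which(sizes <= max_px_area), border_ids)
  mask[inv %in% fill_ids & inv > 0] <- TRUE
  mask
}

gaussian_blur <- function(h, sigma_px) {
  if (sigma_px <= 0) return(h)
  EBImage::gblur(h, sigma = sigma_px)
}

#' Resample a trace to uniform arc-length spacing
#'
#' Linear interpolation of positions and heights at fixed spacing along
#' the contour (default one base pair = 0.36 nm), giving one point per bp.
#'
#' @param trace a `molecule_trace`.
#' @param spacing_nm spacing between resampled points.
#' @export
resample_trace <- function(trace, spacing_nm = NM_PER_BP) {
  seg <- sqrt(rowSums(diff(trace$path)^2))
  cs <- c(0, cumsum(seg))
  s <- seq(0, cs[length(cs)], by = spacing_nm)
  x <- stats::approx(cs, trace$path[, 1], xout = s)$y
  y <- stats::approx(cs, trace$path[, 2], xout = s)$y
  ht <- stats::approx(cs, trace$heights, xout = s)$y
  out <- molecule_trace(cbind(x = x, y = y), ht, trace$pixel_size,
                        trace$frame_time)
  out$oriented <- trace$oriented
  out$origin_end <- trace$origin_end
  out
}

#' Export traces as TSV (molecule, index, x, y, height)
#' @param traces list of `molecule_trace`.
#' @param path output file.
#' @export
write_traces_tsv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(molecule = i, index = seq_len(nrow(tr$path)),
               x = tr$path[, 1], y = tr$path[, 2], height = tr$heights)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
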