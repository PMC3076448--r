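#' Ends-ratio curvature profile of a point path
#'
#' The Ends ratio of a window is the contour length along the path divided
#' by the straight-line (chord) distance between the window's two
#' endpoints; it is 1 for a straight segment and grows with curvature
#' (pi/2 for a semicircle). Windows slide along the molecule at a fixed
#' step; each value is reported at the window's center position.
#'
#' @param points n x 2 or n x 3 coordinate matrix (nm), ordered along the
#'   molecule; consecutive points are `spacing_bp` base pairs apart.
#' @param spacing_bp base pairs per inter-point segment (1 for per-bp
#'   trajectories).
#' @param window_len window length in bp (default 150).
#' @param step slide step in bp (default 1).
#' @return class `ends_ratio_profile`: data.frame with columns `center`
#'   (bp position along the molecule, first point = 1) and `value` (>= 1),
#'   with attributes `window_len`, `step`, `spacing_bp`. Empty (with a
#'   warning) when the window does not fit.
#' @export
ends_ratio <- function(points, spacing_bp = 1, window_len = 150, step = 1) {
  points <- as.matrix(points)
  n <- nrow(points)
  m <- max(1L, round(window_len / spacing_bp))   # segments per window
  if (n < m + 1) {
    warning("window (", window_len, " bp) longer than molecule; ",
            "empty profile")
    return(empty_er_profile(window_len, step, spacing_bp))
  }
  seg <- sqrt(rowSums(diff(points)^2))
  cs <- c(0, cumsum(seg))
  kstep <- max(1L, round(step / spacing_bp))
  i <- seq.int(1L, n - m, by = kstep)
  j <- i + m
  arc <- cs[j] - cs[i]
  chord <- sqrt(rowSums((points[j, , drop = FALSE] -
                         points[i, , drop = FALSE])^2))
  val <- pmax(1, arc / chord)
  center <- ((i - 1) + (j - 1)) / 2 * spacing_bp + 1
  structure(data.frame(center = center, value = val),
            window_len = window_len, step = step, spacing_bp = spacing_bp,
            class = c("ends_ratio_profile", "data.frame"))
}

empty_er_profile <- function(window_len, step, spacing_bp) {
  structure(data.frame(center = numeric(), value = numeric()),
            window_len = window_len, step = step, spacing_bp = spacing_bp,
            class = c("ends_ratio_profile", "data.frame"))
}

#' Ends-ratio profile of a sequence at a given phasing pitch
#'
#' Builds the 3D helix-axis trajectory (optionally twist-rescaled to a
#' phasing pitch) and computes the Ends-ratio profile on its 3D
#' coordinates. Centers are reported in promoter coordinates.
#'
#' @inheritParams build_trajectory
#' @inheritParams ends_ratio
#' @export
seq_ends_ratio <- function(seq, table = default_step_table(), pitch = NULL,
                           window_len = 150, step = 1) {
  traj <- build_trajectory(seq, table, pitch = pitch)
  prof <- ends_ratio(traj$points, spacing_bp = 1,
                     window_len = window_len, step = step)
  prof$center <- offset_to_promoter(as.integer(round(prof$center - 1)),
                                    seq$origin)
  prof
}

#' Curvature map over a phasing-pitch grid
#'
#' One Ends-ratio profile per pitch, each computed on the pitch-rescaled
#' trajectory of the same sequence, assembled into a (window center x
#' pitch) matrix. A sequence-encoded superhelix that is invisible as planar
#' curvature at the canonical repeat becomes a strong localized maximum at
#' the pitch matching its phasing period.
#'
#' @inheritParams build_trajectory
#' @param pitches phasing-pitch grid in bp per turn (default 5..15 by 0.5;
#'   finer than integer steps so peaks near 7.5 bp are resolvable).
#' @param window_len,step Ends-ratio window and slide step in bp.
#' @return class `curvature_map`: list with `pitches`, `centers` (promoter
#'   coordinates), `values` (centers x pitches matrix), `window_len`.
#' @export
curvature_map <- function(seq, table = default_step_table(),
                          pitches = seq(5, 15, by = 0.5),
                          window_len = 150, step = 1) {
  if (length(pitches) == 0) stop("pitches must be non-empty")
  profs <- lapply(pitches, function(p)
    seq_ends_ratio(seq, table, pitch = p, window_len = window_len,
                   step = step))
  centers <- profs[[1]]$center
  vals <- vapply(profs, function(p) p$value, numeric(length(centers)))
  structure(list(pitches = pitches, centers = centers,
                 values = matrix(vals, nrow = length(centers)),
                 window_len = window_len, step = step,
                 origin = seq$origin),
            class = "curvature_map")
}

#' @export
print.curvature_map <- function(x, ...) {
  cat(sprintf("<curvature_map> %d centers x %d pitches (%.1f..%.1f bp/turn), max %.3f\n",
              length(x$centers), length(x$pitches), min(x$pitches),
              max(x$pitches), max(x$values)))
  invisible(x)
}

#' Call sequence-encoded supercoils from a curvature map
#'
#' A supercoil call is a localized Ends-ratio maximum at a pitch away from
#' the canonical helical repeat that (i) exceeds an absolute amplitude
#' floor, (ii) exceeds the same-center canonical-pitch value by a contrast
#' factor (a genuine superhelix is invisible as planar curvature at the
#' canonical repeat), and (iii) stands above its pitch row's background by
#' at least `min_prominence`. Random sequences carry substantial intrinsic
#' curvature at every pitch, so the amplitude floor is set from the
#' empirical null of the scan rather than just above 1. Handedness follows
#' the phasing rule: a peak below the canonical pitch is a left-handed
#' (negative) superhelix, above it right-handed (positive).
#'
#' @param map a [curvature_map()].
#' @param canonical_pitch canonical helical repeat (10.5 bp/turn).
#' @param min_amplitude absolute Ends-ratio floor for a peak (default 2).
#' @param min_contrast required ratio of peak value to the same-center
#'   canonical-pitch value (default 2).
#' @param min_prominence required height of the peak above its pitch row's
#'   median (default 0.05).
#' @param canonical_exclusion half-width in bp/turn of the pitch band
#'   around canonical excluded from calling (default 1.5): planar curvature
#'   spreads over nearby pitches and is not a supercoil.
#' @return data.frame with one row per call: `start`, `end` (promoter
#'   coordinates of window centers above half-prominence), `peak_center`,
#'   `peak_pitch`, `handedness` ("left" or "right"), `amplitude`. Zero rows
#'   when nothing qualifies.
#' @export
call_supercoils <- function(map, canonical_pitch = 10.5,
                            min_amplitude = 2, min_contrast = 2,
                            min_prominence = 0.05,
                            canonical_exclusion = 1.5) {
  if (min(map$pitches) >= canonical_pitch ||
      max(map$pitches) <= canonical_pitch)
    stop("pitch grid must cover both sides of the canonical pitch")
  V <- map$values
  can_col <- which.min(abs(map$pitches - canonical_pitch))
  can <- V[, can_col]
  off <- abs(map$pitches - canonical_pitch) >= canonical_exclusion
  nc <- nrow(V); np <- ncol(V)
  calls <- list()
  # 2D local maxima among qualifying off-canonical cells
  cand <- which(off[col(V)] & V >= min_amplitude & V >= min_contrast * can,
                arr.ind = FALSE)
  if (length(cand)) {
    rc <- arrayInd(cand, dim(V))
    is_max <- vapply(seq_len(nrow(rc)), function(k) {
      r <- rc[k, 1]; p <- rc[k, 2]
      nb <- V[max(1, r - 1):min(nc, r + 1), max(1, p - 1):min(np, p + 1)]
      V[r, p] >= max(nb)
    }, logical(1))
    rc <- rc[is_max, , drop = FALSE]
    if (nrow(rc)) {
      ord <- order(V[rc], decreasing = TRUE)
      rc <- rc[ord, , drop = FALSE]
      # one call per handedness per region: a weaker same-handed maximum
      # within half a window of an accepted call is the same physical
      # structure leaking into neighboring pitch rows; a weaker maximum at
      # half or double an accepted pitch in the same region is its phasing
      # harmonic (tracts recurring every second turn), not a second coil
      taken <- list(left = rep(FALSE, nc), right = rep(FALSE, nc))
      accepted <- list()
      pad <- max(1L, round(map$window_len / (2 * max(1, map$step))))
      for (k in seq_len(nrow(rc))) {
        r <- rc[k, 1]; p <- rc[k, 2]
        row <- V[, p]
        base <- stats::median(row)
        peak <- row[r]
        if (peak - base < min_prominence) next
        half <- base + (peak - base) / 2
        lo <- r; while (lo > 1 && row[lo - 1] >= half) lo <- lo - 1
        hi <- r; while (hi < nc && row[hi + 1] >= half) hi <- hi + 1
        hand <- if (map$pitches[p] < canonical_pitch) "left" else "right"
        plo <- max(1, lo - pad); phi <- min(nc, hi + pad)
        if (any(taken[[hand]][plo:phi])) next
        harmonic <- any(vapply(accepted, function(a)
          a$lo <= phi && a$hi >= plo &&
            abs(map$pitches[p] - a$pitch / 2) <= 0.75, logical(1)))
        if (harmonic) next
        taken[[hand]][plo:phi] <- TRUE
        accepted[[length(accepted) + 1]] <-
          list(lo = plo, hi = phi, pitch = map$pitches[p])
        calls[[length(calls) + 1]] <- data.frame(
          start = map$centers[lo], end = map$centers[hi],
          peak_center = map$centers[r], peak_pitch = map$pitches[p],
          handedness = hand,
          amplitude = peak)
      }
    }
  }
  if (length(calls)) do.call(rbind, calls)
  else data.frame(start = integer(), end = integer(),
                  peak_center = integer(), peak_pitch = numeric(),
                  handedness = character(), amplitude = numeric())
}

#' Position of the curvature apex
#'
#' Center coordinate of the profile's global maximum; ties are broken
#' toward the 3' end (the largest center).
#'
#' @param profile an `ends_ratio_profile`.
#' @export
apex_position <- function(profile) {
  if (nrow(profile) == 0) stop("empty profile has no apex")
  idx <- which(profile$value == max(profile$value))
  profile$center[idx[length(idx)]]
}

#' Export a curvature map as long-format TSV (center, pitch, value)
#' @param map a `curvature_map`.
#' @param path output file.
#' @export
write_curvature_map_tsv <- function(map, path) {
  d <- data.frame(center = rep(map$centers, times = length(map$pitches)),
                  pitch = rep(map$pitches, each = length(map$centers)),
                  value = as.vector(map$values))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a profile as a wiggle-like track keyed by promoter coordinate
#' @param profile an `ends_ratio_profile` (or any data.frame with center
#'   and value columns).
#' @param path output file.
#' @param name track name.
#' @export
write_profile_wig <- function(profile, path, name = "ends_ratio") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  writeLines(sprintf("%d\t%g", as.integer(round(profile$center)),
                     profile$value), con)
  invisible(path)
}

#' Export supercoil calls as BED-like TSV (handedness in the name field)
#' @param calls output of [call_supercoils()].
#' @param path output file.
#' @export
write_supercoils_bed <- function(calls, path) {
  d <- data.frame(start = calls$start, end = calls$end,
                  name = paste0("supercoil_", calls$handedness),
                  peak_pitch = calls$peak_pitch,
                  amplitude = calls$amplitude)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
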