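#' Build the 3D helix-axis trajectory of a sequence
#'
#' The double-helix axis is reconstructed base pair by base pair from the
#' dinucleotide step table. Each step applies to the local frame a rotation
#'
#'   R = Rz(twist/2) W Rz(twist/2),
#'
#' where W is a single rotation by the wedge angle sqrt(roll^2 + tilt^2)
#' about the in-plane axis with rotation vector tilt*x + roll*y (x, y, z
#' the local frame axes, z the helix axis), i.e. the wedge deflection is
#' applied between two half-twists. The next point lies `rise` nm along the
#' direction bisecting the incoming and outgoing helix axes, so consecutive
#' points are spaced exactly `rise` nm apart. This mid-step convention makes
#' the model exactly symmetric under reverse complementation whenever the
#' table obeys dinucleotide complement symmetry (roll equal, tilt negated,
#' twist equal), which the default table does: the trajectory of the
#' reverse complement superimposes on the reversed trajectory after a rigid
#' motion to numerical precision.
#'
#' @param seq a [genomic_sequence()] (or plain ACGT string).
#' @param table a `step_table`; default the packaged wedge-angle set.
#' @param pitch optional phasing-pitch override in bp per turn (4..20):
#'   the table's twists are uniformly rescaled via [rescale_twist()] before
#'   the build. `NULL` uses the native twists.
#' @param rise helix rise per step in nm; defaults to the table's rise
#'   (0.34 nm for B-DNA). The 0.36 nm/bp figure used to convert AFM contour
#'   lengths to bp is a separate, image-calibration constant.
#' @return object of class `trajectory3d`: list with `points` (n x 3 matrix,
#'   nm), `frames` (3 x 3 x n array of orthonormal triads), `pitch_used`
#'   ("native" or the override), `origin` (promoter coordinate of the first
#'   point).
#' @export
build_trajectory <- function(seq, table = default_step_table(),
                             pitch = NULL, rise = attr(table, "rise")) {
  if (is.character(seq)) seq <- genomic_sequence(seq)
  n <- length(seq)
  if (!is.null(pitch)) {
    if (pitch < 4 || pitch > 20)
      stop("pitch override must lie in [4, 20] bp per turn")
    table <- rescale_twist(table, pitch)
  }
  b <- strsplit(seq$bases, "")[[1]]
  dinucs <- paste0(b[-n], b[-1])
  idx <- match(dinucs, DINUCS)
  if (anyNA(idx))
    stop("unknown dinucleotide at step ", which(is.na(idx))[1])
  rots <- step_rotations(table)
  P <- matrix(0, n, 3)
  Fr <- array(0, c(3, 3, n))
  f <- diag(3)
  Fr[, , 1] <- f
  for (i in seq_len(n - 1)) {
    fn <- f %*% rots[[idx[i]]]
    u <- f[, 3] + fn[, 3]
    P[i + 1, ] <- P[i, ] + rise * u / sqrt(sum(u * u))
    f <- fn
    Fr[, , i + 1] <- f
  }
  structure(list(points = P, frames = Fr,
                 pitch_used = if (is.null(pitch)) "native" else pitch,
                 origin = seq$origin, rise = rise),
            class = "trajectory3d")
}

# one composite rotation matrix per dinucleotide
step_rotations <- function(table) {
  lapply(seq_len(nrow(table)), function(i) {
    step_rotation(table$roll[i], table$tilt[i], table$twist[i])
  })
}

step_rotation <- function(roll, tilt, twist) {
  hz <- rot_z(twist / 2)
  w <- sqrt(roll^2 + tilt^2)
  W <- if (w < 1e-12) diag(3) else rot_axis(c(tilt, roll, 0), w)
  hz %*% W %*% hz
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation by `deg` degrees about `axis`
rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d points, rise %.2f nm, pitch %s\n",
              nrow(x$points), x$rise,
              format(x$pitch_used)))
  invisible(x)
}

#' Contour length of a trajectory or point path (nm)
#' @param x a `trajectory3d` or an n x d coordinate matrix.
#' @export
contour_length <- function(x) {
  P <- if (inherits(x, "trajectory3d")) x$points else x
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Per-base model signal used to orient AFM molecules
#'
#' The orientation of an imaged molecule is decided by comparing its height
#' profile to a sequence-computed signal: the local twist (helical pitch
#' modulation) along the molecule, smoothed with a running mean. Regions of
#' unusual pitch read out as height modulation in AFM topography.
#'
#' @param seq a [genomic_sequence()].
#' @param table a `step_table`.
#' @param smooth running-mean half-width in bp.
#' @return numeric vector, one value per base (the last step value is
#'   repeated), standardized to zero mean and unit variance.
#' @export
model_height_profile <- function(seq, table = default_step_table(),
                                 smooth = 15L) {
  b <- strsplit(seq$bases, "")[[1]]
  n <- length(b)
  tw <- table$twist[match(paste0(b[-n], b[-1]), DINUCS)]
  x <- c(tw, tw[n - 1])
  if (smooth > 0) {
    k <- 2L * as.integer(smooth) + 1L
    x <- stats::filter(x, rep(1 / k, k), sides = 2)
    x <- as.numeric(x)
    x[is.na(x)] <- mean(tw)
  }
  as.numeric(scale(x))
}

#' Export a trajectory as an XYZ-like TSV (index, x, y, z in nm)
#' @param traj a `trajectory3d`.
#' @param path output file.
#' @export
write_trajectory_tsv <- function(traj, path) {
  d <- data.frame(index = seq_len(nrow(traj$points)) - 1L,
                  x = traj$points[, 1], y = traj$points[, 2],
                  z = traj$points[, 3])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
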