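#' Orient a molecule trace against the sequence model
#'
#' The measured height profile is resampled to the model length and
#' Pearson-correlated with the sequence-computed signal
#' ([model_height_profile()]) in both orientations. The orientation with
#' the higher correlation wins; the molecule counts as oriented only when
#' the winning correlation beats the other by at least `margin`. The
#' returned trace runs 5' to 3' (reversed if needed).
#'
#' @param trace a [molecule_trace()].
#' @param model_profile per-bp model signal (numeric vector).
#' @param margin required correlation advantage (default 0.1).
#' @param length_tol maximum relative difference between the trace bp
#'   length and the model length (default 0.15); beyond it the molecule is
#'   returned unoriented with a reason.
#' @return list: `trace` (flipped to 5'->3' when oriented), `orientation`
#'   ("forward", "reverse" or "unknown"), `r_forward`, `r_reverse`,
#'   `oriented` (logical), `reason` (NULL or why not).
#' @export
orient_molecule <- function(trace, model_profile, margin = 0.1,
                            length_tol = 0.15) {
  n_model <- length(model_profile)
  rel <- abs(trace$bp_length - n_model) / n_model
  if (rel > length_tol) {
    return(list(trace = trace, orientation = "unknown",
                r_forward = NA_real_, r_reverse = NA_real_,
                oriented = FALSE,
                reason = sprintf(
                  "length mismatch: %.0f bp measured vs %d bp model (%.0f%%)",
                  trace$bp_length, n_model, 100 * rel)))
  }
  seg <- sqrt(rowSums(diff(trace$path)^2))
  cs <- c(0, cumsum(seg))
  s <- seq(0, cs[length(cs)], length.out = n_model)
  prof <- stats::approx(cs, trace$heights, xout = s)$y
  r_fwd <- stats::cor(prof, model_profile)
  r_rev <- stats::cor(rev(prof), model_profile)
  forward <- r_fwd >= r_rev
  ok <- abs(r_fwd - r_rev) >= margin
  out <- trace
  if (!forward) {
    out$path <- out$path[rev(seq_len(nrow(out$path))), , drop = FALSE]
    out$heights <- rev(out$heights)
  }
  out$oriented <- ok
  out$origin_end <- if (ok) "5'" else "unknown"
  list(trace = out,
       orientation = if (!ok) "unknown" else if (forward) "forward"
                     else "reverse",
       r_forward = r_fwd, r_reverse = r_rev, oriented = ok,
       reason = if (ok) NULL else "correlation margin not reached")
}

#' Nucleosome dyad position from arm lengths
#'
#' With total fragment length L and the two free-DNA arm lengths L_plus
#' (longer) and L_minus (shorter), the wrapped length is
#' Lc = L - (L_plus + L_minus) and the dyad sits at L_plus + Lc/2 measured
#' from the long-arm end (equivalently L - (L_minus + Lc/2)).
#'
#' @param L total fragment length in bp.
#' @param L_plus,L_minus free arm lengths in bp, `L_plus >= L_minus >= 0`.
#' @return one-row data.frame (kind = "nucleosome_dyad", position = dyad in
#'   bp from the long-arm end, height = NA, extra = Lc).
#' @export
map_nucleosome <- function(L, L_plus, L_minus) {
  if (L_minus < 0 || L_plus < L_minus)
    stop("need L_plus >= L_minus >= 0")
  Lc <- L - (L_plus + L_minus)
  if (Lc <= 0) stop("no wrapped DNA: L_plus + L_minus >= L")
  dyad <- L_plus + Lc / 2
  stopifnot(abs((L - (L_minus + Lc / 2)) - dyad) < 1e-9)
  data.frame(kind = "nucleosome_dyad", position = dyad, height = NA_real_,
             extra = Lc)
}

#' Locate a nucleosome on a trace and map its dyad
#'
#' The nucleosome reads out as a contiguous stretch of the height profile
#' above `blob_threshold`; the free arms are the contour outside it. Arm
#' lengths (in bp, via 0.36 nm/bp) feed [map_nucleosome()] with the known
#' fragment length, so the wrapped DNA hidden inside the particle is
#' restored arithmetically. The dyad is reported from the long-arm end.
#'
#' @param trace a `molecule_trace`.
#' @param L_bp known total fragment length in bp.
#' @param blob_threshold nm above background marking particle pixels
#'   (default 1.8: above the 0.8-1.2 nm double helix, below particle tops).
#' @return one-row data.frame as in [map_nucleosome()] plus the measured
#'   arm lengths as attributes, or NULL when no particle region is found.
#' @export
measure_nucleosome <- function(trace, L_bp, blob_threshold = 1.8) {
  tr <- resample_trace(trace)
  h <- tr$heights
  above <- which(h >= blob_threshold)
  if (length(above) == 0) return(NULL)
  a <- min(above); b <- max(above)
  arm1 <- a - 1
  arm2 <- length(h) - b
  Lp <- max(arm1, arm2); Lm <- min(arm1, arm2)
  if (Lp + Lm >= L_bp) return(NULL)
  call <- map_nucleosome(L_bp, Lp, Lm)
  call$height <- max(h)
  attr(call, "L_plus") <- Lp
  attr(call, "L_minus") <- Lm
  call
}

#' Map a bound protein as the most prominent height maximum
#'
#' The height profile along the skeleton (per-bp resampled, lightly
#' smoothed) is scanned for local maxima exceeding the DNA baseline
#' (profile median) by at least `margin_nm`. The most prominent one is the
#' call; `verbose = TRUE` returns all qualifying maxima.
#'
#' @param trace a `molecule_trace` (oriented if positions are to be read
#'   in sequence coordinates).
#' @param margin_nm required excess over the DNA baseline (default 0.4).
#' @param smooth_bp running-mean window for the height profile.
#' @param verbose return every qualifying maximum, not just the best.
#' @return data.frame (kind = "protein", position in bp, height, extra =
#'   prominence), zero rows if nothing qualifies.
#' @export
map_protein <- function(trace, margin_nm = 0.4, smooth_bp = 7,
                        verbose = FALSE) {
  tr <- resample_trace(trace)
  h <- tr$heights
  n <- length(h)
  k <- min(smooth_bp, n - (1 - n %% 2))
  hs <- stats::filter(h, rep(1 / k, k), sides = 2)
  hs <- as.numeric(hs); hs[is.na(hs)] <- h[is.na(hs)]
  base <- stats::median(hs)
  cand <- which(diff(sign(c(-Inf, diff(hs), Inf))) < 0)
  cand <- cand[hs[cand] - base >= margin_nm]
  if (length(cand) == 0)
    return(data.frame(kind = character(), position = numeric(),
                      height = numeric(), extra = numeric()))
  out <- data.frame(kind = "protein", position = cand,
                    height = h[pmin(cand, n)],
                    extra = hs[cand] - base)
  out <- out[order(-out$extra), , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) out else out[1, , drop = FALSE]
}

#' Detect a DNA loop through a self-crossing of the trace
#'
#' The per-bp resampled path is searched for two contour-distant passages
#' that approach each other within `proximity_nm`: that is the crossing.
#' The loop is the contour between the two passages; its length and
#' contour middle point are reported. The over-strand is the passage with
#' the greater height at the crossing; the summit height is the maximum
#' height near the crossing (from `image` when given, else from the
#' trace).
#'
#' @param trace a `molecule_trace` containing a self-crossing.
#' @param image optional source `afm_image` for the summit height.
#' @param proximity_nm maximum distance between the two passages (default
#'   4 nm, about two pixel widths at typical scan resolution).
#' @param min_separation_bp minimum contour separation between passages.
#' @param midpoint "contour" (default) reports the loop's contour middle
#'   point, "apex" the loop point geometrically farthest from the crossing.
#' @return NULL when the path never crosses itself; otherwise a list with
#'   `placement` (kind = "loop_midpoint", position in bp, extra = loop
#'   length in bp) and `crossing` (location nm, over_strand "first" or
#'   "second" passage, summit_height nm).
#' @export
detect_loop <- function(trace, image = NULL, proximity_nm = 4,
                        min_separation_bp = 50,
                        midpoint = c("contour", "apex")) {
  midpoint <- match.arg(midpoint)
  tr <- resample_trace(trace)
  P <- tr$path
  n <- nrow(P)
  if (n < min_separation_bp + 2) return(NULL)
  D <- as.matrix(stats::dist(P))
  sep <- abs(row(D) - col(D))
  D[sep < min_separation_bp] <- Inf
  if (min(D) > proximity_nm) return(NULL)
  idx <- arrayInd(which.min(D), dim(D))
  i <- min(idx); j <- max(idx)
  loop_len <- j - i
  pos <- switch(midpoint,
    contour = (i + j) / 2,
    apex = {
      cross_pt <- (P[i, ] + P[j, ]) / 2
      seg <- i:j
      seg[which.max(sqrt(rowSums(sweep(P[seg, , drop = FALSE], 2,
                                       cross_pt)^2)))]
    })
  loc <- (P[i, ] + P[j, ]) / 2
  w <- 3
  h1 <- mean(tr$heights[max(1, i - w):min(n, i + w)])
  h2 <- mean(tr$heights[max(1, j - w):min(n, j + w)])
  summit <- if (!is.null(image)) {
    px <- loc / image$pixel_size + 1
    r0 <- max(1, round(px[2]) - 2); r1 <- min(nrow(image$heights), round(px[2]) + 2)
    c0 <- max(1, round(px[1]) - 2); c1 <- min(ncol(image$heights), round(px[1]) + 2)
    max(image$heights[r0:r1, c0:c1])
  } else max(tr$heights[c(max(1, i - w):min(n, i + w),
                          max(1, j - w):min(n, j + w))])
  list(placement = data.frame(kind = "loop_midpoint", position = pos,
                              height = summit, extra = loop_len),
       crossing = list(location = loc,
                       over_strand = if (h1 >= h2) "first" else "second",
                       summit_height = summit))
}

#' Ends-ratio profile along a measured molecule
#'
#' Delegates to [ends_ratio()] on the 2D path after per-bp resampling
#' (0.36 nm/bp), so the same statistic is applied to imaged molecules as
#' to model trajectories.
#'
#' @param trace a `molecule_trace`.
#' @param window_len,step window and slide step in bp.
#' @export
trace_ends_ratio <- function(trace, window_len = 150, step = 1) {
  tr <- resample_trace(trace)
  ends_ratio(tr$path, spacing_bp = 1, window_len = window_len, step = step)
}

#' Track the curvature apex over a time-lapse series
#'
#' Each oriented frame contributes the apex (position of maximal Ends
#' ratio) of its curvature profile; the net displacement is the signed
#' shift from the first to the last frame in bp (positive = toward the
#' trace's 3' end, i.e. toward the TSS when the fragment is oriented with
#' the TSS downstream). Unoriented frames are dropped with a warning.
#'
#' @param series list of `molecule_trace` objects with `frame_time` set,
#'   all oriented consistently (5' to 3').
#' @param window_len Ends-ratio window in bp.
#' @return data.frame (frame, time, apex in bp) with attribute
#'   `net_displacement_bp`.
#' @export
track_apex <- function(series, window_len = 150) {
  ok <- vapply(series, function(tr) isTRUE(tr$oriented), logical(1))
  if (any(!ok))
    warning(sum(!ok), " unoriented frame(s) dropped from apex tracking")
  series <- series[ok]
  if (length(series) < 2)
    stop("need at least 2 oriented frames")
  times <- vapply(series, function(tr)
    if (is.null(tr$frame_time)) NA_real_ else tr$frame_time, numeric(1))
  ord <- order(times)
  series <- series[ord]; times <- times[ord]
  apex <- vapply(series, function(tr)
    apex_position(trace_ends_ratio(tr, window_len)), numeric(1))
  out <- data.frame(frame = seq_along(series), time = times, apex = apex)
  attr(out, "net_displacement_bp") <- apex[length(apex)] - apex[1]
  out
}

#' Export placement calls as TSV keyed by molecule and bp position
#' @param calls data.frame of placement calls with a molecule column.
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
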