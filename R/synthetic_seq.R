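#' Generate a sequence with phased A-tracts
#'
#' A-tracts of `tract_len` bases are placed with their starts every
#' `phasing_period` bp (rounded to the nearest integer position) inside
#' `tract_region`, on an i.i.d. random background of the given GC content.
#' When the phasing period matches the helical repeat the tract bends add
#' up in one plane (detectable planar curvature); a period below or above
#' the repeat encodes a left- or right-handed superhelix that the
#' phasing-pitch scan converts into a planar signal at the matching pitch.
#'
#' @param length total sequence length in bp.
#' @param phasing_period tract-start period in bp (may be fractional, e.g.
#'   10.5: positions are rounded, so the period is realized on average).
#' @param tract_len A-tract length in bp (default 5).
#' @param tract_region integer vector c(first, last), 1-based positions
#'   delimiting where tracts are placed; default the whole sequence.
#' @param gc background GC fraction.
#' @param seed RNG seed (generation is fully reproducible).
#' @param origin promoter coordinate of the first base.
#' @return a [genomic_sequence()] with attribute `ground_truth`: list with
#'   the planned period, region and tract starts.
#' @export
gen_phased_sequence <- function(length, phasing_period, tract_len = 5,
                                tract_region = c(1, length), gc = 0.5,
                                seed = 1, origin = 1L) {
  stopifnot(phasing_period > tract_len)
  lo <- tract_region[1]; hi <- tract_region[2]
  if (hi - lo + 1 < phasing_period + tract_len)
    stop("tract_region too small for one phasing period")
  withr_seed(seed)
  b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  starts <- unique(round(seq(lo, hi - tract_len + 1, by = phasing_period)))
  for (st in starts) b[st:(st + tract_len - 1)] <- "A"
  # tract boundaries must be G/C so the runs are maximal as planned
  for (st in starts) {
    if (st > 1 && b[st - 1] %in% c("A", "T")) b[st - 1] <- "G"
    en <- st + tract_len - 1
    if (en < length && b[en + 1] %in% c("A", "T")) b[en + 1] <- "C"
  }
  out <- genomic_sequence(paste(b, collapse = ""), origin = origin)
  attr(out, "ground_truth") <- list(period = phasing_period,
                                    region = tract_region,
                                    tract_starts = starts,
                                    tract_len = tract_len)
  out
}

#' Generate an i.i.d. control sequence
#'
#' Random bases at a given GC content; the control analogue of a
#' plasmid-derived fragment with no engineered phasing, used to establish
#' the null behavior of the supercoil scan.
#'
#' @param length sequence length in bp.
#' @param gc GC fraction (0 gives an all-A/T sequence).
#' @param seed RNG seed.
#' @param origin promoter coordinate of the first base.
#' @export
gen_control_sequence <- function(length, gc = 0.5, seed = 1, origin = 1L) {
  withr_seed(seed)
  b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genomic_sequence(paste(b, collapse = ""), origin = origin)
}

withr_seed <- function(seed) set.seed(seed)

#' Synthetic promoter-like test sequence
#'
#' A 1290 bp construct on the promoter axis -869..+421 that emulates the
#' documented structural organisation of an inducible promoter fragment:
#'
#' * PRRII (-137..-64) carries three maximal A/T tracts separated by 6 and
#'   7 bp of G/C, the longest 19 bp — the multi-AT-tract architecture that
#'   supports architectural-factor binding;
#' * flanking the PRRII tract cluster, short A-tracts phased at 7.5 bp
#'   (below the canonical ~10.5 bp repeat) encode a left-handed (negative)
#'   superhelix over roughly -180..-64;
#' * upstream (about -250..-190), A-tracts phased at 13.5 bp encode a
#'   smaller right-handed (positive) superhelix;
#' * around the TSS (-20..+40), A-tracts phased at 10.5 bp produce planar
#'   curvature detectable at the canonical pitch;
#' * the TATA box (TACTTAAA) sits at -48..-41; PRRI (-289..-216) is
#'   annotated but left as background.
#'
#' This is a synthetic stand-in, not the real promoter sequence: tract
#' placements follow the published verbal description, everything else is
#' seeded random background.
#'
#' @param seed RNG seed for the background.
#' @return a [genomic_sequence()] spanning -869..+421 with features TATA,
#'   PRRI, PRRII, TSS.
#' @export
synthetic_promoter <- function(seed = 20110413) {
  origin <- -869L
  n <- 1290L
  withr_seed(seed)
  gc <- 0.55
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  off <- function(pos) promoter_to_offset(pos, origin, n) + 1L  # 1-based
  put <- function(pos, s) {
    i <- off(pos)
    b[i:(i + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]
  }
  phase <- function(from, to, period, tract = 3) {
    starts <- unique(round(seq(off(from), off(to) - tract, by = period)))
    for (st in starts) {
      b[st:(st + tract - 1)] <<- "A"
      if (st > 1) b[st - 1] <<- "G"
      if (st + tract <= n) b[st + tract] <<- "C"
    }
  }
  # right-handed (positive) cassette upstream of PRRII
  phase(-280, -195, 13.5, tract = 4)
  # left-handed (negative) cassette flanking and entering PRRII
  phase(-190, -140, 7.5)
  # PRRII three-tract cluster: 19 + 6 gc + 8 + 7 gc + 9
  put(-138, paste0("G", strrep("A", 10), strrep("T", 9), "GCCGCC",
                   strrep("A", 8), "GCCGCGC", strrep("T", 9)))
  # continuation of the negative cassette to the PRRII 3' edge
  phase(-87, -64, 7.5)
  # canonical planar curvature around the TSS
  phase(-20, +40, 10.5)
  put(-48, "TACTTAAA")
  feats <- data.frame(
    name = c("PRRI", "PRRII", "TATA", "TSS"),
    start = c(-289L, -137L, -48L, 1L),
    end = c(-216L, -64L, -41L, 1L))
  genomic_sequence(paste(b, collapse = ""), origin = origin,
                   features = feats)
}
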