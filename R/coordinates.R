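#' Promoter coordinate convention
#'
#' Positions along a promoter fragment are counted relative to the
#' transcription start site (TSS), which is position +1. There is no
#' position 0: the base immediately upstream of the TSS is -1, so the
#' coordinate axis runs ..., -2, -1, +1, +2, ... . Under this convention a
#' fragment spanning -869..+421 contains exactly 869 + 421 = 1290 bases.
#' All public functions speak promoter coordinates; internal arrays are
#' 0-based offsets.
#'
#' @name promoter-coordinates
NULL

check_promoter_pos <- function(pos, what = "position") {
  if (any(!is.finite(pos))) stop(what, " must be finite")
  if (any(pos == 0))
    stop(what, " 0 is not a valid promoter coordinate: the axis skips 0 ",
         "(... -2, -1, +1, +2 ...)")
  if (any(pos != trunc(pos))) stop(what, " must be integer-valued")
  invisible(pos)
}

#' Convert a promoter coordinate to a 0-based array offset
#'
#' @param pos integer promoter coordinate(s); 0 is rejected.
#' @param origin promoter coordinate of the first base of the fragment.
#' @param length optional fragment length in bp; when given, `pos` must fall
#'   inside the fragment.
#' @return 0-based offset(s) into the base array.
#' @examples
#' promoter_to_offset(-869, -869)  # 0
#' promoter_to_offset(+1, -869)    # 869
#' @export
promoter_to_offset <- function(pos, origin, length = NULL) {
  check_promoter_pos(pos, "pos")
  check_promoter_pos(origin, "origin")
  off <- pos - origin
  # crossing the TSS from a negative origin removes the non-existent 0
  off <- off - ifelse(origin < 0 & pos > 0, 1L, 0L)
  off <- off + ifelse(origin > 0 & pos < 0, 1L, 0L)
  if (any(off < 0)) stop("position ", pos[which(off < 0)[1]],
                         " lies upstream of the fragment start ", origin)
  if (!is.null(length) && any(off >= length))
    stop("position ", pos[which(off >= length)[1]],
         " lies beyond the fragment end")
  as.integer(off)
}

#' Convert a 0-based offset back to a promoter coordinate
#'
#' Inverse of [promoter_to_offset()].
#' @param offset 0-based offset(s).
#' @param origin promoter coordinate of the first base.
#' @export
offset_to_promoter <- function(offset, origin) {
  check_promoter_pos(origin, "origin")
  if (any(offset < 0)) stop("offset must be >= 0")
  pos <- origin + offset
  pos <- pos + ifelse(origin < 0 & pos >= 0, 1L, 0L)
  as.integer(pos)
}

#' Length in bp of a closed promoter-coordinate interval
#'
#' @param start,end promoter coordinates, `start <= end` on the skip-zero axis.
#' @export
promoter_span_length <- function(start, end) {
  check_promoter_pos(start, "start")
  check_promoter_pos(end, "end")
  n <- end - start + 1L - ifelse(start < 0 & end > 0, 1L, 0L)
  if (any(n < 1)) stop("end precedes start")
  as.integer(n)
}
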