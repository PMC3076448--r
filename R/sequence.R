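#' Construct a genomic sequence with a promoter coordinate system
#'
#' A `genomic_sequence` couples a plain ACGT base string to the skip-zero
#' promoter coordinate axis (see [promoter-coordinates]) and an optional
#' feature table (named closed intervals such as TATA, PRRI, PRRII).
#'
#' @param bases single string over {A,C,G,T}; lower case is normalized.
#'   IUPAC ambiguity codes are rejected because the dinucleotide step and
#'   nearest-neighbor tables downstream are defined only for ACGT.
#' @param origin promoter coordinate of the first base (never 0).
#' @param features optional data.frame with columns name, start, end
#'   (promoter coordinates, closed intervals).
#' @return object of class `genomic_sequence`.
#' @export
genomic_sequence <- function(bases, origin = 1L, features = NULL) {
  stopifnot(is.character(bases), length(bases) == 1)
  bases <- toupper(bases)
  if (nchar(bases) < 2) stop("sequence must contain at least 2 bases")
  if (grepl("[^ACGT]", bases))
    stop("sequence contains characters outside ACGT; ",
         "ambiguity codes are not supported")
  check_promoter_pos(origin, "origin")
  if (!is.null(features)) {
    stopifnot(all(c("name", "start", "end") %in% names(features)))
    features <- as.data.frame(features)[, c("name", "start", "end")]
    n <- nchar(bases)
    for (k in seq_len(nrow(features))) {
      promoter_to_offset(features$start[k], origin, n)
      promoter_to_offset(features$end[k], origin, n)
    }
  } else {
    features <- data.frame(name = character(), start = integer(),
                           end = integer())
  }
  structure(list(bases = bases, origin = as.integer(origin),
                 features = features),
            class = "genomic_sequence")
}

#' @export
length.genomic_sequence <- function(x) nchar(x$bases)

#' @export
print.genomic_sequence <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<genomic_sequence> %d bp, span %+d..%+d\n",
              n, x$origin, seq_end(x)))
  if (nrow(x$features))
    cat("  features:", paste(sprintf("%s[%+d..%+d]", x$features$name,
                                     x$features$start, x$features$end),
                             collapse = " "), "\n")
  invisible(x)
}

#' Promoter coordinate of the last base
#' @param seq a `genomic_sequence`.
#' @export
seq_end <- function(seq) offset_to_promoter(length(seq) - 1L, seq$origin)

#' Extract a sub-sequence by promoter coordinates
#'
#' The extracted fragment keeps the promoter axis: its origin is `start`.
#' Features are clipped to the new span.
#' @param seq a `genomic_sequence`.
#' @param start,end closed promoter-coordinate interval.
#' @export
subseq_promoter <- function(seq, start, end) {
  i <- promoter_to_offset(start, seq$origin, length(seq))
  j <- promoter_to_offset(end, seq$origin, length(seq))
  if (j < i) stop("end precedes start")
  feats <- seq$features
  keep <- feats$start <= end & feats$end >= start
  feats <- feats[keep, , drop = FALSE]
  if (nrow(feats)) {
    feats$start <- pmax(feats$start, start)
    feats$end <- pmin(feats$end, end)
  }
  genomic_sequence(substr(seq$bases, i + 1L, j + 1L), origin = start,
                   features = feats)
}

#' Read a single-record FASTA file
#'
#' Standard FASTA via Biostrings; the first record is used and uppercased.
#' Records containing symbols outside ACGT are rejected.
#'
#' @param path FASTA file.
#' @param origin promoter coordinate assigned to the first base.
#' @param features optional feature data.frame (name, start, end).
#' @export
read_fasta <- function(path, origin = 1L, features = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no FASTA record in ", path)
  genomic_sequence(as.character(set[[1]]), origin = origin,
                   features = features)
}

#' Write a genomic sequence as FASTA
#' @param seq a `genomic_sequence`.
#' @param path output file.
#' @param name FASTA header; defaults to the promoter span.
#' @export
write_fasta <- function(seq, path,
                        name = sprintf("span_%+d_%+d", seq$origin,
                                       seq_end(seq))) {
  set <- Biostrings::DNAStringSet(seq$bases)
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement
#'
#' The coordinate axis is mirrored: the new origin is the (negated) old end,
#' so that a feature at promoter positions \[s, e\] maps to \[-e', -s'\] on
#' the mirrored axis. An involution: `reverse_complement(reverse_complement(x))`
#' reproduces `x` exactly, features included.
#' @param seq a `genomic_sequence`.
#' @export
reverse_complement <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq$bases)))
  n <- length(seq)
  mirror <- function(pos) {
    off <- promoter_to_offset(pos, seq$origin, n)
    offset_to_promoter((n - 1L) - off, mirror_origin)
  }
  old_end_off <- n - 1L
  # mirrored origin: coordinate axis flips sign and direction
  mirror_origin <- -offset_to_promoter(old_end_off, seq$origin)
  check_promoter_pos(mirror_origin, "origin")
  feats <- seq$features
  if (nrow(feats)) {
    ns <- vapply(feats$end, mirror, integer(1))
    ne <- vapply(feats$start, mirror, integer(1))
    feats <- data.frame(name = feats$name, start = ns, end = ne)
  }
  genomic_sequence(rc, origin = mirror_origin, features = feats)
}

#' Find maximal A/T tracts
#'
#' A tract is a maximal run of A/T (IUPAC W) of at least `min_len` bases:
#' the flanking bases are G, C, or the sequence ends, and the run contains
#' no G/C. Composition is by definition 1 and is reported for the record.
#'
#' @param seq a `genomic_sequence`.
#' @param min_len minimum tract length in bp (default 5).
#' @return data.frame (start, end in promoter coordinates, length,
#'   composition), sorted by start; tracts never overlap.
#' @export
find_at_tracts <- function(seq, min_len = 5L) {
  if (min_len < 2) stop("min_len must be >= 2")
  b <- strsplit(seq$bases, "")[[1]]
  r <- rle(b %in% c("A", "T"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(
    start = offset_to_promoter(starts[keep] - 1L, seq$origin),
    end = offset_to_promoter(ends[keep] - 1L, seq$origin),
    length = r$lengths[keep],
    composition = rep(1, sum(keep)))
  out[order(out$start), , drop = FALSE]
}

#' Read features from a BED-like TSV (name, start, end in promoter coords)
#' @param path TSV file with header.
#' @export
read_features_tsv <- function(path) {
  f <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(f)))
  f[, c("name", "start", "end")]
}

#' Write an A/T-tract table as TSV
#' @param tracts output of [find_at_tracts()].
#' @param path output file.
#' @export
write_tracts_tsv <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
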