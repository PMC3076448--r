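#' Dinucleotide step tables
#'
#' The helix-axis trajectory model is driven by a table assigning a roll,
#' tilt and twist angle (degrees) to each of the 16 dinucleotide steps,
#' plus one global rise per step (nm). The default table ships as an
#' editable TSV (`inst/extdata/wedge_steps.tsv`) transcribed from the
#' classical dinucleotide wedge-angle set of Bolshoy and co-workers, in
#' which each step's deflection is given as a wedge magnitude and direction;
#' here it is stored pre-decomposed as roll = wedge*cos(direction) and
#' tilt = wedge*sin(direction).
#'
#' @name step-tables
NULL

DINUCS <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
            "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

#' Read a dinucleotide step table from TSV
#'
#' Expected columns: step, roll, tilt, twist (degrees). All 16 dinucleotides
#' must be present, twist must lie in (0, 90) degrees.
#'
#' @param path TSV file.
#' @param rise helix rise per step in nm (0.34 for B-DNA).
#' @return object of class `step_table`: data.frame keyed by dinucleotide
#'   with attribute `rise`.
#' @export
read_step_table <- function(path, rise = 0.34) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("step", "roll", "tilt", "twist") %in% names(t)))
  if (!setequal(t$step, DINUCS))
    stop("step table must contain exactly the 16 dinucleotides")
  if (any(t$twist <= 0 | t$twist >= 90))
    stop("twist values must lie in (0, 90) degrees")
  t <- t[match(DINUCS, t$step), c("step", "roll", "tilt", "twist")]
  rownames(t) <- t$step
  structure(t, rise = rise, class = c("step_table", "data.frame"))
}

the_pkg_cache <- new.env(parent = emptyenv())

#' The packaged wedge-angle step table
#' @export
default_step_table <- function() {
  if (is.null(the_pkg_cache$step_table)) {
    path <- system.file("extdata", "wedge_steps.tsv", package = "curvafm",
                        mustWork = TRUE)
    the_pkg_cache$step_table <- read_step_table(path)
  }
  the_pkg_cache$step_table
}

#' Mean helical repeat of a step table (bp per turn)
#' @param table a `step_table`.
#' @export
helical_repeat <- function(table) 360 / mean(table$twist)

#' Rescale twists to impose a target phasing pitch
#'
#' All 16 twist angles are multiplied by the single factor
#' (360/target_pitch)/mean(native twist), so the rescaled table has mean
#' helical repeat exactly `target_pitch` while the sequence-dependent twist
#' modulation is preserved. Roll and tilt are untouched. At the native
#' repeat the factor is 1 and the table is returned unchanged.
#'
#' @param table a `step_table`.
#' @param target_pitch desired mean helical repeat in bp per turn.
#' @export
rescale_twist <- function(table, target_pitch) {
  if (target_pitch <= 0) stop("target_pitch must be positive")
  f <- (360 / target_pitch) / mean(table$twist)
  out <- table
  out$twist <- table$twist * f
  out
}
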