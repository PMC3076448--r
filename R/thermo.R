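#' Nearest-neighbor duplex thermodynamics
#'
#' Duplex stability is computed from the unified Watson-Crick
#' nearest-neighbor parameter set (SantaLucia's unified library): one
#' enthalpy/entropy pair per each of the 10 unique stacked pairs, at the
#' reference condition 1 M NaCl, pH 7. The 10 unique steps cover all 16
#' dinucleotides through complement symmetry (the stack 5'-XY-3' paired
#' with its complement is the same physical unit as 5'-revcomp(XY)-3').
#' Free energies are evaluated at 25 degrees C from dH and dS
#' (dG = dH - T*dS) rather than read from a 37 C table, matching the
#' stated analysis condition. No salt correction is applied: the stated
#' condition is exactly the table's reference condition.
#'
#' @name nn-thermo
NULL

NN_EQUIV <- c(AA = "AA", TT = "AA", AT = "AT", TA = "TA",
              CA = "CA", TG = "CA", GT = "GT", AC = "GT",
              CT = "CT", AG = "CT", GA = "GA", TC = "GA",
              CG = "CG", GC = "GC", GG = "GG", CC = "GG")

#' Read a nearest-neighbor parameter TSV
#'
#' Columns: step, dH (kcal/mol), dS (cal/(mol K)); rows for the 10 unique
#' steps plus the duplex initiation terms `init_GC` and `init_AT`.
#'
#' @param path TSV file.
#' @return class `nn_params`: data.frame keyed by step.
#' @export
read_nn_params <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c(unique(unname(NN_EQUIV)), "init_GC", "init_AT")
  if (!all(need %in% t$step))
    stop("nearest-neighbor table is missing steps: ",
         paste(setdiff(need, t$step), collapse = ", "))
  rownames(t) <- t$step
  structure(t, class = c("nn_params", "data.frame"))
}

#' The packaged unified nearest-neighbor set
#' @export
default_nn_params <- function() {
  if (is.null(the_pkg_cache$nn)) {
    path <- system.file("extdata", "nn_unified.tsv", package = "curvafm",
                        mustWork = TRUE)
    the_pkg_cache$nn <- read_nn_params(path)
  }
  the_pkg_cache$nn
}

#' Step free energies at a temperature, expanded to all 16 dinucleotides
#'
#' @param params an `nn_params` table.
#' @param temperature_C temperature in degrees Celsius (default 25).
#' @return named numeric vector of dG (kcal/mol) for the 16 dinucleotides.
#' @export
nn_step_dG <- function(params = default_nn_params(), temperature_C = 25) {
  TK <- temperature_C + 273.15
  dG10 <- params$dH - TK * params$dS / 1000
  names(dG10) <- params$step
  dG10[NN_EQUIV[DINUCS]] -> v
  names(v) <- DINUCS
  v
}

#' Mean nearest-neighbor free energy of one window
#'
#' The statistic is the mean of the (w - 1) stacked-pair dG values inside
#' the window, in kcal/mol per base step; initiation terms are not applied
#' inside sliding windows (they belong to whole-duplex formation, not to a
#' window of an intact duplex). Set `statistic = "sum"` for the window
#' total instead.
#'
#' @param window ACGT string (or `genomic_sequence`) of length >= 2.
#' @param params an `nn_params` table.
#' @param temperature_C evaluation temperature (25 C default).
#' @param statistic "mean" (default) or "sum".
#' @export
window_dG <- function(window, params = default_nn_params(),
                      temperature_C = 25,
                      statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (inherits(window, "genomic_sequence")) window <- window$bases
  window <- toupper(window)
  if (nchar(window) < 2) stop("window must contain at least 2 bases")
  if (grepl("[^ACGT]", window)) stop("window contains non-ACGT characters")
  b <- strsplit(window, "")[[1]]
  n <- length(b)
  dg <- nn_step_dG(params, temperature_C)[paste0(b[-n], b[-1])]
  if (statistic == "mean") mean(dg) else sum(dg)
}

#' Sliding-window duplex-stability profile
#'
#' @param seq a [genomic_sequence()].
#' @param window_len window in bp (default 150).
#' @param step slide step in bp (default 1).
#' @inheritParams window_dG
#' @return class `dG_profile`: data.frame (center in promoter coordinates,
#'   dG in kcal/mol per step) with attribute `global_mean`, the mean step
#'   dG over the whole sequence (the horizontal reference line of a
#'   stability plot).
#' @export
dG_profile <- function(seq, window_len = 150, step = 1,
                       params = default_nn_params(), temperature_C = 25,
                       statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  n <- length(seq)
  if (n < window_len) stop("sequence shorter than the window")
  b <- strsplit(seq$bases, "")[[1]]
  dg <- unname(nn_step_dG(params, temperature_C)[paste0(b[-n], b[-1])])
  cs <- c(0, cumsum(dg))
  w <- window_len - 1L          # steps per window
  i <- seq.int(1L, n - window_len + 1L, by = step)
  tot <- cs[i + w] - cs[i]
  val <- if (statistic == "mean") tot / w else tot
  center_off <- (i - 1) + (window_len - 1) / 2
  # half-integer centers for even windows: round half up, uniformly
  centers <- offset_to_promoter(as.integer(floor(center_off + 0.5)),
                                seq$origin)
  structure(data.frame(center = centers, dG = val),
            window_len = window_len, step = step, statistic = statistic,
            global_mean = mean(dg),
            class = c("dG_profile", "data.frame"))
}

#' Export a stability profile as TSV (center, dG, global_mean)
#' @param profile a `dG_profile`.
#' @param path output file.
#' @export
write_dG_tsv <- function(profile, path) {
  d <- data.frame(center = profile$center, dG = profile$dG,
                  global_mean = attr(profile, "global_mean"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
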