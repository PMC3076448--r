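#' Positioning statistics over a molecule population
#'
#' Histogram of placement calls (nucleosome dyads, bound proteins, loop
#' middle points) in a shared coordinate frame, plus the modal bin and the
#' fraction of calls falling inside each named feature.
#'
#' @param calls data.frame of placement calls with columns `kind` and
#'   `position` (bp or promoter coordinate, one frame for all calls).
#' @param bin_width histogram bin width in bp.
#' @param features optional data.frame (name, start, end) in the same
#'   coordinates.
#' @param n_molecules number of molecules the calls came from; defaults to
#'   the number of calls.
#' @param range optional c(lo, hi) histogram range; defaults to the call
#'   range padded to whole bins.
#' @return class `position_histogram`: list with `kind`, `bin_width`,
#'   `breaks`, `counts`, `n_molecules`, `mode_interval`, and
#'   `feature_fractions` (named vector) when features are given.
#' @export
positioning_stats <- function(calls, bin_width = 20, features = NULL,
                              n_molecules = nrow(calls), range = NULL) {
  if (nrow(calls) == 0) {
    return(structure(list(kind = character(0), bin_width = bin_width,
                          breaks = numeric(0), counts = integer(0),
                          n_molecules = 0, mode_interval = c(NA, NA),
                          feature_fractions = NULL),
                     class = "position_histogram"))
  }
  if (n_molecules < nrow(calls) &&
      length(unique(calls$kind)) == 1)
    stop("more calls than molecules for a single-call kind; ",
         "positions from mixed fragments need registration first")
  pos <- calls$position
  if (is.null(range))
    range <- c(floor(min(pos) / bin_width) * bin_width,
               ceiling(max(pos) / bin_width + 1e-9) * bin_width)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < max(pos))
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  counts <- as.integer(table(cut(pos, breaks, include.lowest = TRUE)))
  imode <- which.max(counts)
  ff <- NULL
  if (!is.null(features) && nrow(features)) {
    ff <- vapply(seq_len(nrow(features)), function(k)
      mean(pos >= features$start[k] & pos <= features$end[k]), numeric(1))
    names(ff) <- features$name
  }
  structure(list(kind = unique(calls$kind), bin_width = bin_width,
                 breaks = breaks, counts = counts,
                 n_molecules = n_molecules,
                 mode_interval = c(breaks[imode], breaks[imode + 1]),
                 feature_fractions = ff),
            class = "position_histogram")
}

#' @export
print.position_histogram <- function(x, ...) {
  cat(sprintf("<position_histogram> %s: %d calls / %d molecules, bin %d bp, mode [%g, %g]\n",
              paste(x$kind, collapse = "+"), sum(x$counts), x$n_molecules,
              x$bin_width, x$mode_interval[1], x$mode_interval[2]))
  if (!is.null(x$feature_fractions)) {
    cat("  in features:",
        paste(sprintf("%s %.0f%%", names(x$feature_fractions),
                      100 * x$feature_fractions), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run the full structural report on a sequence (and optional images)
#'
#' Orchestrates the sequence-side stages — A/T tracts, native-pitch
#' curvature profile, curvature map, supercoil calls, duplex-stability
#' profile — and, when AFM images are supplied, molecule tracing and
#' placement calls. Every output lands as TSV under `outdir` and is listed
#' in a `manifest.tsv` with md5 checksums; rerunning with the same inputs
#' and seeds reproduces the manifest exactly.
#'
#' @param seq a [genomic_sequence()].
#' @param images optional list of [afm_image()] objects.
#' @param outdir output directory (created if needed).
#' @param config list of stage parameters; recognized entries (with
#'   defaults): `window_len` (150), `step` (1), `pitches` (5..15 by 0.5),
#'   `min_tract_len` (5), `height_threshold` (0.5), `canonical_pitch`
#'   (10.5).
#' @return list with the computed objects plus `manifest` (data.frame
#'   file, md5), invisibly written to `outdir/manifest.tsv`.
#' @export
run_report <- function(seq, images = NULL, outdir = "curvafm_report",
                       config = list()) {
  cfg <- utils::modifyList(list(window_len = 150, step = 1,
                                pitches = seq(5, 15, by = 0.5),
                                min_tract_len = 5, height_threshold = 0.5,
                                canonical_pitch = 10.5), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }
  files <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(outdir, fname)
    writer(path)
    files <<- c(files, path)
  }

  out$tracts <- stage("tracts", find_at_tracts(seq, cfg$min_tract_len))
  emit("at_tracts.tsv", function(p) write_tracts_tsv(out$tracts, p))

  out$profile <- stage("curvature_profile",
    seq_ends_ratio(seq, window_len = cfg$window_len, step = cfg$step))
  emit("ends_ratio_native.tsv", function(p)
    utils::write.table(out$profile, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  out$map <- stage("curvature_map",
    curvature_map(seq, pitches = cfg$pitches,
                  window_len = cfg$window_len, step = cfg$step))
  emit("curvature_map.tsv", function(p) write_curvature_map_tsv(out$map, p))

  out$supercoils <- stage("supercoils",
    call_supercoils(out$map, canonical_pitch = cfg$canonical_pitch))
  emit("supercoils.bed.tsv", function(p)
    write_supercoils_bed(out$supercoils, p))

  out$dG <- stage("duplex_stability",
    dG_profile(seq, window_len = cfg$window_len, step = cfg$step))
  emit("dG_profile.tsv", function(p) write_dG_tsv(out$dG, p))

  if (!is.null(images)) {
    model <- stage("orientation_model", model_height_profile(seq))
    traces <- list(); calls <- list()
    for (i in seq_along(images)) {
      trs <- stage(paste0("skeletonize_", i),
        skeletonize_molecule(images[[i]],
                             height_threshold = cfg$height_threshold))
      for (tr in trs) {
        o <- orient_molecule(tr, model)
        if (!o$oriented) {
          warning("image ", i, ": molecule left unoriented (", o$reason,
                  ")")
          next
        }
        traces[[length(traces) + 1]] <- o$trace
        pc <- map_protein(o$trace)
        if (nrow(pc)) {
          pc$molecule <- length(traces)
          calls[[length(calls) + 1]] <- pc
        }
      }
    }
    out$traces <- traces
    if (length(traces))
      emit("traces.tsv", function(p) write_traces_tsv(traces, p))
    if (length(calls)) {
      out$calls <- do.call(rbind, calls)
      emit("calls.tsv", function(p) write_calls_tsv(out$calls, p))
      out$histogram <- positioning_stats(out$calls,
                                         features = seq$features)
    }
  }

  md5 <- tools::md5sum(files)
  out$manifest <- data.frame(file = basename(files), md5 = unname(md5))
  utils::write.table(out$manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
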