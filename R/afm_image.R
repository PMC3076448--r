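#' AFM height image container
#'
#' @param heights numeric matrix of heights in nm (rows = scan lines).
#' @param pixel_size lateral calibration in nm per pixel (> 0).
#' @param frame_time optional acquisition time of the frame in seconds
#'   (used to order time-lapse series).
#' @return object of class `afm_image`.
#' @export
afm_image <- function(heights, pixel_size, frame_time = NULL) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive nm/pixel value")
  structure(list(heights = heights, pixel_size = pixel_size,
                 frame_time = frame_time),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("<afm_image> %d x %d px, %.2f nm/px, heights %.2f..%.2f nm%s\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights),
              if (is.null(x$frame_time)) ""
              else sprintf(", t = %gs", x$frame_time)))
  invisible(x)
}

#' Read a plain-text AFM raster with a sidecar config
#'
#' The raster is a whitespace-separated matrix of heights in nm. Pixel size
#' (and optionally frame time) come either from arguments or from a
#' sidecar file `<path>.cfg` with `key = value` lines (`pixel_size_nm`,
#' `frame_time_s`).
#'
#' @param path raster text file.
#' @param pixel_size nm/pixel; overrides the sidecar when given.
#' @param frame_time seconds; overrides the sidecar when given.
#' @export
read_afm_raster <- function(path, pixel_size = NULL, frame_time = NULL) {
  h <- as.matrix(utils::read.table(path))
  dimnames(h) <- NULL
  cfg_path <- paste0(path, ".cfg")
  cfg <- list()
  if (file.exists(cfg_path)) {
    lines <- readLines(cfg_path)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    cfg <- stats::setNames(
      lapply(kv, function(p) as.numeric(trimws(p[2]))),
      vapply(kv, function(p) trimws(p[1]), character(1)))
  }
  if (is.null(pixel_size)) pixel_size <- cfg$pixel_size_nm
  if (is.null(frame_time)) frame_time <- cfg$frame_time_s
  if (is.null(pixel_size))
    stop("pixel_size not given and no sidecar ", cfg_path)
  afm_image(h, pixel_size, frame_time)
}

#' Write a plain-text AFM raster (and sidecar config)
#' @param image an `afm_image`.
#' @param path output raster file; the sidecar goes to `<path>.cfg`.
#' @export
write_afm_raster <- function(image, path) {
  utils::write.table(signif(image$heights, 7), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cfg <- sprintf("pixel_size_nm = %g", image$pixel_size)
  if (!is.null(image$frame_time))
    cfg <- c(cfg, sprintf("frame_time_s = %g", image$frame_time))
  writeLines(cfg, paste0(path, ".cfg"))
  invisible(path)
}

#' Line-by-line polynomial background flattening
#'
#' Each scan line (matrix row) gets a least-squares polynomial of the given
#' order fitted on its background pixels and subtracted. Background pixels
#' are found in two passes: a first fit on the whole line, then a refit on
#' pixels whose residual stays below `threshold` (molecules stick out of
#' the background). A line whose pixels are all masked falls back to a fit
#' on the whole line. Idempotent up to numerical precision.
#'
#' @param image an `afm_image`.
#' @param polynomial_order order of the per-line background polynomial
#'   (<= 3; 2 is the standard choice).
#' @param threshold height above the fitted background (nm) above which a
#'   pixel is treated as foreground and excluded from the second fit.
#' @export
flatten <- function(image, polynomial_order = 2, threshold = 0.5) {
  if (polynomial_order > 3) stop("polynomial_order must be <= 3")
  h <- image$heights
  x <- seq_len(ncol(h))
  X <- stats::poly(x, degree = polynomial_order, raw = TRUE)
  X <- cbind(1, X)
  for (r in seq_len(nrow(h))) {
    y <- h[r, ]
    res <- stats::lm.fit(X, y)$residuals
    for (it in 1:3) {   # iterate the background mask to convergence
      bg <- res < threshold
      if (sum(bg) <= polynomial_order + 1) break
      co <- stats::lm.fit(X[bg, , drop = FALSE], y[bg])$coefficients
      res <- y - drop(X %*% co)
    }
    h[r, ] <- res
  }
  afm_image(h, image$pixel_size, image$frame_time)
}
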