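#' Gel image container
#'
#' A `gel_image` bundles a 2DE gel scan with its coordinate metadata: a
#' numeric pixel matrix in scanned polarity (bright background, dark
#' protein spots; 16-bit scale), the physical resolution, an analysis ROI
#' (the protein map area) nested inside a working ROI (which may also
#' contain the molecular-mass marker lane), and an optional pI /
#' molecular-mass calibration.
#'
#' ROIs use the half-open convention `c(r0, r1, c0, c1)`: rows
#' `r0 .. r1 - 1` and columns `c0 .. c1 - 1`, 1-based.
#'
#' @param pixels numeric matrix of non-negative intensities (high value =
#'   bright background).
#' @param label gel identifier, e.g. `"G1"`.
#' @param dpi scan resolution in dots per inch.
#' @param analysis_roi,working_roi half-open ROIs; default to the full image.
#' @param calibration optional [calibration_model()].
#' @return an object of class `gel_image`.
#' @export
gel_image <- function(pixels, label = "gel", dpi = 300,
                      analysis_roi = NULL, working_roi = NULL,
                      calibration = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (any(pixels < 0)) stop("pixels must be non-negative")
  nr <- nrow(pixels); nc <- ncol(pixels)
  full <- c(1L, nr + 1L, 1L, nc + 1L)
  if (is.null(working_roi)) working_roi <- full
  if (is.null(analysis_roi)) analysis_roi <- working_roi
  working_roi <- check_roi(working_roi, nr, nc, "working_roi")
  analysis_roi <- check_roi(analysis_roi, nr, nc, "analysis_roi")
  if (!roi_contains(working_roi, analysis_roi))
    stop("analysis_roi must lie inside working_roi")
  if (!is.null(calibration) && !inherits(calibration, "calibration_model"))
    stop("calibration must be a calibration_model")
  structure(list(pixels = pixels, label = label, dpi = dpi,
                 analysis_roi = analysis_roi, working_roi = working_roi,
                 calibration = calibration),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("gel_image '%s': %d x %d px, %g dpi\n",
              x$label, nrow(x$pixels), ncol(x$pixels), x$dpi))
  cat(sprintf("  analysis ROI rows [%d,%d) cols [%d,%d); calibration: %s\n",
              x$analysis_roi[1], x$analysis_roi[2], x$analysis_roi[3],
              x$analysis_roi[4],
              if (is.null(x$calibration)) "none" else "set"))
  invisible(x)
}

#' @export
dim.gel_image <- function(x) dim(x$pixels)

#' Read a gel scan from TIFF
#'
#' Reads a single-channel 8- or 16-bit TIFF scan bit-exactly (intensities
#' on the native integer scale). Multi-channel files are rejected: gels are
#' scanned in grayscale transmission mode and an RGB file signals a wrong
#' scanner setting. The resolution is taken from the TIFF tags when
#' present, else from `dpi`.
#'
#' @param path TIFF file path.
#' @param label gel identifier stored on the result.
#' @param dpi fallback resolution when the file carries none.
#' @return a [gel_image()].
#' @export
read_gel <- function(path, label = sub("\\.tiff?$", "", basename(path)),
                     dpi = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) stop("unreadable TIFF: ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3L && dim(img)[3] > 1L)
    stop("expected single-channel gel scan, got ", dim(img)[3], " channels")
  if (length(dim(img)) == 3L) img <- img[, , 1]
  info <- attributes(img)
  if (!is.null(info$x.resolution) && isTRUE(info$x.resolution > 0) &&
      identical(info$res.unit, "inch"))
    dpi <- info$x.resolution
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (diff(range(m)) == 0)
    warning("all-constant image: likely a blank scan")
  gel_image(m, label = label, dpi = dpi)
}

#' Write a gel image to TIFF
#'
#' Writes the pixel matrix as an uncompressed single-channel TIFF at the
#' requested bit depth. Integer-valued matrices round-trip bit-exactly
#' through [read_gel()].
#'
#' @param gel a [gel_image()].
#' @param path output path.
#' @param bits 8 or 16.
#' @export
write_gel <- function(gel, path, bits = 16L) {
  stopifnot(inherits(gel, "gel_image"), bits %in% c(8L, 16L))
  mx <- if (bits == 16L) INT_MAX_16 else 255
  p <- clamp(gel$pixels, 0, mx)
  tiff::writeTIFF(p / mx, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Crop a gel to its working region
#'
#' Restricts the pixel raster to `working_roi` and re-expresses
#' `analysis_roi` and any calibration pixel coordinates relative to the new
#' origin, so that the mapping from a physical gel point to (Mw, pI) is
#' unchanged by cropping.
#'
#' @param gel a [gel_image()].
#' @param analysis_roi,working_roi half-open ROIs in the *input* gel's
#'   coordinates; `analysis_roi` must lie inside `working_roi`.
#' @return cropped [gel_image()].
#' @export
crop_to_roi <- function(gel, analysis_roi, working_roi) {
  stopifnot(inherits(gel, "gel_image"))
  nr <- nrow(gel$pixels); nc <- ncol(gel$pixels)
  working_roi <- check_roi(working_roi, nr, nc, "working_roi")
  analysis_roi <- check_roi(analysis_roi, nr, nc, "analysis_roi")
  if (!roi_contains(working_roi, analysis_roi))
    stop("analysis_roi must lie inside working_roi")
  px <- gel$pixels[working_roi[1]:(working_roi[2] - 1L),
                   working_roi[3]:(working_roi[4] - 1L), drop = FALSE]
  dr <- working_roi[1] - 1L; dc <- working_roi[3] - 1L
  new_analysis <- analysis_roi - c(dr, dr, dc, dc)
  cal <- gel$calibration
  if (!is.null(cal)) cal <- shift_calibration(cal, -dr, -dc)
  gel_image(px, label = gel$label, dpi = gel$dpi,
            analysis_roi = new_analysis, calibration = cal)
}

#' Calibration model for the gel axes
#'
#' Ties pixel coordinates to physical coordinates: molecular mass from the
#' marker-ladder lane (row vs kDa) and isoelectric point from the
#' immobilized pH gradient strip endpoints (column vs pI). Molecular mass
#' is interpolated piecewise-linearly in log10(kDa) against row — the
#' standard migration law for SDS gels — and pI linearly against column.
#'
#' @param mw_markers 2-column matrix or data frame `(row, kda)`; at least
#'   two markers, rows strictly monotone, masses strictly monotone and > 0.
#' @param pi_anchors 2-column matrix or data frame `(col, pi)`; at least
#'   two anchors, columns strictly monotone, pI strictly monotone in
#'   `[0, 14]`.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(mw_markers, pi_anchors) {
  mw <- as.data.frame(mw_markers); names(mw) <- c("row", "kda")
  pa <- as.data.frame(pi_anchors); names(pa) <- c("col", "pi")
  if (nrow(mw) < 2L) stop("need >= 2 molecular-mass markers")
  if (nrow(pa) < 2L) stop("need >= 2 pI anchors")
  mw <- mw[order(mw$row), , drop = FALSE]
  pa <- pa[order(pa$col), , drop = FALSE]
  if (any(diff(mw$row) <= 0)) stop("marker rows must be strictly monotone")
  if (any(mw$kda <= 0)) stop("masses must be positive")
  dk <- diff(mw$kda)
  if (!(all(dk > 0) || all(dk < 0)))
    stop("marker masses must be strictly monotone")
  if (any(diff(pa$col) <= 0)) stop("anchor columns must be strictly monotone")
  dp <- diff(pa$pi)
  if (!(all(dp > 0) || all(dp < 0)))
    stop("anchor pI values must be strictly monotone")
  if (any(pa$pi < 0 | pa$pi > 14)) stop("pI must lie in [0, 14]")
  structure(list(mw_markers = mw, pi_anchors = pa),
            class = "calibration_model")
}

shift_calibration <- function(cal, dr, dc) {
  mw <- cal$mw_markers; mw$row <- mw$row + dr
  pa <- cal$pi_anchors; pa$col <- pa$col + dc
  calibration_model(mw, pa)
}

# piecewise-linear interpolation with end-segment extrapolation up to
# `margin` (fraction of the node span), erroring beyond it
interp_margin <- function(xs, ys, x, margin, what) {
  span <- diff(range(xs))
  lo <- min(xs) - margin * span; hi <- max(xs) + margin * span
  if (any(x < lo | x > hi))
    stop(what, " query outside calibrated span (allowed extrapolation ",
         round(100 * margin), "% of span)")
  # rule = 2 clamps; extend end segments linearly instead
  y <- stats::approx(xs, ys, xout = x, rule = 2)$y
  below <- x < min(xs); above <- x > max(xs)
  if (any(below)) {
    s <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    y[below] <- ys[1] + s * (x[below] - xs[1])
  }
  if (any(above)) {
    n <- length(xs)
    s <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    y[above] <- ys[n] + s * (x[above] - xs[n])
  }
  y
}

#' Molecular mass at a pixel row
#'
#' Piecewise-linear interpolation of `log10(kDa)` against row; exact at
#' marker rows, strictly monotone across the span, and linearly
#' extrapolated up to `margin` of the marker span beyond the end markers
#' (gel tables routinely report masses above the heaviest ladder point).
#'
#' @param cal a [calibration_model()].
#' @param row pixel row(s), sub-pixel allowed.
#' @param margin allowed extrapolation as a fraction of the marker span.
#' @return mass in kDa.
#' @export
calibrate_mw <- function(cal, row, margin = 0.1) {
  stopifnot(inherits(cal, "calibration_model"))
  10^interp_margin(cal$mw_markers$row, log10(cal$mw_markers$kda),
                   row, margin, "molecular-mass")
}

#' Isoelectric point at a pixel column
#'
#' Linear interpolation of pI against column; exact at anchors, with the
#' same bounded extrapolation rule as [calibrate_mw()].
#'
#' @inheritParams calibrate_mw
#' @param col pixel column(s).
#' @return pI value(s).
#' @export
calibrate_pi <- function(cal, col, margin = 0.1) {
  stopifnot(inherits(cal, "calibration_model"))
  interp_margin(cal$pi_anchors$col, cal$pi_anchors$pi, col, margin, "pI")
}

#' Calibrated coordinates of spot centers
#'
#' Maps sub-pixel spot positions to physical coordinates. Positions whose
#' pI falls outside the anchor range are flagged as extrapolated.
#'
#' @param cal a [calibration_model()].
#' @param row,col sub-pixel positions.
#' @return data frame with `row`, `col`, `mw_kda`, `pi`, `extrapolated`.
#' @export
spot_coordinates <- function(cal, row, col) {
  mw <- calibrate_mw(cal, row)
  pi_ <- calibrate_pi(cal, col)
  extrap <- row < min(cal$mw_markers$row) | row > max(cal$mw_markers$row) |
    col < min(cal$pi_anchors$col) | col > max(cal$pi_anchors$col)
  data.frame(row = row, col = col, mw_kda = mw, pi = pi_,
             extrapolated = extrap)
}
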