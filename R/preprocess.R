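#' Median smoothing for impulse-noise removal
#'
#' Replaces each pixel by the exact median of its `window x window`
#' neighborhood (mirror-reflected borders). Salt/pepper impulses from dust
#' and stain particles are removed while spots, which are much larger than
#' the window, keep their position and depth.
#'
#' @param gel a [gel_image()].
#' @param window odd window side, >= 3.
#' @return smoothed [gel_image()].
#' @export
median_smooth <- function(gel, window = 3L) {
  stopifnot(inherits(gel, "gel_image"))
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  out <- gel
  out$pixels <- median_filter_rect(gel$pixels, window, window)
  out
}

#' Morphological background removal (top-hat)
#'
#' Estimates the smoothly varying staining background by a grayscale
#' opening with a disk structuring element and subtracts it. The gel is
#' inverted internally so protein spots are peaks: the result is the
#' white-top-hat of the inverted image, i.e. a non-negative spot-signal
#' image in which background-only areas map to ~0 and pit depth is
#' preserved as long as the spot diameter is below twice the disk radius.
#'
#' @param gel a [gel_image()].
#' @param disk_radius structuring-element radius in px; choose it larger
#'   than the radius of the largest expected spot.
#' @return a [gel_image()] whose pixels are the spot signal (bright =
#'   protein, background ~ 0).
#' @export
subtract_background <- function(gel, disk_radius = 20) {
  stopifnot(inherits(gel, "gel_image"))
  if (disk_radius <= 0) stop("disk_radius must be positive")
  inv <- max(gel$pixels) - gel$pixels
  brush <- EBImage::makeBrush(2L * as.integer(disk_radius) + 1L, "disc")
  # replicate-pad so border erosion does not see an artificial zero rim
  nr <- nrow(inv); nc <- ncol(inv)
  p <- as.integer(disk_radius) + 1L
  ri <- c(rep(1L, p), seq_len(nr), rep(nr, p))
  ci <- c(rep(1L, p), seq_len(nc), rep(nc, p))
  # EBImage grayscale morphology works on the [0, 1] scale
  sc <- max(inv, 1)
  opened <- as.matrix(EBImage::opening(inv[ri, ci] / sc, brush)) * sc
  opened <- opened[p + seq_len(nr), p + seq_len(nc)]
  out <- gel
  out$pixels <- pmax(inv - opened, 0)
  out
}

#' Score vertical geometric distortion of a gel
#'
#' Quantifies how far the gel's iso-molecular-mass structure departs from
#' horizontal, following the master-gel selection recipe: (a) elongated
#' ("asymmetric") median filtering that suppresses point features while
#' keeping horizontal ridges, (b) horizontal Gaussian smoothing that links
#' the spots of one molecular-mass row into a continuous ridge, (c) ridge
#' isolation by per-column vertical non-maximum suppression of the ridge
#' intensity (the near-horizontal-edge specialization of an edge
#' detector), contour linking across columns, (d) removal of short
#' contours, (e) polynomial fits `row(col)` per contour, (g) robust
#' rejection of outlier tilt coefficients (median +/- 3 MAD), and (h)
#' aggregation into the scalar score `D`: the length-weighted RMS over
#' retained contours of the fitted row minus the contour's median row, in
#' px. `D` is zero for perfectly horizontal structure and invariant to
#' shifting the whole image vertically.
#'
#' @param gel a [gel_image()] (denoised scan, dark-spot polarity).
#' @param median_window width of the 1 x k horizontal median (odd).
#' @param hsmooth_sigma horizontal smoothing sigma in px.
#' @param min_contour_frac minimum contour length as a fraction of the
#'   image width.
#' @param poly_degree degree of the per-contour polynomial fit.
#' @param ridge_quantile per-image intensity quantile a ridge maximum must
#'   exceed to be kept.
#' @param max_jump largest row step allowed when linking a ridge across
#'   neighboring columns.
#' @return object of class `distortion_profile`: per-contour data
#'   (`contours`, a data frame of `contour, col, row`), polynomial fits
#'   (`fits`), tilt coefficients, and the scalar score `D`.
#' @export
distortion_profile <- function(gel, median_window = 9L, hsmooth_sigma = 10,
                               min_contour_frac = 0.3, poly_degree = 2L,
                               ridge_quantile = 0.7, max_jump = 2.5) {
  stopifnot(inherits(gel, "gel_image"))
  px <- gel$pixels
  nr <- nrow(px); nc <- ncol(px)
  # (a) wide horizontal median keeps ridges, kills spots/impulses
  f <- median_filter_rect(px, 1L, as.integer(median_window))
  # work in spot-signal polarity so ridges are maxima
  f <- max(f) - f
  # (b) strong horizontal smoothing links spot rows into ridges
  f <- filter2_rep(f, gaussian_kernel(1.5, hsmooth_sigma))
  thr <- stats::quantile(f, ridge_quantile)
  # (c) vertical non-maximum suppression: per-column local maxima
  up <- rbind(f[1, ], f[-nr, ]); dn <- rbind(f[-1, ], f[nr, ])
  is_max <- f >= up & f > dn & f > thr
  # link maxima column-to-column into contours
  contours <- list()            # each: list(col = ..., row = ...)
  active <- list()              # open contours, last col/row tracked
  for (cl in seq_len(nc)) {
    rows <- which(is_max[, cl])
    used <- rep(FALSE, length(rows))
    if (length(active) > 0) {
      for (ai in seq_along(active)) {
        a <- active[[ai]]
        if (cl - a$last_col > 3L) next  # stale, will be closed below
        if (length(rows) == 0) next
        d <- abs(rows - a$last_row)
        j <- which.min(d)
        if (d[j] <= max_jump * (cl - a$last_col) && !used[j]) {
          a$col <- c(a$col, cl); a$row <- c(a$row, rows[j])
          a$last_col <- cl; a$last_row <- rows[j]
          active[[ai]] <- a; used[j] <- TRUE
        }
      }
    }
    for (j in which(!used)) {
      active[[length(active) + 1L]] <-
        list(col = cl, row = rows[j], last_col = cl, last_row = rows[j])
    }
    stale <- vapply(active, function(a) cl - a$last_col > 3L, TRUE)
    contours <- c(contours, active[stale])
    active <- active[!stale]
  }
  contours <- c(contours, active)
  # (d) drop short contours
  min_len <- ceiling(min_contour_frac * nc)
  contours <- Filter(function(a) length(a$col) >= min_len, contours)
  if (length(contours) == 0)
    stop("no horizontal contours found: distortion score undefined ",
         "(image may lack row structure or thresholds are too strict)")
  # (e) polynomial fits row(col)
  fits <- lapply(contours, function(a) {
    d <- min(poly_degree, length(a$col) - 1L)
    stats::lm(row ~ poly(col, degree = d, raw = TRUE),
              data = data.frame(col = a$col, row = a$row))
  })
  tilt <- vapply(seq_along(contours), function(i) {
    co <- stats::coef(fits[[i]])
    if (length(co) >= 2) co[[2]] else 0
  }, 0)
  # (g) robust tilt filtering: median +/- 3 MAD
  keep <- rep(TRUE, length(tilt))
  if (length(tilt) >= 3) {
    md <- stats::median(tilt); s <- stats::mad(tilt)
    if (s > 0) keep <- abs(tilt - md) <= 3 * s
  }
  if (!any(keep)) keep <- rep(TRUE, length(tilt))
  # (h) D: length-weighted RMS deviation of the fit from a flat line at
  # the contour's median row
  dev2 <- 0; wsum <- 0
  for (i in which(keep)) {
    a <- contours[[i]]
    pred <- stats::predict(fits[[i]])
    d <- pred - stats::median(a$row)
    dev2 <- dev2 + sum(d^2); wsum <- wsum + length(d)
  }
  D <- sqrt(dev2 / wsum)
  cdf <- do.call(rbind, lapply(seq_along(contours), function(i)
    data.frame(contour = i, col = contours[[i]]$col,
               row = contours[[i]]$row)))
  structure(list(contours = cdf, fits = fits, tilt = tilt, kept = keep,
                 D = D, shape = c(nr, nc)),
            class = "distortion_profile")
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat(sprintf("distortion_profile: %d contours (%d kept), D = %.3f px\n",
              length(x$fits), sum(x$kept), x$D))
  invisible(x)
}

#' Select the master gel
#'
#' Returns the index of the gel with the smallest vertical distortion
#' score `D`; every other gel is later registered onto it. Ties break
#' toward the earlier gel in the list.
#'
#' @param gels list of [gel_image()].
#' @param ... passed to [distortion_profile()].
#' @return integer index into `gels`.
#' @export
select_master <- function(gels, ...) {
  stopifnot(is.list(gels), length(gels) >= 1)
  if (length(gels) == 1) {
    warning("single gel supplied: selecting it as master")
    return(1L)
  }
  D <- vapply(gels, function(g) distortion_profile(g, ...)$D, 0)
  which.min(D)   # which.min is first-index on ties
}

# estimated vertical shift field (one value per column) from a profile:
# length-weighted mean over kept contours of (fit - contour median row)
profile_shift_field <- function(profile) {
  nc <- profile$shape[2]
  num <- rep(0, nc); den <- rep(0, nc)
  for (i in which(profile$kept)) {
    sub <- profile$contours[profile$contours$contour == i, ]
    pred <- stats::predict(profile$fits[[i]],
                           newdata = data.frame(col = seq_len(nc)))
    d <- pred - stats::median(sub$row)
    w <- rep(0, nc); w[sub$col] <- 1
    # trust the fit only over the contour's observed span
    span <- range(sub$col)
    idx <- span[1]:span[2]
    num[idx] <- num[idx] + d[idx] * length(sub$col)
    den[idx] <- den[idx] + length(sub$col)
  }
  s <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  # fill uncovered columns by nearest covered value, then smooth lightly
  if (anyNA(s)) {
    ok <- which(!is.na(s))
    if (length(ok) == 0) return(rep(0, nc))
    s <- stats::approx(ok, s[ok], xout = seq_len(nc), rule = 2)$y
  }
  as.vector(stats::filter(c(rep(s[1], 5), s, rep(s[nc], 5)),
                          rep(1 / 11, 11), sides = 2))[6:(nc + 5)]
}

#' Straighten a gel's iso-molecular-mass rows
#'
#' Estimates the smooth column-dependent vertical shift field from a
#' [distortion_profile()] and resamples the gel so that structure of
#' identical molecular mass sits at the same row across the full width.
#' Calibration marker rows are remapped consistently (the shift at the
#' marker-lane column is applied to marker rows).
#'
#' @param gel a [gel_image()].
#' @param profile its [distortion_profile()].
#' @param max_allowed largest tolerated `|shift|` (px); a field beyond
#'   this signals bad contour fits and errors.
#' @return straightened [gel_image()].
#' @export
straighten <- function(gel, profile, max_allowed = 15) {
  stopifnot(inherits(gel, "gel_image"),
            inherits(profile, "distortion_profile"))
  px <- gel$pixels
  nr <- nrow(px); nc <- ncol(px)
  stopifnot(all(profile$shape == c(nr, nc)))
  s <- profile_shift_field(profile)
  if (max(abs(s)) > max_allowed)
    stop("estimated shift field exceeds ", max_allowed,
         " px: contour fits look unreliable")
  out <- px
  rows <- seq_len(nr)
  for (cl in seq_len(nc)) {
    # feature sits at r0 + s(cl); sample input at r + s(cl) to undo
    src <- rows + s[cl]
    src <- clamp(src, 1, nr)
    lo <- floor(src); hi <- pmin(lo + 1, nr); fr <- src - lo
    out[, cl] <- (1 - fr) * px[cbind(lo, cl)] + fr * px[cbind(hi, cl)]
  }
  res <- gel
  res$pixels <- out
  if (!is.null(gel$calibration)) {
    cal <- gel$calibration
    mid <- round(stats::median(cal$mw_markers$row))
    # marker lane is a column band; apply the lane-local shift
    lane_col <- clamp(round(mean(range(cal$pi_anchors$col))), 1, nc)
    cal$mw_markers$row <- cal$mw_markers$row - s[lane_col]
    res$calibration <- calibration_model(cal$mw_markers, cal$pi_anchors)
  }
  attr(res, "shift_field") <- s
  res
}
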