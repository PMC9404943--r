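# Intensity ceiling of the 16-bit scanner scale.
INT_MAX_16 <- 65535

#' Reflect-pad a matrix
#'
#' Pads `x` by `pr` rows top/bottom and `pc` columns left/right using
#' mirror reflection (the border pixel itself is not repeated), the border
#' rule used by the neighborhood filters in this package.
#'
#' @param x numeric matrix.
#' @param pr,pc padding extent in rows / columns.
#' @return padded matrix of size `(nrow + 2 pr) x (ncol + 2 pc)`.
#' @keywords internal
pad_reflect <- function(x, pr, pc) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(pr < nr, pc < nc)
  ri <- c(if (pr > 0) (pr + 1L):2L else integer(0), 1L:nr,
          if (pr > 0) (nr - 1L):(nr - pr) else integer(0))
  ci <- c(if (pc > 0) (pc + 1L):2L else integer(0), 1L:nc,
          if (pc > 0) (nc - 1L):(nc - pc) else integer(0))
  x[ri, ci, drop = FALSE]
}

#' Exact rectangular-window median filter
#'
#' Replaces each pixel by the exact median of its `wr x wc` neighborhood,
#' with mirror-reflected borders. `wr`/`wc` must be odd. A 1 x k window
#' gives the horizontally elongated ("asymmetric") median used to keep
#' iso-molecular-mass ridges while suppressing isolated impulses and spots.
#'
#' @param x numeric matrix.
#' @param wr,wc odd window height and width in pixels.
#' @return filtered matrix, same dimensions as `x`.
#' @keywords internal
median_filter_rect <- function(x, wr, wc) {
  stopifnot(wr %% 2 == 1, wc %% 2 == 1, wr >= 1, wc >= 1)
  if (wr == 1 && wc == 1) return(x)
  pr <- (wr - 1L) %/% 2L; pc <- (wc - 1L) %/% 2L
  xp <- pad_reflect(x, pr, pc)
  nr <- nrow(x); nc <- ncol(x)
  k <- wr * wc
  arr <- matrix(0, nr * nc, k)
  j <- 1L
  for (dr in 0:(wr - 1L)) for (dc in 0:(wc - 1L)) {
    arr[, j] <- as.vector(xp[(1L + dr):(nr + dr), (1L + dc):(nc + dc)])
    j <- j + 1L
  }
  # exact median over the window; k is small so a row-wise sort is fine
  med <- apply(arr, 1L, stats::median)
  matrix(med, nr, nc)
}

#' Linear filtering with replicated borders
#'
#' Thin wrapper over [EBImage::filter2()] (FFT-based correlation with a
#' centered kernel) used by the symmetry, LoG and smoothing stages.
#'
#' @param x numeric matrix.
#' @param k centered odd-sized kernel matrix.
#' @keywords internal
filter2_rep <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  if (kr > nr || kc > nc) {
    # small images (training patches): reflect-pad up to the kernel size
    pr <- min(ceiling(max(0, kr - nr) / 2) + 1L, nr - 1L)
    pc <- min(ceiling(max(0, kc - nc) / 2) + 1L, nc - 1L)
    xp <- pad_reflect(x, pr, pc)
    if (nrow(xp) < kr || ncol(xp) < kc)
      stop("kernel too large for image")
    f <- as.matrix(EBImage::filter2(xp, k, boundary = "replicate"))
    return(f[(pr + 1):(pr + nr), (pc + 1):(pc + nc), drop = FALSE])
  }
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

#' Gaussian kernel (optionally anisotropic)
#' @param sigma_r,sigma_c standard deviations along rows / columns (px).
#' @keywords internal
gaussian_kernel <- function(sigma_r, sigma_c = sigma_r) {
  hr <- max(1L, ceiling(3 * sigma_r)); hc <- max(1L, ceiling(3 * sigma_c))
  r <- (-hr):hr; c <- (-hc):hc
  kr <- exp(-r^2 / (2 * sigma_r^2)); kc <- exp(-c^2 / (2 * sigma_c^2))
  k <- outer(kr, kc)
  k / sum(k)
}

#' Laplacian-of-Gaussian kernel
#'
#' Returns the standard LoG kernel (second derivative of a Gaussian).
#' Convolved with a dark-spot-polarity gel image, the response is positive
#' at the core of an intensity pit and negative at a bright bump.
#'
#' @param sigma Gaussian scale in pixels.
#' @keywords internal
log_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  h <- max(2L, ceiling(3 * sigma))
  d <- (-h):h
  r2 <- outer(d^2, d^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- (r2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)    # zero-sum: constant images map to exactly 0
}

#' Image gradient by central differences
#' @return list with components `gr` (d/drow) and `gc` (d/dcol).
#' @keywords internal
image_gradient <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  gr <- (x[c(2:nr, nr), ] - x[c(1, 1:(nr - 1)), ]) / 2
  gc <- (x[, c(2:nc, nc)] - x[, c(1, 1:(nc - 1))]) / 2
  list(gr = gr, gc = gc)
}

#' Clamp values into a range
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# RNG state save/restore: generator functions seed the RNG for their own
# body and put the caller's stream back on exit, so all synthetic output
# is a pure function of (spec, seed) without perturbing user RNG streams.
save_rng <- function() get0(".Random.seed", globalenv(), inherits = FALSE)

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Validate a half-open ROI against image bounds
#'
#' ROIs are length-4 vectors `c(r0, r1, c0, c1)`, 1-based half-open:
#' rows `r0 .. r1 - 1`, columns `c0 .. c1 - 1`.
#' @keywords internal
check_roi <- function(roi, nr, nc, what = "roi") {
  if (length(roi) != 4L || any(!is.finite(roi)))
    stop(what, " must be c(r0, r1, c0, c1)")
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[3] < 1L || roi[2] > nr + 1L || roi[4] > nc + 1L)
    stop(what, " outside image bounds")
  if (roi[2] <= roi[1] || roi[4] <= roi[3])
    stop(what, " is empty")
  roi
}

roi_contains <- function(outer, inner) {
  inner[1] >= outer[1] && inner[2] <= outer[2] &&
    inner[3] >= outer[3] && inner[4] <= outer[4]
}
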