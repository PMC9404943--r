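#' Second-order rotational symmetry map
#'
#' Computes the complex rotational feature strength map `S` of a gel
#' image: the gradient orientation field in double-angle representation,
#' `z = (g_c + i g_r)^2` normalized to unit magnitude, is correlated with
#' the conjugate of the second-order rotational basis
#' `b(x, y) = ((x + i y)/|x + i y|)^2` weighted by a Gaussian annulus at
#' the given scale. Around the center of a rotationally symmetric blob
#' the gradient points radially, the double-angle field matches the basis
#' phase exactly, and the real part `S_R = Re(S)` peaks — for dark pits
#' and bright bumps alike, at any contrast. The watershed stage then
#' floods `-S_R`.
#'
#' @param gel a [gel_image()] or numeric matrix (preprocessed image; the
#'   response is polarity-blind so either polarity works).
#' @param scale annulus radius in px (>= 1); choose it near the typical
#'   spot radius. Several scales can be averaged by [detect_spots()].
#' @param smooth_sigma Gaussian pre-smoothing for gradient stability.
#' @return object of class `symmetry_map` with `S_R`, `S_I` (real and
#'   imaginary response), `scale`.
#' @export
symmetry_map <- function(gel, scale = 6, smooth_sigma = scale / 4) {
  px <- if (inherits(gel, "gel_image")) gel$pixels else as.matrix(gel)
  if (scale < 1) stop("scale must be >= 1 px")
  if (smooth_sigma > 0)
    px <- filter2_rep(px, gaussian_kernel(smooth_sigma))
  g <- image_gradient(px)
  zr <- g$gc^2 - g$gr^2          # Re[(gc + i gr)^2]
  zi <- 2 * g$gc * g$gr          # Im
  mag <- sqrt(zr^2 + zi^2)
  eps <- 1e-6 * max(mag, 1e-12)
  zr <- ifelse(mag > eps, zr / mag, 0)
  zi <- ifelse(mag > eps, zi / mag, 0)
  # kernel: conj(double-angle basis) on a Gaussian annulus of radius scale
  h <- ceiling(2 * scale) + 2L
  d <- (-h):h
  dc <- matrix(d, length(d), length(d), byrow = TRUE)
  dr <- matrix(d, length(d), length(d))
  r <- sqrt(dr^2 + dc^2)
  w <- exp(-(r - scale)^2 / (2 * (scale / 2)^2))
  w[r < 1e-9] <- 0
  phi <- atan2(dr, dc)
  kr <- cos(2 * phi) * w         # Re[conj(b)] = cos(2 phi)
  ki <- -sin(2 * phi) * w        # Im[conj(b)]
  sw <- sum(w)
  kr <- kr / sw; ki <- ki / sw
  # complex correlation; the kernel is symmetric under point reflection,
  # so FFT convolution and correlation coincide
  SR <- filter2_rep(zr, kr) - filter2_rep(zi, ki)
  SI <- filter2_rep(zr, ki) + filter2_rep(zi, kr)
  structure(list(S_R = SR, S_I = SI, scale = scale), class = "symmetry_map")
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat(sprintf("symmetry_map: %d x %d, scale %g px, S_R in [%.3f, %.3f]\n",
              nrow(x$S_R), ncol(x$S_R), x$scale, min(x$S_R), max(x$S_R)))
  invisible(x)
}

#' Phase symmetry map (log-Gabor bank)
#'
#' Phase-based symmetry measure over a bank of log-Gabor filters
#' (`nscale` scales x `norient` orientations): at symmetric points the
#' even (real) filter responses dominate the odd ones across scales, so
#' the symmetry energy is `sum_s(|even| - |odd|)` (for dark features, with
#' the sign of the even part flipped), noise-compensated by a floor `T`
#' estimated from the smallest-scale amplitude and normalized by the total
#' amplitude sum. Only the per-region maximum of this map is consumed as
#' a region feature.
#'
#' @param img numeric matrix (dark-spot polarity).
#' @param nscale,norient filter bank size.
#' @param min_wavelength wavelength of the smallest-scale filter (px).
#' @param mult wavelength multiplier between scales.
#' @param sigma_onf log-Gabor radial bandwidth parameter.
#' @param k noise floor, in multiples of the smallest-scale mean amplitude.
#' @param polarity `-1` for dark features (gel spots), `+1` bright, `0` both.
#' @return numeric matrix in `[0, 1]`.
#' @export
phase_symmetry <- function(img, nscale = 3L, norient = 4L,
                           min_wavelength = 3, mult = 2.1,
                           sigma_onf = 0.55, k = 2, polarity = -1L) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  IM <- stats::fft(img)
  # frequency grids (cycles/px), DC at [1,1]
  fr <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr) / nr
  fc <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc) / nc
  u <- matrix(fc, nr, nc, byrow = TRUE)
  v <- matrix(fr, nr, nc)
  radius <- sqrt(u^2 + v^2); radius[1, 1] <- 1
  theta <- atan2(-v, u)
  st <- sin(theta); ct <- cos(theta)
  sigma_theta <- pi / norient / 1.2
  total_energy <- matrix(0, nr, nc)
  total_amp <- matrix(0, nr, nc)
  Tfloor <- 0
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- st * cos(angl) - ct * sin(angl)
    dc_ <- ct * cos(angl) + st * sin(angl)
    dtheta <- abs(atan2(ds, dc_))
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))
    wavelength <- min_wavelength
    for (s in seq_len(nscale)) {
      fo <- 1 / wavelength
      log_gabor <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2))
      log_gabor[1, 1] <- 0
      flt <- log_gabor * spread
      eo <- stats::fft(IM * flt, inverse = TRUE) / (nr * nc)
      re <- Re(eo); im_ <- Im(eo)
      an <- sqrt(re^2 + im_^2)
      total_amp <- total_amp + an
      e <- switch(as.character(polarity),
                  "-1" = -re - abs(im_),
                  "1"  =  re - abs(im_),
                  abs(re) - abs(im_))
      total_energy <- total_energy + e
      if (s == 1) Tfloor <- Tfloor + k * mean(an)
      wavelength <- wavelength * mult
    }
  }
  sym <- pmax(total_energy - Tfloor, 0) / (total_amp + 1e-4)
  sym
}
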