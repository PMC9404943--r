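#' Specification of one synthetic protein spot
#'
#' Spots are anisotropic Gaussian pits subtracted from a bright background:
#' the profile at offset `(dr, dc)` from the center is
#' `A * exp(-(dr^2 / (2 sigma_r^2) + dc^2 / (2 sigma_c^2)))` (optionally
#' with a correlation term `rho`). The analytic pit volume is
#' `2 * pi * A * sigma_r * sigma_c * sqrt(1 - rho^2)`, which is what makes
#' Gaussian pits the right test substrate: every measured volume has a
#' closed-form truth.
#'
#' @param row,col sub-pixel center.
#' @param amplitude pit depth `A` in intensity units (> 0; must stay below
#'   the background level so pixels remain non-negative).
#' @param sigma_r,sigma_c Gaussian radii in px (> 0).
#' @param rho optional row/column correlation (skew), `|rho| < 1`.
#' @return an object of class `spot_spec`.
#' @export
spot_spec <- function(row, col, amplitude, sigma_r = 4, sigma_c = sigma_r,
                      rho = 0) {
  stopifnot(amplitude > 0, sigma_r > 0, sigma_c > 0, abs(rho) < 1)
  structure(list(row = row, col = col, amplitude = amplitude,
                 sigma_r = sigma_r, sigma_c = sigma_c, rho = rho),
            class = "spot_spec")
}

true_volume <- function(s) {
  2 * pi * s$amplitude * s$sigma_r * s$sigma_c * sqrt(1 - s$rho^2)
}

#' Specification of a synthetic 2DE gel
#'
#' Defines the rendering conditions the generator emulates: a Coomassie
#' scan with a bright, smoothly varying background, dark Gaussian spot
#' pits, a smooth column-dependent vertical distortion of
#' iso-molecular-mass rows (the migration artefact gel warping corrects),
#' additive Gaussian scanner noise and salt/pepper impulse noise from dust
#' and stain particles.
#'
#' The background at pixel `(r, c)` is
#' `bg_base + bg_coefs[1] u + bg_coefs[2] v + bg_coefs[3] u^2 + bg_coefs[4] v^2`
#' with `u, v` the column/row coordinates scaled to `[-1, 1]`. The vertical
#' shift at column `c` is `distortion[1] + distortion[2] u +
#' distortion[3] u^2` pixels (positive = downwards).
#'
#' @param shape `c(rows, cols)` of the raster.
#' @param spots list of [spot_spec()].
#' @param bg_base background plateau intensity (16-bit scale).
#' @param bg_coefs length-4 polynomial background coefficients.
#' @param distortion length-3 polynomial vertical-shift coefficients (px).
#' @param max_shift declared bound on `|shift|`; rendering errors beyond it.
#' @param gaussian_noise_sd additive noise standard deviation.
#' @param impulse_rate fraction of pixels replaced by 0 / 65535 impulses;
#'   must stay below 0.2 (beyond that a 3x3 median no longer guarantees
#'   impulse removal, which the preprocessing tests rely on).
#' @param seed RNG seed; all generator output is a pure function of
#'   (spec, seed).
#' @return an object of class `gel_spec`.
#' @export
gel_spec <- function(shape = c(192L, 256L), spots = list(),
                     bg_base = 52000, bg_coefs = c(-2500, -1500, -1200, 0),
                     distortion = c(0, 0, 0), max_shift = 10,
                     gaussian_noise_sd = 0, impulse_rate = 0,
                     seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 16L))
  stopifnot(impulse_rate >= 0, impulse_rate < 0.2)
  stopifnot(length(distortion) == 3L, length(bg_coefs) == 4L)
  stopifnot(gaussian_noise_sd >= 0)
  for (s in spots) stopifnot(inherits(s, "spot_spec"))
  structure(list(shape = as.integer(shape), spots = spots,
                 bg_base = bg_base, bg_coefs = bg_coefs,
                 distortion = distortion, max_shift = max_shift,
                 gaussian_noise_sd = gaussian_noise_sd,
                 impulse_rate = impulse_rate, seed = as.integer(seed)),
            class = "gel_spec")
}

spec_background <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  v <- 2 * (seq_len(nr) - 1) / (nr - 1) - 1   # row coordinate in [-1, 1]
  u <- 2 * (seq_len(nc) - 1) / (nc - 1) - 1   # col coordinate in [-1, 1]
  b <- spec$bg_base +
    outer(rep(1, nr), spec$bg_coefs[1] * u + spec$bg_coefs[3] * u^2) +
    outer(spec$bg_coefs[2] * v + spec$bg_coefs[4] * v^2, rep(1, nc))
  b
}

spec_shift <- function(spec, cols) {
  nc <- spec$shape[2]
  u <- 2 * (cols - 1) / (nc - 1) - 1
  spec$distortion[1] + spec$distortion[2] * u + spec$distortion[3] * u^2
}

# sum of spot pits evaluated at undistorted coordinates (rr, cc can be
# matrices of the same shape)
spot_field <- function(spots, rr, cc) {
  f <- array(0, dim(rr))
  for (s in spots) {
    dr <- (rr - s$row) / s$sigma_r
    dc <- (cc - s$col) / s$sigma_c
    q <- (dr^2 - 2 * s$rho * dr * dc + dc^2) / (1 - s$rho^2)
    f <- f + s$amplitude * exp(-q / 2)
  }
  f
}

#' Render a synthetic gel with ground truth
#'
#' Renders `background - sum(spot pits)`, then applies the spec's smooth
#' column-dependent vertical distortion, then adds Gaussian and impulse
#' noise, clipping to the 16-bit range. Deterministic given
#' `(spec, spec$seed)`.
#'
#' The returned truth records the *post-distortion* spot centers
#' (`row + shift(col)`), the analytic pit volumes, the applied shift field
#' and the noise seed.
#'
#' @param spec a [gel_spec()].
#' @param label gel label.
#' @param allow_edge allow spot centers closer than `3 sigma` to the image
#'   border (used when constructing partial-spot training patches).
#' @return list with components `gel` (a [gel_image()]) and `truth`.
#' @export
render_gel <- function(spec, label = "synthetic", allow_edge = FALSE) {
  stopifnot(inherits(spec, "gel_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  shift <- spec_shift(spec, seq_len(nc))
  if (any(abs(shift) > spec$max_shift))
    stop("distortion shift exceeds declared max_shift")
  bg <- spec_background(spec)
  for (s in spec$spots) {
    if (s$amplitude >= bg[clamp(round(s$row), 1, nr), clamp(round(s$col), 1, nc)])
      stop("spot amplitude exceeds background at its center")
    if (!allow_edge &&
        (s$row - 3 * s$sigma_r < 1 || s$row + 3 * s$sigma_r > nr ||
         s$col - 3 * s$sigma_c < 1 || s$col + 3 * s$sigma_c > nc))
      stop("spot center within 3 sigma of the border (set allow_edge)")
  }
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # feature at undistorted row r0 appears at r0 + shift(c): evaluate the
  # spot field at (r - shift(c), c)
  rshift <- sweep(rr, 2L, shift, "-")
  px <- bg - spot_field(spec$spots, rshift, cc)
  orng <- save_rng(); on.exit(restore_rng(orng), add = TRUE)
  set.seed(spec$seed)
  if (spec$gaussian_noise_sd > 0)
    px <- px + matrix(stats::rnorm(nr * nc, 0, spec$gaussian_noise_sd), nr, nc)
  if (spec$impulse_rate > 0) {
    n_imp <- round(spec$impulse_rate * nr * nc)
    idx <- sample.int(nr * nc, n_imp)
    px[idx] <- ifelse(stats::runif(n_imp) < 0.5, 0, INT_MAX_16)
  }
  # quantize to the scanner's integer scale; keeps TIFF round-trips exact
  px <- round(clamp(px, 0, INT_MAX_16))
  centers <- if (length(spec$spots) > 0)
    data.frame(
      spot = seq_along(spec$spots),
      row = vapply(spec$spots, function(s)
        s$row + spec_shift(spec, s$col), 0),
      col = vapply(spec$spots, function(s) s$col, 0),
      amplitude = vapply(spec$spots, function(s) s$amplitude, 0),
      volume = vapply(spec$spots, true_volume, 0))
  else data.frame(spot = integer(0), row = numeric(0), col = numeric(0),
                  amplitude = numeric(0), volume = numeric(0))
  list(gel = gel_image(px, label = label),
       truth = list(centers = centers, shift = shift, seed = spec$seed))
}

#' Render a matched pair of gels with known fold changes
#'
#' The second gel shares the first gel's spot layout with amplitudes
#' scaled per spot by `fold_changes` (second-gel / first-gel amplitude
#' ratio), its own distortion field and independent noise. The truth
#' contains the exact one-to-one pairing, the raw amplitude ratios, and
#' the signed fold-change of the *normalized* quantities (per-gel volumes
#' divided by the gel total), which is what the quantification pipeline
#' estimates.
#'
#' @param spec a [gel_spec()] describing the first gel.
#' @param fold_changes numeric vector, one positive ratio per spot.
#' @param warp length-3 distortion polynomial for the second gel.
#' @param seed2 noise seed for the second gel.
#' @return list with `gelA`, `gelB` ([gel_image()]s) and `truth`.
#' @export
render_pair <- function(spec, fold_changes = NULL, warp = c(0, 0, 0),
                        seed2 = spec$seed + 1L) {
  stopifnot(inherits(spec, "gel_spec"))
  n <- length(spec$spots)
  if (is.null(fold_changes)) fold_changes <- rep(1, n)
  stopifnot(length(fold_changes) == n, all(fold_changes > 0))
  a <- render_gel(spec, label = "G1")
  spots2 <- lapply(seq_len(n), function(i) {
    s <- spec$spots[[i]]
    spot_spec(s$row, s$col, s$amplitude * fold_changes[i],
              s$sigma_r, s$sigma_c, s$rho)
  })
  spec2 <- gel_spec(shape = spec$shape, spots = spots2,
                    bg_base = spec$bg_base, bg_coefs = spec$bg_coefs,
                    distortion = warp, max_shift = spec$max_shift,
                    gaussian_noise_sd = spec$gaussian_noise_sd,
                    impulse_rate = spec$impulse_rate, seed = seed2)
  b <- render_gel(spec2, label = "G2")
  vA <- a$truth$centers$volume
  vB <- b$truth$centers$volume
  qA <- vA / sum(vA); qB <- vB / sum(vB)
  truth <- list(
    centersA = a$truth$centers, centersB = b$truth$centers,
    pairing = data.frame(spotA = seq_len(n), spotB = seq_len(n)),
    amplitude_ratio = fold_changes,
    true_fc = mapply(fold_change, qA, qB),
    shiftA = a$truth$shift, shiftB = b$truth$shift)
  list(gelA = a$gel, gelB = b$gel, truth = truth)
}

#' Labeled region patches for classifier training
#'
#' Generates balanced, ground-truth-labeled watershed regions emulating
#' the three classes the segmentation classifier must separate:
#' `C1` — one whole spot in the region; `C2` — only part of a spot in the
#' region; `C3` — no spot in the region. Each example is a rendered patch
#' plus a region mask shaped like the masks the detector produces: the
#' patch's symmetry-map watershed cell around the spot (C1), that cell cut
#' through the spot center so only part of the spot remains (C2,
#' emulating over-segmentation), or a cell of a background/noise-only
#' patch (C3). Deterministic per seed.
#'
#' @param n_per_class patches per class (>= 1).
#' @param seed RNG seed.
#' @param patch patch side length in px.
#' @param scales symmetry-map scales used to build the watershed cells
#'   (keep equal to the detector's scales).
#' @return list of elements `list(pixels, mask, class)`; `pixels` is a
#'   dark-spot-polarity patch on the 16-bit scale, `mask` a logical region
#'   mask, `class` one of `"C1" "C2" "C3"`.
#' @export
labeled_regions <- function(n_per_class, seed = 1L, patch = 32L,
                            scales = c(4, 8)) {
  stopifnot(n_per_class >= 1)
  orng <- save_rng(); on.exit(restore_rng(orng), add = TRUE)
  set.seed(seed)
  out <- vector("list", 3L * n_per_class)
  k <- 0L
  mk_patch <- function(center_row, center_col, amp, sg) {
    sp <- if (is.null(center_row)) list() else
      list(spot_spec(center_row, center_col, amp, sg,
                     sg * stats::runif(1, 0.8, 1.25)))
    spec <- gel_spec(shape = c(patch, patch), spots = sp,
                     bg_base = stats::runif(1, 45000, 56000),
                     bg_coefs = stats::runif(4, -800, 800),
                     gaussian_noise_sd = stats::runif(1, 150, 600),
                     impulse_rate = stats::runif(1, 0, 0.01),
                     seed = sample.int(2^30, 1))
    # the detector always sees median-smoothed input; train on the same
    median_filter_rect(render_gel(spec, allow_edge = TRUE)$gel$pixels,
                       3L, 3L)
  }
  ws_cell <- function(px, r, c) {
    sms <- lapply(scales, function(s) symmetry_map(px, scale = s))
    SR <- Reduce("+", lapply(sms, function(s) s$S_R)) / length(sms)
    SR <- filter2_rep(SR, gaussian_kernel(mean(scales) / 2))
    labels <- watershed_transform(SR)
    labels == labels[clamp(round(r), 1, nrow(px)),
                     clamp(round(c), 1, ncol(px))]
  }
  halfplane <- function(px, r, c, angle) {
    rr <- matrix(seq_len(nrow(px)), nrow(px), ncol(px))
    cc <- matrix(seq_len(ncol(px)), nrow(px), ncol(px), byrow = TRUE)
    (rr - r) * cos(angle) + (cc - c) * sin(angle) >= 0
  }
  for (i in seq_len(n_per_class)) {
    ctr <- patch / 2
    r0 <- ctr + stats::runif(1, -2, 2); c0 <- ctr + stats::runif(1, -2, 2)
    amp <- stats::runif(1, 4000, 28000); sg <- stats::runif(1, 2.5, 5)
    # C1: the watershed cell containing one whole spot
    px <- mk_patch(r0, c0, amp, sg)
    k <- k + 1L
    out[[k]] <- list(pixels = px, mask = ws_cell(px, r0, c0), class = "C1")
    # C2: the same kind of cell cut through the spot center, so the
    # region keeps only part of the spot
    px <- mk_patch(r0, c0, stats::runif(1, 4000, 28000),
                   stats::runif(1, 2.5, 5))
    cell <- ws_cell(px, r0, c0)
    cut <- cell & halfplane(px, r0 + stats::runif(1, -1, 1),
                            c0 + stats::runif(1, -1, 1),
                            stats::runif(1, 0, 2 * pi))
    if (!any(cut)) cut <- cell
    k <- k + 1L
    out[[k]] <- list(pixels = px, mask = cut, class = "C2")
    # C3: a watershed cell of a background/noise-only patch
    px <- mk_patch(NULL, NULL, 0, 1)
    cell <- ws_cell(px, stats::runif(1, patch * 0.25, patch * 0.75),
                    stats::runif(1, patch * 0.25, patch * 0.75))
    k <- k + 1L
    out[[k]] <- list(pixels = px, mask = cell, class = "C3")
  }
  out
}
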