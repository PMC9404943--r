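# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; nothing binary ships with the package.

.cache <- new.env(parent = emptyenv())

# one classifier trained at the study condition (500 patches/class,
# seed 1), shared across test files to keep the suite fast
test_classifier <- function(n_per_class = 500L, seed = 1L) {
  key <- sprintf("cl_%d_%d", n_per_class, seed)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- train_region_classifier(n_per_class, seed = seed)
  .cache[[key]]
}

# 20 well-separated spots on a jittered grid over a 192 x 256 raster
grid_spots <- function(seed = 7, amp_lo = 8000, amp_hi = 24000,
                       amp_const = NULL) {
  set.seed(seed)
  g <- expand.grid(r = seq(30, 160, by = 32), c = seq(30, 230, by = 40))[1:20, ]
  lapply(1:20, function(i) {
    amp <- if (is.null(amp_const)) runif(1, amp_lo, amp_hi) else amp_const
    spot_spec(g$r[i] + runif(1, -3, 3), g$c[i] + runif(1, -3, 3),
              amp, runif(1, 3, 5))
  })
}

# row-structured gel (spots on iso-molecular-mass rows) for the
# distortion-scoring and straightening stages
row_gel_spec <- function(distortion = c(0, 0, 0), seed = 1,
                         noise = 300, imp = 0.005) {
  set.seed(seed)
  spots <- list()
  for (r in seq(35, 165, by = 26)) for (c in seq(24, 232, by = 16)) {
    spots[[length(spots) + 1]] <-
      spot_spec(r, c + runif(1, -2, 2), runif(1, 5000, 20000),
                runif(1, 2.5, 4.5), runif(1, 2.5, 4.5))
  }
  gel_spec(shape = c(192L, 256L), spots = spots, distortion = distortion,
           gaussian_noise_sd = noise, impulse_rate = imp, seed = seed)
}

# index of the nearest truth spot for each detected spot
nearest_truth <- function(det, truth) {
  apply(outer(det$row, truth$row, "-")^2 +
          outer(det$col, truth$col, "-")^2, 1, which.min)
}

# full detection -> pairing -> quantification -> comparison chain on a
# rendered pair; returns recovered vs true fold changes
e2e_compare <- function(pr, cl, gate = 6, tophat = 20) {
  gA <- median_smooth(pr$gelA, 3); gB <- median_smooth(pr$gelB, 3)
  dA <- detect_spots(gA, cl, polarity = "dark")
  dB <- detect_spots(gB, cl, polarity = "dark")
  model <- fit_tps(initial_landmarks(gA, gB))
  mt <- pair_spots(dA$spots, dB$spots, model, gate = gate)
  tA <- nearest_truth(dA$spots, pr$truth$centersA)
  tB <- nearest_truth(dB$spots, pr$truth$centersB)
  ia <- match(mt$matches$spot_id_A, dA$spots$spot_id)
  ib <- match(mt$matches$spot_id_B, dB$spots$spot_id)
  qA <- data.frame(spot_id = dA$spots$spot_id, quantity =
    normalize_quantities(region_volumes(subtract_background(gA, tophat),
                                        dA$regions, ids = dA$spots$id)$volume))
  qB <- data.frame(spot_id = dB$spots$spot_id, quantity =
    normalize_quantities(region_volumes(subtract_background(gB, tophat),
                                        dB$regions, ids = dB$spots$id)$volume))
  cmp <- compare_gels(qA, qB, mt)
  key <- paste(mt$matches$spot_id_A, mt$matches$spot_id_B)
  ckey <- paste(cmp$spot_id_A, cmp$spot_id_B)
  list(n_pairs = nrow(mt$matches),
       pair_correct = tA[ia] == tB[ib],
       rec_fc = cmp$fc[match(key, ckey)],
       true_fc = pr$truth$true_fc[tA[ia]],
       amp_ratio = pr$truth$amplitude_ratio[tA[ia]],
       changed = cmp$changed[match(key, ckey)],
       detA = dA, detB = dB, matches = mt, cmp = cmp)
}

# Independent watershed oracle: per-pixel greedy hill climb with the same
# deterministic plateau tie-break (infinitesimal ramp in linear index)
# as the implementation, written as a plain loop rather than pointer
# jumping.
ws_flood_oracle <- function(x) {
  nr <- nrow(x); nc <- ncol(x); n <- nr * nc
  ux <- sort(unique(as.vector(x)))
  gap <- if (length(ux) > 1) min(diff(ux)) else 1
  xe <- x + (gap / (2 * n)) * matrix(seq_len(n), nr, nc)
  climb <- function(r, c) {
    repeat {
      best <- c(r, c); bv <- xe[r, c]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (xe[rr, cc] > bv) { bv <- xe[rr, cc]; best <- c(rr, cc) }
      }
      if (best[1] == r && best[2] == c) return((c - 1L) * nr + r)
      r <- best[1]; c <- best[2]
    }
  }
  roots <- matrix(0L, nr, nc)
  for (c in seq_len(nc)) for (r in seq_len(nr)) roots[r, c] <- climb(r, c)
  matrix(match(roots, sort(unique(as.vector(roots)))), nr, nc)
}

# discrete second-difference curvature oracle: sign of the Laplacian of
# the Gaussian-smoothed image at a point, from 1-D second differences
# along the row and column slices
second_diff_sign <- function(px, sigma, r, c) {
  sm <- gelmap2d:::filter2_rep(px, gelmap2d:::gaussian_kernel(sigma))
  d2r <- sm[r - 1, c] - 2 * sm[r, c] + sm[r + 1, c]
  d2c <- sm[r, c - 1] - 2 * sm[r, c] + sm[r, c + 1]
  sign(d2r + d2c)
}
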