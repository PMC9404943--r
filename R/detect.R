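#' Curvature filter on region cores (Laplacian of Gaussian)
#'
#' The rotational-symmetry response is identical for dark and bright
#' blobs, so candidate regions are filtered by the sign of the smoothed
#' second derivative at the core: dark protein spots are pits in the
#' intensity surface, hence the Laplacian-of-Gaussian response at a spot
#' core is positive; regions whose core response is negative (bright
#' bumps, background) are removed.
#'
#' @param gel a [gel_image()] or matrix in dark-spot polarity (bright
#'   background, dark spots).
#' @param regions a `region_set` from [watershed_regions()].
#' @param sigma LoG scale in px.
#' @return the `region_set` with the surviving regions' table gaining an
#'   `i_log` column; removed regions stay in the partition (their pixels
#'   are still labeled) but are dropped from the candidate table.
#' @export
log_filter <- function(gel, regions, sigma = 4) {
  if (sigma <= 0) stop("sigma must be positive")
  px <- if (inherits(gel, "gel_image")) gel$pixels else as.matrix(gel)
  stopifnot(inherits(regions, "region_set"))
  lmap <- filter2_rep(px, log_kernel(sigma))
  tab <- regions$table
  tab$i_log <- lmap[cbind(tab$row, tab$col)]
  regions$table <- tab[tab$i_log > 0, , drop = FALSE]
  regions$log_map <- lmap
  regions
}

#' Five-feature descriptor of candidate regions
#'
#' For every region in the candidate table, extracts the feature vector
#' used by the region classifier, in this fixed order:
#' \enumerate{
#'   \item mode of the region's gel intensities (256-bin histogram mode);
#'   \item weighted max-min difference of gel intensity over the region's
#'     contour pixels (weighted by the inverse equivalent diameter, making
#'     the contrast scale-comparable across region sizes);
#'   \item the same weighted contour range on the symmetry map `S_R`;
#'   \item maximum of the phase-symmetry detector over the region;
#'   \item maximum Laplacian-of-Gaussian response over the region.
#' }
#' Contour pixels of a region are its pixels adjacent to another region or
#' to the image border.
#'
#' @param gel a [gel_image()] or matrix, dark-spot polarity.
#' @param regions a `region_set` (its `S_R` map is feature 3's surface).
#' @param log_sigma LoG scale for feature 5.
#' @param phase_map optional precomputed [phase_symmetry()] map.
#' @return numeric matrix, one row per candidate-table region, 5 columns.
#' @export
region_features <- function(gel, regions, log_sigma = 4, phase_map = NULL) {
  px <- if (inherits(gel, "gel_image")) gel$pixels else as.matrix(gel)
  stopifnot(inherits(regions, "region_set"))
  labels <- regions$labels
  tab <- regions$table
  if (nrow(tab) == 0) return(matrix(0, 0, 5))
  SR <- regions$S_R
  lmap <- regions$log_map
  if (is.null(lmap)) lmap <- filter2_rep(px, log_kernel(log_sigma))
  if (is.null(phase_map)) phase_map <- phase_symmetry(px)
  bmask <- boundary_mask(labels)
  lv <- as.vector(labels)
  # per-label aggregates over all labels present, then subset to the table
  rng <- function(vals, mask) {
    l <- lv[mask]; v <- vals[mask]
    mx <- tapply(v, l, max); mn <- tapply(v, l, min)
    cbind(mx, mn)
  }
  all_ids <- sort(unique(lv))
  area <- tabulate(lv, nbins = max(lv))[all_ids]
  eqd <- 2 * sqrt(area / pi)
  names(eqd) <- all_ids
  ci <- rng(as.vector(px), as.vector(bmask))
  cs <- rng(as.vector(SR), as.vector(bmask))
  # histogram mode of gel intensity per region, 256 bins over image range
  lo <- min(px); hi <- max(px)
  bins <- if (hi > lo) pmin(floor((as.vector(px) - lo) / (hi - lo) * 256), 255)
          else rep(0L, length(px))
  mode_bin <- tapply(bins, lv, function(b) {
    tb <- tabulate(b + 1L, nbins = 256L)
    which.max(tb) - 1L
  })
  mode_val <- lo + (as.numeric(mode_bin) + 0.5) / 256 * (hi - lo)
  names(mode_val) <- names(mode_bin)
  pmax_ <- tapply(as.vector(phase_map), lv, max)
  lmax_ <- tapply(as.vector(lmap), lv, max)
  key <- as.character(tab$id)
  f <- cbind(
    mode_val[key],
    (ci[key, 1] - ci[key, 2]) / eqd[key],
    (cs[key, 1] - cs[key, 2]) / eqd[key],
    pmax_[key],
    lmax_[key])
  dimnames(f) <- list(NULL,
    c("mode", "contour_range", "sym_contour_range", "phase_sym_max",
      "log_max"))
  if (any(!is.finite(f))) stop("non-finite region feature")
  f
}

#' Train the region classifier
#'
#' Generates balanced labeled patches with [labeled_regions()], extracts
#' the five region features from each, standardizes them, and fits the
#' 5-10-3-2 tangent-sigmoid feedforward network that sorts watershed
#' regions into C1 ("one spot in the region"), C2 ("only part of a spot")
#' and C3 ("no spot"). Deterministic per seed; the fitted weights can be
#' serialized with [save_classifier()].
#'
#' @param n_per_class training patches per class.
#' @param seed RNG seed for both patch generation and weight init.
#' @param log_sigma LoG scale used for patch features.
#' @return object of class `region_classifier`: network weights, feature
#'   standardization statistics, and training metadata.
#' @export
train_region_classifier <- function(n_per_class = 500L, seed = 1L,
                                    log_sigma = 4) {
  patches <- labeled_regions(n_per_class, seed = seed)
  X <- patch_features(patches, log_sigma = log_sigma)
  y <- vapply(patches, function(p) p$class, "")
  mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  Y <- CLASS_CODES[y, , drop = FALSE]
  par <- mlp_train(Xs, Y, seed = seed)
  structure(list(par = par, mu = mu, sd = sd_, classes = rownames(CLASS_CODES),
                 n_per_class = n_per_class, seed = seed,
                 log_sigma = log_sigma, version = "1"),
            class = "region_classifier")
}

# features of labeled patches: each patch is treated as a two-region
# partition (mask vs complement) and the mask region's features are used;
# the symmetry surface averages the same scales the detector uses
patch_features <- function(patches, log_sigma = 4, scales = c(4, 8)) {
  t(vapply(patches, function(p) {
    labels <- matrix(2L, nrow(p$pixels), ncol(p$pixels))
    labels[p$mask] <- 1L
    sms <- lapply(scales, function(s) symmetry_map(p$pixels, scale = s))
    SR <- Reduce("+", lapply(sms, function(s) s$S_R)) / length(sms)
    rs <- region_set(labels, SR)
    rs$table <- rs$table[rs$table$id == 1L, , drop = FALSE]
    region_features(p$pixels, rs, log_sigma = log_sigma)[1, ]
  }, numeric(5)))
}

#' Classify candidate regions
#'
#' Runs the trained network on standardized feature vectors and decodes
#' the 2-unit output code to C1/C2/C3 by nearest class code; exact ties
#' resolve to C2 so ambiguous regions surface for review. Confidence is
#' the relative margin between the nearest and second-nearest code.
#'
#' @param features matrix from [region_features()] (5 columns).
#' @param model a `region_classifier`.
#' @return data frame with `class` and `confidence`.
#' @export
classify_regions <- function(features, model) {
  stopifnot(inherits(model, "region_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != 5) stop("feature dimension must be 5")
  if (nrow(features) == 0)
    return(data.frame(class = character(0), confidence = numeric(0)))
  Xs <- sweep(sweep(features, 2L, model$mu), 2L, model$sd, "/")
  out <- mlp_predict_codes(model$par, Xs)
  d <- vapply(seq_len(nrow(CLASS_CODES)), function(k)
    rowSums(sweep(out, 2L, CLASS_CODES[k, ])^2), numeric(nrow(out)))
  d <- matrix(d, nrow = nrow(out))
  cls <- apply(d, 1L, function(dd) {
    j <- which(dd == min(dd))
    if (length(j) > 1) 2L else j   # ties toward C2
  })
  ds <- t(apply(d, 1L, sort))
  conf <- (ds[, 2] - ds[, 1]) / (ds[, 2] + ds[, 1] + 1e-12)
  data.frame(class = model$classes[cls], confidence = conf,
             stringsAsFactors = FALSE)
}

#' Save / load classifier weights
#'
#' Serializes a `region_classifier` to a versioned JSON file (plain text),
#' or reads one back.
#' @param model a `region_classifier`.
#' @param path JSON file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "region_classifier"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$par <- as.numeric(m$par); m$mu <- as.numeric(m$mu)
  m$sd <- as.numeric(m$sd)
  structure(m, class = "region_classifier")
}

#' Detect and segment protein spots
#'
#' The full detection chain: symmetry maps at the requested scales are
#' averaged into one rotational-feature-strength surface, the watershed
#' of its inverted real part partitions the image into candidate regions
#' (one per symmetry maximum), cores with negative Laplacian-of-Gaussian
#' response are removed, the five region features are extracted, the
#' network assigns C1/C2/C3, and C1 regions become accepted spots with
#' sub-pixel centers (quadratic refinement of the symmetry peak) and
#' calibrated coordinates when the gel carries a calibration.
#'
#' The input should be preprocessed ([median_smooth()], and for stained
#' scans with background drift [subtract_background()]); `detect_spots`
#' accepts either polarity and standardizes internally using the stated
#' `polarity`.
#'
#' @param gel a [gel_image()].
#' @param model a `region_classifier`.
#' @param scales symmetry-map scales in px (averaged).
#' @param log_sigma LoG scale for the curvature filter and feature 5.
#' @param polarity `"dark"` if spots are dark on bright background (raw
#'   scans), `"signal"` if spots are positive peaks (output of
#'   [subtract_background()]).
#' @param ws_smooth Gaussian sigma for regularizing the flooding surface
#'   before the watershed (0 = none). Smoothing suppresses the spurious
#'   shallow maxima that noise and background gradients leave in the
#'   symmetry surface, so each spot's basin extends to the true ridge
#'   between spots; region maxima are still read from the unsmoothed map.
#' @return list with `regions` (a `region_set` whose table carries class,
#'   confidence and features) and `spots` (data frame of accepted C1
#'   spots: `spot_id, row, col, smax, i_log, area, confidence`, plus
#'   `mw_kda, pi` when calibrated).
#' @export
detect_spots <- function(gel, model, scales = c(4, 8), log_sigma = 4,
                         polarity = c("dark", "signal"),
                         ws_smooth = mean(scales) / 2) {
  stopifnot(inherits(gel, "gel_image"), inherits(model, "region_classifier"))
  polarity <- match.arg(polarity)
  px <- gel$pixels
  dark <- if (polarity == "dark") px else max(px) - px
  sms <- lapply(scales, function(s) symmetry_map(dark, scale = s))
  SR <- Reduce("+", lapply(sms, function(s) s$S_R)) / length(sms)
  # spatial regularization of the flooding surface: suppresses spurious
  # background maxima that would otherwise truncate faint spots' basins
  SRw <- if (ws_smooth > 0)
    filter2_rep(SR, gaussian_kernel(ws_smooth)) else SR
  regions <- region_set(watershed_transform(SRw), SR)
  regions <- log_filter(dark, regions, sigma = log_sigma)
  f <- region_features(dark, regions, log_sigma = log_sigma)
  cl <- classify_regions(f, model)
  regions$table <- cbind(regions$table, cl)
  regions$features <- f
  spots <- regions$table[regions$table$class == "C1", , drop = FALSE]
  if (nrow(spots) > 0) {
    ref <- t(vapply(seq_len(nrow(spots)), function(i)
      refine_peak(SR, spots$row[i], spots$col[i]), numeric(2)))
    spots$row <- ref[, 1]; spots$col <- ref[, 2]
    spots$spot_id <- seq_len(nrow(spots))
    if (!is.null(gel$calibration)) {
      cc <- spot_coordinates(gel$calibration, spots$row, spots$col)
      spots$mw_kda <- cc$mw_kda; spots$pi <- cc$pi
    }
  } else spots$spot_id <- integer(0)
  rownames(spots) <- NULL
  list(regions = regions, spots = spots)
}

# sub-pixel peak refinement: separable quadratic fit on the 3x3
# neighborhood, offsets clamped to half a pixel
refine_peak <- function(S, r, c) {
  nr <- nrow(S); nc <- ncol(S)
  if (r <= 1 || r >= nr || c <= 1 || c >= nc) return(c(r, c))
  dr <- 0.5 * (S[r - 1, c] - S[r + 1, c]) /
    (S[r - 1, c] - 2 * S[r, c] + S[r + 1, c])
  dc <- 0.5 * (S[r, c - 1] - S[r, c + 1]) /
    (S[r, c - 1] - 2 * S[r, c] + S[r, c + 1])
  if (!is.finite(dr)) dr <- 0
  if (!is.finite(dc)) dc <- 0
  c(r + clamp(dr, -0.5, 0.5), c + clamp(dc, -0.5, 0.5))
}

#' Edit the segmentation
#'
#' Programmatic counterpart of interactive segment repair. Every edit
#' preserves the partition invariant (region masks stay disjoint and
#' jointly cover the image) and is appended to the region set's audit log.
#'
#' Actions:
#' \describe{
#'   \item{merge}{`args = list(ids = c(id1, id2, ...))`; regions must be
#'     pairwise-connected through adjacency; masks are unioned under the
#'     first id.}
#'   \item{split}{`args = list(id, line = c(r0, c0, r1, c1))`; pixels on
#'     the two sides of the dividing line become two regions; the line
#'     must actually cross the region.}
#'   \item{add}{`args = list(polygon = data.frame(row, col))`; pixels
#'     inside the polygon are carved out of their current regions into a
#'     new region.}
#'   \item{remove}{`args = list(id)`; the region's pixels are returned to
#'     the surrounding pool (reassigned to the neighbor region sharing the
#'     longest boundary).}
#' }
#'
#' @param regions a `region_set`.
#' @param action one of `"merge" "split" "add" "remove"`.
#' @param args action arguments, see above.
#' @return edited `region_set`.
#' @export
edit_segments <- function(regions, action = c("merge", "split", "add",
                                              "remove"), args = list()) {
  stopifnot(inherits(regions, "region_set"))
  action <- match.arg(action)
  labels <- regions$labels
  present <- sort(unique(as.vector(labels)))
  need_ids <- switch(action, merge = args$ids, split = args$id,
                     remove = args$id, add = NULL)
  if (!all(need_ids %in% present))
    stop("unknown region id(s): ",
         paste(setdiff(need_ids, present), collapse = ", "))
  if (action == "merge") {
    ids <- args$ids
    stopifnot(length(ids) >= 2)
    for (i in 2:length(ids)) {
      if (!any(vapply(ids[1:(i - 1)], function(j)
        regions_adjacent(labels, j, ids[i]), TRUE)))
        stop("cannot merge non-adjacent regions ", ids[1], " and ", ids[i])
      labels[labels == ids[i]] <- ids[1]
    }
  } else if (action == "split") {
    ln <- args$line
    stopifnot(length(ln) == 4)
    m <- labels == args$id
    idx <- which(m, arr.ind = TRUE)
    side <- (idx[, 1] - ln[1]) * (ln[4] - ln[2]) -
      (idx[, 2] - ln[2]) * (ln[3] - ln[1])
    if (all(side >= 0) || all(side < 0))
      stop("split line does not cross region ", args$id)
    newid <- max(present) + 1L
    labels[m][side < 0] <- newid
  } else if (action == "add") {
    poly <- args$polygon
    stopifnot(!is.null(poly), nrow(poly) >= 3)
    inside <- points_in_polygon(labels, poly)
    if (!any(inside)) stop("polygon contains no pixels")
    newid <- max(present) + 1L
    labels[inside] <- newid
  } else {                               # remove
    m <- labels == args$id
    if (length(present) == 1)
      stop("cannot remove the only region")
    # reassign to the neighbor with the longest shared boundary
    nbr <- neighbor_votes(labels, args$id)
    labels[m] <- as.integer(names(which.max(nbr)))
  }
  out <- region_set_relabel(labels, regions$S_R)
  out$log <- c(regions$log,
               sprintf("%s(%s)", action,
                       paste(deparse(args, control = NULL), collapse = "")))
  out
}

# rebuild a region_set keeping original (possibly non-contiguous) ids
region_set_relabel <- function(labels, SR) {
  ids <- sort(unique(as.vector(labels)))
  lab2 <- matrix(match(labels, ids), nrow(labels), ncol(labels))
  rs <- region_set(lab2, SR)
  rs$table$id <- ids[rs$table$id]
  rs$labels <- matrix(ids[lab2], nrow(labels), ncol(labels))
  rs
}

# counts of 4-neighbor labels around region `id`
neighbor_votes <- function(labels, id) {
  m <- labels == id
  nr <- nrow(labels); nc <- ncol(labels)
  votes <- integer(0)
  shift_pairs <- list(
    list(a = m[-1, ], b = labels[-nr, ]),
    list(a = m[-nr, ], b = labels[-1, ]),
    list(a = m[, -1], b = labels[, -nc]),
    list(a = m[, -nc], b = labels[, -1]))
  vals <- unlist(lapply(shift_pairs, function(s) s$b[s$a & s$b != id]))
  if (length(vals) == 0) stop("region ", id, " has no neighbors")
  table(vals)
}

# even-odd rule point-in-polygon over the label grid
points_in_polygon <- function(labels, poly) {
  nr <- nrow(labels); nc <- ncol(labels)
  pr <- poly[[1]]; pc <- poly[[2]]
  rs <- matrix(seq_len(nr), nr, nc)
  cs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- matrix(FALSE, nr, nc)
  n <- length(pr); j <- n
  for (i in seq_len(n)) {
    cross <- ((pr[i] > rs) != (pr[j] > rs)) &
      (cs < (pc[j] - pc[i]) * (rs - pr[i]) / (pr[j] - pr[i]) + pc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Flag uncertain segmentations
#'
#' Returns the ids a reviewer should look at: all regions classified C2
#' ("only part of a spot") plus C1 regions whose classifier confidence
#' falls below the threshold.
#'
#' @param regions a `region_set` whose table has `class`/`confidence`
#'   (from [detect_spots()]).
#' @param conf_threshold minimum C1 confidence.
#' @return integer vector of region ids.
#' @export
flag_uncertain <- function(regions, conf_threshold = 0.2) {
  tab <- regions$table
  if (is.null(tab$class)) stop("regions are not classified")
  tab$id[tab$class == "C2" |
           (tab$class == "C1" & tab$confidence < conf_threshold)]
}
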