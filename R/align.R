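#' Initial high-certainty landmark pairs between two gels
#'
#' Finds salient points on both gels (cores of dark blobs: local maxima of
#' the dark-polarity Laplacian-of-Gaussian response), describes each with
#' a local gradient-orientation-histogram descriptor (4 x 4 spatial cells
#' x 8 orientation bins, Gaussian-weighted, contrast-normalized), and
#' matches descriptors by mutual nearest neighbor with a
#' best/second-best ratio test. Because spot intensities may change
#' several-fold between the gels being compared, appearance matches alone
#' are unreliable; the candidates are therefore vetted by geometric
#' consensus — a Hough vote over the candidate displacement field finds
#' the dominant translation, pairs within `inlier_gate` of it are kept,
#' and a robust rigid fit refines the inlier set. At least `min_pairs`
#' consistent, non-collinear pairs are required, otherwise the gels are
#' declared too dissimilar to register (a pure-noise image fails here).
#'
#' @param gelA,gelB [gel_image()]s (preprocessed scans, dark-spot
#'   polarity).
#' @param max_points strongest keypoints kept per gel.
#' @param ratio nearest/second-nearest descriptor distance threshold;
#'   matches above it are dropped before the consensus vote.
#' @param log_sigma blob scale for keypoint detection.
#' @param patch_radius descriptor window radius in px.
#' @param inlier_gate residual (px) below which a pair counts as
#'   geometrically consistent; loose by design, since smooth non-rigid
#'   row distortion of several px must survive to the spline stage.
#' @param min_pairs minimum number of consistent pairs.
#' @return data frame of class `landmark_pairs`: `rA, cA, rB, cB, score,
#'   source`.
#' @export
initial_landmarks <- function(gelA, gelB, max_points = 60L, ratio = 0.95,
                              log_sigma = 4, patch_radius = 24L,
                              inlier_gate = 10, min_pairs = 3L) {
  pA <- if (inherits(gelA, "gel_image")) gelA$pixels else as.matrix(gelA)
  pB <- if (inherits(gelB, "gel_image")) gelB$pixels else as.matrix(gelB)
  kA <- keypoints(pA, max_points, log_sigma, patch_radius)
  kB <- keypoints(pB, max_points, log_sigma, patch_radius)
  if (nrow(kA) < min_pairs || nrow(kB) < min_pairs)
    stop("insufficient reliable landmarks: too few salient points")
  dA <- keypoint_descriptors(pA, kA, patch_radius)
  dB <- keypoint_descriptors(pB, kB, patch_radius)
  # pairwise Euclidean distances between descriptor sets
  dist2 <- outer(rowSums(dA^2), rowSums(dB^2), "+") - 2 * dA %*% t(dB)
  dist2 <- pmax(dist2, 0)
  nnAB <- apply(dist2, 1L, which.min)
  nnBA <- apply(dist2, 2L, which.min)
  pairs <- list()
  for (i in seq_len(nrow(kA))) {
    j <- nnAB[i]
    if (nnBA[j] != i) next                       # mutual check
    d <- sort(dist2[i, ])
    if (length(d) >= 2 && sqrt(d[1]) > ratio * sqrt(d[2])) next
    pairs[[length(pairs) + 1L]] <-
      data.frame(rA = kA$row[i], cA = kA$col[i],
                 rB = kB$row[j], cB = kB$col[j],
                 score = 1 - sqrt(d[1]) / (sqrt(d[2]) + 1e-12))
  }
  if (length(pairs) < min_pairs)
    stop("insufficient reliable landmarks: ", length(pairs),
         " mutual ratio-test matches")
  pr <- do.call(rbind, pairs)
  # geometric consensus: Hough vote on the displacement field
  dr <- pr$rB - pr$rA; dc <- pr$cB - pr$cA
  bin <- inlier_gate
  key <- paste(round(dr / bin), round(dc / bin))
  mode_key <- names(which.max(table(key)))
  seedpairs <- key == mode_key
  t0 <- c(stats::median(dr[seedpairs]), stats::median(dc[seedpairs]))
  keep <- abs(dr - t0[1]) <= inlier_gate & abs(dc - t0[2]) <= inlier_gate
  if (sum(keep) >= min_pairs && sum(keep) > 3) {
    # refine with a robust rigid fit over the translation inliers
    rg <- fit_rigid(pr[keep, , drop = FALSE])
    pred <- rigid_apply(rg, pr[, c("rA", "cA")])
    res <- sqrt((pred[, 1] - pr$rB)^2 + (pred[, 2] - pr$cB)^2)
    keep <- res <= inlier_gate
  }
  if (sum(keep) < min_pairs || sum(keep) < 0.15 * nrow(pr))
    stop("insufficient reliable landmarks: matches are not geometrically ",
         "consistent (", sum(keep), " inliers of ", nrow(pr), ")")
  pr <- pr[keep, , drop = FALSE]
  if (collinear(pr$rA, pr$cA))
    stop("insufficient reliable landmarks: all matches collinear")
  pr$source <- "auto_initial"
  rownames(pr) <- NULL
  class(pr) <- c("landmark_pairs", "data.frame")
  pr
}

collinear <- function(r, c, tol = 1e-6) {
  if (length(r) < 3) return(TRUE)
  m <- cbind(r - mean(r), c - mean(c))
  sv <- svd(m, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

# dark-blob keypoints: local maxima of the LoG response of the
# dark-polarity image, strongest first, margin-clipped
keypoints <- function(px, max_points, log_sigma, margin) {
  L <- filter2_rep(px, log_kernel(log_sigma))
  nr <- nrow(L); nc <- ncol(L)
  is_max <- L == max_filter3(L) & L > 0
  is_max[c(1:(margin + 1), (nr - margin):nr), ] <- FALSE
  is_max[, c(1:(margin + 1), (nc - margin):nc)] <- FALSE
  idx <- which(is_max)
  if (length(idx) == 0)
    return(data.frame(row = integer(0), col = integer(0), val = numeric(0)))
  ord <- order(L[idx], decreasing = TRUE)
  idx <- idx[ord][seq_len(min(max_points, length(idx)))]
  data.frame(row = ((idx - 1L) %% nr) + 1L,
             col = ((idx - 1L) %/% nr) + 1L,
             val = L[idx])
}

max_filter3 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  xp <- matrix(-Inf, nr + 2L, nc + 2L)
  xp[2:(nr + 1), 2:(nc + 1)] <- x
  out <- x
  for (dr in -1:1) for (dc in -1:1) {
    out <- pmax(out, xp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  out
}

# 4x4 spatial cells x 8 orientation bins, Gaussian-weighted gradient
# histogram, L2-normalized with 0.3 clipping (robust to contrast). The
# window is wide enough that the surrounding spot constellation enters
# the descriptor: individual gel spots look alike, their neighborhoods
# do not.
keypoint_descriptors <- function(px, kp, radius) {
  g <- image_gradient(px)
  mag <- sqrt(g$gr^2 + g$gc^2)
  ang <- atan2(g$gr, g$gc)            # [-pi, pi]
  obin <- pmin(floor((ang + pi) / (2 * pi) * 8), 7)
  d <- (-radius):radius
  w <- exp(-outer(d^2, d^2, "+") / (2 * radius^2))
  cell1 <- pmin(floor((d + radius) / (2 * radius + 1) * 4), 3)
  nbin <- 4L * 4L * 8L
  nr <- nrow(px); nc <- ncol(px)
  t(vapply(seq_len(nrow(kp)), function(i) {
    r0 <- kp$row[i]; c0 <- kp$col[i]
    rs <- clamp(r0 + d, 1, nr); cs <- clamp(c0 + d, 1, nc)
    m <- mag[rs, cs] * w
    ob <- obin[rs, cs]
    cr <- matrix(cell1, length(d), length(d))
    cc <- matrix(cell1, length(d), length(d), byrow = TRUE)
    bin <- (cr * 4L + cc) * 8L + ob
    h <- vapply(seq_len(nbin) - 1L, function(b) sum(m[bin == b]), 0)
    h <- h / sqrt(sum(h^2) + 1e-12)
    h <- pmin(h, 0.3)
    h / sqrt(sum(h^2) + 1e-12)
  }, numeric(128)))
}

#' Rigid (Procrustes) registration of landmark pairs
#'
#' Least-squares rotation + translation (optionally isotropic scale)
#' mapping the A points onto the B points, computed in closed form by SVD
#' with the reflection excluded, and made robust to a minority of gross
#' outlier pairs by iteratively reweighted least squares with Huber
#' weights.
#'
#' @param pairs `landmark_pairs` or data frame with `rA, cA, rB, cB`.
#' @param allow_scale estimate an isotropic scale factor (off by default:
#'   gels are scanned at fixed resolution).
#' @param iters IRLS iterations.
#' @return object of class `rigid_transform`: `theta` (radians), 2x2
#'   rotation `R`, translation `t`, `scale`.
#' @export
fit_rigid <- function(pairs, allow_scale = FALSE, iters = 10L) {
  A <- cbind(pairs$rA, pairs$cA)
  B <- cbind(pairs$rB, pairs$cB)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 pairs")
  w <- rep(1, n)
  fit1 <- function(w) {
    w <- w / sum(w)
    ca <- colSums(A * w); cb <- colSums(B * w)
    A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
    H <- t(A0 * w) %*% B0
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    S <- diag(c(1, dsign))
    R <- sv$v %*% S %*% t(sv$u)
    s <- if (allow_scale)
      sum(diag(S) * sv$d) / sum(w * rowSums(A0^2)) else 1
    tt <- cb - s * as.vector(R %*% ca)
    list(R = R, t = tt, s = s)
  }
  f <- fit1(w)
  for (it in seq_len(iters)) {
    pred <- t(f$s * f$R %*% t(A)) + matrix(f$t, n, 2, byrow = TRUE)
    res <- sqrt(rowSums((pred - B)^2))
    sig <- stats::median(res) * 1.4826
    if (!is.finite(sig) || sig < 1e-9) break
    k <- 1.345 * sig
    w <- ifelse(res <= k, 1, k / res)
    f <- fit1(w)
  }
  if (any(!is.finite(f$R))) stop("degenerate landmark configuration")
  structure(list(theta = atan2(f$R[2, 1], f$R[1, 1]), R = f$R, t = f$t,
                 scale = f$s),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param pts matrix/data frame of `(row, col)`.
#' @return matrix of transformed points.
#' @export
rigid_apply <- function(transform, pts) {
  P <- as.matrix(pts)
  t(transform$scale * transform$R %*% t(P)) +
    matrix(transform$t, nrow(P), 2, byrow = TRUE)
}

#' Thin-plate-spline registration
#'
#' Fits the standard thin-plate spline with kernel `U(r) = r^2 log(r)`
#' mapping the A landmarks onto the B landmarks: an affine part plus
#' kernel weights solving the bordered linear system, with smoothing
#' parameter `lambda` on the kernel block. With `lambda = 0` the spline
#' interpolates every landmark exactly; when the landmarks are related by
#' an affine map the fitted spline has zero bending energy and reduces to
#' that affine map everywhere. Coordinates are internally normalized to
#' the unit box for conditioning.
#'
#' @param pairs `landmark_pairs` or data frame with `rA, cA, rB, cB`.
#' @param lambda regularization, >= 0 (0 = exact interpolation).
#' @return object of class `tps_model` with the alignment (rigid part is
#'   implicit in the affine term), landmark list, coefficients and
#'   `bending_energy`.
#' @export
fit_tps <- function(pairs, lambda = 0) {
  A <- cbind(pairs$rA, pairs$cA)
  B <- cbind(pairs$rB, pairs$cB)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 landmark pairs")
  if (collinear(A[, 1], A[, 2])) stop("landmarks are collinear")
  if (anyDuplicated(A)) stop("duplicate source landmarks")
  ctr <- colMeans(A)
  scl <- max(stats::sd(A[, 1]), stats::sd(A[, 2]), 1e-9)
  An <- sweep(A, 2L, ctr) / scl
  K <- tps_kernel_matrix(An, An)
  P <- cbind(1, An)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(B, matrix(0, 3, 2))
  coefs <- solve(L, rhs)
  W <- coefs[seq_len(n), , drop = FALSE]
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(src = A, src_norm = An, ctr = ctr, scl = scl,
                 W = W, a = coefs[n + 1:3, , drop = FALSE],
                 lambda = lambda, bending_energy = be,
                 landmarks = as.data.frame(pairs)),
            class = "tps_model")
}

tps_kernel_matrix <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2 <- pmax(d2, 0)
  U <- ifelse(d2 > 0, d2 * log(d2) / 2, 0)   # r^2 log r = d2 log(sqrt(d2))
  U
}

#' Map points through a fitted thin-plate spline
#' @param model a `tps_model`.
#' @param pts matrix/data frame of `(row, col)` in the A frame.
#' @return matrix of mapped points in the B frame.
#' @export
tps_apply <- function(model, pts) {
  P <- as.matrix(pts)
  if (ncol(P) != 2) P <- t(P)
  Pn <- sweep(P, 2L, model$ctr) / model$scl
  U <- tps_kernel_matrix(Pn, model$src_norm)
  cbind(1, Pn) %*% model$a + U %*% model$W
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("tps_model: %d landmarks, lambda = %g, bending energy %.4g\n",
              nrow(x$src), x$lambda, x$bending_energy))
  invisible(x)
}

#' Pair spots across two gels
#'
#' Maps A-spot centers through the fitted alignment into the B frame and
#' solves a one-to-one assignment among candidate pairs closer than
#' `gate`, greedily by ascending residual (each spot used at most once).
#' Unmatched spots on either side are reported.
#'
#' @param spotsA,spotsB data frames with `spot_id, row, col` (e.g. from
#'   [detect_spots()]).
#' @param model a `tps_model` (or `NULL` for the identity map).
#' @param gate residual gate in B-frame px.
#' @return list with `matches` (`spot_id_A, spot_id_B, residual`),
#'   `unmatched_A`, `unmatched_B`.
#' @export
pair_spots <- function(spotsA, spotsB, model = NULL, gate = 6) {
  if (nrow(spotsA) == 0 || nrow(spotsB) == 0)
    return(list(matches = data.frame(spot_id_A = integer(0),
                                     spot_id_B = integer(0),
                                     residual = numeric(0)),
                unmatched_A = spotsA$spot_id, unmatched_B = spotsB$spot_id))
  PA <- cbind(spotsA$row, spotsA$col)
  if (!is.null(model)) PA <- tps_apply(model, PA)
  PB <- cbind(spotsB$row, spotsB$col)
  d2 <- outer(rowSums(PA^2), rowSums(PB^2), "+") - 2 * PA %*% t(PB)
  d <- sqrt(pmax(d2, 0))
  cand <- which(d <= gate, arr.ind = TRUE)
  matches <- data.frame(spot_id_A = integer(0), spot_id_B = integer(0),
                        residual = numeric(0))
  if (nrow(cand) > 0) {
    ord <- order(d[cand])
    usedA <- logical(nrow(PA)); usedB <- logical(nrow(PB))
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (usedA[i] || usedB[j]) next
      usedA[i] <- TRUE; usedB[j] <- TRUE
      matches <- rbind(matches,
                       data.frame(spot_id_A = spotsA$spot_id[i],
                                  spot_id_B = spotsB$spot_id[j],
                                  residual = d[i, j]))
    }
  }
  list(matches = matches,
       unmatched_A = setdiff(spotsA$spot_id, matches$spot_id_A),
       unmatched_B = setdiff(spotsB$spot_id, matches$spot_id_B))
}

#' Edit spot matches
#'
#' Manual repair of the pairing: `add` inserts a pair (removing, with a
#' warning, any existing pair that uses either spot, so the one-to-one
#' invariant always holds); `remove` deletes a pair. Edits are recorded in
#' the `log` attribute.
#'
#' @param matching result of [pair_spots()].
#' @param action `"add"` or `"remove"`.
#' @param pair `c(spot_id_A, spot_id_B)`.
#' @param spotsA,spotsB the spot tables (to validate ids on `add`).
#' @return edited matching.
#' @export
edit_matches <- function(matching, action = c("add", "remove"), pair,
                         spotsA = NULL, spotsB = NULL) {
  action <- match.arg(action)
  m <- matching$matches
  lg <- attr(matching, "log"); if (is.null(lg)) lg <- character(0)
  if (action == "add") {
    if (!is.null(spotsA) && !pair[1] %in% spotsA$spot_id)
      stop("unknown A spot ", pair[1])
    if (!is.null(spotsB) && !pair[2] %in% spotsB$spot_id)
      stop("unknown B spot ", pair[2])
    conflict <- m$spot_id_A == pair[1] | m$spot_id_B == pair[2]
    if (any(conflict)) {
      warning("removing ", sum(conflict), " conflicting pair(s)")
      matching$unmatched_A <- union(matching$unmatched_A,
                                    setdiff(m$spot_id_A[conflict], pair[1]))
      matching$unmatched_B <- union(matching$unmatched_B,
                                    setdiff(m$spot_id_B[conflict], pair[2]))
      m <- m[!conflict, , drop = FALSE]
    }
    m <- rbind(m, data.frame(spot_id_A = pair[1], spot_id_B = pair[2],
                             residual = NA_real_))
    matching$unmatched_A <- setdiff(matching$unmatched_A, pair[1])
    matching$unmatched_B <- setdiff(matching$unmatched_B, pair[2])
  } else {
    hit <- m$spot_id_A == pair[1] & m$spot_id_B == pair[2]
    if (!any(hit)) stop("no such pair")
    m <- m[!hit, , drop = FALSE]
    matching$unmatched_A <- union(matching$unmatched_A, pair[1])
    matching$unmatched_B <- union(matching$unmatched_B, pair[2])
  }
  matching$matches <- m
  attr(matching, "log") <- c(lg, sprintf("%s(%d,%d)", action, pair[1],
                                         pair[2]))
  matching
}
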