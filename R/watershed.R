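#' Watershed transform by steepest ascent
#'
#' Partitions an intensity landscape into catchment regions, one per
#' regional maximum, using 8-connected steepest ascent: every pixel
#' follows its largest-valued neighbor uphill until a regional maximum is
#' reached, and all pixels draining to the same maximum form one region.
#' This is the watershed of the inverted surface with no flooding
#' tolerance — every regional maximum seeds a region.
#'
#' Ties (exact plateaus, common where a symmetry map is exactly zero over
#' featureless background) are broken deterministically by adding an
#' infinitesimal ramp in linear pixel index, far below the smallest real
#' intensity gap: each plateau then drains to a single well-defined pixel,
#' so a flat background becomes one region rather than thousands.
#'
#' @param x numeric matrix (the surface whose maxima seed regions; pass
#'   `S_R` to flood the inverted symmetry map).
#' @return integer label matrix, same shape as `x`; labels `1..K` cover
#'   every pixel (regions partition the image), numbered by the linear
#'   index of their seed maximum.
#' @export
watershed_transform <- function(x) {
  x <- as.matrix(x)
  nr <- nrow(x); nc <- ncol(x); n <- nr * nc
  if (n == 0) return(matrix(integer(0), nr, nc))
  ux <- sort(unique(as.vector(x)))
  gap <- if (length(ux) > 1) min(diff(ux)) else 1
  xe <- x + (gap / (2 * n)) * matrix(seq_len(n), nr, nc)
  # padded neighbor lookup
  xp <- matrix(-Inf, nr + 2L, nc + 2L)
  xp[2:(nr + 1), 2:(nc + 1)] <- xe
  idxp <- matrix(0L, nr + 2L, nc + 2L)
  idxp[2:(nr + 1), 2:(nc + 1)] <- seq_len(n)
  best_val <- xe
  parent <- matrix(seq_len(n), nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nv <- xp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    ni <- idxp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    upd <- nv > best_val
    best_val[upd] <- nv[upd]
    parent[upd] <- ni[upd]
  }
  parent <- as.vector(parent)
  # pointer jumping to the draining maximum
  repeat {
    pp <- parent[parent]
    if (identical(pp, parent)) break
    parent <- pp
  }
  roots <- sort(unique(parent))
  lab <- match(parent, roots)
  matrix(as.integer(lab), nr, nc)
}

#' Watershed regions of a symmetry map
#'
#' Applies [watershed_transform()] to the real part `S_R` of a
#' [symmetry_map()] (equivalently, floods `-S_R`) and records, for each
#' region, the location and strength of its symmetry maximum — the most
#' probable spot core.
#'
#' @param sym a [symmetry_map()], or a plain numeric matrix used as `S_R`.
#' @return object of class `region_set`: `labels` (integer partition
#'   matrix), `S_R`, and `table`, a data frame with one row per region:
#'   `id, row, col, smax, area`.
#' @export
watershed_regions <- function(sym) {
  SR <- if (inherits(sym, "symmetry_map")) sym$S_R else as.matrix(sym)
  labels <- watershed_transform(SR)
  region_set(labels, SR)
}

# build a region_set (labels partition + per-region maxima) from a label
# matrix and the surface it was derived from
region_set <- function(labels, SR) {
  n <- length(labels)
  tab <- if (n == 0 || max(labels) == 0) {
    data.frame(id = integer(0), row = numeric(0), col = numeric(0),
               smax = numeric(0), area = integer(0))
  } else {
    lv <- as.vector(labels); sv <- as.vector(SR)
    ord <- order(lv, sv)                  # within each label, max is last
    last <- ord[cumsum(tabulate(lv))]
    nr <- nrow(labels)
    data.frame(id = lv[last],
               row = ((last - 1L) %% nr) + 1L,
               col = ((last - 1L) %/% nr) + 1L,
               smax = sv[last],
               area = tabulate(lv))
  }
  structure(list(labels = labels, S_R = SR, table = tab,
                 log = character(0)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions over %d x %d px\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels)))
  if (!is.null(x$table$class))
    print(table(x$table$class))
  invisible(x)
}

# boundary (contour) mask: region pixels adjacent (4-conn) to another
# region or to the image border
boundary_mask <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  b[1, ] <- TRUE; b[nr, ] <- TRUE; b[, 1] <- TRUE; b[, nc] <- TRUE
  b[-1, ] <- b[-1, ] | labels[-1, ] != labels[-nr, ]
  b[-nr, ] <- b[-nr, ] | labels[-nr, ] != labels[-1, ]
  b[, -1] <- b[, -1] | labels[, -1] != labels[, -nc]
  b[, -nc] <- b[, -nc] | labels[, -nc] != labels[, -1]
  b
}

# are two regions 8-adjacent?
regions_adjacent <- function(labels, id1, id2) {
  m1 <- labels == id1
  nr <- nrow(labels); nc <- ncol(labels)
  grown <- m1
  grown[-1, ] <- grown[-1, ] | m1[-nr, ]
  grown[-nr, ] <- grown[-nr, ] | m1[-1, ]
  grown[, -1] <- grown[, -1] | m1[, -nc]
  grown[, -nc] <- grown[, -nc] | m1[, -1]
  grown[-1, -1] <- grown[-1, -1] | m1[-nr, -nc]
  grown[-nr, -nc] <- grown[-nr, -nc] | m1[-1, -1]
  grown[-1, -nc] <- grown[-1, -nc] | m1[-nr, -1]
  grown[-nr, -1] <- grown[-nr, -1] | m1[-1, -nc]
  any(grown & labels == id2)
}
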