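#' Raw spot volume
#'
#' Spot quantity is the total intensity of the spot: the sum of the
#' (background-corrected, spot-positive) pixel signal over the spot's
#' region mask, measured above the region's local baseline. The baseline
#' is the median signal on the region's contour pixels — after global
#' background removal a residual pedestal can remain under dense spot
#' clusters, and referencing each region to its own boundary removes it.
#' Set `local_baseline = FALSE` for the plain mask sum.
#'
#' @param signal a [gel_image()] or matrix in spot-signal polarity
#'   (protein = positive), e.g. the output of [subtract_background()].
#' @param mask logical matrix, or a `region_set` plus `id`.
#' @param id region id when `mask` is a `region_set`.
#' @param local_baseline subtract the contour-median baseline.
#' @return non-negative scalar volume.
#' @export
spot_volume <- function(signal, mask, id = NULL, local_baseline = TRUE) {
  px <- if (inherits(signal, "gel_image")) signal$pixels else
    as.matrix(signal)
  if (inherits(mask, "region_set")) {
    stopifnot(!is.null(id))
    mask <- mask$labels == id
  }
  if (!any(mask)) stop("empty spot mask")
  base <- 0
  if (local_baseline) {
    labels <- matrix(1L, nrow(px), ncol(px))
    labels[!mask] <- 2L
    cont <- boundary_mask(labels) & mask
    base <- stats::median(px[cont])
  }
  # no per-pixel clipping: rectifying noise would bias faint spots up
  max(sum(px[mask] - base), 0)
}

#' Volumes of all accepted spots
#'
#' Sums the spot signal over each listed region, above each region's
#' contour-median local baseline (see [spot_volume()]).
#'
#' @param signal spot-signal image (see [spot_volume()]).
#' @param regions a `region_set`.
#' @param ids region ids to quantify (default: the candidate table).
#' @param local_baseline subtract per-region contour-median baselines.
#' @return data frame `id, volume`.
#' @export
region_volumes <- function(signal, regions, ids = regions$table$id,
                           local_baseline = TRUE) {
  px <- if (inherits(signal, "gel_image")) signal$pixels else
    as.matrix(signal)
  lv <- as.vector(regions$labels)
  pv <- as.vector(px)
  if (local_baseline) {
    bm <- as.vector(boundary_mask(regions$labels))
    base <- tapply(pv[bm], lv[bm], stats::median)
    vols <- pmax(tapply(pv - as.numeric(base[as.character(lv)]), lv, sum), 0)
  } else {
    vols <- tapply(pv, lv, sum)
  }
  data.frame(id = ids, volume = as.numeric(vols[as.character(ids)]))
}

#' Normalized spot quantities
#'
#' Divides each spot volume by the total volume of all accepted spots in
#' the gel, removing exposure and protein-load differences between gels;
#' quantities sum to 1 per gel.
#'
#' @param volumes numeric vector of raw volumes (>= 1 spot, total > 0).
#' @return numeric vector summing to 1.
#' @export
normalize_quantities <- function(volumes) {
  if (length(volumes) == 0) stop("no spots to normalize")
  tot <- sum(volumes)
  if (tot <= 0) stop("total spot volume is zero")
  volumes / tot
}

#' Signed fold change between paired spot quantities
#'
#' The ratio convention used throughout the comparison tables: a spot
#' higher in the first gel gives a positive fold change `q1/q2`, one
#' higher in the second gel a negative fold change `-q2/q1`, so
#' `|FC| >= 1` always and equality returns `+1`.
#'
#' @param q1,q2 positive normalized quantities (first / second gel).
#' @return signed fold change.
#' @export
fold_change <- function(q1, q2) {
  if (any(c(q1, q2) <= 0))
    stop("nonpositive quantity: a spot absent from one gel is reported ",
         "as present-only, not as a fold change")
  ifelse(q1 >= q2, q1 / q2, -q2 / q1)
}

#' 2-fold change rule
#'
#' Because single-pair 2DE comparisons carry biological and technical
#' variance, only spots whose quantity changes by more than `threshold`
#' fold (default 2) are called changed (increased or decreased). The
#' boundary is strict: `|FC| = 2` exactly is unchanged.
#'
#' @param fc signed fold change(s), `|fc| >= 1`.
#' @param threshold fold threshold.
#' @return logical vector.
#' @export
call_changed <- function(fc, threshold = 2) {
  abs(fc) > threshold
}

#' Isoform share percentages within a spot group
#'
#' A protein spread over several spots of different pI (isoforms from
#' post-translational modification) forms a spot group; each spot's share
#' is its percentage of the group's total quantity, summing to 100 per
#' group.
#'
#' @param quantities positive quantities of one group's spots, or a data
#'   frame with columns `group` and `quantity` for many groups at once.
#' @return numeric vector of shares (%), or the data frame with a
#'   `share_pct` column appended.
#' @export
group_shares <- function(quantities) {
  if (is.data.frame(quantities)) {
    stopifnot(all(c("group", "quantity") %in% names(quantities)))
    tot <- stats::ave(quantities$quantity, quantities$group, FUN = sum)
    if (any(tot <= 0)) stop("zero group total")
    quantities$share_pct <- 100 * quantities$quantity / tot
    return(quantities)
  }
  tot <- sum(quantities)
  if (tot <= 0) stop("zero group total")
  100 * quantities / tot
}

#' Compare spot quantities across two gels
#'
#' Joins the per-gel normalized quantities through the spot pairing and
#' reports, per matched pair, the signed fold change and the 2-fold-rule
#' call; spots present in only one gel are listed with a presence-only
#' status and no fold change. When `group` columns are present, shares
#' within groups are computed per gel. Rows are ordered by group then
#' column position (pI direction) for a deterministic table.
#'
#' @param quantA,quantB data frames with `spot_id, quantity` (normalized,
#'   see [normalize_quantities()]); optional `group`, `row`, `col`,
#'   `mw_kda`, `pi` columns are carried through.
#' @param matching result of [pair_spots()].
#' @param threshold fold-change threshold for [call_changed()].
#' @return data frame with one row per spot pair or one-sided spot:
#'   `spot_id_A, spot_id_B, qA, qB, fc, changed, status` (plus carried
#'   columns and `share_pct_A/B` when groups are given).
#' @export
compare_gels <- function(quantA, quantB, matching, threshold = 2) {
  m <- matching$matches
  if (!all(m$spot_id_A %in% quantA$spot_id))
    stop("match references unknown A spot")
  if (!all(m$spot_id_B %in% quantB$spot_id))
    stop("match references unknown B spot")
  ia <- match(m$spot_id_A, quantA$spot_id)
  ib <- match(m$spot_id_B, quantB$spot_id)
  paired <- data.frame(spot_id_A = m$spot_id_A, spot_id_B = m$spot_id_B,
                       qA = quantA$quantity[ia], qB = quantB$quantity[ib])
  # a paired spot whose measured quantity vanished (volume at or below
  # its local baseline) gets no fold change, like a one-sided spot
  quantified <- paired$qA > 0 & paired$qB > 0
  paired$fc <- NA_real_
  paired$fc[quantified] <- mapply(fold_change, paired$qA[quantified],
                                  paired$qB[quantified])
  paired$changed <- call_changed(paired$fc, threshold)
  paired$status <- ifelse(quantified, "paired", "below-baseline")
  carry <- intersect(c("group", "row", "col", "mw_kda", "pi"),
                     names(quantA))
  for (cn in carry) paired[[cn]] <- quantA[[cn]][ia]
  onlyA <- quantA[quantA$spot_id %in% matching$unmatched_A, , drop = FALSE]
  onlyB <- quantB[quantB$spot_id %in% matching$unmatched_B, , drop = FALSE]
  add_side <- function(tab, side) {
    if (nrow(tab) == 0) return(NULL)
    out <- data.frame(spot_id_A = if (side == "A") tab$spot_id else NA,
                      spot_id_B = if (side == "B") tab$spot_id else NA,
                      qA = if (side == "A") tab$quantity else NA,
                      qB = if (side == "B") tab$quantity else NA,
                      fc = NA_real_, changed = NA, status = paste0(side,
                                                                   "-only"))
    for (cn in carry) out[[cn]] <- if (cn %in% names(tab)) tab[[cn]] else NA
    out
  }
  res <- rbind(paired, add_side(onlyA, "A"), add_side(onlyB, "B"))
  if ("group" %in% names(res)) {
    ok <- res$status == "paired"
    res$share_pct_A <- NA_real_
    res$share_pct_A[ok] <- group_shares(
      data.frame(group = res$group[ok], quantity = res$qA[ok]))$share_pct
    res$share_pct_B <- NA_real_
    res$share_pct_B[ok] <- group_shares(
      data.frame(group = res$group[ok], quantity = res$qB[ok]))$share_pct
  }
  ord <- if ("group" %in% names(res) && "col" %in% names(res))
    order(res$group, res$col) else order(res$status, res$spot_id_A,
                                         res$spot_id_B, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
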