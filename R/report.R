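#' Parse a spot identification table
#'
#' Reads the CSV schema of the study-style identification tables: one row
#' per identified spot, labels of the form group number plus optional
#' isoform letter (`"9a"`, `"23B"`), accession / entry / description /
#' theoretical columns printed only on the first row of each group and
#' blank on continuation rows (the blanks inherit downward within the
#' group), and a final quantitative column (fold change or share %).
#'
#' @param path CSV file path.
#' @param na_ok names of numeric columns where blanks are data (not
#'   inherited), e.g. an absent share.
#' @return data frame of identification records with parsed `group`
#'   (integer) and `isoform` (letter or `""`), accession metadata and
#'   typed numeric columns.
#' @export
parse_id_table <- function(path, na_ok = c("fc", "share_pct")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  stopifnot("label" %in% names(tab))
  m <- regmatches(tab$label, regexec("^([0-9]+)([A-Za-z]?)$",
                                     as.character(tab$label)))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("malformed spot label(s): ",
         paste(tab$label[bad], collapse = ", "))
  tab$group <- as.integer(vapply(m, `[`, "", 2L))
  tab$isoform <- vapply(m, `[`, "", 3L)
  inherit_cols <- setdiff(names(tab),
                          c("label", "group", "isoform", na_ok,
                            "score", "match", "dp",
                            "exp_mw_kda", "exp_pi"))
  # carry the group's leading value into blank continuation cells (the
  # printed tables leave repeated cells empty below the group's first row)
  for (cn in inherit_cols) {
    v <- tab[[cn]]
    for (i in seq_along(v)) {
      if (i > 1 && is.na(v[i]) && tab$group[i] == tab$group[i - 1])
        v[i] <- v[i - 1]
    }
    tab[[cn]] <- v
  }
  num_cols <- intersect(c("score", "match", "tp", "dp", "theor_mw_kda",
                          "theor_pi", "exp_mw_kda", "exp_pi", "fc",
                          "share_pct"), names(tab))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(v) & !is.na(tab[[cn]])))
      stop("non-numeric value in column ", cn)
    tab[[cn]] <- v
  }
  if ("exp_mw_kda" %in% names(tab) && any(tab$exp_mw_kda <= 0, na.rm = TRUE))
    stop("molecular mass must be positive")
  if ("exp_pi" %in% names(tab) &&
      any(tab$exp_pi < 0 | tab$exp_pi > 14, na.rm = TRUE))
    stop("pI out of [0, 14]")
  dup <- stats::aggregate(isoform ~ group, tab,
                          function(x) anyDuplicated(x[x != ""]) > 0)
  if (any(dup$isoform))
    stop("duplicate isoform letters in group(s): ",
         paste(dup$group[dup$isoform], collapse = ", "))
  tab
}

#' Count distinct spot groups in a parsed table
#' @param records output of [parse_id_table()].
#' @return integer count.
#' @export
count_groups <- function(records) length(unique(records$group))

#' Reconcile identifications across two pI ranges
#'
#' Joins two parsed identification tables (e.g. a wide pI 3-11
#' fractionation and a narrow pI 4-7 one) by accession and reports how
#' many isoform spots each protein shows in each range, flagging proteins
#' that spread into several spots of different pI under the narrow
#' fractionation.
#'
#' @param recsA,recsB outputs of [parse_id_table()].
#' @return data frame `accession, entry, n_spots_A, n_spots_B, in_A,
#'   in_B, spread_B`, one row per accession, ordered by accession.
#' @export
reconcile_ranges <- function(recsA, recsB) {
  cnt <- function(recs) {
    if (nrow(recs) == 0)
      return(data.frame(accession = character(0), entry = character(0),
                        n = integer(0)))
    ag <- stats::aggregate(list(n = recs$label),
                           list(accession = recs$ac, entry = recs$entry),
                           length)
    ag
  }
  a <- cnt(recsA); b <- cnt(recsB)
  accs <- sort(union(a$accession, b$accession))
  ia <- match(accs, a$accession); ib <- match(accs, b$accession)
  entry <- ifelse(!is.na(ia), a$entry[ia], b$entry[ib])
  out <- data.frame(accession = accs, entry = entry,
                    n_spots_A = ifelse(is.na(ia), 0L, a$n[ia]),
                    n_spots_B = ifelse(is.na(ib), 0L, b$n[ib]))
  out$in_A <- out$n_spots_A > 0
  out$in_B <- out$n_spots_B > 0
  out$spread_B <- out$n_spots_B > 1
  out
}

#' Pseudocolor overlay of two aligned gels
#'
#' Renders a deterministic two-color fusion PNG: the first gel's spot
#' signal in blue, the second gel's (warped through the alignment into
#' the first gel's frame) in orange. The tints are chosen so that
#' identical images give a neutral gray fusion: where only gel A has
#' protein the overlay is blue, only gel B orange, both dark gray.
#'
#' @param gelA,gelB [gel_image()]s, dark-spot polarity.
#' @param model a `tps_model` mapping A coordinates to B coordinates, or
#'   `NULL` for the identity.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
render_overlay <- function(gelA, gelB, model = NULL, path) {
  A <- gelA$pixels / INT_MAX_16
  B <- gelB$pixels / INT_MAX_16
  nr <- nrow(A); nc <- ncol(A)
  if (!is.null(model)) {
    if (!inherits(model, "tps_model")) stop("model must be a tps_model")
    pts <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
    mapped <- tps_apply(model, pts)
    B <- matrix(bilinear_sample(B, mapped[, 1], mapped[, 2]), nr, nc)
  }
  sA <- clamp(1 - A, 0, 1)    # spot signal
  sB <- clamp(1 - B, 0, 1)
  blue <- c(0, 0.45, 0.9); orange <- c(0.9, 0.45, 0)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3)
    img[, , ch] <- clamp(1 - sA * blue[ch] - sB * orange[ch], 0, 1)
  png::writePNG(img, path)
  invisible(path)
}

bilinear_sample <- function(x, r, c) {
  nr <- nrow(x); nc <- ncol(x)
  r <- clamp(r, 1, nr); c <- clamp(c, 1, nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  x[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    x[cbind(r1, c0)] * fr * (1 - fc) +
    x[cbind(r0, c1)] * (1 - fr) * fc +
    x[cbind(r1, c1)] * fr * fc
}
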