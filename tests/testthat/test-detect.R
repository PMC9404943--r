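test_that("symmetry map peaks at blob centers and is polarity-blind", {
  spec <- gel_spec(shape = c(96, 96),
                   spots = list(spot_spec(48, 40, 12000, 4)))
  px <- render_gel(spec)$gel$pixels
  sm <- symmetry_map(px, scale = 6)
  pk <- which(sm$S_R == max(sm$S_R), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((pk[1] - 48)^2 + (pk[2] - 40)^2), 1.01)

  # a bright bump gives the same peak location (rotational symmetry is
  # contrast-sign-blind; the LoG stage is what separates them)
  smb <- symmetry_map(max(px) - px, scale = 6)
  pkb <- which(smb$S_R == max(smb$S_R), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), unname(pkb))
  expect_error(symmetry_map(px, scale = 0.5), "scale")
})

test_that("symmetry response to pure noise stays below the spot response", {
  spec <- gel_spec(shape = c(96, 96),
                   spots = list(spot_spec(48, 48, 12000, 4)),
                   gaussian_noise_sd = 300, seed = 2)
  s_spot <- symmetry_map(render_gel(spec)$gel$pixels, scale = 6)
  nspec <- gel_spec(shape = c(96, 96), gaussian_noise_sd = 300, seed = 2)
  s_noise <- symmetry_map(render_gel(nspec)$gel$pixels, scale = 6)
  # compare peak responses away from the border
  inner <- 10:86
  expect_lt(max(abs(s_noise$S_R[inner, inner])),
            0.55 * max(abs(s_spot$S_R[inner, inner])))
})

test_that("|S| commutes with a 90-degree rotation", {
  spec <- gel_spec(shape = c(80, 80),
                   spots = list(spot_spec(30, 50, 12000, 4),
                                spot_spec(55, 25, 9000, 3)),
                   gaussian_noise_sd = 200, seed = 6)
  px <- render_gel(spec)$gel$pixels
  rot90 <- function(m) t(m)[ncol(m):1, ]
  a <- symmetry_map(px, scale = 5)
  b <- symmetry_map(rot90(px), scale = 5)
  magA <- sqrt(a$S_R^2 + a$S_I^2)
  magB <- sqrt(b$S_R^2 + b$S_I^2)
  inner <- 8:72
  expect_lt(max(abs(rot90(magA)[inner, inner] - magB[inner, inner])), 0.02)
})

test_that("watershed partitions every fixture and matches the flooding oracle", {
  set.seed(3)
  for (k in 1:4) {
    base <- matrix(rnorm(16 * 16), 16, 16)
    x <- gelmap2d:::filter2_rep(
      matrix(rnorm(64 * 64), 64, 64),
      gelmap2d:::gaussian_kernel(2 + k))
    lab <- watershed_transform(x)
    expect_true(all(lab >= 1))                       # full coverage
    expect_equal(sort(unique(as.vector(lab))), seq_len(max(lab)))
    oracle <- ws_flood_oracle(x)
    expect_identical(lab, oracle)
  }
  # constant surface collapses to a single region
  expect_equal(max(watershed_transform(matrix(5, 32, 32))), 1L)
})

test_that("two separated spots give two spot regions holding the centers", {
  spec <- gel_spec(shape = c(64, 64),
                   spots = list(spot_spec(20, 20, 12000, 3.5),
                                spot_spec(45, 44, 12000, 3.5)))
  px <- render_gel(spec)$gel$pixels
  sm <- symmetry_map(px, scale = 6)
  rs <- watershed_regions(sm)
  l1 <- rs$labels[20, 20]; l2 <- rs$labels[45, 44]
  expect_true(l1 != l2)
  # the recorded maxima of those regions are the spot cores
  t1 <- rs$table[rs$table$id == l1, ]
  expect_lt(sqrt((t1$row - 20)^2 + (t1$col - 20)^2), 1.01)
  # per-region maximum bookkeeping holds for every region
  for (i in seq_len(nrow(rs$table))) {
    id <- rs$table$id[i]
    expect_equal(rs$table$smax[i], max(rs$S_R[rs$labels == id]))
  }
})

test_that("LoG filter keeps dark pits, removes bright bumps, matches the
           second-difference oracle", {
  bg <- 40000
  px <- matrix(bg, 96, 96)
  d <- outer((1:96 - 30)^2, (1:96 - 30)^2, "+")
  px <- px - 12000 * exp(-d / (2 * 16))              # dark pit at (30,30)
  d2 <- outer((1:96 - 70)^2, (1:96 - 64)^2, "+")
  px <- px + 12000 * exp(-d2 / (2 * 16))             # bright bump
  labels <- matrix(1L, 96, 96); labels[49:96, ] <- 2L
  rs <- gelmap2d:::region_set(labels, px * 0)
  rs$table$row <- c(30, 70); rs$table$col <- c(30, 64)
  out <- log_filter(px, rs, sigma = 4)
  expect_identical(out$table$row, 30)                # pit retained
  expect_gt(out$table$i_log, 0)
  expect_equal(second_diff_sign(px, 4, 30, 30), 1)   # oracle agrees
  expect_equal(second_diff_sign(px, 4, 70, 64), -1)
  expect_error(log_filter(px, rs, sigma = -1), "positive")
})

test_that("LoG filter separates pits from bright artifacts on a full gel", {
  set.seed(9)
  spots <- lapply(1:10, function(i)
    spot_spec(20 + 25 * ((i - 1) %% 4), 25 + 50 * ((i - 1) %/% 4),
              runif(1, 8000, 20000), runif(1, 3, 4.5)))
  r <- render_gel(gel_spec(shape = c(128, 192), spots = spots))
  px <- r$gel$pixels
  # paint three bright artifacts (e.g. scanner glare)
  bright <- cbind(c(110, 40, 100), c(40, 170, 140))
  for (i in 1:3) {
    d <- outer((seq_len(128) - bright[i, 1])^2,
               (seq_len(192) - bright[i, 2])^2, "+")
    px <- px + 12000 * exp(-d / (2 * 12))
  }
  px <- pmin(px, 65535)
  sm <- symmetry_map(px, scale = 6)
  rs <- watershed_regions(sm)
  out <- log_filter(px, rs, sigma = 4)
  tr <- r$truth$centers
  kept_spot <- vapply(seq_len(10), function(i)
    rs$labels[round(tr$row[i]), round(tr$col[i])] %in% out$table$id, TRUE)
  expect_true(all(kept_spot))
  kept_bright <- vapply(1:3, function(i)
    rs$labels[bright[i, 1], bright[i, 2]] %in% out$table$id, TRUE)
  expect_false(any(kept_bright))
})

test_that("region features follow their defining identities", {
  # constant region: contour max = min, so feature 2 is exactly 0
  px <- matrix(1000, 48, 48)
  labels <- matrix(1L, 48, 48); labels[25:48, ] <- 2L
  rs <- gelmap2d:::region_set(labels, px * 0)
  f <- region_features(px, rs, log_sigma = 3)
  expect_equal(unname(f[, "contour_range"]), c(0, 0))

  # LoG feature is larger for a deeper pit of the same shape
  mk <- function(amp) {
    spec <- gel_spec(shape = c(64, 64),
                     spots = list(spot_spec(32, 32, amp, 4)),
                     bg_base = 50000, bg_coefs = c(0, 0, 0, 0))
    p <- render_gel(spec)$gel$pixels
    l <- matrix(1L, 64, 64)
    r <- gelmap2d:::region_set(l, p * 0)
    region_features(p, r, log_sigma = 4)
  }
  f_deep <- mk(20000); f_shallow <- mk(6000)
  expect_gt(f_deep[, "log_max"], f_shallow[, "log_max"])

  # determinism and finiteness
  f2 <- mk(20000)
  expect_identical(f_deep, f2)
  expect_true(all(is.finite(f_deep)))
})

test_that("classifier rejects malformed features and decodes codes", {
  cl <- test_classifier()
  expect_error(classify_regions(matrix(0, 2, 4), cl), "dimension")
  p <- labeled_regions(5, seed = 31)
  f <- gelmap2d:::patch_features(p)
  pred <- classify_regions(f, cl)
  expect_true(all(pred$class %in% c("C1", "C2", "C3")))
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
})

test_that("classifier weights survive a JSON round-trip", {
  cl <- test_classifier()
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(cl, f)
  cl2 <- load_classifier(f)
  p <- labeled_regions(5, seed = 13)
  feats <- gelmap2d:::patch_features(p)
  expect_equal(classify_regions(feats, cl),
               classify_regions(feats, cl2))
})

test_that("segment edits preserve the partition and are invertible", {
  spec <- gel_spec(shape = c(64, 64),
                   spots = list(spot_spec(20, 20, 12000, 3.5),
                                spot_spec(45, 44, 12000, 3.5)))
  px <- render_gel(spec)$gel$pixels
  rs <- watershed_regions(symmetry_map(px, scale = 6))
  part_ok <- function(r) {
    all(r$labels >= 1) && sum(r$table$area) == length(r$labels)
  }
  expect_true(part_ok(rs))
  ids <- rs$table$id[order(-rs$table$area)][1:2]
  if (!gelmap2d:::regions_adjacent(rs$labels, ids[1], ids[2])) {
    nb <- gelmap2d:::neighbor_votes(rs$labels, ids[1])
    ids[2] <- as.integer(names(nb)[1])
  }
  a1 <- sum(rs$labels == ids[1]); a2 <- sum(rs$labels == ids[2])
  merged <- edit_segments(rs, "merge", list(ids = ids))
  expect_true(part_ok(merged))
  expect_equal(sum(merged$labels == ids[1]), a1 + a2)

  # split then re-merge restores the original mask
  big <- merged$table$id[which.max(merged$table$area)]
  m0 <- merged$labels == big
  ctr <- which(m0, arr.ind = TRUE)
  line <- c(mean(ctr[, 1]), mean(ctr[, 2]) - 5,
            mean(ctr[, 1]) + 1, mean(ctr[, 2]) + 5)
  sp <- edit_segments(merged, "split", list(id = big, line = line))
  expect_true(part_ok(sp))
  newid <- setdiff(sp$table$id, merged$table$id)
  back <- edit_segments(sp, "merge", list(ids = c(big, newid)))
  expect_identical(back$labels == big, m0)

  # remove returns the area to a neighbor and drops the region
  rm1 <- edit_segments(rs, "remove", list(id = ids[2]))
  expect_true(part_ok(rm1))
  expect_equal(nrow(rm1$table), nrow(rs$table) - 1L)
  expect_false(ids[2] %in% rm1$table$id)

  # add carves a polygon into a new region
  poly <- data.frame(row = c(5, 5, 15, 15), col = c(5, 15, 15, 5))
  ad <- edit_segments(rs, "add", list(polygon = poly))
  expect_true(part_ok(ad))
  expect_equal(nrow(ad$table), nrow(rs$table) + 1L)

  # errors: unknown ids, non-crossing split line
  expect_error(edit_segments(rs, "merge", list(ids = c(ids[1], 9999L))),
               "unknown region")
  expect_error(edit_segments(rs, "split",
                             list(id = ids[1], line = c(-50, -50, -49, -50))),
               "does not cross")
  expect_gt(length(ad$log), 0)
})

test_that("flag_uncertain lists C2 regions and low-confidence C1", {
  tab <- data.frame(id = 1:4, class = c("C1", "C2", "C1", "C3"),
                    confidence = c(0.9, 0.9, 0.05, 0.9))
  rs <- structure(list(table = tab), class = "region_set")
  expect_identical(flag_uncertain(rs, conf_threshold = 0.2), c(2L, 3L))
  tab2 <- data.frame(id = 1:2, class = c("C1", "C1"),
                     confidence = c(0.9, 0.8))
  rs2 <- structure(list(table = tab2), class = "region_set")
  expect_length(flag_uncertain(rs2, conf_threshold = 0.2), 0)
})

test_that("a half-cropped spot at the gel edge is flagged for review", {
  cl <- test_classifier()
  set.seed(77)
  p <- labeled_regions(6, seed = 77)
  c2 <- p[vapply(p, function(x) x$class, "") == "C2"]
  f <- gelmap2d:::patch_features(c2)
  pred <- classify_regions(f, cl)
  tab <- data.frame(id = seq_len(nrow(pred)), class = pred$class,
                    confidence = pred$confidence)
  rs <- structure(list(table = tab), class = "region_set")
  flagged <- flag_uncertain(rs, conf_threshold = 0.2)
  expect_gte(length(flagged), ceiling(0.8 * nrow(tab)))
})
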