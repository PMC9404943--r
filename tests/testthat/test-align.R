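make_pair_gels <- function(seed = 3, dshift = c(-12, 7)) {
  spots <- grid_spots(seed = 7, amp_lo = 6000, amp_hi = 25000)
  spA <- gel_spec(shape = c(192L, 256L), spots = spots,
                  gaussian_noise_sd = 300, impulse_rate = 0.005, seed = seed)
  spots2 <- lapply(spots, function(s)
    spot_spec(s$row + dshift[1], s$col + dshift[2], s$amplitude,
              s$sigma_r, s$sigma_c))
  spB <- gel_spec(shape = c(192L, 256L), spots = spots2,
                  gaussian_noise_sd = 300, impulse_rate = 0.005,
                  seed = seed + 1)
  list(A = median_smooth(render_gel(spA)$gel, 3),
       B = median_smooth(render_gel(spB, allow_edge = TRUE)$gel, 3))
}

test_that("landmarks match a gel to itself with zero residual", {
  g <- make_pair_gels()$A
  lm <- initial_landmarks(g, g)
  expect_gte(nrow(lm), 10)
  expect_equal(lm$rA, lm$rB)
  expect_equal(lm$cA, lm$cB)
})

test_that("landmarks recover a known translation", {
  gl <- make_pair_gels(dshift = c(-12, 7))
  lm <- initial_landmarks(gl$A, gl$B)
  expect_gte(nrow(lm), 3)
  consistent <- abs(lm$rB - lm$rA + 12) <= 2 & abs(lm$cB - lm$cA - 7) <= 2
  expect_gte(mean(consistent), 0.9)
})

test_that("matching a gel against pure noise fails loudly", {
  gl <- make_pair_gels()
  nz <- render_gel(gel_spec(shape = c(192L, 256L),
                            gaussian_noise_sd = 500, seed = 9))$gel
  expect_error(initial_landmarks(gl$A, median_smooth(nz, 3)),
               "insufficient reliable landmarks")
})

test_that("rigid fit recovers exact transforms and resists outliers", {
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(2)
  P <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  Q <- t(R %*% t(P)) + matrix(c(5, 3), 12, 2, byrow = TRUE)
  pairs <- data.frame(rA = P[, 1], cA = P[, 2], rB = Q[, 1], cB = Q[, 2])
  fit <- fit_rigid(pairs)
  expect_lt(abs(fit$theta - th), 1e-6)
  expect_lt(max(abs(fit$t - c(5, 3))), 1e-6)

  # identity correspondence gives the identity transform
  idp <- data.frame(rA = P[, 1], cA = P[, 2], rB = P[, 1], cB = P[, 2])
  idf <- fit_rigid(idp)
  expect_lt(abs(idf$theta), 1e-9)
  expect_lt(max(abs(idf$t)), 1e-9)

  # two gross outliers among ten true pairs barely move the estimate
  Q2 <- Q; Q2[1, ] <- Q2[1, ] + c(40, -30); Q2[2, ] <- Q2[2, ] + c(-25, 33)
  fit2 <- fit_rigid(data.frame(rA = P[, 1], cA = P[, 2],
                               rB = Q2[, 1], cB = Q2[, 2]))
  expect_lt(abs(fit2$theta - th) * 180 / pi, 0.1)

  # equivariance: pre-rotating both point sets rotates the estimate
  R2 <- matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2)
  Pr <- t(R2 %*% t(P)); Qr <- t(R2 %*% t(Q))
  fr <- fit_rigid(data.frame(rA = Pr[, 1], cA = Pr[, 2],
                             rB = Qr[, 1], cB = Qr[, 2]))
  expect_lt(abs(fr$theta - th), 1e-6)
})

test_that("TPS interpolates exactly, reproduces affine maps, recovers warps", {
  set.seed(1)
  A <- cbind(runif(25, 10, 180), runif(25, 10, 240))
  warpf <- function(p) cbind(p[, 1] + 3 * sin(p[, 2] / 40),
                             p[, 2] + 2 * cos(p[, 1] / 30))
  B <- warpf(A)
  pairs <- data.frame(rA = A[, 1], cA = A[, 2], rB = B[, 1], cB = B[, 2])
  m <- fit_tps(pairs, lambda = 0)
  expect_lt(max(abs(tps_apply(m, A) - B)), 1e-9)

  gr <- as.matrix(expand.grid(seq(40, 150, by = 10), seq(40, 210, by = 10)))
  err <- sqrt(rowSums((tps_apply(m, gr) - warpf(gr))^2))
  expect_lt(sqrt(mean(err^2)), 0.5)

  Aff <- cbind(A[, 1] * 1.1 + A[, 2] * 0.05 + 3,
               A[, 2] * 0.95 - A[, 1] * 0.02 - 7)
  m2 <- fit_tps(data.frame(rA = A[, 1], cA = A[, 2],
                           rB = Aff[, 1], cB = Aff[, 2]))
  expect_lt(m2$bending_energy, 1e-12)
  grA <- cbind(gr[, 1] * 1.1 + gr[, 2] * 0.05 + 3,
               gr[, 2] * 0.95 - gr[, 1] * 0.02 - 7)
  expect_lt(max(abs(tps_apply(m2, gr) - grA)), 1e-9)

  expect_error(fit_tps(pairs[1:2, ]), "at least 3")
  dup <- pairs; dup$rA[2] <- dup$rA[1]; dup$cA[2] <- dup$cA[1]
  expect_error(fit_tps(dup), "duplicate")
})

test_that("pair_spots is one-to-one and reports unmatched spots", {
  sA <- data.frame(spot_id = 1:4, row = c(10, 30, 50, 70),
                   col = c(10, 30, 50, 70))
  self <- pair_spots(sA, sA, NULL, gate = 3)
  expect_equal(nrow(self$matches), 4)
  expect_equal(self$matches$residual, rep(0, 4))

  sB <- rbind(sA, data.frame(spot_id = 5, row = 90, col = 90))
  mt <- pair_spots(sA, sB, NULL, gate = 3)
  expect_equal(mt$unmatched_B, 5)
  expect_length(mt$unmatched_A, 0)
  expect_equal(anyDuplicated(mt$matches$spot_id_B), 0)

  empty <- pair_spots(sA[0, ], sB, NULL)
  expect_equal(nrow(empty$matches), 0)
  expect_equal(empty$unmatched_B, sB$spot_id)
})

test_that("match edits keep the one-to-one invariant with an audit log", {
  sA <- data.frame(spot_id = 1:3, row = c(10, 30, 50), col = c(10, 30, 50))
  mt <- pair_spots(sA, sA, NULL, gate = 3)
  m1 <- edit_matches(mt, "remove", c(2, 2))
  expect_equal(nrow(m1$matches), 2)
  expect_true(2 %in% m1$unmatched_A)
  m2 <- edit_matches(m1, "add", c(2, 2), spotsA = sA, spotsB = sA)
  expect_setequal(paste(m2$matches$spot_id_A, m2$matches$spot_id_B),
                  paste(mt$matches$spot_id_A, mt$matches$spot_id_B))
  expect_length(m2$unmatched_A, 0)

  # adding a conflicting pair evicts the conflict with a warning
  expect_warning(m3 <- edit_matches(m2, "add", c(1, 2),
                                    spotsA = sA, spotsB = sA),
                 "conflicting")
  expect_equal(anyDuplicated(m3$matches$spot_id_B), 0)
  expect_error(edit_matches(m2, "add", c(99, 1), spotsA = sA, spotsB = sA),
               "unknown")
  expect_gt(length(attr(m3, "log")), 0)
})
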