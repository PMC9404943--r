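test_that("spot volume matches the truncated-Gaussian integral and is linear", {
  mk_signal <- function(amp) {
    spec <- gel_spec(shape = c(96, 96),
                     spots = list(spot_spec(48, 48, amp, 4)),
                     bg_base = 50000, bg_coefs = c(0, 0, 0, 0))
    subtract_background(render_gel(spec)$gel, 20)
  }
  d2 <- outer((1:96 - 48)^2, (1:96 - 48)^2, "+")
  mask3 <- d2 <= (3 * 4)^2
  v <- spot_volume(mk_signal(1000), mask3, local_baseline = FALSE)
  # mass of a symmetric Gaussian inside 3 sigma: 1 - exp(-9/2)
  expect_equal(v, 2 * pi * 1000 * 16 * (1 - exp(-4.5)), tolerance = 0.02)
  v2 <- spot_volume(mk_signal(2000), mask3, local_baseline = FALSE)
  expect_equal(v2 / v, 2, tolerance = 0.02)
  expect_equal(spot_volume(matrix(0, 8, 8), matrix(TRUE, 8, 8)), 0)
  expect_error(spot_volume(matrix(0, 8, 8), matrix(FALSE, 8, 8)), "empty")
})

test_that("normalization sums to one and is exposure-invariant", {
  expect_equal(normalize_quantities(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_quantities(7), 1)
  v <- runif(10, 1, 100)
  expect_equal(normalize_quantities(v), normalize_quantities(3.7 * v))
  expect_error(normalize_quantities(numeric(0)), "no spots")
  expect_error(normalize_quantities(c(0, 0)), "zero")
})

test_that("signed fold-change follows the table convention", {
  expect_equal(fold_change(2, 1), 2)
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(1 / 12.51, 1), -12.51, tolerance = 1e-12)
  expect_error(fold_change(0, 1), "present-only")
})

test_that("fold-change is antisymmetric with |FC| >= 1 on random pairs", {
  set.seed(5)
  q1 <- runif(1e4, 1e-4, 1); q2 <- runif(1e4, 1e-4, 1)
  fc12 <- fold_change(q1, q2); fc21 <- fold_change(q2, q1)
  expect_true(all(abs(fc12) >= 1))
  neq <- q1 != q2
  expect_equal(fc12[neq], -fc21[neq])
  expect_true(all(fc12[!neq] == 1))
})

test_that("the 2-fold rule is strict at the boundary", {
  expect_true(call_changed(-12.51))
  expect_false(call_changed(-1.57))
  expect_false(call_changed(2))
  expect_false(call_changed(-2))
  expect_true(call_changed(2.0001))
  expect_true(call_changed(3, threshold = 2.5))
})

test_that("group shares sum to 100 and reproduce the isoform split", {
  expect_equal(group_shares(c(0.682, 0.318)), c(68.2, 31.8))
  expect_equal(group_shares(5), 100)
  set.seed(8)
  df <- data.frame(group = rep(1:20, each = 3),
                   quantity = runif(60, 0.01, 1))
  out <- group_shares(df)
  sums <- tapply(out$share_pct, out$group, sum)
  expect_true(all(abs(sums - 100) <= 0.1))
  # invariance to rescaling the whole gel
  df2 <- df; df2$quantity <- df2$quantity * 13
  expect_equal(group_shares(df2)$share_pct, out$share_pct)
  expect_error(group_shares(c(0, 0)), "zero")
})

test_that("compare_gels joins pairs, flags changes, lists one-sided spots", {
  qA <- data.frame(spot_id = 1:3, quantity = c(0.5, 0.3, 0.2))
  qB <- data.frame(spot_id = 11:14,
                   quantity = c(0.25, 0.3, 0.05, 0.4))
  matching <- list(matches = data.frame(spot_id_A = 1:3,
                                        spot_id_B = 11:13,
                                        residual = c(0, 0, 0)),
                   unmatched_A = integer(0), unmatched_B = 14L)
  cmp <- compare_gels(qA, qB, matching)
  paired <- cmp[cmp$status == "paired", ]
  expect_equal(paired$fc[paired$spot_id_A == 1], 2)
  expect_equal(paired$fc[paired$spot_id_A == 2], 1)
  expect_equal(paired$fc[paired$spot_id_A == 3], 4)
  expect_equal(paired$changed, c(FALSE, FALSE, TRUE),
               ignore_attr = TRUE)
  bonly <- cmp[cmp$status == "B-only", ]
  expect_equal(bonly$spot_id_B, 14)
  expect_true(is.na(bonly$fc))

  # identical gels through the identity matching: all +1, none changed
  self <- compare_gels(qA, qA,
                       list(matches = data.frame(spot_id_A = 1:3,
                                                 spot_id_B = 1:3,
                                                 residual = 0),
                            unmatched_A = integer(0),
                            unmatched_B = integer(0)))
  expect_true(all(self$fc == 1))
  expect_false(any(self$changed))

  bad <- matching; bad$matches$spot_id_A[1] <- 99
  expect_error(compare_gels(qA, qB, bad), "unknown")
})
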