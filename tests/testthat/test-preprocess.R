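test_that("median smoothing removes isolated impulses and fixes nothing else", {
  m <- matrix(100, 50, 50)
  m[25, 25] <- 65535
  out <- median_smooth(gel_image(m), 3)
  expect_true(all(out$pixels == 100))
  expect_error(median_smooth(gel_image(m), 4), "odd")

  # constant images are fixed points; shape and non-negativity preserved
  cm <- median_smooth(gel_image(matrix(7, 40, 30)), 5)
  expect_identical(cm$pixels, matrix(7, 40, 30))
  set.seed(1)
  g <- gel_image(matrix(runif(900, 0, 65535), 30))
  sm <- median_smooth(g, 3)
  expect_equal(dim(sm$pixels), dim(g$pixels))
  expect_true(all(sm$pixels >= 0))
})

test_that("median smoothing recovers the clean gel under impulse noise", {
  spots <- list(spot_spec(40, 40, 15000, 4), spot_spec(70, 90, 10000, 4))
  clean <- render_gel(gel_spec(shape = c(112, 128), spots = spots))
  noisy <- render_gel(gel_spec(shape = c(112, 128), spots = spots,
                               gaussian_noise_sd = 200,
                               impulse_rate = 0.01, seed = 8))
  sm <- median_smooth(noisy$gel, 3)
  resid <- abs(sm$pixels - clean$gel$pixels)
  # residual stays at the Gaussian-noise level: every impulse is gone
  expect_lt(max(resid), 6 * 200)
  # spot minima barely move
  for (i in 1:2) {
    tr <- clean$truth$centers[i, ]
    win <- sm$pixels[(tr$row - 5):(tr$row + 5), (tr$col - 5):(tr$col + 5)]
    idx <- which(win == min(win), arr.ind = TRUE)[1, ]
    expect_lt(max(abs(idx - 6)), 1.5)
  }
})

test_that("top-hat removes constant and ramp backgrounds, keeps pit depth", {
  cst <- subtract_background(gel_image(matrix(30000, 120, 120)), 20)
  expect_true(all(cst$pixels == 0))

  ramp <- outer(rep(1, 120), seq(20000, 40000, length.out = 120))
  th <- subtract_background(gel_image(ramp), 20)
  expect_lt(max(th$pixels), 0.05 * 20000)

  spec <- gel_spec(shape = c(120, 120),
                   spots = list(spot_spec(60, 60, 10000, 4)),
                   bg_base = 40000, bg_coefs = c(0, 0, 0, 0))
  pit <- subtract_background(render_gel(spec)$gel, 20)
  expect_equal(max(pit$pixels), 10000, tolerance = 0.02)
  expect_error(subtract_background(gel_image(ramp), 0), "positive")
})

test_that("distortion score D orders gels by applied distortion", {
  g0 <- median_smooth(render_gel(row_gel_spec(c(0, 0, 0)))$gel, 3)
  g2 <- median_smooth(render_gel(row_gel_spec(c(0, 0, 2)))$gel, 3)
  g5 <- median_smooth(render_gel(row_gel_spec(c(0, 0, 5)))$gel, 3)
  p0 <- distortion_profile(g0)
  p2 <- distortion_profile(g2)
  p5 <- distortion_profile(g5)
  expect_lt(p0$D, 0.3)            # straight rows score at the noise floor
  expect_lt(p0$D, p2$D)
  expect_lt(p2$D, p5$D)
  .cache$dist_gels <- list(g0 = g0, g2 = g2, g5 = g5, p5 = p5, p0 = p0)
})

test_that("D is invariant to a whole-image vertical shift", {
  g0 <- .cache$dist_gels$g0
  shifted <- gel_image(g0$pixels[c(6:192, rep(192, 5)), ])
  pS <- distortion_profile(shifted)
  expect_lt(abs(pS$D - .cache$dist_gels$p0$D), 0.15)
})

test_that("an image without row structure yields a diagnostic error", {
  flat <- gel_image(matrix(30000, 192, 256))
  expect_error(distortion_profile(flat), "no horizontal contours")
})

test_that("select_master picks the least distorted gel, ties to the first", {
  gl <- .cache$dist_gels
  expect_identical(select_master(list(gl$g5, gl$g0, gl$g2)), 2L)
  expect_identical(select_master(list(gl$g0, gl$g0)), 1L)
  expect_warning(idx <- select_master(list(gl$g0)), "single gel")
  expect_identical(idx, 1L)
})

test_that("straighten recovers the applied shift field and flattens D", {
  gl <- .cache$dist_gels
  s5 <- straighten(gl$g5, gl$p5)
  p5s <- distortion_profile(s5)
  expect_lt(p5s$D, 0.25 * gl$p5$D)
  # recovered field matches the applied parabola up to a constant
  sf <- attr(s5, "shift_field")
  u <- 2 * (seq_len(256) - 1) / 255 - 1
  true_shift <- 5 * u^2
  expect_lt(sqrt(mean(((sf - mean(sf)) - (true_shift - mean(true_shift)))^2)),
            0.5)
  # straightening an already straight gel is near the identity
  s0 <- straighten(gl$g0, gl$p0)
  expect_lt(max(abs(attr(s0, "shift_field"))), 0.6)
  # a second pass changes D by little compared to the first reduction
  p2nd <- distortion_profile(straighten(s5, p5s))
  expect_lt(abs(p2nd$D - p5s$D), 0.1 * (gl$p5$D - p5s$D))
})
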