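test_that("forward decomposition: zero volume, symmetry, and dominance", {
  z <- volume(array(0, c(16, 16, 16)))
  sc <- swd_forward(z, 2, 2, center = c(7.5, 7.5, 7.5), R = 7)
  expect_true(all(Mod(sc$c) == 0))
  expect_equal(sc$fit_residual_rms, 0)

  # a single-mode band-limited phantom is recovered with one dominant term
  bl <- band_limited_phantom(shape = c(32, 32, 32), L = 3, N = 2,
                             terms = list(c(1, 2, 0, 1)))
  fit <- swd_forward(bl$vol, 3, 2, center = bl$center, R = bl$R)
  dom <- Mod(fit$c[1, 3, 3])
  rest <- fit$c; rest[1, 3, 3] <- 0
  expect_lt(max(Mod(rest)) / dom, 1e-3)

  # spherically symmetric ball: all l > 0 coefficients negligible
  ball <- make_ball(32, radius = 10)
  fb <- swd_forward(ball, 3, 3)
  e0 <- sum(Mod(fb$c[, 1, ])^2)
  expect_lt(sum(Mod(fb$c)^2) - e0, 1e-10 * e0)

  # conjugate symmetry for real input
  vv <- make_ball(24, center = c(10, 12, 11), radius = 7)
  fv <- swd_forward(vv, 3, 2)
  for (l in 1:3) for (m in 1:l) for (n in 1:2)
    expect_lt(Mod(fv$c[n, l + 1, -m + l + 1] -
                    (-1)^m * Conj(fv$c[n, l + 1, m + l + 1])), 1e-8)
})

test_that("synthesis is linear and round trips band-limited input", {
  bl <- band_limited_phantom(shape = c(32, 32, 32), L = 3, N = 2)
  z <- bl$coef; z$c[] <- 0
  expect_true(all(swd_inverse(z, bl$vol)$data == 0))
  two <- bl$coef; two$c <- 2 * two$c
  expect_equal(swd_inverse(two, bl$vol)$data, 2 * bl$vol$data,
               tolerance = 1e-12)
  fit <- swd_forward(bl$vol, 3, 2, center = bl$center, R = bl$R,
                     method = "least_squares")
  rec <- swd_inverse(fit, bl$vol)
  expect_lt(rel_rms(rec$data, bl$vol$data), 1e-6)
})

test_that("Parseval/Bessel inequality holds for projection fits", {
  v <- textured_ball(32, radius = 11, seed = 9)
  ctr <- c(15.5, 15.5, 15.5); R <- 14
  grid <- swdmorph:::default_swd_grid(4, 3, ctr, R)
  sc <- swd_forward(v, 4, 3, center = ctr, R = R, method = "projection",
                    grid = grid)
  pts <- swdmorph:::grid_points(grid)
  f <- as.numeric(sample_volume_spherical(v, grid))
  expect_lte(swd_energy(sc), sum(pts$w * f^2) * (1 + 1e-9))
})

test_that("projection converges to least squares as the grid refines", {
  v <- make_ball(32, radius = 10, smooth_edge = 2)
  ctr <- c(15.5, 15.5, 15.5); R <- 13
  diffs <- sapply(c(1, 2), function(k) {
    g <- spherical_grid(ctr, R, 8 * k, 4 * k, 9 * k)
    p <- swd_forward(v, 3, 2, center = ctr, R = R, method = "projection",
                     grid = g)
    l <- swd_forward(v, 3, 2, center = ctr, R = R, method = "least_squares",
                     samples = "grid", grid = g)
    max(Mod(p$c - l$c))
  })
  expect_lt(diffs[2], 0.55 * diffs[1])  # halves or better
})

test_that("model-order selection finds the cubic and its noisy behaviour", {
  s <- make_polynomial_series()  # fixed cubic, noiseless
  mo <- select_model_order(s, "polynomial", 0:10)
  expect_equal(mo$selected_order, 3)
  expect_lt(mo$rms[mo$orders == 3], 1e-9)
  # nested-model monotonicity
  expect_true(all(diff(mo$rms) <= 1e-12))

  # per-order least-squares oracle: refit each order independently
  oracle <- vapply(0:10, function(p) {
    X <- outer(s$x, 0:p, `^`)
    sqrt(mean(stats::lm.fit(X, s$y)$residuals^2))
  }, numeric(1))
  expect_equal(mo$rms, oracle, tolerance = 1e-10)

  # noise at sigma = 2 * mean abs deviation: rms keeps decreasing past 3
  sig <- 2 * mean(abs(s$y - mean(s$y)))
  sn <- make_polynomial_series(sigma = sig, seed = 1)
  mn <- select_model_order(sn, "polynomial", 0:10)
  expect_true(all(diff(mn$rms[mn$orders >= 3]) < 0))
  oracle_n <- vapply(0:10, function(p) {
    X <- outer(sn$x, 0:p, `^`)
    sqrt(mean(stats::lm.fit(X, sn$y)$residuals^2))
  }, numeric(1))
  expect_equal(mn$rms, oracle_n, tolerance = 1e-10)
  expect_true(mn$selected_order %in% mn$orders)

  expect_error(select_model_order(s, "polynomial", 3), "at least 2")
  expect_error(select_model_order(list(x = 1:3, y = 1:3), "polynomial", 0:10),
               "more samples")
})

test_that("constant volume selects angular order 0", {
  ball <- make_ball(24, radius = 8)
  mo <- select_model_order(ball, "swd_angular", 0:4, n_radial = 3)
  expect_equal(mo$selected_order, 0)
})

test_that("spectral smoothing damps energy monotonically to the DC mode", {
  v <- textured_ball(24, radius = 8, seed = 4)
  sc <- swd_forward(v, 3, 3)
  expect_identical(weighted_smoothing(sc, 0)$c, sc$c)
  en <- vapply(c(0, 0.003, 0.01, 0.05, 0.2),
               function(s) swd_energy(weighted_smoothing(sc, s)), numeric(1))
  expect_true(all(diff(en) <= 0))
  big <- weighted_smoothing(sc, 50)
  rel <- Mod(big$c) / max(Mod(big$c))
  rel[1, 1, 1] <- 0
  expect_lt(max(rel), 1e-12)
})

test_that("shape complexity reports the corrugation degree", {
  ball <- make_ball(48, radius = 16)
  expect_equal(as.integer(shape_complexity(ball, orders = 0:6)), 0)
  cb <- make_corrugated_ball(48, radius = 16, l = 4, amp = 0.15)
  c4 <- shape_complexity(cb, orders = 0:6)
  expect_equal(as.integer(c4), 4)
  expect_equal(attr(c4, "n_coefficients"), 4 * (4 + 1)^2)
  # complexity does not decrease when finer detail is superimposed
  curve_smooth <- attr(shape_complexity(cb, orders = 0:6), "curve")
  expect_lte(curve_smooth$selected_order, 6)
})

test_that("coefficient container round trips through JSON", {
  td <- withr::local_tempdir()
  v <- make_ball(20, radius = 6, smooth_edge = 1)
  sc <- swd_forward(v, 2, 2)
  p <- file.path(td, "c.json")
  write_swd(sc, p)
  r <- read_swd(p)
  expect_equal(r$c, sc$c, tolerance = 1e-12)
  expect_equal(r$center, sc$center)
  expect_equal(r$k, sc$k)
  expect_equal(r$L, sc$L)
  rec1 <- swd_inverse(sc, v)
  rec2 <- swd_inverse(r, v)
  expect_equal(rec1$data, rec2$data, tolerance = 1e-12)
})
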