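test_that("Gaussian coupling kernel preserves mass and matches its moments", {
  d <- c(33, 33, 33)
  f <- array(0, c(d, 3)); f[17, 17, 17, ] <- 1
  S <- solve(diag(c(4, 2.25, 1)))  # covariance diag(2^2, 1.5^2, 1^2)
  sm <- esp_kernel(f, S)
  g <- sm[, , , 1]
  expect_equal(sum(g), 1, tolerance = 1e-9)
  off <- seq_len(33) - 17
  m2 <- c(sum(g * array(rep(off^2, 33 * 33), d)),
          sum(g * array(rep(rep(off^2, each = 33), 33), d)),
          sum(g * array(rep(off^2, each = 33 * 33), d)))
  expect_equal(m2, c(4, 2.25, 1), tolerance = 0.02 * 4)
  # constant field unchanged (normalization)
  cf <- array(5, c(9, 9, 9, 3))
  expect_equal(esp_kernel(cf, 2), cf, tolerance = 1e-12)
  # high-frequency checkerboard loses energy
  ch <- array((-1)^(outer(outer(1:9, 1:9, `+`), 1:9, `+`)), c(9, 9, 9))
  chf <- array(ch, c(9, 9, 9, 3))
  expect_lt(sum(esp_kernel(chf, 1.5)^2), 0.1 * sum(chf^2))
  expect_error(esp_kernel(cf, matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive definite")
  expect_error(esp_kernel(cf, matrix(rnorm(9), 3)), "symmetric")
})

test_that("full-covariance kernel path agrees with the separable path", {
  set.seed(2)
  f <- array(rnorm(17^3), c(17, 17, 17, 1))[, , , 1]
  Sd <- diag(1 / c(2, 2, 2)^2)
  a <- esp_kernel(array(f, c(17, 17, 17, 3)), Sd)[, , , 1]
  Sfull <- Sd; Sfull[1, 2] <- Sfull[2, 1] <- 1e-9  # forces the FFT path
  b <- esp_kernel(array(f, c(17, 17, 17, 3)), Sfull)[, , , 1]
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("matching force is zero at alignment, points toward it, and is scale-invariant in direction", {
  f <- array(0, c(16, 6, 6)); f[9:16, , ] <- 1
  expect_true(all(matching_force(f, f) == 0))
  m <- array(0, c(16, 6, 6)); m[10:16, , ] <- 1  # shifted +1 along x
  F <- matching_force(f, m)
  # pull-back warp must sample the moving image at larger x
  expect_gt(F[9, 3, 3, 1], 0)
  Fs <- matching_force(5 * f, 5 * m)
  nz <- abs(F[, , , 1]) > 1e-9
  expect_true(all(sign(Fs[, , , 1][nz]) == sign(F[, , , 1][nz])))
})

test_that("symplectic step: drift, exact unit Jacobian, reversibility", {
  st <- phase_space_state(c(3, 3, 3))
  st$p[] <- 0.25
  zero <- array(0, c(3, 3, 3, 3))
  s1 <- symplectic_step(st, zero, dt = 0.4, damping = 0)
  expect_equal(s1$q, st$q + 0.4 * st$p, tolerance = 1e-14)
  expect_equal(s1$p, st$p, tolerance = 1e-14)

  # trilinearly interpolated random smooth force field; the one-particle
  # (q, p) map is piecewise linear, so central differences are exact up
  # to rounding
  set.seed(3)
  Fg <- esp_kernel(array(rnorm(9^3 * 3), c(9, 9, 9, 3)), 1 / 1.5^2 * diag(3))
  force_at <- function(q) {
    vapply(1:3, function(cpt)
      swdmorph:::interp_trilinear(Fg[, , , cpt], q[1], q[2], q[3]),
      numeric(1))
  }
  stepmap <- function(z, dt = 0.37) {
    st <- phase_space_state(c(1, 1, 1))
    st$q[1, 1, 1, ] <- z[1:3]; st$p[1, 1, 1, ] <- z[4:6]
    Fa <- array(force_at(z[1:3]), c(1, 1, 1, 3))
    out <- symplectic_step(st, Fa, dt = dt, damping = 0)
    c(out$q[1, 1, 1, ], out$p[1, 1, 1, ])
  }
  for (z0 in list(c(3.3, 4.7, 5.1, 0.21, -0.4, 0.13),
                  c(2.2, 6.1, 3.4, -0.11, 0.3, 0.05))) {
    h <- 1e-4
    J <- matrix(0, 6, 6)
    for (j in 1:6) {
      e <- rep(0, 6); e[j] <- h
      J[, j] <- (stepmap(z0 + e) - stepmap(z0 - e)) / (2 * h)
    }
    expect_lt(abs(det(J) - 1), 1e-10)
  }

  # reversibility: kick-drift forward, momentum flip, adjoint drift-kick
  # back retraces the trajectory exactly
  z0 <- c(3.3, 4.7, 5.1, 0.21, -0.4, 0.13)
  dt <- 0.37
  s0 <- phase_space_state(c(1, 1, 1))
  s0$q[1, 1, 1, ] <- z0[1:3]; s0$p[1, 1, 1, ] <- z0[4:6]
  s1 <- symplectic_step(s0, array(force_at(z0[1:3]), c(1, 1, 1, 3)), dt)
  s1$p <- -s1$p
  qd <- s1$q[1, 1, 1, ] + dt * s1$p[1, 1, 1, ]  # drifted position = q0
  s2 <- symplectic_step(s1, array(force_at(qd), c(1, 1, 1, 3)), dt,
                        variant = "drift_kick")
  expect_lt(max(abs(s2$q[1, 1, 1, ] - z0[1:3])), 1e-10)
  expect_lt(max(abs(-s2$p[1, 1, 1, ] - z0[4:6])), 1e-10)
})

test_that("displacement application, composition, inversion, Jacobians", {
  v <- textured_ball(24, radius = 8, seed = 6)
  d <- dim(v$data)
  zero <- displacement_field(array(0, c(d, 3)))
  expect_equal(apply_displacement(v, zero)$data, v$data)
  # uniform integer shift is exact
  sh <- array(0, c(d, 3)); sh[, , , 1] <- 2
  out <- apply_displacement(v, displacement_field(sh))
  expect_equal(out$data[1:(d[1] - 2), , ], v$data[3:d[1], , ],
               tolerance = 1e-12)
  # jacobian determinant: zero field -> 1; linear scaling field -> 1.1^3
  expect_true(all(abs(jacobian_determinant(zero)$data - 1) < 1e-12))
  lin <- array(0, c(d, 3))
  id <- phase_space_state(d)$q
  for (cpt in 1:3) lin[, , , cpt] <- 0.1 * id[, , , cpt]
  jd <- jacobian_determinant(displacement_field(lin))
  expect_equal(max(abs(jd$data - 1.1^3)), 0, tolerance = 1e-6)
  # smooth random field vs dense finite-difference oracle at interior voxels
  w <- make_deformed_pair(v, field_amp = 1.5, field_scale = 4,
                          seed = 9)$true_field
  jw <- jacobian_determinant(w)$data
  a <- w$vectors
  i <- c(12, 13, 11)
  J <- matrix(0, 3, 3)
  for (cpt in 1:3) for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    up <- i + e; dn <- i - e
    J[cpt, ax] <- (a[up[1], up[2], up[3], cpt] - a[dn[1], dn[2], dn[3], cpt]) / 2
  }
  expect_equal(jw[i[1], i[2], i[3]], det(diag(3) + J), tolerance = 1e-8)
  # inversion: w o w^{-1} ~ identity on the intensity scale
  inv <- invert_displacement(w)
  back <- apply_displacement(apply_displacement(v, w), inv)
  core <- make_ball(24, radius = 6)$data > 0
  expect_lt(sqrt(mean((back$data[core] - v$data[core])^2)) /
              diff(range(v$data)), 0.05)
})

test_that("registering a volume to itself stays at the identity", {
  v <- textured_ball(24, radius = 8, seed = 1)
  rr <- register(v, v, list(iters = 10, levels = 2))
  expect_lt(max(abs(rr$warp$vectors)), 1e-6)
  expect_lt(max(unlist(rr$similarity_trace)), 1e-20)
  expect_true(rr$diffeomorphic)
})

test_that("registration recovers a known smooth field and reduces MSD", {
  base <- textured_ball(48, radius = 17, seed = 42)
  pair <- make_deformed_pair(base, field_amp = 3, field_scale = 7, seed = 2)
  rr <- register(pair$moving, pair$fixed, list(iters = 40, sigma = 3))
  sup <- make_ball(48, radius = 17, intensity = 100, smooth_edge = 2)$data > 50
  epe <- field_mag(rr$warp$vectors - pair$true_field$vectors)
  expect_lt(mean(epe[sup]), 0.5)
  msd0 <- similarity_msd(pair$moving, pair$fixed)
  tl <- rr$similarity_trace[[length(rr$similarity_trace)]]
  expect_lt(tl[length(tl)] / msd0, 0.5)
  expect_gt(rr$jacobian_min, 0)
  # trace non-increasing within each level (step control)
  for (tr in rr$similarity_trace)
    expect_true(all(diff(tr) <= 1e-9 * tr[1]))
  # deterministic given params
  rr2 <- register(pair$moving, pair$fixed, list(iters = 40, sigma = 3))
  expect_identical(rr$warp$vectors, rr2$warp$vectors)
})

test_that("template of identical inputs is the input; translated pair centers", {
  v <- textured_ball(24, radius = 8, seed = 3)
  tp <- build_template(list(v, v, v), iters = 1,
                       reg_params = list(iters = 5, levels = 2),
                       rigid = FALSE)
  expect_lt(max(abs(tp$warps[[1]]$vectors)), 1e-6)
  expect_lt(max(abs(tp$template$data - v$data)), 1e-6)
  b1 <- make_ball(32, center = c(13.5, 15.5, 15.5), radius = 8,
                  smooth_edge = 1.5)
  b2 <- make_ball(32, center = c(17.5, 15.5, 15.5), radius = 8,
                  smooth_edge = 1.5)
  tp2 <- build_template(list(b1, b2), iters = 2,
                        reg_params = list(iters = 30), rigid = FALSE)
  ctr <- auto_support(tp2$template)$center
  expect_lt(abs(ctr[1] - 15.5), 0.5)
})
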