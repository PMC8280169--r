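test_that("spherical harmonics follow the orthonormal CS convention", {
  expect_equal(Re(spherical_harmonic(0, 0, 0.7, 1.3)), 1 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  expect_lt(abs(spherical_harmonic(1, 0, pi / 2, 2.1)), 1e-12)
  expect_error(spherical_harmonic(2, 3, 1, 1), "m")
  # Y_{l,-m} = (-1)^m conj(Y_{lm})
  th <- c(0.4, 1.1, 2.3); ph <- c(0.2, 2.8, 5.0)
  expect_equal(spherical_harmonic(3, -2, th, ph),
               (-1)^2 * Conj(spherical_harmonic(3, 2, th, ph)),
               tolerance = 1e-12)
})

test_that("<Y_21, Y_21> = 1 under the product angular quadrature", {
  gt <- pracma::gaussLegendre(12, -1, 1)
  nph <- 16
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  th <- acos(gt$x)
  ip <- 0
  for (j in seq_len(nph)) {
    Y <- spherical_harmonic(2, 1, th, rep(phi[j], length(th)))
    ip <- ip + sum(gt$w * Mod(Y)^2) * (2 * pi / nph)
  }
  expect_equal(ip, 1, tolerance = 1e-8)
})

test_that("spherical Bessel functions are stable near zero and at roots", {
  expect_equal(spherical_bessel(0, 0), 1)
  expect_equal(spherical_bessel(1, 0), 0)
  expect_lt(abs(spherical_bessel(0, pi)), 1e-12)
  # series branch agrees with the closed forms where both are stable
  xs <- c(2e-4, 1e-3, 0.01, 0.1, 1, 5)
  expect_equal(spherical_bessel(0, xs), sin(xs) / xs, tolerance = 1e-12)
  expect_equal(spherical_bessel(1, xs), sin(xs) / xs^2 - cos(xs) / xs,
               tolerance = 1e-9)
  # and the two branches meet continuously at the switch point
  for (l in 0:4)
    expect_lt(abs(spherical_bessel(l, 1e-4 * (1 + 1e-6)) -
                    spherical_bessel(l, 1e-4 * (1 - 1e-6))), 1e-9)
})

test_that("Dirichlet wavenumbers hit Bessel roots and interlace", {
  expect_equal(radial_wavenumbers(0, 3, 1), pi * (1:3), tolerance = 1e-10)
  expect_equal(radial_wavenumbers(0, 2, 2)[2], pi, tolerance = 1e-10)
  # first root of j_1 solves tan x = x: brute-force oracle value
  expect_equal(radial_wavenumbers(1, 1, 1), 4.493409457909064,
               tolerance = 1e-9)
  # interlacing z_{l,n} < z_{l+1,n} < z_{l,n+1}
  z <- sapply(0:5, function(l) radial_wavenumbers(l, 4, 1))
  for (l in 1:5) for (n in 1:3) {
    expect_lt(z[n, l], z[n, l + 1])
    expect_lt(z[n, l + 1], z[n + 1, l])
  }
})

test_that("basis counting and Gram orthonormality hold", {
  g0 <- spherical_grid(c(0, 0, 0), 1, 8, 4, 5)
  expect_equal(ncol(swdmorph:::basis_matrix(build_basis(0, 1, g0),
                                            0.5, 0.5, 0.5)), 1)
  g1 <- spherical_grid(c(0, 0, 0), 1, 12, 6, 9)
  b1 <- build_basis(2, 3, g1)
  pts <- swdmorph:::grid_points(g1)
  expect_equal(ncol(swdmorph:::basis_matrix(b1, pts$r, pts$theta, pts$phi)),
               27)  # N (L+1)^2
  # Gram at L=4, N=4 on a fine grid = identity within 1e-6
  g <- spherical_grid(c(0, 0, 0), 1, 40, 10, 15)
  b <- build_basis(4, 4, g)
  p <- swdmorph:::grid_points(g)
  A <- swdmorph:::basis_matrix(b, p$r, p$theta, p$phi)
  G <- t(Conj(A)) %*% (A * p$w)
  expect_lt(max(abs(G - diag(ncol(A)))), 1e-6)
})

test_that("angular quadrature weights sum to 4*pi and grids warn when coarse", {
  g <- spherical_grid(c(0, 0, 0), 2, 10, 7, 11)
  expect_equal(sum(g$wt) * 2 * pi, 4 * pi, tolerance = 1e-12)
  expect_warning(build_basis(6, 2, spherical_grid(c(0, 0, 0), 1, 8, 3, 4)),
                 "under-resolved")
  expect_error(build_basis(6, 2, spherical_grid(c(0, 0, 0), 1, 8, 3, 4),
                           strict = TRUE), "under-resolved")
})

test_that("rotation mixes coefficients only within a degree (closure)", {
  # sample a pure l=2 field at rotated node directions (analytically exact)
  ctr <- c(0, 0, 0); R <- 1
  grid <- swdmorph:::default_swd_grid(4, 2, ctr, R)
  b <- build_basis(4, 2, grid)
  cf <- array(0i, c(2, 5, 9)); cf[1, 3, 3] <- 1  # (n=1, l=2, m=0)
  pts <- swdmorph:::grid_points(grid)
  alpha <- 0.7  # rotation about x
  Rm <- rbind(c(1, 0, 0), c(0, cos(alpha), -sin(alpha)),
              c(0, sin(alpha), cos(alpha)))
  xyz <- rbind(pts$r * sin(pts$theta) * cos(pts$phi),
               pts$r * sin(pts$theta) * sin(pts$phi),
               pts$r * cos(pts$theta))
  rot <- t(Rm) %*% xyz
  rr <- sqrt(colSums(rot^2))
  thr <- acos(pmin(1, pmax(-1, rot[3, ] / pmax(rr, 1e-12))))
  phr <- atan2(rot[2, ], rot[1, ])
  f <- Re(swdmorph:::swd_eval_core(b, rr, thr, phr, coef = cf))
  A <- swdmorph:::basis_matrix(b, pts$r, pts$theta, pts$phi)
  sw <- sqrt(pts$w)
  cf2 <- qr.coef(qr(A * sw, LAPACK = TRUE), complex(real = f * sw))
  idx <- swdmorph:::basis_column_index(4, 2)
  energy <- tapply(Mod(cf2)^2, idx$l, sum)
  expect_equal(unname(energy[["2"]]), 1, tolerance = 1e-6)
  expect_lt(sum(energy[names(energy) != "2"]), 1e-6)
})

test_that("spherical sampling interpolates fields and clips with fill 0", {
  con <- volume(array(3.25, c(20, 20, 20)))
  g <- spherical_grid(c(9.5, 9.5, 9.5), 6, 8, 6, 9)
  s <- sample_volume_spherical(con, g)
  expect_true(all(abs(s - 3.25) < 1e-12))
  expect_equal(attr(s, "n_clipped"), 0)
  # affine field is reproduced exactly by trilinear interpolation
  cw <- swdmorph:::voxel_world_coords(volume(array(0, c(20, 20, 20))))
  va <- volume(1.5 + 0.2 * cw$x - 0.3 * cw$y + 0.05 * cw$z)
  pts <- swdmorph:::grid_points(g)
  wx <- 9.5 + pts$r * sin(pts$theta) * cos(pts$phi)
  wy <- 9.5 + pts$r * sin(pts$theta) * sin(pts$phi)
  wz <- 9.5 + pts$r * cos(pts$theta)
  expect_equal(as.numeric(sample_volume_spherical(va, g)),
               1.5 + 0.2 * wx - 0.3 * wy + 0.05 * wz, tolerance = 1e-10)
  # radial ramp f = r: trilinear error is O(h^2 / r) away from the apex
  rad <- swdmorph:::voxel_radius_array(c(20, 20, 20), c(9.5, 9.5, 9.5))
  sr <- sample_volume_spherical(volume(rad$r), g)
  away <- pts$r > 2
  expect_lt(max(abs(sr[away] - pts$r[away])), 0.1)
  # sphere poking out of the volume: clipped nodes get 0 and are counted
  gbig <- spherical_grid(c(18, 9.5, 9.5), 6, 8, 6, 9)
  sb <- sample_volume_spherical(con, gbig)
  expect_gt(attr(sb, "n_clipped"), 0)
  expect_true(any(sb == 0))
  expect_error(sample_volume_spherical(con, spherical_grid(c(40, 9, 9), 3, 4, 4, 5)),
               "outside")
})

test_that("analytic basis gradients match finite differences", {
  ctr <- c(0, 0, 0)
  grid <- swdmorph:::default_swd_grid(3, 2, ctr, 1)
  b <- build_basis(3, 2, grid)
  cf <- array(0i, c(2, 4, 7))
  cf[1, 1, 1] <- 0.8; cf[2, 2, 2] <- 0.4 + 0.1i; cf[2, 2, 4] <- -Conj(cf[2, 2, 2])
  cf[1, 4, 6] <- 0.3i; cf[1, 4, 2] <- (-1)^2 * Conj(cf[1, 4, 6])
  p0 <- rbind(c(0.31, 0.22, 0.4), c(-0.2, 0.5, -0.1), c(0.05, -0.33, 0.21))
  sph <- function(x) {
    r <- sqrt(sum(x^2))
    c(r, acos(x[3] / r), atan2(x[2], x[1]))
  }
  evalf <- function(x) {
    s <- sph(x)
    Re(swdmorph:::swd_eval_core(b, s[1], s[2], s[3], coef = cf))
  }
  h <- 1e-6
  for (k in seq_len(nrow(p0))) {
    x <- p0[k, ]
    s <- sph(x)
    ev <- swdmorph:::swd_eval_core(b, s[1], s[2], s[3], coef = cf,
                                   gradient = TRUE)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- h
      fd <- (evalf(x + e) - evalf(x - e)) / (2 * h)
      expect_equal(Re(ev[[c("gx", "gy", "gz")[ax]]]), fd, tolerance = 1e-5)
    }
  }
})
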