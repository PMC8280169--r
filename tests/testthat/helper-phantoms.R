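# shared fixtures (all generated in code; nothing on disk)

# smooth multiplicative texture so displacement fields are observable to
# intensity matching inside the object
textured_ball <- function(size = 64, radius = 24, tex_scale = 3,
                          tex_amp = 0.5, seed = 42) {
  ball <- make_ball(size, radius = radius, intensity = 100, smooth_edge = 2)
  tex <- swdmorph:::with_seed(seed,
                              array(stats::rnorm(size^3), rep(size, 3)))
  tex <- swdmorph:::smooth_periodic_3d(tex, tex_scale)
  volume(ball$data * (1 + tex_amp * tex / max(abs(tex))),
         ball$spacing, ball$origin)
}

# build coefficients directly in the basis (exactly band-limited volume)
band_limited_phantom <- function(shape = c(48, 48, 48), L = 4, N = 3,
                                 terms = list(c(1, 0, 0, 1),
                                              c(2, 2, 0, 0.5),
                                              c(1, 2, 2, 0.3))) {
  ctr <- (shape - 1) / 2
  R <- min(shape - 1) / 2 - 2
  grid <- swdmorph:::default_swd_grid(L, N, ctr, R)
  b <- build_basis(L, N, grid)
  cf <- array(0i, c(N, L + 1, 2 * L + 1))
  for (t in terms) {
    n <- t[1]; l <- t[2]; m <- t[3]; a <- t[4]
    cf[n, l + 1, m + l + 1] <- cf[n, l + 1, m + l + 1] + a
    if (m != 0)  # keep the synthesized field real
      cf[n, l + 1, -m + l + 1] <- (-1)^m * Conj(cf[n, l + 1, m + l + 1])
  }
  sc <- swdmorph:::new_swd_coefficients(cf, b, c(1, 1, 1), "manual", 0)
  list(coef = sc,
       vol = swd_inverse(sc, list(shape = shape, spacing = c(1, 1, 1),
                                  origin = c(0, 0, 0))),
       center = ctr, R = R)
}

rel_rms <- function(x, y) sqrt(mean((x - y)^2)) / sqrt(mean(y^2))

field_mag <- function(w) {
  a <- if (inherits(w, "displacement_field")) w$vectors else w
  sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
}

# three-shell fossil analogue: air core / bone shell / rock matrix
shells_fixture <- function(size = 64) {
  truth <- make_nested_shells(size, radii = round(size * c(12, 20, 26) / 64),
                              intensities = c(0, 100, 40))
  gt <- array(1L, dim(truth$data))
  gt[truth$data == 40] <- 2L
  gt[truth$data == 100] <- 3L
  list(vol = truth, gt = gt)
}
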