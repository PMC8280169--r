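#' Rippled sand-dune height field
#'
#' The classic plane-wave worked example: one low-frequency high-amplitude
#' wave along y (the dune) plus two high-frequency low-amplitude waves
#' oriented at +45 and -45 degrees from the y axis (the ripples), on the
#' unit square. Ripple wavevector components are snapped to the integer
#' frequency lattice `fc = round(ripple_freq / sqrt(2))` so the discrete
#' spectrum is leak-free: the FFT magnitude has exactly three symmetric
#' non-DC peak pairs, the high-frequency pair exactly 45 degrees off the
#' k_y axis.
#'
#' @param size Grid side (default 256).
#' @param dune_amp,dune_freq Dune amplitude and frequency (cycles per unit;
#'   defaults 1 and 2).
#' @param ripple_amp,ripple_freq Ripple amplitude and nominal frequency
#'   (defaults 0.2 and 24); requires `ripple_freq > dune_freq` and
#'   `dune_amp > ripple_amp`.
#' @return `size` x `size` numeric height matrix (first index x, second y),
#'   with attribute `components` listing the constituent wavevectors.
#' @export
make_dune <- function(size = 256, dune_amp = 1, dune_freq = 2,
                      ripple_amp = 0.2, ripple_freq = 24) {
  if (ripple_freq <= dune_freq) stopf("ripple_freq must exceed dune_freq")
  if (dune_amp <= ripple_amp) stopf("dune_amp must exceed ripple_amp")
  fc <- round(ripple_freq / sqrt(2))
  x <- (seq_len(size) - 1) / size
  y <- (seq_len(size) - 1) / size
  X <- matrix(x, size, size)
  Y <- matrix(y, size, size, byrow = TRUE)
  h <- dune_amp * sin(2 * pi * dune_freq * Y) +
    ripple_amp * (sin(2 * pi * fc * (X + Y)) + sin(2 * pi * fc * (X - Y)))
  attr(h, "components") <- data.frame(
    kx = c(0, fc, fc), ky = c(dune_freq, fc, -fc),
    amplitude = c(dune_amp, ripple_amp, ripple_amp))
  h
}

#' Symmetric peak pairs of a 2D FFT magnitude spectrum
#'
#' Detects local maxima of the FFT magnitude above `rel_threshold` times
#' the strongest non-DC peak and groups them into +/-k mirror pairs. For
#' each pair the representative with `ky >= 0` is reported with its
#' spatial frequency and its signed angle from the k_y axis.
#'
#' @param mat Real matrix (first index x, second y).
#' @param rel_threshold Detection threshold relative to the peak.
#' @return Data frame with one row per pair: `kx`, `ky` (cycles per field
#'   of view), `magnitude`, `freq`, `angle_from_ky` (degrees, in
#'   (-90, 90]).
#' @export
fft_peak_pairs <- function(mat, rel_threshold = 0.1) {
  d <- dim(mat)
  mag <- Mod(stats::fft(mat))
  mag[1, 1] <- 0
  peak <- max(mag)
  shift <- function(m, di, dj) {
    i <- ((seq_len(d[1]) - 1 + di) %% d[1]) + 1
    j <- ((seq_len(d[2]) - 1 + dj) %% d[2]) + 1
    m[i, j]
  }
  ismax <- mag > rel_threshold * peak
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (mag >= shift(mag, di, dj))
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(kx = numeric(0), ky = numeric(0),
                                    magnitude = numeric(0), freq = numeric(0),
                                    angle_from_ky = numeric(0)))
  tofreq <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  kx <- tofreq(idx[, 1], d[1]); ky <- tofreq(idx[, 2], d[2])
  mg <- mag[idx]
  keep <- ky > 0 | (ky == 0 & kx > 0)
  out <- data.frame(kx = kx[keep], ky = ky[keep], magnitude = mg[keep])
  out$freq <- sqrt(out$kx^2 + out$ky^2)
  out$angle_from_ky <- atan2(out$kx, out$ky) * 180 / pi
  out[order(out$freq), , drop = FALSE]
}

#' Polynomial test series for model-order selection
#'
#' Equally spaced samples of \eqn{y = \sum_i c_i x^i} on `[-1, 1]`, plus
#' optional zero-mean Gaussian noise. The default coefficients are the
#' package's fixed cubic demo, `c(1, 2, -1, 0.5)`.
#'
#' @param coeffs Polynomial coefficients, constant term first.
#' @param n Number of samples (> length(coeffs)).
#' @param sigma Noise standard deviation.
#' @param seed Seed for the noise (reproducible; `NULL` = current stream).
#' @return Data frame with columns `x`, `y`.
#' @export
make_polynomial_series <- function(coeffs = c(1, 2, -1, 0.5), n = 101,
                                   sigma = 0, seed = NULL) {
  stopifnot(n > length(coeffs))
  x <- seq(-1, 1, length.out = n)
  y <- drop(outer(x, seq_along(coeffs) - 1, `^`) %*% coeffs)
  if (sigma > 0) y <- y + with_seed(seed, stats::rnorm(n, 0, sigma))
  data.frame(x = x, y = y)
}

voxel_radius_array <- function(size, center, spacing = c(1, 1, 1)) {
  size <- rep_len(as.integer(size), 3)
  cx <- ((seq_len(size[1]) - 1) - center[1]) * spacing[1]
  cy <- ((seq_len(size[2]) - 1) - center[2]) * spacing[2]
  cz <- ((seq_len(size[3]) - 1) - center[3]) * spacing[3]
  X <- array(rep(cx, times = size[2] * size[3]), size)
  Y <- array(rep(rep(cy, each = size[1]), times = size[3]), size)
  Z <- array(rep(cz, each = size[1] * size[2]), size)
  list(X = X, Y = Y, Z = Z, r = sqrt(X^2 + Y^2 + Z^2), size = size)
}

edge_profile <- function(dist_inside, smooth_edge) {
  # dist_inside > 0 inside the shape; dims of the input are preserved
  out <- if (smooth_edge <= 0) (dist_inside > 0) * 1
  else stats::plogis(dist_inside / smooth_edge)
  if (!is.null(dim(dist_inside))) dim(out) <- dim(dist_inside)
  out
}

#' Solid ball phantom
#'
#' @param size Grid shape (scalar or 3-vector).
#' @param center Ball center in 0-based voxel coordinates (`NULL` = grid
#'   center).
#' @param radius Ball radius (voxels).
#' @param intensity Interior intensity.
#' @param spacing Voxel spacing.
#' @param smooth_edge Soft-edge width in voxels (0 = hard voxelized edge,
#'   so voxel-count oracles are exact; > 0 gives a logistic intensity
#'   profile, useful for registration where image gradients carry the
#'   information).
#' @return A [volume()].
#' @export
make_ball <- function(size, center = NULL, radius, intensity = 1,
                      spacing = c(1, 1, 1), smooth_edge = 0) {
  size <- rep_len(as.integer(size), 3)
  center <- center %||% ((size - 1) / 2)
  if (radius > min((size - 1) / 2) + max(abs(center - (size - 1) / 2)) + 1)
    swd_log("ball touches or exceeds the grid boundary")
  g <- voxel_radius_array(size, center, spacing)
  volume(intensity * edge_profile(radius - g$r, smooth_edge),
         spacing, c(0, 0, 0))
}

#' Nested concentric shells phantom
#'
#' Each voxel takes the intensity of the innermost shell containing it
#' (shell i spans radii `(radii[i-1], radii[i]]`); voxels beyond the last
#' radius are 0.
#'
#' @param size Grid shape.
#' @param radii Increasing radii (voxels); must fit inside the grid.
#' @param intensities One intensity per shell.
#' @param center 0-based voxel center (`NULL` = grid center).
#' @param spacing Voxel spacing.
#' @return A [volume()]. Empty `radii` gives the zero volume.
#' @export
make_nested_shells <- function(size, radii, intensities, center = NULL,
                               spacing = c(1, 1, 1)) {
  size <- rep_len(as.integer(size), 3)
  center <- center %||% ((size - 1) / 2)
  if (length(radii) != length(intensities))
    stopf("need one intensity per shell")
  if (is.unsorted(radii, strictly = TRUE)) stopf("radii must be increasing")
  if (length(radii) && max(radii) > min(pmin(center, size - 1 - center)))
    stopf("radii exceed the grid")
  g <- voxel_radius_array(size, center, spacing)
  data <- array(0, size)
  for (i in rev(seq_along(radii))) data[g$r <= radii[i]] <- intensities[i]
  volume(data, spacing, c(0, 0, 0))
}

#' Ball with a pure spherical-harmonic surface corrugation
#'
#' Indicator of \eqn{r < R\,[1 + a\,\mathrm{Re}Y_{lm}(\theta,\phi) /
#' \max|\mathrm{Re}Y_{lm}|]}: a ball whose surface carries angular detail
#' of a single known degree l, so its shape complexity is l by
#' construction.
#'
#' @inheritParams make_ball
#' @param l,m Degree and order of the corrugation harmonic.
#' @param amp Relative corrugation amplitude (< 1).
#' @return A [volume()].
#' @export
make_corrugated_ball <- function(size, radius, l, m = 0, amp = 0.15,
                                 center = NULL, intensity = 1,
                                 spacing = c(1, 1, 1), smooth_edge = 0) {
  stopifnot(amp < 1, abs(m) <= l)
  if (amp == 0)
    return(make_ball(size, center, radius, intensity, spacing, smooth_edge))
  size <- rep_len(as.integer(size), 3)
  center <- center %||% ((size - 1) / 2)
  g <- voxel_radius_array(size, center, spacing)
  rr <- pmax(g$r, 1e-9)
  theta <- acos(pmin(1, pmax(-1, g$Z / rr)))
  phi <- atan2(g$Y, g$X)
  ReY <- Re(spherical_harmonic(l, m, as.vector(theta), as.vector(phi)))
  thg <- seq(0, pi, length.out = 2001)
  maxY <- max(abs(legendre_norm(l, cos(thg))[abs(m) + 1, ]))
  rloc <- radius * (1 + amp * array(ReY, size) / maxY)
  volume(intensity * edge_profile(rloc - g$r, smooth_edge),
         spacing, c(0, 0, 0))
}

#' Registration test pair with known ground-truth field
#'
#' Draws a smooth random displacement (white noise smoothed by a
#' stationary periodic Gaussian kernel, rescaled to peak amplitude
#' `field_amp`), verifies it is diffeomorphic, and warps the base volume
#' with it. The
#' returned `fixed` is the warped base and `moving` the base itself, so a
#' registration of moving onto fixed should recover `true_field`.
#'
#' @param base A [volume()].
#' @param field_amp Maximum displacement magnitude (voxels).
#' @param field_scale Smoothing SD of the random field (voxels).
#' @param seed RNG seed (reproducible).
#' @return List `fixed`, `moving`, `true_field` ([displacement_field()]).
#' @export
make_deformed_pair <- function(base, field_amp, field_scale = 6, seed = 1) {
  stopifnot(is_volume(base), field_amp >= 0)
  d <- dim(base$data)
  u <- with_seed(seed, array(stats::rnorm(prod(d) * 3), c(d, 3)))
  if (field_amp > 0) {
    for (cpt in 1:3)
      u[, , , cpt] <- smooth_periodic_3d(u[, , , cpt], field_scale)
    mx <- sqrt(max(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
    u <- u * (field_amp / mx)
  } else {
    u[] <- 0
  }
  w <- displacement_field(u)
  jmin <- min(jacobian_determinant(w)$data)
  if (jmin <= 0)
    stopf("requested amplitude %.3g gives a non-diffeomorphic field (min |J| = %.3g)",
          field_amp, jmin)
  list(fixed = apply_displacement(base, w), moving = base, true_field = w)
}

#' Two-segment articulated limb phantom
#'
#' Two capsules (cylinder + hemispherical caps; femur and tibia analogue)
#' meeting at a joint with a given interior angle, in the xy plane.
#' Thickness distinguishes "species"; the joint angle changes posture but
#' not size.
#'
#' @param size Grid shape.
#' @param segment_lengths Lengths of the two segments (voxels).
#' @param thicknesses Capsule radii (voxels).
#' @param joint_angle Interior angle between the segments in degrees,
#'   within `[20, 180]` (180 = fully extended, collinear).
#' @param intensity Interior intensity.
#' @param smooth_edge Soft-edge width (voxels).
#' @return A [volume()].
#' @export
make_articulated_limb <- function(size, segment_lengths = c(20, 16),
                                  thicknesses = c(4, 4), joint_angle = 180,
                                  intensity = 1, smooth_edge = 0) {
  stopifnot(joint_angle >= 20, joint_angle <= 180)
  size <- rep_len(as.integer(size), 3)
  a2 <- (180 - joint_angle) * pi / 180
  u1 <- c(0, 1, 0)
  u2 <- c(sin(a2), -cos(a2), 0)
  ctr <- (size - 1) / 2
  e1 <- segment_lengths[1] * u1
  e2 <- segment_lengths[2] * u2
  joint <- ctr - (e1 + e2) / 2
  ends <- rbind(joint + e1, joint + e2)
  pad <- max(thicknesses) + 1
  if (any(rbind(joint, ends) < pad - 1) ||
      any(t(rbind(joint, ends)) > size - pad))
    stopf("limb does not fit in the grid")
  g <- voxel_radius_array(size, c(0, 0, 0))
  capsule_dist <- function(a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((g$X - a[1]) * ab[1] + (g$Y - a[2]) * ab[2] +
            (g$Z - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    sqrt((g$X - (a[1] + t * ab[1]))^2 + (g$Y - (a[2] + t * ab[2]))^2 +
           (g$Z - (a[3] + t * ab[3]))^2)
  }
  d1 <- capsule_dist(joint, joint + e1)
  d2 <- capsule_dist(joint, joint + e2)
  inside <- pmax(edge_profile(thicknesses[1] - d1, smooth_edge),
                 edge_profile(thicknesses[2] - d2, smooth_edge))
  volume(intensity * inside, c(1, 1, 1), c(0, 0, 0))
}

#' Add Gaussian intensity noise
#' @param v A [volume()].
#' @param sigma Noise standard deviation (`0` = unchanged).
#' @param seed RNG seed.
#' @return A [volume()].
#' @export
add_noise <- function(v, sigma, seed = NULL) {
  stopifnot(is_volume(v), sigma >= 0)
  if (sigma == 0) return(v)
  v$data <- v$data + with_seed(seed, array(stats::rnorm(length(v$data), 0, sigma),
                                           dim(v$data)))
  v
}

#' Scatter isointense speckles ("sand grains") into a volume
#'
#' Places exactly `count` connected blobs of 1..`max_size` voxels at the
#' given intensity, in regions whose current value equals `region_value`
#' (well separated, so the blobs stay distinct components). Emulates the
#' isolated grains that contaminate histogram-threshold segmentations of
#' fossil CT.
#'
#' @param v A [volume()].
#' @param intensity Speckle intensity.
#' @param count Number of speckles, >= 0.
#' @param max_size Maximum voxels per speckle (default 2).
#' @param seed RNG seed.
#' @param region_value Only voxels at this value receive speckles.
#' @return A [volume()] with attribute `speckle_voxels`: matrix of the
#'   voxel indices used (1-based).
#' @export
add_speckle <- function(v, intensity, count, max_size = 2, seed = NULL,
                        region_value = 0) {
  stopifnot(is_volume(v), count >= 0, max_size >= 1)
  if (count == 0) return(v)
  d <- dim(v$data)
  ok <- v$data == region_value
  # interior of the region: all 26 neighbours must match too
  er <- ok
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    er <- er & ok[ix, iy, iz]
  }
  border <- 2 + max_size
  er[c(seq_len(border), d[1] + 1 - seq_len(border)), , ] <- FALSE
  er[, c(seq_len(border), d[2] + 1 - seq_len(border)), ] <- FALSE
  er[, , c(seq_len(border), d[3] + 1 - seq_len(border))] <- FALSE
  cand <- which(er)
  if (length(cand) < count) stopf("not enough room for %d speckles", count)
  placed <- matrix(0L, 0, 3)
  used <- integer(0)
  sep <- max_size + 2
  with_seed(seed, {
    ord <- sample(cand)
    ci <- arrayInd(ord, d)
    for (i in seq_along(ord)) {
      p <- ci[i, ]
      if (nrow(placed) &&
          any(sqrt(rowSums(sweep(placed, 2, p)^2)) < sep)) next
      vox <- matrix(p, 1)
      sz <- sample.int(max_size, 1)
      while (nrow(vox) < sz) {
        q <- vox[sample.int(nrow(vox), 1), ] +
          sample(c(-1L, 0L, 1L), 3, replace = TRUE)
        if (all(q >= 1) && all(q <= d) && v$data[q[1], q[2], q[3]] == region_value &&
            !any(vox[, 1] == q[1] & vox[, 2] == q[2] & vox[, 3] == q[3]))
          vox <- rbind(vox, q)
      }
      placed <- rbind(placed, p)
      used <- c(used, vox[, 1] + d[1] * (vox[, 2] - 1) +
                  d[1] * d[2] * (vox[, 3] - 1))
      if (nrow(placed) == count) break
    }
  })
  if (nrow(placed) < count) stopf("could not place %d well-separated speckles", count)
  v$data[used] <- intensity
  attr(v, "speckle_voxels") <- arrayInd(used, d)
  v
}
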