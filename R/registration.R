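#' Displacement field in voxel units
#'
#' @param vectors 4D numeric array `[nx, ny, nz, 3]` of per-voxel
#'   displacement vectors (voxel units, pull-back convention: the warped
#'   image samples the source at `x + w(x)`).
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stopf("displacement field must be [nx, ny, nz, 3]")
  structure(list(vectors = vectors, reference_shape = d[1:3]),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mx <- sqrt(max(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 +
                   x$vectors[, , , 3]^2))
  cat(sprintf("<displacement_field %s  max |w| = %.4g voxels>\n",
              paste(x$reference_shape, collapse = "x"), mx))
  invisible(x)
}

as_field_array <- function(w) {
  if (inherits(w, "displacement_field")) w$vectors else w
}

# clamped-edge convolution along one axis with a symmetric kernel g
# (odd length); edge replication keeps constant fields exactly constant
conv_axis_clamped <- function(arr, g, axis) {
  d <- dim(arr)
  r <- (length(g) - 1L) / 2L
  out <- array(0, d)
  n <- d[axis]
  base <- seq_len(n)
  for (j in -r:r) {
    idx <- pmin(pmax(base + j, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + g[j + r + 1L] * shifted
  }
  out
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

smooth_gaussian_3d <- function(arr, sigmas) {
  for (axis in 1:3)
    if (sigmas[axis] > 0)
      arr <- conv_axis_clamped(arr, gauss_kernel_1d(sigmas[axis]), axis)
  arr
}

# full-covariance smoothing via FFT with edge-replicated padding
smooth_gaussian_full <- function(arr, S) {
  cov <- solve(S)
  sig_max <- sqrt(max(eigen(cov, symmetric = TRUE)$values))
  r <- max(1L, ceiling(4 * sig_max))
  d <- dim(arr)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  ap <- arr[pad_idx(d[1]), pad_idx(d[2]), pad_idx(d[3])]
  dp <- dim(ap)
  off <- function(n) {
    x <- seq_len(n) - 1
    ifelse(x > n / 2, x - n, x)  # wrapped offsets centered at 0
  }
  ox <- off(dp[1]); oy <- off(dp[2]); oz <- off(dp[3])
  OX <- array(rep(ox, times = dp[2] * dp[3]), dp)
  OY <- array(rep(rep(oy, each = dp[1]), times = dp[3]), dp)
  OZ <- array(rep(oz, each = dp[1] * dp[2]), dp)
  q <- S[1, 1] * OX^2 + S[2, 2] * OY^2 + S[3, 3] * OZ^2 +
    2 * (S[1, 2] * OX * OY + S[1, 3] * OX * OZ + S[2, 3] * OY * OZ)
  kern <- exp(-0.5 * q)
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(ap) * fft(kern), inverse = TRUE)) / prod(dp)
  sm[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

#' Gaussian coupling (ESP) regularization kernel
#'
#' Smooths each component of a vector field by convolution with the
#' normalized Gaussian of covariance \eqn{S^{-1}} — the simplest spatial
#' coupling density \eqn{Q(x, x') \sim N(x', S^{-1})}, i.e. the common
#' Gaussian regularizer of fluid registration. The kernel sums to 1
#' (mass-preserving), so constant fields pass through unchanged.
#'
#' @param field 4D array `[nx,ny,nz,3]`, a [displacement_field()], or a
#'   single 3D array.
#' @param S 3x3 symmetric positive definite *inverse* covariance matrix,
#'   or a positive scalar `sigma` shorthand for \eqn{S = I/\sigma^2}
#'   (isotropic smoothing with standard deviation `sigma` voxels).
#' @return Smoothed object of the same kind as the input.
#' @export
esp_kernel <- function(field, S) {
  if (length(S) == 1) {
    stopifnot(S > 0)
    sigmas <- rep(as.numeric(S), 3)
    diagonal <- TRUE
  } else {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stopf("S must be symmetric")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stopf("S must be positive definite")
    offd <- max(abs(S[upper.tri(S)]))
    diagonal <- offd < 1e-12 * max(diag(S))
    if (diagonal) sigmas <- sqrt(1 / diag(S))
  }
  smooth1 <- function(a)
    if (diagonal) smooth_gaussian_3d(a, sigmas) else smooth_gaussian_full(a, S)
  if (inherits(field, "displacement_field")) {
    for (cpt in 1:3) field$vectors[, , , cpt] <- smooth1(field$vectors[, , , cpt])
    return(field)
  }
  d <- dim(field)
  if (length(d) == 3L) return(smooth1(field))
  if (length(d) == 4L && d[4] == 3L) {
    for (cpt in 1:3) field[, , , cpt] <- smooth1(field[, , , cpt])
    return(field)
  }
  stopf("field must be 3D, [nx,ny,nz,3], or a displacement_field")
}

# central differences (one-sided at borders), voxel units
gradient_cd <- function(arr) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (axis in 1:3) {
    n <- d[axis]
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    h <- (up - dn)  # 2 interior, 1 at borders
    pick <- function(idx) switch(axis,
                                 arr[idx, , , drop = FALSE],
                                 arr[, idx, , drop = FALSE],
                                 arr[, , idx, drop = FALSE])
    hh <- switch(axis,
                 array(rep(h, times = d[2] * d[3]), d),
                 array(rep(rep(h, each = d[1]), times = d[3]), d),
                 array(rep(h, each = d[1] * d[2]), d))
    g[[axis]] <- (pick(up) - pick(dn)) / hh
  }
  g
}

# circular (periodic) Gaussian convolution; stationary, so smoothed white
# noise has uniform variance — used for random-field generation, where the
# clamped-edge kernel would inflate the variance at the volume borders
smooth_periodic_3d <- function(arr, sigma) {
  d <- dim(arr)
  off <- function(n) {
    x <- seq_len(n) - 1
    ifelse(x > n / 2, x - n, x)
  }
  gx <- exp(-off(d[1])^2 / (2 * sigma^2))
  gy <- exp(-off(d[2])^2 / (2 * sigma^2))
  gz <- exp(-off(d[3])^2 / (2 * sigma^2))
  kern <- outer(outer(gx, gy), gz)
  dim(kern) <- d
  kern <- kern / sum(kern)
  Re(fft(fft(arr) * fft(kern), inverse = TRUE)) / prod(d)
}

#' Demons-style image matching force
#'
#' Descent direction for the sum-of-squared-differences image potential:
#' \eqn{F = (f - m_w)\,\nabla f / (\|\nabla f\|^2 + (f - m_w)^2 +
#' \epsilon)} with \eqn{\epsilon} = `eps_frac` times the squared fixed-
#' image intensity range. The force is zero wherever both the residual
#' and the gradient vanish, and its direction is invariant to a common
#' intensity rescaling of both images.
#'
#' @param fixed,warped_moving [volume()]s or 3D arrays of equal shape
#'   (the moving image already resampled through the current warp).
#' @param grad_fixed Optional precomputed gradient (list gx, gy, gz) of
#'   the fixed image.
#' @param eps_frac Stabilizer fraction (default 1e-3).
#' @return 4D force array `[nx, ny, nz, 3]` in voxel units.
#' @export
matching_force <- function(fixed, warped_moving, grad_fixed = NULL,
                           eps_frac = 1e-3) {
  f <- if (is_volume(fixed)) fixed$data else fixed
  m <- if (is_volume(warped_moving)) warped_moving$data else warped_moving
  if (!identical(dim(f), dim(m))) stopf("shape mismatch in matching_force")
  if (is.null(grad_fixed)) grad_fixed <- gradient_cd(f)
  resid <- f - m
  g2 <- grad_fixed[[1]]^2 + grad_fixed[[2]]^2 + grad_fixed[[3]]^2
  rng <- diff(range(f))
  eps <- max(eps_frac * rng^2, .Machine$double.eps)
  denom <- g2 + resid^2 + eps
  out <- array(0, c(dim(f), 3))
  for (cpt in 1:3) out[, , , cpt] <- resid * grad_fixed[[cpt]] / denom
  out
}

#' Phase-space state of the registration grid
#'
#' Positions `q` start on the identity grid (0-based voxel coordinates)
#' and momenta `p` at zero.
#'
#' @param shape Integer 3-vector.
#' @return Object of class `phase_space_state` with 4D arrays `q`, `p`.
#' @export
phase_space_state <- function(shape) {
  shape <- as.integer(shape)
  q <- array(0, c(shape, 3))
  q[, , , 1] <- array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape)
  q[, , , 2] <- array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]),
                          times = shape[3]), shape)
  q[, , , 3] <- array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape)
  structure(list(q = q, p = array(0, c(shape, 3))),
            class = "phase_space_state")
}

#' One symplectic (semi-implicit Euler) integration step
#'
#' The default `"kick_drift"` variant updates momenta then positions:
#' \eqn{p \leftarrow (1-\gamma) p + dt\, F(q)};
#' \eqn{q \leftarrow q + dt\, p}.
#' With `damping = 0` the `(q, p)` map is a composition of two shears and
#' has Jacobian determinant exactly 1 (a symplectomorphism); `damping > 0`
#' trades exact phase-space volume preservation for convergence. The
#' adjoint `"drift_kick"` variant drifts first (`force` is then the force
#' at the drifted positions); a kick-drift step followed by a
#' momentum-flipped drift-kick step retraces the trajectory exactly.
#'
#' @param state A [phase_space_state()].
#' @param force 4D force array (evaluated at the current positions for
#'   `"kick_drift"`, at the drifted positions `q + dt p` for
#'   `"drift_kick"`).
#' @param dt Step size, > 0.
#' @param damping Momentum damping \eqn{\gamma \in [0, 1)}.
#' @param variant `"kick_drift"` (default) or its adjoint `"drift_kick"`.
#' @return Updated `phase_space_state`.
#' @export
symplectic_step <- function(state, force, dt, damping = 0,
                            variant = c("kick_drift", "drift_kick")) {
  stopifnot(inherits(state, "phase_space_state"), dt > 0,
            damping >= 0, damping < 1)
  variant <- match.arg(variant)
  if (variant == "kick_drift") {
    state$p <- (1 - damping) * state$p + dt * force
    state$q <- state$q + dt * state$p
  } else {
    state$q <- state$q + dt * state$p
    state$p <- (1 - damping) * state$p + dt * force
  }
  state
}

#' Warp a volume through a displacement field
#'
#' Pull-back interpolation: the output at voxel `x` is the input sampled
#' trilinearly at `x + w(x)` (0-based voxel coordinates); out-of-grid
#' samples are 0.
#'
#' @param v A [volume()].
#' @param w A [displacement_field()] (or 4D array) matching `dim(v$data)`.
#' @return Warped [volume()] on the same grid.
#' @export
apply_displacement <- function(v, w) {
  stopifnot(is_volume(v))
  wv <- as_field_array(w)
  d <- dim(v$data)
  if (!identical(dim(wv)[1:3], d)) stopf("field shape does not match volume")
  id <- phase_space_state(d)$q
  vals <- interp_trilinear(v$data,
                           as.vector(id[, , , 1] + wv[, , , 1]),
                           as.vector(id[, , , 2] + wv[, , , 2]),
                           as.vector(id[, , , 3] + wv[, , , 3]))
  volume(array(vals, d), v$spacing, v$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map `(id + w1) o (id + w2)`, i.e.
#' `w(x) = w2(x) + w1(x + w2(x))` (components interpolated trilinearly).
#'
#' @param w1,w2 [displacement_field()]s of equal shape.
#' @return A [displacement_field()].
#' @export
compose_displacement <- function(w1, w2) {
  a1 <- as_field_array(w1); a2 <- as_field_array(w2)
  d <- dim(a1)[1:3]
  id <- phase_space_state(d)$q
  xi <- as.vector(id[, , , 1] + a2[, , , 1])
  yi <- as.vector(id[, , , 2] + a2[, , , 2])
  zi <- as.vector(id[, , , 3] + a2[, , , 3])
  out <- a2
  for (cpt in 1:3)
    out[, , , cpt] <- a2[, , , cpt] +
      array(interp_trilinear(a1[, , , cpt], xi, yi, zi), d)
  displacement_field(out)
}

#' Approximate inverse of a displacement field
#'
#' Fixed-point iteration `v(x) <- -w(x + v(x))`, adequate for smooth
#' small-amplitude fields.
#'
#' @param w A [displacement_field()].
#' @param iters Fixed-point iterations.
#' @return A [displacement_field()] with `compose(w, invert(w)) ~ 0`.
#' @export
invert_displacement <- function(w, iters = 20) {
  a <- as_field_array(w)
  d <- dim(a)[1:3]
  id <- phase_space_state(d)$q
  v <- array(0, dim(a))
  for (it in seq_len(iters)) {
    xi <- as.vector(id[, , , 1] + v[, , , 1])
    yi <- as.vector(id[, , , 2] + v[, , , 2])
    zi <- as.vector(id[, , , 3] + v[, , , 3])
    for (cpt in 1:3)
      v[, , , cpt] <- -array(interp_trilinear(a[, , , cpt], xi, yi, zi), d)
  }
  displacement_field(v)
}

#' Jacobian determinant map of a displacement field
#'
#' Central-difference \eqn{\det(I + \nabla w)} per voxel (one-sided at the
#' borders). Everywhere-positive values certify a diffeomorphic warp.
#'
#' @param w A [displacement_field()] or 4D array.
#' @return A [volume()] of determinants (unit spacing).
#' @export
jacobian_determinant <- function(w) {
  a <- as_field_array(w)
  J <- vector("list", 3)
  for (cpt in 1:3) J[[cpt]] <- gradient_cd(a[, , , cpt])
  # rows: derivative of component cpt along axis ax -> J[[cpt]][[ax]]
  det <- (1 + J[[1]][[1]]) * ((1 + J[[2]][[2]]) * (1 + J[[3]][[3]]) -
                                J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * (1 + J[[3]][[3]]) -
                     J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] -
                     (1 + J[[2]][[2]]) * J[[3]][[1]])
  volume(det, c(1, 1, 1), c(0, 0, 0))
}

downsample_array <- function(arr, factor) {
  if (factor == 1) return(arr)
  sm <- smooth_gaussian_3d(arr, rep(factor / 2, 3))
  d <- dim(arr)
  sm[seq(1, d[1], by = factor), seq(1, d[2], by = factor),
     seq(1, d[3], by = factor), drop = FALSE]
}

upsample_field <- function(w, target_shape, ratio) {
  d <- dim(w)[1:3]
  out <- array(0, c(target_shape, 3))
  xi <- (seq_len(target_shape[1]) - 1) / ratio
  yi <- (seq_len(target_shape[2]) - 1) / ratio
  zi <- (seq_len(target_shape[3]) - 1) / ratio
  X <- rep(pmin(xi, d[1] - 1), times = target_shape[2] * target_shape[3])
  Y <- rep(rep(pmin(yi, d[2] - 1), each = target_shape[1]),
           times = target_shape[3])
  Z <- rep(pmin(zi, d[3] - 1), each = target_shape[1] * target_shape[2])
  for (cpt in 1:3)
    out[, , , cpt] <- ratio *
      array(interp_trilinear(w[, , , cpt], X, Y, Z), target_shape)
  out
}

default_reg_params <- function() {
  list(sigma = 2, sigma_field = 1, dt = 0.5, damping = 0.2, iters = 50,
       levels = 3, eps_frac = 1e-3, max_halvings = 5)
}

#' Non-linear symplectomorphic registration
#'
#' Multi-resolution (coarse-to-fine) phase-space registration: at each
#' level the loop is matching force ([matching_force()]) -> Gaussian
#' coupling smoothing ([esp_kernel()]) -> symplectic momentum/position
#' update ([symplectic_step()]). The step size is halved (up to
#' `max_halvings`, then the level stops) whenever a step would increase
#' the mean squared difference, so the similarity trace is non-increasing
#' within each level. Fully deterministic given its parameters.
#'
#' @param moving,fixed [volume()]s of equal shape (rigidly pre-aligned;
#'   see [rigid_align()]).
#' @param params Named list overriding the defaults: `sigma` (Gaussian
#'   coupling SD applied to the force — fluid-like regularization;
#'   voxels, per level; default 2), `sigma_field` (Gaussian SD applied to
#'   the accumulated displacement — diffusion-like regularization that
#'   suppresses unobservable tangential drift; default 1, 0 disables),
#'   `dt` (0.5), `damping` (0.2), `iters` per level (50), `levels` (3:
#'   x4, x2, x1), `eps_frac` (1e-3), `max_halvings` (5).
#' @return Object of class `registration_result`: `warp`
#'   ([displacement_field()], pull-back, voxel units), `warped` (moving
#'   image in fixed space), `similarity_trace` (list of per-level MSD
#'   vectors), `jacobian_min`, `diffeomorphic` flag (with a warning when
#'   the final warp folds), `params`.
#' @export
register <- function(moving, fixed, params = list()) {
  stopifnot(is_volume(moving), is_volume(fixed))
  if (!identical(dim(moving$data), dim(fixed$data)))
    stopf("moving and fixed must share a grid (rigid pre-alignment / resampling first)")
  p <- utils::modifyList(default_reg_params(), params)
  d <- dim(fixed$data)
  factors <- 2^((p$levels - 1):0)
  factors <- factors[factors < min(d)]  # skip levels coarser than the image
  w <- NULL
  trace <- list()
  for (li in seq_along(factors)) {
    fac <- factors[li]
    f_l <- downsample_array(fixed$data, fac)
    m_l <- downsample_array(moving$data, fac)
    dl <- dim(f_l)
    if (is.null(w)) {
      w <- array(0, c(dl, 3))
    } else if (!identical(dim(w)[1:3], dl)) {
      w <- upsample_field(w, dl, ratio = fac_prev / fac)
    }
    fac_prev <- fac
    res <- register_level(m_l, f_l, w, p)
    w <- res$w
    trace[[li]] <- res$msd
  }
  wf <- displacement_field(w)
  jd <- jacobian_determinant(wf)
  jmin <- min(jd$data)
  diffeo <- jmin > 0
  if (!diffeo)
    warnf("warp is not diffeomorphic (min Jacobian determinant %.4g)", jmin)
  warped <- apply_displacement(moving, wf)
  structure(list(warp = wf, warped = warped, similarity_trace = trace,
                 jacobian_min = jmin, diffeomorphic = diffeo, params = p),
            class = "registration_result")
}

register_level <- function(m, f, w, p) {
  d <- dim(f)
  id <- phase_space_state(d)$q
  gf <- gradient_cd(f)
  mom <- array(0, c(d, 3))
  dt <- p$dt
  halvings <- 0L
  eval_msd <- function(wc) {
    mw <- array(interp_trilinear(m,
                                 as.vector(id[, , , 1] + wc[, , , 1]),
                                 as.vector(id[, , , 2] + wc[, , , 2]),
                                 as.vector(id[, , , 3] + wc[, , , 3])), d)
    list(mw = mw, msd = mean((mw - f)^2))
  }
  cur <- eval_msd(w)
  msd_trace <- cur$msd
  for (it in seq_len(p$iters)) {
    F <- matching_force(f, cur$mw, grad_fixed = gf, eps_frac = p$eps_frac)
    Fs <- esp_kernel(F, 1 / p$sigma^2 * diag(3))
    restarted <- FALSE
    repeat {
      mom_new <- (1 - p$damping) * mom + dt * Fs
      w_new <- w + dt * mom_new
      if (p$sigma_field > 0)   # diffusion-like prior on the field itself
        for (cpt in 1:3)
          w_new[, , , cpt] <- smooth_gaussian_3d(w_new[, , , cpt],
                                                 rep(p$sigma_field, 3))
      nxt <- eval_msd(w_new)
      if (nxt$msd <= cur$msd * (1 + 1e-12)) break
      if (!restarted) {
        # momentum overshoot: restart the heavy ball before touching dt
        mom <- array(0, dim(mom))
        restarted <- TRUE
      } else {
        halvings <- halvings + 1L
        dt <- dt / 2
        if (halvings > p$max_halvings) break
      }
    }
    if (halvings > p$max_halvings) break
    w <- w_new; mom <- mom_new; cur <- nxt
    msd_trace <- c(msd_trace, cur$msd)
  }
  list(w = w, msd = msd_trace)
}

#' @export
print.registration_result <- function(x, ...) {
  msd0 <- x$similarity_trace[[1]][1]
  tl <- x$similarity_trace[[length(x$similarity_trace)]]
  cat(sprintf(
    "<registration_result  MSD %.4g -> %.4g  jacobian_min %.4g  %s>\n",
    msd0, tl[length(tl)], x$jacobian_min,
    if (x$diffeomorphic) "diffeomorphic" else "NOT diffeomorphic"))
  invisible(x)
}

#' Mean gradient energy of a volume (sharpness statistic)
#' @param v A [volume()].
#' @return Scalar mean squared gradient magnitude (voxel units).
#' @export
gradient_energy <- function(v) {
  stopifnot(is_volume(v))
  g <- gradient_cd(v$data)
  mean(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
}

#' Groupwise template construction
#'
#' Iteratively registers every (rigidly pre-aligned) volume to the current
#' template and averages the warped volumes. The initial template is the
#' first volume: registering all subjects onto one sharp reference keeps
#' the first averaged template sharp (a naive voxelwise mean is blurred by
#' the residual shape variation, and registering onto a blurred mean
#' merely reproduces its blur). After each averaging step the mean of the
#' subject warps is subtracted from the template (the usual unbiased
#' shape update), so the template drifts to the population mean shape
#' instead of staying at the reference geometry.
#'
#' @param volumes List of >= 2 [volume()]s of equal shape.
#' @param iters Template update iterations (default 3).
#' @param reg_params Passed to [register()].
#' @param rigid Rigidly pre-align all volumes to the first one.
#' @return List with `template` ([volume()]), `warps` (list of
#'   [displacement_field()]s, one per subject), and `msd` (subjects x
#'   iterations matrix of final registration MSDs).
#' @export
build_template <- function(volumes, iters = 3, reg_params = list(),
                           rigid = TRUE) {
  stopifnot(length(volumes) >= 2, all(vapply(volumes, is_volume, logical(1))))
  if (rigid && length(volumes) > 1)
    for (i in seq_along(volumes)[-1])
      volumes[[i]] <- rigid_align(volumes[[i]], volumes[[1]])$aligned
  ref <- volumes[[1]]
  template <- ref
  warps <- vector("list", length(volumes))
  msd <- matrix(NA_real_, length(volumes), iters)
  for (t in seq_len(iters)) {
    warped <- vector("list", length(volumes))
    for (i in seq_along(volumes)) {
      rr <- register(volumes[[i]], template, reg_params)
      warped[[i]] <- rr$warped$data
      warps[[i]] <- rr$warp
      tl <- rr$similarity_trace[[length(rr$similarity_trace)]]
      msd[i, t] <- tl[length(tl)]
    }
    avg <- volume(Reduce(`+`, warped) / length(volumes),
                  ref$spacing, ref$origin)
    # unbiased shape update: pull the average back by the mean warp
    mean_w <- Reduce(`+`, lapply(warps, as_field_array)) / length(volumes)
    template <- apply_displacement(avg, -mean_w)
  }
  list(template = template, warps = warps, msd = msd)
}
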