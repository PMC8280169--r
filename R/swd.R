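#' Automatic support sphere of a volume
#'
#' Center defaults to the intensity centroid (of the nonnegative part);
#' the radius is the maximum world distance from the center to any voxel
#' above `threshold_frac` of the peak intensity, times a 5% margin.
#'
#' @param v A [volume()].
#' @param threshold_frac Support threshold as a fraction of the maximum.
#' @param margin Multiplicative radius margin.
#' @return List with `center` (world 3-vector) and `R`.
#' @export
auto_support <- function(v, threshold_frac = 0.1, margin = 1.05) {
  stopifnot(is_volume(v))
  w <- pmax(v$data, 0)
  tot <- sum(w)
  d <- dim(v$data)
  cw <- voxel_world_coords(v)
  if (tot <= 0) {
    center <- v$origin + (d - 1) * v$spacing / 2
    return(list(center = center,
                R = sqrt(sum(((d - 1) * v$spacing / 2)^2)) * margin))
  }
  center <- c(sum(cw$x * w), sum(cw$y * w), sum(cw$z * w)) / tot
  sup <- v$data > threshold_frac * max(v$data)
  if (!any(sup)) sup <- w > 0
  r2 <- (cw$x[sup] - center[1])^2 + (cw$y[sup] - center[2])^2 +
    (cw$z[sup] - center[3])^2
  list(center = center, R = max(sqrt(max(r2)), max(v$spacing)) * margin)
}

# default quadrature sizing for a given (L, N): exact in the angles up to
# products of degree 2L, and enough radial nodes for the oscillations of
# j_l(z_{L,N} r)
default_swd_grid <- function(L, N, center, R) {
  nt <- max(L + 4, 8)
  np <- max(2 * L + 5, 9)
  nr <- max(24, ceiling(2.5 * (N + L / 2)) + 8)
  spherical_grid(center, R, nr, nt, np)
}

new_swd_coefficients <- function(cf, basis, spacing, fit_method, rms) {
  structure(list(c = cf, center = basis$center, R = basis$R,
                 L = basis$L, N = basis$N, spacing = spacing,
                 fit_method = fit_method, fit_residual_rms = rms,
                 k = basis$k, normc = basis$normc),
            class = "swd_coefficients")
}

#' @export
print.swd_coefficients <- function(x, ...) {
  cat(sprintf(
    "<swd_coefficients L=%d N=%d (%d terms)  R=%.4g  fit=%s  rms=%.4g>\n",
    x$L, x$N, n_basis_functions(x$L, x$N), x$R, x$fit_method,
    x$fit_residual_rms))
  invisible(x)
}

# reconstruct a basis-like evaluator from a coefficient container
coef_basis <- function(sc) {
  structure(list(L = sc$L, N = sc$N, R = sc$R, center = sc$center,
                 k = sc$k, normc = sc$normc), class = "swd_basis")
}

coef_vec_to_array <- function(vec, L, N) {
  idx <- basis_column_index(L, N)
  arr <- array(0i, c(N, L + 1, 2 * L + 1))
  arr[cbind(idx$n, idx$l + 1, idx$m + idx$l + 1)] <- vec
  arr
}

coef_array_to_vec <- function(arr, L, N) {
  idx <- basis_column_index(L, N)
  arr[cbind(idx$n, idx$l + 1, idx$m + idx$l + 1)]
}

#' Forward spherical wave decomposition
#'
#' Samples the volume on a spherical quadrature grid about the support
#' center and estimates the expansion coefficients `c[n, l, m]`, either by
#' quadrature projection (fast, exact only for band-limited input on a
#' resolving grid) or by solving the overdetermined linear system by
#' weighted least squares via QR (the reconstruction route; the naive
#' adjoint is generally not the inverse of the basis). Anisotropic volumes
#' are first resampled isotropically, since the spherical basis assumes an
#' isotropic metric.
#'
#' @param v A [volume()].
#' @param L Maximum angular degree.
#' @param N Number of radial orders.
#' @param center,R Support sphere (world units); `NULL` for automatic
#'   ([auto_support()]).
#' @param method `"least_squares"` (default) or `"projection"`.
#' @param samples Sample set for the least-squares system: `"voxels"`
#'   (default; every voxel inside the support sphere — exact for volumes
#'   band-limited within (L, N)) or `"grid"` (the spherical quadrature
#'   nodes, cheaper at high bandwidth). The projection method always uses
#'   the quadrature grid.
#' @param grid Optional [spherical_grid()] overriding the default sizing.
#' @return An `swd_coefficients` object; `fit_residual_rms` holds the RMS
#'   misfit over the fitted samples (quadrature-weighted on the grid).
#' @export
swd_forward <- function(v, L, N, center = NULL, R = NULL,
                        method = c("least_squares", "projection"),
                        samples = c("voxels", "grid"), grid = NULL) {
  stopifnot(is_volume(v))
  method <- match.arg(method)
  samples <- match.arg(samples)
  if (diff(range(v$spacing)) > 1e-9 * min(v$spacing))
    v <- resample_isotropic(v, min(v$spacing))
  if (is.null(center) || is.null(R)) {
    sup <- auto_support(v)
    center <- center %||% sup$center
    R <- R %||% sup$R
  }
  if (is.null(grid)) grid <- default_swd_grid(L, N, center, R)
  basis <- build_basis(L, N, grid)
  if (method == "projection" || samples == "grid") {
    pts <- grid_points(grid)
    f <- as.numeric(sample_volume_spherical(v, grid))
    A <- basis_matrix(basis, pts$r, pts$theta, pts$phi)
    w <- pts$w
  } else {
    geo <- sphere_voxel_geometry(
      list(center = center, R = R),
      list(shape = dim(v$data), spacing = v$spacing, origin = v$origin))
    if (sum(geo$mask) <= n_basis_functions(L, N))
      stopf("support sphere holds %d voxels for %d basis functions; enlarge R or the grid",
            sum(geo$mask), n_basis_functions(L, N))
    f <- as.vector(v$data)[geo$mask]
    A <- basis_matrix(basis, geo$r, geo$theta, geo$phi)
    w <- rep(prod(v$spacing), length(f))
  }
  if (method == "projection") {
    cf <- as.vector(crossprod(Conj(A), w * f))
  } else {
    sw <- sqrt(w)
    B <- A * sw
    qrB <- qr(B, LAPACK = TRUE)
    rd <- abs(diag(qr.R(qrB)))
    kappa <- max(rd) / max(min(rd), .Machine$double.eps)
    if (min(rd) < 1e-10 * max(rd))
      stopf("basis ill-conditioned on these samples (condition ~ %.3g); refine the grid", kappa)
    swd_log(sprintf("least-squares fit, %d pts x %d terms, cond ~ %.3g",
                    nrow(B), ncol(B), kappa))
    cf <- as.vector(qr.coef(qrB, complex(real = f * sw)))
  }
  resid <- f - Re(A %*% cf)
  rms <- sqrt(sum(w * resid^2) / sum(w))
  new_swd_coefficients(coef_vec_to_array(cf, L, N), basis, v$spacing,
                       method, rms)
}

#' Inverse spherical wave decomposition (synthesis)
#'
#' Evaluates the expansion on a voxel grid. Voxels outside the support
#' sphere are 0. The synthesis is linear in the coefficients.
#'
#' @param sc An `swd_coefficients` object.
#' @param like A [volume()] supplying shape/spacing/origin of the target,
#'   or a list with elements `shape`, `spacing`, `origin`.
#' @return A [volume()] holding the real part of the reconstruction.
#' @export
swd_inverse <- function(sc, like) {
  stopifnot(inherits(sc, "swd_coefficients"))
  tgt <- as_target(like)
  geo <- sphere_voxel_geometry(sc, tgt)
  out <- numeric(prod(tgt$shape))
  if (any(geo$mask)) {
    vals <- swd_eval_core(coef_basis(sc), geo$r, geo$theta, geo$phi,
                          coef = sc$c, gradient = FALSE)
    out[geo$mask] <- Re(vals)
  }
  volume(array(out, tgt$shape), tgt$spacing, tgt$origin)
}

as_target <- function(like) {
  if (is_volume(like))
    return(list(shape = dim(like$data), spacing = like$spacing,
                origin = like$origin))
  stopifnot(is.list(like), !is.null(like$shape))
  list(shape = as.integer(like$shape),
       spacing = as.numeric(like$spacing %||% c(1, 1, 1)),
       origin = as.numeric(like$origin %||% c(0, 0, 0)))
}

# spherical coordinates of the in-sphere voxels of a target grid
sphere_voxel_geometry <- function(sc, tgt) {
  d <- tgt$shape
  ix <- (seq_len(d[1]) - 1) * tgt$spacing[1] + tgt$origin[1] - sc$center[1]
  iy <- (seq_len(d[2]) - 1) * tgt$spacing[2] + tgt$origin[2] - sc$center[2]
  iz <- (seq_len(d[3]) - 1) * tgt$spacing[3] + tgt$origin[3] - sc$center[3]
  X <- rep(ix, times = d[2] * d[3])
  Y <- rep(rep(iy, each = d[1]), times = d[3])
  Z <- rep(iz, each = d[1] * d[2])
  r <- sqrt(X^2 + Y^2 + Z^2)
  mask <- r <= sc$R
  rr <- r[mask]
  theta <- acos(pmin(1, pmax(-1, ifelse(rr > 0, Z[mask] / rr, 1))))
  phi <- atan2(Y[mask], X[mask])
  list(mask = mask, r = rr, theta = theta, phi = phi)
}

#' Gradient of an SWD reconstruction from analytic basis derivatives
#'
#' Differentiates the expansion termwise using closed-form derivatives of
#' \eqn{j_l} and ladder identities for \eqn{\partial_\theta Y_{lm}} (no
#' finite differences), and assembles the Cartesian gradient.
#'
#' @inheritParams swd_inverse
#' @return List of three [volume()]s: `gx`, `gy`, `gz`.
#' @export
swd_gradient <- function(sc, like) {
  stopifnot(inherits(sc, "swd_coefficients"))
  tgt <- as_target(like)
  geo <- sphere_voxel_geometry(sc, tgt)
  gx <- gy <- gz <- numeric(prod(tgt$shape))
  if (any(geo$mask)) {
    ev <- swd_eval_core(coef_basis(sc), geo$r, geo$theta, geo$phi,
                        coef = sc$c, gradient = TRUE)
    gx[geo$mask] <- Re(ev$gx); gy[geo$mask] <- Re(ev$gy)
    gz[geo$mask] <- Re(ev$gz)
  }
  list(gx = volume(array(gx, tgt$shape), tgt$spacing, tgt$origin),
       gy = volume(array(gy, tgt$shape), tgt$spacing, tgt$origin),
       gz = volume(array(gz, tgt$shape), tgt$spacing, tgt$origin))
}

#' Spectral smoothing of SWD coefficients
#'
#' Heat-kernel damping in both spectral indices:
#' \eqn{c_{nlm} \leftarrow c_{nlm} \exp\{-\sigma [l(l+1) + (k_{l,n} R)^2]\}}.
#' `sigma = 0` is the identity; large `sigma` leaves only the smoothest
#' mode (n = 1, l = 0).
#'
#' @param sc An `swd_coefficients` object.
#' @param sigma Dimensionless smoothing scale, >= 0.
#' @return A smoothed `swd_coefficients` object.
#' @export
weighted_smoothing <- function(sc, sigma) {
  stopifnot(inherits(sc, "swd_coefficients"), sigma >= 0)
  if (sigma == 0) return(sc)
  for (l in 0:sc$L) {
    damp <- exp(-sigma * (l * (l + 1) + (sc$k[, l + 1] * sc$R)^2))
    sc$c[, l + 1, ] <- sc$c[, l + 1, ] * damp
  }
  sc
}

#' Total spectral energy of a coefficient set
#' @param sc An `swd_coefficients` object.
#' @return Scalar \eqn{\sum |c_{nlm}|^2} (the quadrature energy of the
#'   reconstruction, by orthonormality).
#' @export
swd_energy <- function(sc) sum(Mod(sc$c)^2)

# weighted modified Gram-Schmidt giving residual RMS for every nested
# prefix of the (ordered) columns; the workhorse of model-order search
nested_ls_rms <- function(A, w, y, prefixes) {
  sw <- sqrt(w)
  Q <- A * sw
  yw <- y * sw
  tot <- sum(Mod(yw)^2)
  n <- ncol(Q)
  expl <- numeric(n)
  for (j in seq_len(n)) {
    qj <- Q[, j]
    if (j > 1) {
      prev <- Q[, 1:(j - 1), drop = FALSE]
      qj <- qj - prev %*% crossprod(Conj(prev), qj)
    }
    nj <- sqrt(sum(Mod(qj)^2))
    if (nj > 1e-12 * sqrt(tot + 1)) {
      qj <- qj / nj
      expl[j] <- Mod(sum(Conj(qj) * yw))^2
    }
    Q[, j] <- qj
  }
  cum <- cumsum(expl)
  sapply(prefixes, function(p) {
    res2 <- max(tot - if (p > 0) cum[p] else 0, 0)
    sqrt(res2 / sum(w))
  })
}

#' Model-order selection by the RMS-plateau rule
#'
#' Fits a nested family of models of increasing order by least squares and
#' records the RMS misfit per order. An improvement from one order to the
#' next is *significant* when it exceeds
#' `max(noise_floor_fraction * rms, abs_tol)`; the selected order is the
#' one reached by the last significant improvement (equivalently, the
#' smallest order beyond which the RMS curve is flat to within the noise).
#' The procedure is deterministic given its input.
#'
#' @param samples For `family = "polynomial"`: a data frame or list with
#'   elements `x` and `y`. For `family = "swd_angular"`: a [volume()],
#'   fitted at increasing angular degree L with the radial order fixed at
#'   `n_radial`.
#' @param family `"polynomial"` or `"swd_angular"` (nested families).
#' @param orders Increasing integer vector of candidate orders (>= 2 of
#'   them); for polynomials, the polynomial degree; for `swd_angular`, the
#'   maximum degree L.
#' @param noise_floor_fraction,abs_tol Plateau-rule constants.
#' @param n_radial Radial orders held fixed in the `swd_angular` family.
#' @param center,R Optional support sphere for `swd_angular`.
#' @return An object of class `model_order_curve` with fields `orders`,
#'   `rms`, `selected_order`, `noise_floor`.
#' @export
select_model_order <- function(samples, family = c("polynomial", "swd_angular"),
                               orders, noise_floor_fraction = 0.01,
                               abs_tol = 1e-9, n_radial = 4,
                               center = NULL, R = NULL) {
  family <- match.arg(family)
  orders <- sort(as.integer(orders))
  if (length(orders) < 2) stopf("need at least 2 candidate orders")
  if (family == "polynomial") {
    x <- samples$x; y <- samples$y
    if (is.null(x) || is.null(y)) stopf("polynomial samples need x and y")
    if (length(y) <= max(orders) + 1)
      stopf("need more samples than the largest model's parameter count")
    rms <- vapply(orders, function(p) {
      X <- outer(x, 0:p, `^`)
      sqrt(mean(qr.resid(qr(X), y)^2))
    }, numeric(1))
  } else {
    v <- samples
    stopifnot(is_volume(v))
    if (diff(range(v$spacing)) > 1e-9 * min(v$spacing))
      v <- resample_isotropic(v, min(v$spacing))
    if (is.null(center) || is.null(R)) {
      sup <- auto_support(v)
      center <- center %||% sup$center
      R <- R %||% sup$R
    }
    Lmax <- max(orders)
    grid <- default_swd_grid(Lmax, n_radial, center, R)
    basis <- build_basis(Lmax, n_radial, grid)
    pts <- grid_points(grid)
    f <- as.numeric(sample_volume_spherical(v, grid))
    if (length(f) <= n_basis_functions(Lmax, n_radial))
      stopf("grid has fewer samples than the largest model's parameter count")
    A <- basis_matrix(basis, pts$r, pts$theta, pts$phi)
    prefixes <- n_basis_functions(orders, n_radial)
    rms <- nested_ls_rms(A, pts$w, complex(real = f), prefixes)
  }
  no <- length(orders)
  imp <- rms[-no] - rms[-1]
  thr <- pmax(noise_floor_fraction * rms[-1], abs_tol)
  sig <- imp > thr
  sel_idx <- if (any(sig)) max(which(sig)) + 1L else 1L
  structure(list(orders = orders, rms = rms,
                 selected_order = orders[sel_idx],
                 noise_floor = rms[no], family = family),
            class = "model_order_curve")
}

#' @export
print.model_order_curve <- function(x, ...) {
  cat(sprintf("<model_order_curve (%s): selected order %d, noise floor %.4g>\n",
              x$family, x$selected_order, x$noise_floor))
  print(data.frame(order = x$orders, rms = signif(x$rms, 6)),
        row.names = FALSE)
  invisible(x)
}

#' Shape complexity of a volume
#'
#' The optimal angular model order of the spherical wave decomposition,
#' selected by the RMS-plateau rule: the smallest maximum degree L whose
#' fit is not significantly improved by any higher degree. A ball has
#' complexity 0; a surface corrugation of pure degree l raises the
#' complexity to l.
#'
#' @inheritParams select_model_order
#' @param v A [volume()].
#' @param orders Candidate maximum degrees.
#' @param ... Passed to [select_model_order()].
#' @return Integer complexity, with attributes `curve` (the full
#'   [select_model_order()] result) and `n_coefficients`
#'   (`n_radial * (L+1)^2` at the selected L).
#' @export
shape_complexity <- function(v, orders = 0:8, n_radial = 4, ...) {
  curve <- select_model_order(v, family = "swd_angular", orders = orders,
                              n_radial = n_radial, ...)
  out <- curve$selected_order
  attr(out, "curve") <- curve
  attr(out, "n_coefficients") <-
    n_basis_functions(curve$selected_order, n_radial)
  out
}

#' Write SWD coefficients to a JSON container
#'
#' Layout: datasets `c_real`, `c_imag` of shape `[N, L+1, 2L+1]` (the m
#' index packed as `m + l`), attributes `center`, `R`, `L`, `N`,
#' `spacing`, `fit_method`, plus the wavenumber and normalization tables
#' needed to re-evaluate the expansion exactly.
#'
#' @param sc An `swd_coefficients` object.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_swd <- function(sc, path) {
  stopifnot(inherits(sc, "swd_coefficients"))
  obj <- list(c_real = Re(sc$c), c_imag = Im(sc$c),
              center = sc$center, R = sc$R, L = sc$L, N = sc$N,
              spacing = sc$spacing, fit_method = sc$fit_method,
              fit_residual_rms = sc$fit_residual_rms,
              k = sc$k, normc = sc$normc)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read SWD coefficients from a JSON container
#' @param path Path written by [write_swd()].
#' @return An `swd_coefficients` object.
#' @export
read_swd <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- c(o$N, o$L + 1, 2 * o$L + 1)
  cr <- array(as.numeric(o$c_real), dims)
  ci <- array(as.numeric(o$c_imag), dims)
  structure(list(c = array(complex(real = cr, imaginary = ci), dims),
                 center = as.numeric(o$center), R = o$R,
                 L = as.integer(o$L), N = as.integer(o$N),
                 spacing = as.numeric(o$spacing),
                 fit_method = o$fit_method,
                 fit_residual_rms = o$fit_residual_rms,
                 k = matrix(as.numeric(o$k), o$N, o$L + 1),
                 normc = matrix(as.numeric(o$normc), o$N, o$L + 1)),
            class = "swd_coefficients")
}
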