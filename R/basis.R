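#' Spherical harmonic \eqn{Y_{lm}(\theta,\phi)}
#'
#' Complex orthonormal spherical harmonics with the Condon-Shortley phase:
#' \eqn{Y_{lm} = \sqrt{(2l+1)/(4\pi)\,(l-m)!/(l+m)!}\, P_l^m(\cos\theta)
#' e^{im\phi}}, with \eqn{Y_{l,-m} = (-1)^m \overline{Y_{lm}}}.
#'
#' @param l Degree, integer >= 0.
#' @param m Order, integer with |m| <= l.
#' @param theta Polar angle(s) from the +z axis, radians.
#' @param phi Azimuth(s), radians.
#' @return Complex vector of the same length as `theta`/`phi`.
#' @examples
#' spherical_harmonic(0, 0, 1, 2)   # 1/(2*sqrt(pi))
#' @export
spherical_harmonic <- function(l, m, theta, phi) {
  l <- as.integer(l); m <- as.integer(m)
  if (l < 0 || abs(m) > l) stopf("require 0 <= |m| <= l, got l=%d m=%d", l, m)
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  Yb <- legendre_norm(l, cos(theta))       # (l+1) x n, m = 0..l
  am <- abs(m)
  Y <- Yb[am + 1, ] * exp(1i * am * phi)
  if (m < 0) Y <- (-1)^am * Conj(Y)
  Y
}

# Normalized associated Legendre bar-P_l^m(x) for m = 0..l, as an
# (l+1) x length(x) matrix, Condon-Shortley phase included, such that
# Y_lm = barP[m+1, ] * exp(1i*m*phi).
legendre_norm <- function(l, x) {
  n <- length(x)
  if (l == 0L) return(matrix(rep(1 / (2 * sqrt(pi)), n), nrow = 1))
  P <- pracma::legendre(l, x)
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  m <- 0:l
  Nb <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  P * Nb
}

#' Spherical Bessel function of the first kind \eqn{j_l(x)}
#'
#' Computed from the half-integer Bessel function, with a series branch
#' near zero for stability: \eqn{j_l(x) \approx x^l/(2l+1)!!} as
#' \eqn{x \to 0}.
#'
#' @param l Degree, integer >= 0.
#' @param x Nonnegative numeric vector.
#' @return Numeric vector \eqn{j_l(x)}.
#' @export
spherical_bessel <- function(l, x) {
  l <- as.integer(l)
  if (l < 0) stopf("l must be >= 0")
  if (any(x < 0)) stopf("x must be >= 0")
  out <- numeric(length(x))
  small <- x < 1e-4
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  if (any(small)) {
    xs <- x[small]
    dfact <- prod(seq(1, 2 * l + 1, by = 2))  # (2l+1)!!
    out[small] <- xs^l / dfact * (1 - xs^2 / (2 * (2 * l + 3)))
  }
  out
}

# d j_l(x) / dx, stable near 0 (j_0' = -j_1; else j_{l-1} - (l+1)/x j_l)
spherical_bessel_deriv <- function(l, x) {
  if (l == 0L) return(-spherical_bessel(1L, x))
  out <- numeric(length(x))
  small <- x < 1e-4
  if (any(!small)) {
    xs <- x[!small]
    out[!small] <- spherical_bessel(l - 1L, xs) -
      (l + 1) / xs * spherical_bessel(l, xs)
  }
  if (any(small)) {
    xs <- x[small]
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[small] <- if (l == 1L) 1 / 3 - xs^2 / 10 else
      l * xs^(l - 1) / dfact
  }
  out
}

# positive zeros z_{l,1..n} of j_l, via interlacing brackets
# z_{l-1,k} < z_{l,k} < z_{l-1,k+1}; memoized per session
.bessel_zero_cache <- new.env(parent = emptyenv())

bessel_zeros <- function(l, n) {
  key <- as.character(l)
  have <- .bessel_zero_cache[[key]]
  if (!is.null(have) && length(have) >= n) return(have[seq_len(n)])
  if (l == 0L) {
    z <- pi * seq_len(n)
  } else {
    lower <- bessel_zeros(l - 1L, n + 1L)
    z <- vapply(seq_len(n), function(k) {
      f <- function(x) spherical_bessel(l, x)
      lo <- lower[k]; hi <- lower[k + 1]
      r <- tryCatch(
        stats::uniroot(f, c(lo + 1e-10, hi - 1e-10), tol = 1e-14)$root,
        error = function(e) NA_real_)
      if (!is.finite(r)) stopf("root bracketing failed for j_%d zero %d", l, k)
      r
    }, numeric(1))
  }
  .bessel_zero_cache[[key]] <- z
  z
}

#' Radial wavenumbers for the Dirichlet spherical-Bessel family
#'
#' Returns \eqn{k_{l,n} = z_{l,n}/R} where \eqn{z_{l,n}} is the n-th
#' positive root of \eqn{j_l}; the Dirichlet condition \eqn{j_l(kR)=0}
#' makes the radial modes orthogonal on \eqn{[0,R]} with weight
#' \eqn{r^2}.
#'
#' @param l Angular degree.
#' @param n_max Number of radial modes, >= 1.
#' @param R Support radius, > 0.
#' @return Strictly increasing numeric vector of length `n_max`.
#' @export
radial_wavenumbers <- function(l, n_max, R) {
  stopifnot(n_max >= 1, R > 0)
  bessel_zeros(as.integer(l), as.integer(n_max)) / R
}

#' Spherical sampling grid with quadrature weights
#'
#' Product quadrature over the ball of radius `R` about `center`:
#' Gauss-Legendre in the radius on \eqn{(0, R]} (weight \eqn{r^2}),
#' Gauss-Legendre in \eqn{\cos\theta}, uniform in \eqn{\phi}. The angular
#' weights sum to \eqn{4\pi}.
#'
#' @param center World coordinates of the sphere center (3-vector).
#' @param R Support radius, > 0.
#' @param n_radial,n_theta,n_phi Node counts per coordinate.
#' @return An object of class `spherical_grid`.
#' @export
spherical_grid <- function(center, R, n_radial, n_theta, n_phi) {
  stopifnot(R > 0, n_radial >= 1, n_theta >= 1, n_phi >= 1)
  gr <- pracma::gaussLegendre(n_radial, 0, R)
  gt <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  structure(list(center = as.numeric(center), R = R,
                 r = gr$x, wr = gr$w,
                 ct = gt$x, wt = gt$w,
                 phi = phi, wphi = 2 * pi / n_phi),
            class = "spherical_grid")
}

# Flattened grid nodes: theta fastest, then phi, then r.
# w includes the full measure r^2 sin(theta) dr dtheta dphi.
grid_points <- function(grid) {
  nt <- length(grid$ct); np <- length(grid$phi); nr <- length(grid$r)
  theta <- acos(grid$ct)
  th <- rep(theta, times = np * nr)
  ph <- rep(rep(grid$phi, each = nt), times = nr)
  r <- rep(grid$r, each = nt * np)
  wang <- rep(grid$wt * grid$wphi, times = np * nr)
  wrad <- rep(grid$wr * grid$r^2, each = nt * np)
  list(r = r, theta = th, phi = ph, w = wang * wrad,
       n_angular = nt * np, n_radial = nr)
}

n_basis_functions <- function(L, N) N * (L + 1L)^2

# index bookkeeping: columns ordered l = 0..L, n = 1..N, m = -l..l,
# so degrees 0..L' always occupy a prefix (nested angular families).
basis_column_index <- function(L, N) {
  ls <- ns <- ms <- integer(0)
  for (l in 0:L) for (n in 1:N) {
    ls <- c(ls, rep(l, 2 * l + 1)); ns <- c(ns, rep(n, 2 * l + 1))
    ms <- c(ms, -l:l)
  }
  data.frame(l = ls, n = ns, m = ms)
}

#' Build a spherical-wave basis on a sampling grid
#'
#' Basis functions are \eqn{\Psi_{nlm}(r,\theta,\phi) \propto
#' j_l(k_{l,n} r) Y_{lm}(\theta,\phi)} with Dirichlet wavenumbers
#' \eqn{k_{l,n} = z_{l,n}/R}, scaled so every function has unit norm
#' under the grid quadrature. The total count is \eqn{N (L+1)^2}.
#'
#' @param L Maximum angular degree, >= 0.
#' @param N Number of radial orders, >= 1.
#' @param grid A [spherical_grid()]; must resolve (L, N): at least
#'   \eqn{(L+1)^2} angular nodes and \eqn{2N} radial nodes, otherwise a
#'   warning (or an error with `strict = TRUE`).
#' @param strict Error instead of warn on an under-resolved grid.
#' @return An object of class `swd_basis`.
#' @export
build_basis <- function(L, N, grid, strict = FALSE) {
  stopifnot(inherits(grid, "spherical_grid"), L >= 0, N >= 1)
  L <- as.integer(L); N <- as.integer(N)
  nt <- length(grid$ct); np <- length(grid$phi); nr <- length(grid$r)
  if (nt * np < (L + 1)^2 || nr < 2 * N) {
    msg <- sprintf(
      "grid under-resolved for (L=%d, N=%d): %d angular nodes (need >= %d), %d radial (need >= %d)",
      L, N, nt * np, (L + 1)^2, nr, 2 * N)
    if (strict) stopf("%s", msg) else warnf("%s", msg)
  }
  k <- matrix(0, N, L + 1)
  for (l in 0:L) k[, l + 1] <- radial_wavenumbers(l, N, grid$R)
  b <- structure(list(L = L, N = N, R = grid$R, center = grid$center,
                      k = k, normc = matrix(1, N, L + 1), grid = grid),
                 class = "swd_basis")
  pts <- grid_points(grid)
  A <- basis_matrix(b, pts$r, pts$theta, pts$phi)
  nrm <- sqrt(Re(colSums(Conj(A) * A * pts$w)))
  idx <- basis_column_index(L, N)
  # norm depends on (n, l) only; fold back into the (N, L+1) table
  for (j in which(idx$m == 0)) b$normc[idx$n[j], idx$l[j] + 1] <- 1 / nrm[j]
  b
}

#' @export
print.swd_basis <- function(x, ...) {
  cat(sprintf("<swd_basis L=%d N=%d (%d functions)  R=%.4g  center [%s]>\n",
              x$L, x$N, n_basis_functions(x$L, x$N), x$R,
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Evaluate all basis functions at spherical points
#'
#' @param basis An `swd_basis`.
#' @param r,theta,phi Spherical coordinates about the basis center.
#' @return Complex matrix, points x functions, columns ordered as in
#'   `basis_column_index`.
#' @keywords internal
basis_matrix <- function(basis, r, theta, phi) {
  swd_eval_core(basis, r, theta, phi, coef = NULL, gradient = FALSE)
}

# Shared evaluation engine for the spherical-wave family.
# coef = NULL          -> returns the full points x functions matrix
# coef = complex array -> returns the synthesis  sum c_nlm Psi_nlm
#                         (gradient = TRUE: list(f, gx, gy, gz) with the
#                         gradient assembled from analytic derivatives)
swd_eval_core <- function(basis, r, theta, phi, coef = NULL, gradient = FALSE) {
  L <- basis$L; N <- basis$N
  npts <- length(r)
  cth <- cos(theta); sth <- sin(theta)
  cph <- cos(phi); sph <- sin(phi)
  eip <- complex(real = cph, imaginary = sph)
  E <- vector("list", L + 1)  # e^{i m phi}, m = 0..L
  E[[1]] <- rep(1 + 0i, npts)
  if (L >= 1) for (m in 1:L) E[[m + 1]] <- E[[m]] * eip
  as_matrix <- is.null(coef)
  if (as_matrix) {
    out <- matrix(0i, npts, n_basis_functions(L, N))
  } else {
    f <- rep(0i, npts)
    if (gradient) gx <- gy <- gz <- rep(0i, npts)
  }
  if (gradient) {
    eps <- 1e-9
    rc <- pmax(r, eps)
    sthc <- pmax(sth, eps)
  }
  col <- 0L
  for (l in 0:L) {
    Yb <- legendre_norm(l, cth)
    Ym <- vector("list", 2 * l + 1)  # Y_lm, index m + l + 1
    for (m in 0:l) {
      Ym[[m + l + 1]] <- Yb[m + 1, ] * E[[m + 1]]
      if (m > 0) Ym[[-m + l + 1]] <- (-1)^m * Conj(Ym[[m + l + 1]])
    }
    dY <- NULL
    if (gradient) {
      emip <- Conj(eip)
      dY <- vector("list", 2 * l + 1)
      for (m in -l:l) {
        up <- if (m + 1 <= l) 0.5 * sqrt((l - m) * (l + m + 1)) *
          Ym[[m + 1 + l + 1]] * emip else 0
        dn <- if (m - 1 >= -l) 0.5 * sqrt((l + m) * (l - m + 1)) *
          Ym[[m - 1 + l + 1]] * eip else 0
        dY[[m + l + 1]] <- up - dn
      }
    }
    for (n in 1:N) {
      kr <- basis$k[n, l + 1] * r
      Rad <- basis$normc[n, l + 1] * spherical_bessel(l, kr)
      if (gradient)
        dRad <- basis$normc[n, l + 1] * basis$k[n, l + 1] *
          spherical_bessel_deriv(l, kr)
      for (m in -l:l) {
        col <- col + 1L
        Y <- Ym[[m + l + 1]]
        if (as_matrix) {
          out[, col] <- Rad * Y
        } else {
          cf <- coef[n, l + 1, m + l + 1]
          if (cf == 0) next
          f <- f + cf * (Rad * Y)
          if (gradient) {
            tr <- dRad * Y                 # d/dr
            tt <- (Rad / rc) * dY[[m + l + 1]]  # (1/r) d/dtheta
            tp <- if (m == 0) 0 else
              (1i * m) * (Rad * Y) / (rc * sthc)  # (1/(r sin)) d/dphi
            gx <- gx + cf * (sth * cph * tr + cth * cph * tt - sph * tp)
            gy <- gy + cf * (sth * sph * tr + cth * sph * tt + cph * tp)
            gz <- gz + cf * (cth * tr - sth * tt)
          }
        }
      }
    }
  }
  if (as_matrix) return(out)
  if (gradient) list(f = f, gx = gx, gy = gy, gz = gz) else f
}

#' Sample a volume at the nodes of a spherical grid
#'
#' Converts each \eqn{(r,\theta,\phi)} node to world coordinates and
#' interpolates trilinearly. Nodes falling outside the volume get fill
#' value 0; their count is recorded in attribute `n_clipped` (and logged).
#'
#' @param v A [volume()].
#' @param grid A [spherical_grid()]; the center must lie inside the
#'   volume's world extent.
#' @return Numeric vector of samples in `grid_points` order.
#' @export
sample_volume_spherical <- function(v, grid) {
  stopifnot(is_volume(v), inherits(grid, "spherical_grid"))
  d <- dim(v$data)
  lo <- v$origin; hi <- v$origin + (d - 1) * v$spacing
  ctr <- grid$center
  if (any(ctr < lo) || any(ctr > hi))
    stopf("grid center [%s] outside volume extent",
          paste(signif(ctr, 4), collapse = ", "))
  pts <- grid_points(grid)
  wx <- ctr[1] + pts$r * sin(pts$theta) * cos(pts$phi)
  wy <- ctr[2] + pts$r * sin(pts$theta) * sin(pts$phi)
  wz <- ctr[3] + pts$r * cos(pts$theta)
  outside <- wx < lo[1] | wx > hi[1] | wy < lo[2] | wy > hi[2] |
    wz < lo[3] | wz > hi[3]
  vals <- sample_world(v, wx, wy, wz, fill = 0)
  if (any(outside))
    swd_log(sum(outside), " spherical nodes outside volume, filled with 0")
  attr(vals, "n_clipped") <- sum(outside)
  vals
}
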