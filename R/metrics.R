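#' Mean squared intensity difference over the support union
#'
#' The basic volumetric similarity measure: the mean of \eqn{(a-b)^2} over
#' voxels where either volume is nonzero (all voxels when both volumes
#' have full support). Symmetric, nonnegative, zero iff the volumes agree
#' on their joint support.
#'
#' @param a,b [volume()]s (or 3D arrays) of equal shape.
#' @return Scalar MSD (intensity^2 units).
#' @export
similarity_msd <- function(a, b) {
  da <- if (is_volume(a)) a$data else a
  db <- if (is_volume(b)) b$data else b
  if (!identical(dim(da), dim(db))) stopf("shape mismatch in similarity_msd")
  sup <- da != 0 | db != 0
  if (!any(sup)) return(0)
  mean((da[sup] - db[sup])^2)
}

#' Bandwidth-resolved dissimilarity map
#'
#' Reconstructs two coefficient sets at a common truncated angular
#' bandwidth L' and marks voxels whose absolute reconstruction difference
#' exceeds `tau` times the joint intensity scale (99th percentile of the
#' absolute reconstructions) as dissimilar. At low bandwidth only gross
#' shape differs; raising L' exposes progressively finer differences, so
#' the dissimilar fraction grows with L'.
#'
#' @param a,b `swd_coefficients` objects.
#' @param Lp Comparison bandwidth, `<= min(a$L, b$L)`.
#' @param like Target geometry for the reconstructions.
#' @param tau Relative threshold (default 0.1).
#' @return List: `map` (a [volume()] of 0/1 dissimilarity flags) and
#'   `fraction` (dissimilar fraction of the target volume).
#' @export
dissimilarity_map <- function(a, b, Lp, like, tau = 0.1) {
  stopifnot(inherits(a, "swd_coefficients"), inherits(b, "swd_coefficients"))
  if (Lp > min(a$L, b$L))
    stopf("bandwidth L'=%d exceeds the available degree %d", Lp, min(a$L, b$L))
  ra <- swd_inverse(truncate_swd(a, Lp), like)
  rb <- swd_inverse(truncate_swd(b, Lp), like)
  scale <- stats::quantile(abs(c(ra$data, rb$data)), 0.99, names = FALSE)
  if (scale <= 0) scale <- max(abs(c(ra$data, rb$data)), 1e-12)
  dis <- abs(ra$data - rb$data) > tau * scale
  list(map = volume(dis * 1, ra$spacing, ra$origin), fraction = mean(dis))
}

# drop angular degrees above Lp (keeps the container's full tables)
truncate_swd <- function(sc, Lp) {
  if (Lp >= sc$L) return(sc)
  sc$c <- sc$c[, seq_len(Lp + 1), seq_len(2 * Lp + 1), drop = FALSE]
  sc$k <- sc$k[, seq_len(Lp + 1), drop = FALSE]
  sc$normc <- sc$normc[, seq_len(Lp + 1), drop = FALSE]
  sc$L <- as.integer(Lp)
  sc
}

#' Rigid pre-alignment by intensity centroid and principal axes
#'
#' Estimates the translation and rotation between two volumes from their
#' intensity centroids and second-moment principal axes (axis signs fixed
#' by third moments), and resamples the moving volume onto the fixed grid.
#' This captures pose/posture, so only genuinely non-rigid shape change is
#' left for the non-linear registration.
#'
#' @param moving,fixed [volume()]s.
#' @return List: `aligned` (moving resampled into fixed space),
#'   `translation` (world), `rotation` (3x3), `rotation_angle_deg`.
#' @export
rigid_align <- function(moving, fixed) {
  stopifnot(is_volume(moving), is_volume(fixed))
  mo <- moments_frame(moving)
  fo <- moments_frame(fixed)
  Rm <- mo$axes %*% t(fo$axes)  # fixed frame -> moving frame
  d <- dim(fixed$data)
  cw <- voxel_world_coords(fixed)
  rel <- rbind(as.vector(cw$x) - fo$center[1],
               as.vector(cw$y) - fo$center[2],
               as.vector(cw$z) - fo$center[3])
  src <- Rm %*% rel + mo$center
  vals <- sample_world(moving, src[1, ], src[2, ], src[3, ])
  ang <- acos(pmin(1, pmax(-1, (sum(diag(Rm)) - 1) / 2))) * 180 / pi
  list(aligned = volume(array(vals, d), fixed$spacing, fixed$origin),
       translation = mo$center - fo$center, rotation = Rm,
       rotation_angle_deg = ang)
}

moments_frame <- function(v) {
  w <- pmax(v$data, 0)
  tot <- sum(w)
  if (tot <= 0) stopf("cannot orient an empty volume")
  cw <- voxel_world_coords(v)
  ctr <- c(sum(cw$x * w), sum(cw$y * w), sum(cw$z * w)) / tot
  dx <- as.vector(cw$x) - ctr[1]
  dy <- as.vector(cw$y) - ctr[2]
  dz <- as.vector(cw$z) - ctr[3]
  wv <- as.vector(w)
  S <- matrix(c(sum(wv * dx * dx), sum(wv * dx * dy), sum(wv * dx * dz),
                sum(wv * dx * dy), sum(wv * dy * dy), sum(wv * dy * dz),
                sum(wv * dx * dz), sum(wv * dy * dz), sum(wv * dz * dz)),
              3, 3) / tot
  eg <- eigen(S, symmetric = TRUE)
  U <- eg$vectors
  D <- cbind(dx, dy, dz)
  for (i in 1:3) {
    proj <- D %*% U[, i]
    skew <- sum(wv * proj^3)
    if (abs(skew) > 1e-6 * tot * max(abs(proj))^3) {
      if (skew < 0) U[, i] <- -U[, i]
    } else if (U[which.max(abs(U[, i])), i] < 0) {
      U[, i] <- -U[, i]
    }
  }
  if (det(U) < 0) U[, 3] <- -U[, 3]
  list(center = ctr, axes = U, eigenvalues = eg$values)
}

#' Posture-factored morphological distance between two volumes
#'
#' Rigidly pre-aligns `b` to `a` (the rigid/posture component, reported
#' separately), runs the non-linear registration, and combines the
#' post-warp residual with the non-rigid deformation magnitude:
#' \deqn{d = \mathrm{RMS\ residual}/s \; + \; \lambda \,
#'   \overline{|w|}/R}
#' where *s* is the joint 99th-percentile intensity scale and *R* the
#' support radius of `a` in voxels. Both terms are dimensionless: the
#' first measures what the warp could not explain, the second how much
#' non-rigid shape change relative to object size was needed — after a
#' successful warp the deformation term carries the morphological signal.
#' `lambda` defaults to 1.
#'
#' @param a,b [volume()]s of equal shape (roughly overlapping objects).
#' @param reg_params Passed to [register()].
#' @param lambda Weight of the deformation-magnitude term.
#' @param tau Threshold for the reported dissimilar fraction.
#' @return Object of class `comparison_report`: `msd` (post-warp),
#'   `msd_prealign`, `dissimilar_fraction`, `deformation_magnitude`
#'   (mean non-rigid displacement, voxels), `morphological_distance`,
#'   `rigid` (translation, rotation angle), `jacobian_min`.
#' @export
morphological_distance <- function(a, b, reg_params = list(), lambda = 1,
                                   tau = 0.1) {
  stopifnot(is_volume(a), is_volume(b))
  ra <- rigid_align(b, a)
  pre_msd <- similarity_msd(a, ra$aligned)
  rr <- register(ra$aligned, a, reg_params)
  res_msd <- similarity_msd(a, rr$warped)
  wv <- rr$warp$vectors
  wmag <- sqrt(wv[, , , 1]^2 + wv[, , , 2]^2 + wv[, , , 3]^2)
  sup <- a$data != 0 | rr$warped$data != 0
  defmag <- if (any(sup)) mean(wmag[sup]) else mean(wmag)
  scale <- stats::quantile(abs(c(a$data, b$data)), 0.99, names = FALSE)
  if (scale <= 0) scale <- max(abs(c(a$data, b$data)), 1e-12)
  r_obj <- auto_support(a)$R / mean(a$spacing)  # object size, voxels
  dist <- sqrt(res_msd) / scale + lambda * defmag / r_obj
  dfrac <- if (any(sup))
    mean(abs(a$data[sup] - rr$warped$data[sup]) > tau * scale) else 0
  structure(list(msd = res_msd, msd_prealign = pre_msd,
                 dissimilar_fraction = dfrac,
                 deformation_magnitude = defmag,
                 morphological_distance = dist,
                 rigid = list(translation = ra$translation,
                              rotation_angle_deg = ra$rotation_angle_deg),
                 jacobian_min = rr$jacobian_min),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    paste0("<comparison_report  distance %.4g  (MSD %.4g -> %.4g, ",
           "deformation %.3g vox, rigid %.1f deg)>\n"),
    x$morphological_distance, x$msd_prealign, x$msd,
    x$deformation_magnitude, x$rigid$rotation_angle_deg))
  invisible(x)
}

#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm with deterministic lexicographic tie-breaking on the
#' node pair. Relates a collection of specimens through their smallest
#' pairwise morphological distances.
#'
#' @param D Symmetric nonnegative matrix with zero diagonal.
#' @return Data frame of n-1 edges (`from`, `to`, 1-based, `from < to`)
#'   with their weights, ordered as added; attribute `total_weight`.
#' @export
distance_matrix_mst <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n) stopf("D must be square")
  if (any(D < 0)) stopf("D must be nonnegative")
  if (any(abs(diag(D)) > 1e-12)) stopf("D must have zero diagonal")
  if (any(abs(D - t(D)) > 1e-9 * (1 + max(D)))) stopf("D must be symmetric")
  if (n == 1) return(data.frame(from = integer(0), to = integer(0),
                                weight = numeric(0)))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- data.frame(from = integer(n - 1), to = integer(n - 1),
                      weight = numeric(n - 1))
  for (e in seq_len(n - 1)) {
    best <- NULL
    for (i in which(in_tree)) for (j in which(!in_tree)) {
      cand <- c(D[i, j], min(i, j), max(i, j))
      if (is.null(best) ||
          cand[1] < best[1] - 0 ||
          (cand[1] == best[1] &&
             (cand[2] < best[2] || (cand[2] == best[2] && cand[3] < best[3]))))
        best <- cand
    }
    edges[e, ] <- c(min(best[2], best[3]), max(best[2], best[3]), best[1])
    in_tree[if (in_tree[best[2]]) best[3] else best[2]] <- TRUE
  }
  attr(edges, "total_weight") <- sum(edges$weight)
  edges
}

#' Newick export of a minimum spanning tree
#'
#' Serializes the MST as an unrooted tree in Newick format (rooted at the
#' first node for writing), with edge lengths equal to the MST weights.
#'
#' @param edges Edge data frame from [distance_matrix_mst()].
#' @param labels Optional tip labels (default `n1`, `n2`, ...).
#' @return Newick string (terminated by `;`).
#' @export
mst_to_newick <- function(edges, labels = NULL) {
  n <- max(c(edges$from, edges$to, 1))
  labels <- labels %||% paste0("n", seq_len(n))
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    adj[[edges$from[e]]] <- rbind(adj[[edges$from[e]]],
                                  c(edges$to[e], edges$weight[e]))
    adj[[edges$to[e]]] <- rbind(adj[[edges$to[e]]],
                                c(edges$from[e], edges$weight[e]))
  }
  rec <- function(node, parent) {
    kids <- adj[[node]]
    kids <- kids[kids[, 1] != parent, , drop = FALSE]
    if (!nrow(kids)) return(labels[node])
    inner <- paste(vapply(seq_len(nrow(kids)), function(i)
      sprintf("%s:%g", rec(kids[i, 1], node), kids[i, 2]), character(1)),
      collapse = ",")
    sprintf("(%s)%s", inner, labels[node])
  }
  paste0(rec(1, 0), ";")
}
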