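#' Absolute orientation (Kabsch): rigid transform mapping P onto Q
#'
#' Finds rotation R and translation t minimizing sum ||Q_i - (R P_i + t)||^2,
#' with the reflection case corrected via the sign of the smallest singular
#' value. Three non-collinear point pairs suffice.
#'
#' @param P,Q n x 3 matrices of paired points.
#' @return a [rigid_pose] with `Q ~ R P + t`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_pose(R, cq - as.numeric(R %*% cp))
}

#' Grunert's perspective-three-point solver
#'
#' Recovers the camera-from-world pose candidates from three 2D-3D
#' correspondences. The classical distance system (law of cosines on the
#' three viewing rays) is reduced to a degree-4 polynomial in the distance
#' ratio v = s3/s1; rather than transcribing closed-form quartic
#' coefficients, the polynomial is reconstructed exactly by evaluating the
#' cleared-denominator form at five abscissae and solving the Vandermonde
#' system, then rooted with [polyroot].
#'
#' @param P3 3 x 3 matrix of world points (rows).
#' @param rays 3 x 3 matrix of unit viewing rays in the camera frame (rows).
#' @return list of candidate [rigid_pose]s (0 to 4).
#' @export
p3p_grunert <- function(P3, rays) {
  P3 <- as.matrix(P3); rays <- as.matrix(rays)
  a <- sqrt(sum((P3[2L, ] - P3[3L, ])^2))   # opposite ray pair (2,3)
  b <- sqrt(sum((P3[1L, ] - P3[3L, ])^2))   # (1,3)
  cc <- sqrt(sum((P3[1L, ] - P3[2L, ])^2))  # (1,2)
  if (min(a, b, cc) < 1e-9) return(list())
  cos_al <- sum(rays[2L, ] * rays[3L, ])
  cos_be <- sum(rays[1L, ] * rays[3L, ])
  cos_ga <- sum(rays[1L, ] * rays[2L, ])

  # u(v) from the difference of the two homogeneous constraints:
  #   u = [ (c^2 - a^2)(1 + v^2 - 2 v cos_be) - b^2 (1 - v^2) ]
  #       / [ 2 b^2 (v cos_al - cos_ga) ]
  num_u <- function(v) (cc^2 - a^2) * (1 + v^2 - 2 * v * cos_be) -
    b^2 * (1 - v^2)
  den_u <- function(v) 2 * b^2 * (v * cos_al - cos_ga)
  # constraint (b^2 u^2 - 2 b^2 cos_ga u + b^2 - c^2 (1 + v^2 - 2 v cos_be))
  # multiplied by den_u(v)^2 is a degree-4 polynomial in v
  g <- function(v) {
    n <- num_u(v); d <- den_u(v)
    b^2 * n^2 - 2 * b^2 * cos_ga * n * d +
      (b^2 - cc^2 * (1 + v^2 - 2 * v * cos_be)) * d^2
  }
  vs <- c(-2, -1, 0, 1, 2)
  coef <- solve(outer(vs, 0:4, `^`), vapply(vs, g, numeric(1L)))
  if (max(abs(coef)) < 1e-12) return(list())
  roots <- polyroot(coef)
  vreal <- Re(roots[abs(Im(roots)) < 1e-6 * (1 + abs(Re(roots)))])
  vreal <- vreal[vreal > 1e-9]

  out <- list()
  for (v in vreal) {
    s1sq <- b^2 / (1 + v^2 - 2 * v * cos_be)
    if (s1sq <= 0) next
    s1 <- sqrt(s1sq)
    dv <- den_u(v)
    if (abs(dv) > 1e-9 * b^2) {
      us <- num_u(v) / dv
    } else {
      # fall back to the quadratic in u from the (1,2) constraint
      disc <- cos_ga^2 - 1 + cc^2 / s1sq
      if (disc < 0) next
      us <- c(cos_ga + sqrt(disc), cos_ga - sqrt(disc))
    }
    for (u in us) {
      if (!is.finite(u) || u <= 1e-9) next
      s2 <- u * s1; s3 <- v * s1
      # verify all three distance constraints
      r <- c(cc^2 - (s1^2 + s2^2 - 2 * s1 * s2 * cos_ga),
             b^2 - (s1^2 + s3^2 - 2 * s1 * s3 * cos_be),
             a^2 - (s2^2 + s3^2 - 2 * s2 * s3 * cos_al))
      if (max(abs(r)) > 1e-6 * max(a, b, cc)^2) next
      Q <- rays * c(s1, s2, s3)
      pose <- tryCatch(kabsch(P3, Q), error = function(e) NULL)
      if (!is.null(pose)) out[[length(out) + 1L]] <- pose
    }
  }
  out
}

# unit viewing rays in the camera frame for pixel coordinates
pixel_to_rays <- function(uv, cam) {
  uv <- as.matrix(uv)
  d <- cbind((uv[, 1L] - cam$cx) / cam$fx, (uv[, 2L] - cam$cy) / cam$fy, 1)
  d / sqrt(rowSums(d^2))
}

reprojection_errors <- function(pts3d, uv, pose, cam) {
  pr <- project_points(pts3d, pose, cam)
  err <- sqrt(rowSums((pr$uv - uv)^2))
  err[!pr$valid] <- Inf
  err
}

# Levenberg-Marquardt refinement of a pose on a correspondence set
refine_pose <- function(pts3d, uv, cam, init_pose) {
  p0 <- pose_to_params(init_pose)
  resid <- function(p) {
    pose <- tryCatch(params_to_pose(p), error = function(e) NULL)
    if (is.null(pose)) return(rep(1e6, 2L * nrow(uv)))
    pr <- project_points(pts3d, pose, cam)
    r <- as.numeric(pr$uv - uv)
    r[!is.finite(r)] <- 1e6
    r
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-14, ptol = 1e-14))
  params_to_pose(fit$par)
}

#' Are 3D points (near-)coplanar?
#'
#' Coplanar keypoints admit two symmetric camera poses with identical
#' projections, a known pose-flip failure mode of perspective-n-point; the
#' flag documents the condition rather than resolving it.
#'
#' @param pts3d n x 3 matrix.
#' @param tol planar if the smallest singular value of the centred point
#'   matrix is below `tol` times the largest.
#' @return logical scalar.
#' @export
is_planar_configuration <- function(pts3d, tol = 0.01) {
  pts3d <- as.matrix(pts3d)
  if (nrow(pts3d) < 4L) return(TRUE)
  sv <- svd(sweep(pts3d, 2L, colMeans(pts3d)))$d
  sv[3L] < tol * sv[1L]
}

#' RANSAC settings for perspective-n-point registration
#' @param threshold_px reprojection-error inlier threshold (px).
#' @param max_iterations maximum hypothesis draws.
#' @param min_set correspondences per hypothesis (3 drive the minimal P3P
#'   solver, the remainder disambiguate among its candidates).
#' @param confidence adaptive-termination confidence.
#' @param seed RNG seed; fixed seeds give identical results.
#' @return object of class `ransac_settings`.
#' @export
ransac_settings <- function(threshold_px = 3, max_iterations = 1000L,
                            min_set = 4L, confidence = 0.999, seed = 1L) {
  structure(list(threshold_px = threshold_px,
                 max_iterations = as.integer(max_iterations),
                 min_set = as.integer(min_set), confidence = confidence,
                 seed = as.integer(seed)),
            class = "ransac_settings")
}

#' Camera pose from 2D-3D correspondences by PnP + RANSAC
#'
#' Samples minimal subsets, solves perspective-three-point for each (the
#' extra subset points pick among the up-to-four P3P candidates), scores
#' hypotheses by reprojection-error inlier count, and refines the best
#' hypothesis on its inlier consensus with Levenberg-Marquardt. Deterministic
#' under a fixed seed.
#'
#' @param keypoints3d n x 3 matrix of world points (mm).
#' @param keypoints2d_tracked n x 2 matrix of tracked pixel positions.
#' @param cam a [pinhole_camera].
#' @param settings a [ransac_settings].
#' @return list with `success`, `pose` ([rigid_pose] or NULL), `inliers`
#'   (logical vector), `reprojection_px` (per-point errors) and `planar`
#'   (coplanarity flag on the 3D keypoints).
#' @export
pnp_ransac_register <- function(keypoints3d, keypoints2d_tracked, cam,
                                settings = ransac_settings()) {
  P <- as.matrix(keypoints3d)
  uv <- as.matrix(keypoints2d_tracked)
  n <- nrow(P)
  planar <- is_planar_configuration(P)
  fail <- list(success = FALSE, pose = NULL, inliers = rep(FALSE, n),
               reprojection_px = rep(Inf, n), planar = planar)
  if (n < 4L) return(fail)

  set.seed(settings$seed)
  rays <- pixel_to_rays(uv, cam)
  best_pose <- NULL
  best_inl <- -1L
  best_err <- Inf
  needed <- settings$max_iterations
  it <- 0L
  while (it < min(needed, settings$max_iterations)) {
    it <- it + 1L
    idx <- sample.int(n, settings$min_set)
    cands <- p3p_grunert(P[idx[1:3], ], rays[idx[1:3], ])
    if (!length(cands)) next
    extra <- idx[-(1:3)]
    for (pose in cands) {
      # disambiguate on the remaining subset points first
      if (length(extra) &&
          any(reprojection_errors(P[extra, , drop = FALSE],
                                  uv[extra, , drop = FALSE], pose, cam) >
              settings$threshold_px)) next
      err <- reprojection_errors(P, uv, pose, cam)
      inl <- sum(err < settings$threshold_px)
      if (inl > best_inl ||
          (inl == best_inl && median(err) < best_err)) {
        best_inl <- inl
        best_err <- median(err)
        best_pose <- pose
        w <- max(inl / n, 1e-6)
        needed <- ceiling(log(1 - settings$confidence) /
                          log(1 - w^settings$min_set))
      }
    }
  }
  if (is.null(best_pose) || best_inl < 4L) return(fail)

  err <- reprojection_errors(P, uv, best_pose, cam)
  inliers <- err < settings$threshold_px
  refined <- tryCatch(
    refine_pose(P[inliers, , drop = FALSE], uv[inliers, , drop = FALSE],
                cam, best_pose),
    error = function(e) best_pose)
  err2 <- reprojection_errors(P, uv, refined, cam)
  inliers2 <- err2 < settings$threshold_px
  if (sum(inliers2) < sum(inliers)) {       # keep the better consensus
    refined <- best_pose
    err2 <- err
    inliers2 <- inliers
  }
  list(success = TRUE, pose = refined, inliers = inliers2,
       reprojection_px = err2, planar = planar)
}
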