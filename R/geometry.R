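#' Triangle mesh in millimetre units
#'
#' Light-weight surface mesh container used for organ models, cavity shells and
#' cue submeshes. Vertices are world-frame 3D points in millimetres; faces are
#' 1-based vertex index triples.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param face_labels optional vector of length m with per-face labels
#'   (e.g. anatomical structure names, or original face indices of a parent
#'   mesh for cue submeshes).
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, face_labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertices must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- vertices[faces[, 1L], , drop = FALSE]
    b <- vertices[faces[, 2L], , drop = FALSE]
    cc <- vertices[faces[, 3L], , drop = FALSE]
    n <- cross3(b - a, cc - a)
    area2 <- sqrt(rowSums(n^2))
    if (any(area2 <= 1e-12))
      stop("degenerate (zero-area) face at index ",
           which(area2 <= 1e-12)[1L])
  }
  if (!is.null(face_labels) && length(face_labels) != nrow(faces))
    stop("face_labels must have one entry per face")
  structure(list(vertices = vertices, faces = faces,
                 face_labels = face_labels),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  ext <- apply(x$vertices, 2L, function(v) diff(range(v)))
  cat(sprintf(", bbox %.1f x %.1f x %.1f mm\n", ext[1L], ext[2L], ext[3L]))
  invisible(x)
}

#' Row-wise cross product of two n x 3 matrices
#' @param a,b n x 3 matrices.
#' @return n x 3 matrix of cross products.
#' @keywords internal
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Check that every mesh edge is shared by exactly two faces
#'
#' @param mesh a [triangle_mesh].
#' @return logical scalar; `TRUE` for a closed (watertight) surface.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Pinhole camera intrinsics
#'
#' Convention: the camera looks down +Z in its own frame, x right, y down.
#' Pixel (0, 0) is the centre of the top-left pixel (0-based, pixel-centre
#' sampling), so a world point projects to continuous pixel coordinates
#' `u = fx * X/Z + cx`, `v = fy * Y/Z + cy`.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels (inside the image).
#' @param width,height image size in pixels.
#' @return object of class `pinhole_camera`.
#' @export
pinhole_camera <- function(fx, fy, cx, cy, width, height) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 width = as.integer(width), height = as.integer(height)),
            class = "pinhole_camera")
}

#' @export
print.pinhole_camera <- function(x, ...) {
  cat(sprintf("pinhole_camera: %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Rescale camera intrinsics to a different render resolution
#'
#' @param cam a [pinhole_camera].
#' @param factor scale factor applied to focal lengths, principal point and
#'   image size.
#' @return a [pinhole_camera] at the scaled resolution.
#' @export
scale_camera <- function(cam, factor) {
  pinhole_camera(cam$fx * factor, cam$fy * factor,
                 cam$cx * factor, cam$cy * factor,
                 max(1L, round(cam$width * factor)),
                 max(1L, round(cam$height * factor)))
}

#' Rigid camera-from-world pose
#'
#' Maps world-frame points X into the camera frame as `R %*% X + t`.
#' The camera centre in world coordinates is `-t(R) %*% t`.
#'
#' @param rotation 3 x 3 orthonormal matrix with det +1 (tolerance 1e-6).
#' @param translation numeric length-3 vector (mm).
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal within 1e-6")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must have determinant +1")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cen <- camera_center(x)
  cat(sprintf("rigid_pose (camera-from-world): centre (%.2f, %.2f, %.2f) mm\n",
              cen[1L], cen[2L], cen[3L]))
  invisible(x)
}

#' Camera centre in world coordinates
#' @param pose a [rigid_pose].
#' @return numeric length-3 vector, `-t(R) %*% t`.
#' @export
camera_center <- function(pose) {
  as.numeric(-crossprod(pose$rotation, pose$translation))
}

#' Build the camera-from-world pose with a given world-frame camera centre
#' @param rotation 3 x 3 rotation.
#' @param center world-frame camera centre (mm).
#' @return a [rigid_pose] with `translation = -R %*% center`.
#' @export
pose_from_center <- function(rotation, center) {
  rigid_pose(rotation, -as.numeric(rotation %*% center))
}

#' Map a rotation matrix to the continuous 6D rotation representation
#'
#' The 6D representation stores the first two columns of the rotation matrix;
#' the inverse map recovers the matrix by Gram-Schmidt orthonormalization, so
#' the representation is continuous and well suited to gradient descent.
#'
#' @param R 3 x 3 rotation matrix.
#' @return numeric length-6 vector `c(R[,1], R[,2])`.
#' @export
matrix_to_rotation6d <- function(R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("input is not a rotation matrix")
  c(R[, 1L], R[, 2L])
}

#' Map a 6D rotation parameter vector to a rotation matrix
#'
#' Gram-Schmidt: the first 3-vector is normalized, the second is
#' orthogonalized against it and normalized, the third column is their cross
#' product. Scale-invariant in each 3-vector.
#'
#' @param r6 numeric length-6 vector.
#' @return 3 x 3 rotation matrix with det +1.
#' @export
rotation6d_to_matrix <- function(r6) {
  r6 <- as.numeric(r6)
  if (length(r6) != 6L || !all(is.finite(r6)))
    stop("r6 must be a finite length-6 vector")
  a1 <- r6[1:3]; a2 <- r6[4:6]
  n1 <- sqrt(sum(a1^2))
  if (n1 < 1e-12) stop("degenerate 6D rotation: first vector is zero")
  b1 <- a1 / n1
  u2 <- a2 - sum(b1 * a2) * b1
  n2 <- sqrt(sum(u2^2))
  if (n2 < 1e-12)
    stop("degenerate 6D rotation: vectors are parallel or second is zero")
  b2 <- u2 / n2
  b3 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  cbind(b1, b2, b3, deparse.level = 0L)
}

#' Jacobian of the 6D-to-matrix map
#'
#' Analytic derivative of [rotation6d_to_matrix] with respect to each of the
#' six parameters, used to back-propagate image losses into pose parameters.
#'
#' @param r6 numeric length-6 vector (non-degenerate).
#' @return 3 x 3 x 6 array; `[, , k]` is dR/dr6\[k\].
#' @export
rotation6d_jacobian <- function(r6) {
  a1 <- r6[1:3]; a2 <- r6[4:6]
  n1 <- sqrt(sum(a1^2))
  b1 <- a1 / n1
  P1 <- (diag(3) - tcrossprod(b1)) / n1      # db1/da1
  d <- sum(b1 * a2)
  u2 <- a2 - d * b1
  n2 <- sqrt(sum(u2^2))
  b2 <- u2 / n2
  P2 <- (diag(3) - tcrossprod(b2)) / n2      # db2/du2
  J <- array(0, c(3L, 3L, 6L))
  cross_v <- function(x, y) c(x[2L] * y[3L] - x[3L] * y[2L],
                              x[3L] * y[1L] - x[1L] * y[3L],
                              x[1L] * y[2L] - x[2L] * y[1L])
  for (k in 1:6) {
    if (k <= 3L) {
      db1 <- P1[, k]
      # u2 = a2 - (b1.a2) b1  =>  du2 = -(db1.a2) b1 - (b1.a2) db1
      du2 <- -sum(db1 * a2) * b1 - d * db1
    } else {
      db1 <- c(0, 0, 0)
      ek <- c(0, 0, 0); ek[k - 3L] <- 1
      du2 <- ek - sum(b1 * ek) * b1
    }
    db2 <- as.numeric(P2 %*% du2)
    db3 <- cross_v(db1, b2) + cross_v(b1, db2)
    J[, , k] <- cbind(db1, db2, db3, deparse.level = 0L)
  }
  J
}

#' Project world points through a pinhole camera
#'
#' @param pts n x 3 matrix of world-frame points (mm) or a length-3 vector.
#' @param pose a [rigid_pose] (camera-from-world).
#' @param cam a [pinhole_camera].
#' @return list with `uv` (n x 2 pixel coordinates), `depth` (camera-frame Z,
#'   mm) and `valid` (logical; FALSE for points at or behind the camera,
#'   whose `uv` is NA).
#' @export
project_points <- function(pts, pose, cam) {
  pts <- rbind3(pts)
  pc <- transform_points(pts, pose)
  z <- pc[, 3L]
  valid <- is.finite(z) & z > 0
  u <- cam$fx * pc[, 1L] / z + cam$cx
  v <- cam$fy * pc[, 2L] / z + cam$cy
  u[!valid] <- NA_real_
  v[!valid] <- NA_real_
  list(uv = cbind(u, v, deparse.level = 0L), depth = z, valid = valid)
}

#' Apply a rigid pose to world points
#' @param pts n x 3 matrix or length-3 vector.
#' @param pose a [rigid_pose].
#' @return n x 3 matrix of camera-frame points.
#' @export
transform_points <- function(pts, pose) {
  pts <- rbind3(pts)
  sweep(pts %*% t(pose$rotation), 2L, -pose$translation)
}

rbind3 <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  as.matrix(pts)
}

#' Geodesic rotation error in degrees
#'
#' `acos((trace(t(R_est) %*% R_gt) - 1) / 2)`, clamped to \[0, 180\] degrees.
#' Symmetric in its arguments.
#'
#' @param R_est,R_gt 3 x 3 rotation matrices (or [rigid_pose]s).
#' @return angle in degrees.
#' @export
rotation_error_deg <- function(R_est, R_gt) {
  if (inherits(R_est, "rigid_pose")) R_est <- R_est$rotation
  if (inherits(R_gt, "rigid_pose")) R_gt <- R_gt$rotation
  ctheta <- (sum(diag(crossprod(R_est, R_gt))) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

#' Camera-centre translation error in millimetres
#'
#' Euclidean distance between the two camera centres (`-t(R) %*% t`). The
#' pose perturbation protocol moves the camera position, so pose error is
#' measured on the centre.
#'
#' @param pose_est,pose_gt [rigid_pose]s.
#' @return distance in mm.
#' @export
translation_error_mm <- function(pose_est, pose_gt) {
  sqrt(sum((camera_center(pose_est) - camera_center(pose_gt))^2))
}

#' Rotation matrix from intrinsic XYZ Euler angles (degrees)
#' @param rx,ry,rz rotation angles about x, y, z in degrees.
#' @return 3 x 3 rotation matrix `Rx %*% Ry %*% Rz`.
#' @export
euler_xyz_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Uniformly distributed random rotation matrix
#'
#' Draws a unit quaternion uniformly on S^3 and converts it; uses the current
#' RNG state so results are reproducible under `set.seed`.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Look-at rotation for a camera
#'
#' Builds a camera-from-world rotation whose +Z axis points from `eye`
#' towards `target`, with an optional roll about the viewing axis.
#'
#' @param eye camera centre (world, mm).
#' @param target point the camera looks at (world, mm).
#' @param up approximate up direction in world coordinates.
#' @param roll_deg roll about the optical axis, degrees.
#' @return 3 x 3 rotation matrix (camera-from-world).
#' @export
look_at_rotation <- function(eye, target, up = c(0, 0, 1), roll_deg = 0) {
  zc <- target - eye
  zc <- zc / sqrt(sum(zc^2))
  xc <- cross3(matrix(up, 1L), matrix(zc, 1L))[1L, ]
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-8) {  # viewing axis parallel to up: pick another up
    up <- c(1, 0, 0)
    xc <- cross3(matrix(up, 1L), matrix(zc, 1L))[1L, ]
    nx <- sqrt(sum(xc^2))
  }
  xc <- xc / nx
  yc <- cross3(matrix(zc, 1L), matrix(xc, 1L))[1L, ]
  R <- rbind(xc, yc, zc, deparse.level = 0L)  # camera-from-world
  if (roll_deg != 0) R <- euler_xyz_matrix(0, 0, roll_deg) %*% R
  R
}
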