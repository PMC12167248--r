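test_that("triangle_mesh validates its inputs", {
  m <- square_mesh()
  expect_s3_class(m, "triangle_mesh")
  expect_identical(nrow(m$vertices), 4L)
  expect_identical(nrow(m$faces), 2L)
  expect_error(triangle_mesh(m$vertices, rbind(c(1L, 2L, 9L))), "face")
  expect_error(triangle_mesh(m$vertices, rbind(c(1L, 1L, 2L))))
})

test_that("rigid_pose rejects non-rotations and roundtrips its fields", {
  R <- random_rotation()
  t <- c(1, -2, 3)
  p <- rigid_pose(R, t)
  expect_equal(p$rotation, R)
  expect_equal(p$translation, t)
  expect_error(rigid_pose(R * 1.01, t), "rotation")
  expect_error(rigid_pose(R[, c(2, 1, 3)], t), "rotation")
})

test_that("camera_center and pose_from_center are mutually inverse", {
  set.seed(7)
  for (i in 1:20) {
    R <- random_rotation()
    cen <- stats::runif(3, -100, 100)
    p <- pose_from_center(R, cen)
    expect_equal(camera_center(p), cen, tolerance = 1e-10)
    # C = -R^T t by definition
    expect_equal(camera_center(p), -as.numeric(crossprod(R, p$translation)),
                 tolerance = 1e-12)
  }
})

test_that("6D rotation representation roundtrips over 1000 rotations", {
  set.seed(1)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    R2 <- rotation6d_to_matrix(matrix_to_rotation6d(R))
    worst <- max(worst, max(abs(R2 - R)))
  }
  expect_lt(worst, 1e-6)
})

test_that("rotation6d_to_matrix always yields a proper rotation", {
  set.seed(2)
  for (i in 1:50) {
    r6 <- stats::rnorm(6)
    R <- rotation6d_to_matrix(r6)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  expect_error(rotation6d_to_matrix(c(0, 0, 0, 1, 0, 0)), "degenerate")
})

test_that("rotation6d_jacobian matches central finite differences", {
  set.seed(3)
  for (i in 1:10) {
    r6 <- stats::rnorm(6)
    J <- rotation6d_jacobian(r6)
    h <- 1e-6
    for (k in 1:6) {
      e <- numeric(6); e[k] <- h
      fd <- (rotation6d_to_matrix(r6 + e) - rotation6d_to_matrix(r6 - e)) /
        (2 * h)
      expect_equal(J[, , k], fd, tolerance = 1e-4)
    }
  }
})

test_that("project_points matches the closed-form pinhole model", {
  cam <- test_camera()
  # identity pose: u = fx*X/Z + cx, v = fy*Y/Z + cy
  p <- rigid_pose(diag(3), c(0, 0, 0))
  pts <- rbind(c(0, 0, 100), c(10, -20, 200), c(-5, 5, 50))
  uv <- project_points(pts, p, cam)$uv
  expect_equal(uv[, 1], 500 * pts[, 1] / pts[, 3] + 320)
  expect_equal(uv[, 2], 500 * pts[, 2] / pts[, 3] + 256)
  # a world point on the optical axis projects to the principal point
  # under any pose
  set.seed(4)
  for (i in 1:10) {
    pose <- random_pose()
    cen <- camera_center(pose)
    ahead <- cen + as.numeric(crossprod(pose$rotation, c(0, 0, 1))) * 75
    expect_equal(as.numeric(project_points(rbind(ahead), pose, cam)$uv),
                 c(cam$cx, cam$cy), tolerance = 1e-8)
  }
})

test_that("transform_points maps world to camera frame", {
  set.seed(5)
  pose <- random_pose()
  pts <- matrix(stats::rnorm(30), 10, 3)
  pc <- transform_points(pts, pose)
  for (i in 1:10)
    expect_equal(pc[i, ],
                 as.numeric(pose$rotation %*% pts[i, ] + pose$translation),
                 tolerance = 1e-12)
  # the camera centre maps to the origin
  expect_equal(as.numeric(transform_points(rbind(camera_center(pose)), pose)),
               c(0, 0, 0), tolerance = 1e-10)
})

test_that("rotation_error_deg is the geodesic angle", {
  R <- random_rotation()
  expect_equal(rotation_error_deg(R, R), 0, tolerance = 1e-6)
  # rotating about any axis by theta gives error exactly theta
  set.seed(6)
  for (theta in c(0.5, 5, 30, 120)) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    th <- theta * pi / 180
    Rd <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_equal(rotation_error_deg(R, R %*% Rd), theta, tolerance = 1e-6)
  }
})

test_that("translation_error_mm compares camera centres, not t vectors", {
  R1 <- random_rotation()
  R2 <- random_rotation()
  cen <- c(10, 20, 30)
  p1 <- pose_from_center(R1, cen)
  p2 <- pose_from_center(R2, cen + c(3, 0, 4))
  # same centre offset by (3,0,4): error 5 regardless of rotations
  expect_equal(translation_error_mm(p1, p2), 5, tolerance = 1e-10)
  expect_equal(translation_error_mm(p1, p1), 0, tolerance = 1e-12)
})

test_that("euler_xyz_matrix composes Rx %*% Ry %*% Rz in degrees", {
  deg <- c(17, -29, 63)
  a <- deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  expect_equal(euler_xyz_matrix(deg[1], deg[2], deg[3]), Rx %*% Ry %*% Rz,
               tolerance = 1e-12)
  # a single-axis rotation of theta degrees has geodesic error theta
  expect_equal(rotation_error_deg(diag(3), euler_xyz_matrix(0, 40, 0)), 40,
               tolerance = 1e-8)
})

test_that("look_at_rotation points +Z at the target with y down", {
  eye <- c(0, 0, -100); target <- c(0, 0, 0)
  R <- look_at_rotation(eye, target)
  expect_equal(crossprod(R), diag(3), tolerance = 1e-10)
  expect_equal(det(R), 1, tolerance = 1e-10)
  # the camera-frame z axis (third row of R) is the view direction
  d <- (target - eye) / sqrt(sum((target - eye)^2))
  expect_equal(as.numeric(R[3, ]), d, tolerance = 1e-10)
  # and the target projects to the principal point
  cam <- test_camera()
  pose <- pose_from_center(R, eye)
  expect_equal(as.numeric(project_points(rbind(target), pose, cam)$uv),
               c(cam$cx, cam$cy), tolerance = 1e-8)
})

test_that("is_watertight distinguishes closed from open meshes", {
  expect_true(is_watertight(icosphere(1L)))
  open_m <- square_mesh()
  expect_false(is_watertight(open_m))
})
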