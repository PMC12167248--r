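test_that("rasterize_polyline_mask covers an axis-aligned segment exactly", {
  # a horizontal stroke at v = 50 from u = 100 to 140, thickness 5:
  # every pixel centre within 2.5 px of the segment is inside
  kp <- rbind(c(100, 50), c(140, 50))
  mask <- rasterize_polyline_mask(kp, image_size = c(200L, 100L),
                                  thickness_px = 5, closed = FALSE)
  expect_identical(dim(mask), c(100L, 200L))
  grid <- expand.grid(u = 0:199, v = 0:99)
  du <- pmax(100 - grid$u, 0, grid$u - 140)
  dv <- abs(grid$v - 50)
  inside <- sqrt(du^2 + dv^2) <= 2.5
  expect_identical(mask[cbind(grid$v + 1L, grid$u + 1L)],
                   as.integer(inside))
})

test_that("closed strokes fill the gap between last and first keypoint", {
  kp <- rbind(c(50, 50), c(90, 50), c(90, 90), c(50, 90))
  open_m <- rasterize_polyline_mask(kp, c(150L, 150L), 5, closed = FALSE)
  closed_m <- rasterize_polyline_mask(kp, c(150L, 150L), 5, closed = TRUE)
  # the closing edge runs along u = 50 between v = 50 and 90
  expect_identical(open_m[71, 51], 0L)
  expect_identical(closed_m[71, 51], 1L)
  expect_true(all(closed_m >= open_m))
})

test_that("rasterize_polyline_mask validates inputs", {
  expect_error(rasterize_polyline_mask(matrix(0, 0, 2), c(100L, 100L)))
  expect_error(rasterize_polyline_mask(rbind(c(500, 50)), c(100L, 100L)),
               "bounds")
})

test_that("resample_stroke spaces points at the requested arc length", {
  stroke <- rbind(c(0, 0), c(100, 0))
  rs <- resample_stroke(stroke, spacing_px = 10, closed = FALSE)
  d <- sqrt(rowSums(diff(rs)^2))
  expect_true(all(abs(d - 10) < 1e-6))
  expect_equal(rs[1, ], c(0, 0))
  expect_equal(rs[nrow(rs), ], c(100, 0), tolerance = 1e-9)
})

test_that("pixel_rays agree with project_points (projection closure)", {
  set.seed(12)
  cam <- test_camera()
  pose <- pose_from_center(look_at_rotation(c(0, 0, -80), c(0, 0, 0)),
                           c(0, 0, -80))
  uv <- cbind(runif(20, 0, cam$width - 1), runif(20, 0, cam$height - 1))
  rays <- pixel_rays(uv, pose, cam)
  # marching any positive distance along the ray re-projects to uv
  for (s in c(10, 55)) {
    pts <- sweep(rays$dirs * s, 2L, rays$origin, "+")
    expect_equal(project_points(pts, pose, cam)$uv, uv, tolerance = 1e-8)
  }
})

test_that("lift_cue_to_mesh recovers surface points and parent faces", {
  scene <- shared_scene()
  cue <- scene$cue
  # lifted keypoints lie on the organ: re-cast rays in plain R and compare
  cam <- scene$camera
  pose <- scene$keyframe_pose
  origin <- camera_center(pose)
  for (i in seq_len(nrow(cue$keypoints2d))) {
    d <- pixel_rays(cue$keypoints2d[i, , drop = FALSE], pose, cam)
    hit <- raycast_oracle_r(origin, d$dirs[1L, ], scene$organ)
    expect_equal(cue$keypoints3d[i, ], hit$point, tolerance = 1e-6)
  }
  # keypoints re-project onto the drawn 2D keypoints
  uv <- project_points(cue$keypoints3d, pose, cam)$uv
  expect_lt(max(abs(uv - cue$keypoints2d)), 1e-6)
  # the submesh faces are faces of the parent organ
  sm <- cue$submesh3d
  expect_true(all(sm$face_labels %in% seq_len(nrow(scene$organ$faces))))
  parent <- scene$organ$faces[sm$face_labels, , drop = FALSE]
  for (f in seq_len(nrow(sm$faces)))
    expect_equal(sm$vertices[sm$faces[f, ], ],
                 scene$organ$vertices[parent[f, ], ], tolerance = 1e-12)
})

test_that("lift_cue_to_mesh errors when a keypoint misses the mesh", {
  organ <- icosphere(1L)
  cam <- test_camera()
  pose <- pose_from_center(look_at_rotation(c(0, 0, -50), c(0, 0, 0)),
                           c(0, 0, -50))
  kp <- rbind(c(320, 256), c(5, 5))  # second ray misses the unit sphere
  mask <- rasterize_polyline_mask(rbind(c(320, 256), c(322, 256)),
                                  c(cam$width, cam$height))
  expect_error(lift_cue_to_mesh(kp, mask, organ, pose, cam), "2")
})

test_that("submesh reindexes vertices and keeps geometry identical", {
  m <- icosphere(2L)
  idx <- c(3L, 17L, 40L)
  sm <- submesh(m, idx)
  expect_identical(sm$face_labels, idx)
  expect_identical(nrow(sm$faces), 3L)
  for (k in seq_along(idx))
    expect_equal(sm$vertices[sm$faces[k, ], ],
                 m$vertices[m$faces[idx[k], ], ], tolerance = 1e-15)
})

test_that("render_cue_mask_hard respects occluders", {
  # cue square at z = 100, occluder square at z = 50 covering the left half
  cam <- test_camera()
  pose <- rigid_pose(diag(3), c(0, 0, 0))
  cue_sq <- square_mesh(half = 10, z = 100)
  free <- render_cue_mask_hard(cue_sq, pose, cam)
  occ <- triangle_mesh(rbind(c(-20, -20, 50), c(0, -20, 50),
                             c(0, 20, 50), c(-20, 20, 50)),
                       rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  part <- render_cue_mask_hard(cue_sq, pose, cam, occluders = list(occ))
  expect_gt(sum(free), 0)
  # occluder blocks exactly the pixels left of the principal point
  blocked <- free == 1L & part == 0L
  expect_true(all(which(blocked, arr.ind = TRUE)[, 2] <= cam$cx + 1))
  expect_identical(sum(free == 0L & part == 1L), 0L)
  # oracle cross-check of the unoccluded mask
  expect_identical(free, raycast_mask_oracle(cue_sq, pose, cam))
})

test_that("hard z-buffer rasterizer agrees with per-pixel ray casting", {
  # oracle comparison on random small meshes and random poses
  set.seed(13)
  cam <- test_camera(width = 160L, height = 128L, f = 125)
  for (trial in 1:10) {
    mesh <- generate_organ_shape(trial + 400L, subdivisions = 1L)
    cen <- cuereg:::sample_cone(c(0, 0, 1), 60) * runif(1, 45, 70)
    pose <- pose_from_center(look_at_rotation(cen, c(0, 0, 0)), cen)
    mask <- render_cue_mask_hard(mesh, pose, cam)
    oracle <- raycast_mask_oracle(mesh, pose, cam)
    agree <- mean(mask == oracle)
    expect_gte(agree, 0.995)
  }
})
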