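# Draws a smooth synthetic frame with a few blurred blobs, shifted by an
# integer pixel offset per frame.  Integer shifts make the expected track
# positions exact.
blob_frame <- function(centers, width = 120L, height = 100L, sigma = 4) {
  u <- matrix(rep(0:(width - 1L), each = height), height, width)
  v <- matrix(rep(0:(height - 1L), width), height, width)
  img <- matrix(0, height, width)
  for (i in seq_len(nrow(centers)))
    img <- img + exp(-((u - centers[i, 1])^2 + (v - centers[i, 2])^2) /
                       (2 * sigma^2))
  pmin(img, 1)
}

test_that("tracked_points validates shapes and freeze-on-loss", {
  pos <- array(runif(3 * 2 * 2, 10, 20), c(3, 2, 2))
  vis <- matrix(TRUE, 3, 2)
  tr <- tracked_points(pos, vis)
  expect_s3_class(tr, "tracked_points")
  expect_error(tracked_points(pos, matrix(TRUE, 2, 2)))
  expect_error(tracked_points(array(NA_real_, c(3, 2, 2)), vis))
})

test_that("LK tracking recovers pure integer translations exactly", {
  set.seed(23)
  centers <- rbind(c(30, 40), c(70, 30), c(55, 70), c(85, 60))
  shifts <- rbind(c(0, 0), c(2, 1), c(4, 3), c(6, 4), c(5, 6))
  frames <- lapply(seq_len(nrow(shifts)), function(i)
    blob_frame(sweep(centers, 2L, shifts[i, ], "+")))
  tr <- track_points(frames, centers)
  expect_true(all(tr$visible))
  for (i in seq_len(nrow(shifts))) {
    expected <- sweep(centers, 2L, shifts[i, ], "+")
    expect_lt(max(abs(frame_positions(tr, i) - expected)), 0.1)
  }
})

test_that("LK declares points lost when their texture disappears", {
  set.seed(24)
  centers <- rbind(c(30, 40), c(80, 60))
  f1 <- blob_frame(centers)
  f2 <- blob_frame(centers[1L, , drop = FALSE])  # second blob removed
  tr <- track_points(list(f1, f2), centers)
  expect_true(tr$visible[2L, 1L])
  expect_false(tr$visible[2L, 2L])
  # lost points freeze at their last confident position
  expect_equal(frame_positions(tr, 2L)[2L, ], centers[2L, ],
               tolerance = 1e-9)
})

test_that("a custom tracker function can replace the built-in LK", {
  frames <- lapply(1:3, function(i) matrix(0, 50, 60))
  kp <- rbind(c(10, 10), c(20, 30))
  # drifts every point by +1 px per frame
  drift_tracker <- function(frames, pts) {
    nf <- length(frames); np <- nrow(pts)
    pos <- array(0, c(nf, np, 2L))
    for (i in seq_len(nf)) pos[i, , ] <- pts + (i - 1)
    tracked_points(pos, matrix(TRUE, nf, np))
  }
  tr <- track_points(frames, kp, tracker = drift_tracker)
  expect_equal(frame_positions(tr, 3L), kp + 2, tolerance = 1e-12)
})

test_that("ground-truth tracker projects cue keypoints under true poses", {
  scene <- shared_scene()
  kept <- filter_frames(scene)
  poses <- scene$cameras[kept]
  tr <- track_points_ground_truth(scene$cue$keypoints3d, poses,
                                  scene$camera)
  expect_true(all(tr$visible))
  for (i in seq_along(poses)) {
    uv <- project_points(scene$cue$keypoints3d, poses[[i]],
                         scene$camera)$uv
    expect_equal(frame_positions(tr, i), uv, tolerance = 1e-10)
  }
})

test_that("masks_from_tracks matches direct rasterization when all visible", {
  scene <- shared_scene()
  kp <- scene$cue$keypoints2d
  direct <- rasterize_polyline_mask(kp, c(scene$camera$width,
                                          scene$camera$height),
                                    thickness_px = 5, closed = TRUE)
  pos <- array(0, c(2, nrow(kp), 2))
  pos[1, , ] <- kp; pos[2, , ] <- kp
  tr <- tracked_points(pos, matrix(TRUE, 2, nrow(kp)))
  out <- masks_from_tracks(tr, c(scene$camera$width,
                                 scene$camera$height),
                           thickness = 5, closed = TRUE)
  expect_identical(out$masks[[1]], direct)
  expect_identical(out$masks[[2]], direct)
  expect_identical(out$empty, c(FALSE, FALSE))
})

test_that("masks_from_tracks drops segments touching lost points", {
  kp <- rbind(c(20, 20), c(60, 20), c(60, 60), c(20, 60))
  pos <- array(0, c(1, 4, 2)); pos[1, , ] <- kp
  vis <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4)
  m <- masks_from_tracks(tracked_points(pos, vis), c(100L, 100L),
                         thickness = 5, closed = TRUE)$masks[[1]]
  full <- rasterize_polyline_mask(kp, c(100L, 100L), 5, closed = TRUE)
  # the two segments between visible points 1-2 and 2-3 survive
  seg12 <- rasterize_polyline_mask(kp[1:2, ], c(100L, 100L), 5,
                                   closed = FALSE)
  seg23 <- rasterize_polyline_mask(kp[2:3, ], c(100L, 100L), 5,
                                   closed = FALSE)
  expect_true(all(m >= pmax(seg12, seg23)))
  # segments adjacent to the lost point 4 are gone: the left edge pixels
  expect_identical(m[41, 21], 0L)  # (u=20, v=40) on edge 4-1
  expect_true(sum(m) < sum(full))
})

test_that("midpoint_keypoints forms all C(n,2) midpoints", {
  pts <- cbind(c(0, 10, 4, 8, 2), c(0, 2, 6, 8, 12))
  mid <- midpoint_keypoints(pts)
  expect_identical(nrow(mid), 10L)
  pairs <- utils::combn(5L, 2L)
  expected <- t(apply(pairs, 2L, function(ij)
    colMeans(pts[ij, , drop = FALSE])))
  expect_equal(mid, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("evaluate_tracking reports zero error on perfect tracks", {
  # annotations: 4 keypoints in 2 annotated frames; the tracker carries the
  # C(4,2) = 6 constructed midpoints exactly
  kp <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  ann_pos <- array(0, c(2, 4, 2))
  ann_pos[1, , ] <- kp; ann_pos[2, , ] <- kp + 7
  mid1 <- midpoint_keypoints(kp); mid2 <- midpoint_keypoints(kp + 7)
  pos <- array(0, c(2, 6, 2)); pos[1, , ] <- mid1; pos[2, , ] <- mid2
  tr <- tracked_points(pos, matrix(TRUE, 2, 6))
  ev <- evaluate_tracking(tr, list(frame_idx = c(1L, 2L),
                                   positions = ann_pos))
  expect_equal(ev$median_px, 0, tolerance = 1e-9)
  expect_identical(dim(ev$errors_px), c(2L, 6L))
})

test_that("evaluate_tracking measures a constant offset exactly", {
  kp <- rbind(c(10, 10), c(30, 10), c(30, 30), c(10, 30))
  ann_pos <- array(0, c(1, 4, 2))
  ann_pos[1, , ] <- kp
  # tracked midpoints displaced by (3, 0) from the annotation midpoints
  pos <- array(0, c(2, 6, 2))
  pos[1, , ] <- midpoint_keypoints(kp)
  pos[2, , ] <- midpoint_keypoints(kp) + matrix(c(3, 0), 6, 2, byrow = TRUE)
  tr <- tracked_points(pos, matrix(TRUE, 2, 6))
  ev <- evaluate_tracking(tr, list(frame_idx = 2L, positions = ann_pos))
  expect_equal(ev$median_px, 3, tolerance = 1e-9)
  expect_equal(unname(ev$per_point_median_px), rep(3, 6), tolerance = 1e-9)
  # consecutive-pairs mode scores n = 3 midpoints
  tr2 <- tracked_points(pos[, 1:3, , drop = FALSE],
                        matrix(TRUE, 2, 3))
  expect_error(evaluate_tracking(tr2, list(frame_idx = 2L,
                                           positions = ann_pos)),
               "midpoint")
})
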