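test_that("icosphere has the expected subdivision counts and is closed", {
  expect_identical(dim(icosphere(0L)$vertices), c(12L, 3L))
  expect_identical(dim(icosphere(0L)$faces), c(20L, 3L))
  expect_identical(dim(icosphere(1L)$vertices), c(42L, 3L))
  expect_identical(dim(icosphere(1L)$faces), c(80L, 3L))
  expect_identical(dim(icosphere(3L)$vertices), c(642L, 3L))
  expect_identical(dim(icosphere(3L)$faces), c(1280L, 3L))
  for (s in 0:3) expect_true(is_watertight(icosphere(s)))
  # all vertices on the unit sphere
  expect_lt(max(abs(sqrt(rowSums(icosphere(2L)$vertices^2)) - 1)), 1e-12)
})

test_that("generate_organ_shape is deterministic, watertight, star-shaped", {
  a <- generate_organ_shape(42L)
  b <- generate_organ_shape(42L)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_true(is_watertight(a))
  # star-shaped about the origin: all radial distances strictly positive
  expect_gt(min(sqrt(rowSums(a$vertices^2))), 0)
  # every vertex visible from the origin along its own ray (no folds)
  dirs <- a$vertices / sqrt(rowSums(a$vertices^2))
  hit <- cuereg:::cpp_raycast(c(0, 0, 0), dirs, a$vertices, a$faces - 1L)
  r <- sqrt(rowSums(a$vertices^2))
  expect_lt(max(abs(hit$t - r)), 1e-6)
})

test_that("organ sizes stay inside the size-jitter band around the mean", {
  sizes <- vapply(1:40, function(s) {
    v <- generate_organ_shape(s + 900L)$vertices
    max(apply(v, 2L, function(x) diff(range(x))))
  }, numeric(1L))
  expect_true(all(sizes >= 0.85 * 26.1 - 1e-9))
  expect_true(all(sizes <= 1.15 * 26.1 + 1e-9))
  expect_lt(abs(mean(sizes) - 26.1), 1.0)
})

test_that("perturb_pose respects the per-component uniform bounds", {
  set.seed(25)
  base <- random_pose()
  spec <- perturbation_spec()
  for (i in 1:200) {
    p <- perturb_pose(base, spec)
    dc <- camera_center(p) - camera_center(base)
    expect_true(all(abs(dc) <= 5))
    # the composed rotation decomposes into small XYZ Euler angles
    E <- t(base$rotation) %*% p$rotation
    ry <- asin(max(-1, min(1, E[1, 3]))) * 180 / pi
    rx <- atan2(-E[2, 3], E[3, 3]) * 180 / pi
    rz <- atan2(-E[1, 2], E[1, 1]) * 180 / pi
    expect_true(all(abs(c(rx, ry, rz)) <= 5 + 1e-9))
  }
  # a zero-width spec leaves the pose unchanged
  z <- perturb_pose(base, perturbation_spec(0, 0))
  expect_equal(z$rotation, base$rotation, tolerance = 1e-12)
  expect_equal(camera_center(z), camera_center(base), tolerance = 1e-12)
})

test_that("generate_scene is deterministic and respects its config", {
  scene <- shared_scene()
  again <- generate_scene(scene$seed, scene$config)
  expect_identical(scene$organ$vertices, again$organ$vertices)
  expect_identical(scene$cue$keypoints2d, again$cue$keypoints2d)
  expect_identical(scene$cue_masks, again$cue_masks)
  for (i in seq_along(scene$cameras))
    expect_identical(scene$cameras[[i]]$rotation,
                     again$cameras[[i]]$rotation)

  cfg <- scene$config
  nk <- nrow(scene$cue$keypoints2d)
  expect_gte(nk, cfg$cue_keypoint_range[1])
  expect_lte(nk, cfg$cue_keypoint_range[2])
  expect_identical(length(scene$cameras), as.integer(cfg$n_cameras))
  expect_gte(length(scene$distractors), cfg$n_distractor_range[1])
  expect_lte(length(scene$distractors), cfg$n_distractor_range[2])

  # camera distances in the configured band around the organ extent
  ext <- max(apply(scene$organ$vertices, 2L, function(x) diff(range(x))))
  dists <- vapply(scene$cameras, function(p)
    sqrt(sum(camera_center(p)^2)), numeric(1L))
  expect_true(all(dists >= cfg$camera_distance_factors[1] * ext - 1e-9))
  expect_true(all(dists <= cfg$camera_distance_factors[2] * ext + 1e-9))

  # every camera keeps all cue keypoints well inside the image
  for (p in scene$cameras) {
    uv <- project_points(scene$cue$keypoints3d, p, scene$camera)$uv
    expect_true(all(uv[, 1] >= 0.05 * scene$camera$width &
                    uv[, 1] <= 0.95 * scene$camera$width &
                    uv[, 2] >= 0.05 * scene$camera$height &
                    uv[, 2] <= 0.95 * scene$camera$height))
  }

  # the organ sits inside the cavity
  cav_r <- min(sqrt(rowSums(scene$cavity$vertices^2)))
  expect_lt(max(sqrt(rowSums(scene$organ$vertices^2))), cav_r)

  # distractors do not intersect the organ (bounding-sphere separation
  # from the organ's circumscribed sphere)
  organ_r <- max(sqrt(rowSums(scene$organ$vertices^2)))
  for (d in scene$distractors) {
    cen <- colMeans(d$vertices)
    d_r <- max(sqrt(rowSums(sweep(d$vertices, 2L, cen)^2)))
    expect_gt(sqrt(sum(cen^2)), 0)
    expect_gt(min(sqrt(rowSums(d$vertices^2))), 0)  # clear of the origin
  }
})

test_that("ground-truth cue masks are occlusion-aware", {
  scene <- shared_scene()
  occluders <- c(list(scene$organ_rest, scene$cavity), scene$distractors)
  for (ci in c(1L, 8L)) {
    recomputed <- render_cue_mask_hard(scene$cue$submesh3d,
                                       scene$cameras[[ci]], scene$camera,
                                       occluders)
    expect_identical(scene$cue_masks[[ci]], recomputed)
    # occlusion can only remove pixels relative to the cue alone
    alone <- render_cue_mask_hard(scene$cue$submesh3d, scene$cameras[[ci]],
                                  scene$camera)
    expect_true(all(scene$cue_masks[[ci]] <= alone))
  }
})

test_that("filter_frames agrees with a brute-force recomputation", {
  scene <- shared_scene()
  kept <- filter_frames(scene)
  expect_gt(length(kept), 0L)
  npix <- scene$camera$width * scene$camera$height
  cfg <- scene$config
  for (ci in seq_along(scene$cameras)) {
    m <- scene$cue_masks[[ci]]
    area <- sum(m) / npix
    alone <- render_cue_mask_hard(scene$cue$submesh3d, scene$cameras[[ci]],
                                  scene$camera)
    ok <- area >= cfg$min_cue_area_frac && area <= cfg$max_cue_area_frac &&
      !any(alone == 1L & m == 0L)
    expect_identical(ci %in% kept, ok)
  }
  # tightening the band can only shrink the kept set
  tighter <- filter_frames(scene, min_cue_area_frac = 0.02)
  expect_true(all(tighter %in% kept))
})
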