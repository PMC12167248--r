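#' Subdivided icosahedron on the unit sphere
#'
#' Watertight by construction; `subdivisions = 3` gives 642 vertices / 1280
#' faces with outward counter-clockwise winding.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @return a [triangle_mesh] on the unit sphere.
#' @export
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- new.env(hash = TRUE)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- edge_key[[key]]
      if (is.null(idx)) {
        p <- (v[a, ] + v[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        idx <- nrow(v)
        edge_key[[key]] <- idx
      }
      idx
    }
    f2 <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      f2[4L * i - 3L, ] <- c(a, ab, ca)
      f2[4L * i - 2L, ] <- c(b, bc, ab)
      f2[4L * i - 1L, ] <- c(cc, ca, bc)
      f2[4L * i, ] <- c(ab, bc, ca)
    }
    f <- f2
  }
  triangle_mesh(v, f)
}

# smooth radial field on the sphere: 1 + sum of von-Mises-Fisher bumps
# fold any numeric seed into the valid set.seed range (double arithmetic:
# integer sums/products overflow for seeds near 2^31)
wrap_seed <- function(x) as.integer(as.numeric(x) %% 2147483629)

radial_bump_field <- function(dirs, centers, amps, kappas) {
  r <- rep(1, nrow(dirs))
  for (i in seq_along(amps))
    r <- r + amps[i] * exp(kappas[i] * (dirs %*% centers[i, ] - 1))
  pmax(as.numeric(r), 0.3)   # keep star-shaped (no self-intersection)
}

#' Generate a random organ-like closed shape
#'
#' A subdivided icosphere deformed by a smooth low-frequency radial field (a
#' few random von-Mises-Fisher bumps), then scaled so that the population
#' mean of the maximum bounding-box extent matches `target_mean_size_mm`
#' (each draw's size is uniform within +/-15% of the target, so the sample
#' mean converges to it). Radial deformation of a star-shaped surface keeps
#' the mesh watertight and self-intersection-free.
#'
#' @param seed RNG seed.
#' @param target_mean_size_mm population mean of the max bounding-box extent.
#' @param subdivisions icosphere subdivision level.
#' @param n_bumps number of radial bumps.
#' @param bump_amplitude maximum relative bump amplitude (0 gives an exact
#'   sphere of the drawn diameter).
#' @return a [triangle_mesh], watertight, centred at the origin.
#' @export
generate_organ_shape <- function(seed, target_mean_size_mm = 26.1,
                                 subdivisions = 3L, n_bumps = 6L,
                                 bump_amplitude = 0.22) {
  if (target_mean_size_mm <= 0) stop("target size must be positive")
  set.seed(wrap_seed(seed))
  base <- icosphere(subdivisions)
  dirs <- base$vertices
  if (n_bumps > 0L && bump_amplitude > 0) {
    centers <- matrix(stats::rnorm(3L * n_bumps), n_bumps, 3L)
    centers <- centers / sqrt(rowSums(centers^2))
    amps <- stats::runif(n_bumps, -bump_amplitude, bump_amplitude)
    kappas <- stats::runif(n_bumps, 2, 6)
    r <- radial_bump_field(dirs, centers, amps, kappas)
  } else {
    r <- rep(1, nrow(dirs))
  }
  v <- dirs * r
  v <- sweep(v, 2L, colMeans(v))
  size <- target_mean_size_mm * stats::runif(1L, 0.85, 1.15)
  ext <- max(apply(v, 2L, function(x) diff(range(x))))
  triangle_mesh(v * (size / ext), base$faces)
}

#' Pose perturbation protocol
#'
#' The benchmark perturbs each ground-truth camera pose by independent
#' uniform noise: each coordinate of the camera position receives
#' uniform(-range, +range) mm, and each intrinsic XYZ Euler angle of the
#' rotation receives uniform(-range, +range) degrees.
#'
#' @param translation_range_mm half-width of the per-coordinate position
#'   noise (mm).
#' @param rotation_range_deg half-width of the per-Euler-angle noise (deg).
#' @param repeats perturbations drawn per frame at the protocol level.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(translation_range_mm = 5,
                              rotation_range_deg = 5, repeats = 5L) {
  if (translation_range_mm < 0 || rotation_range_deg < 0)
    stop("ranges must be non-negative (symmetric about 0)")
  structure(list(translation_range_mm = translation_range_mm,
                 rotation_range_deg = rotation_range_deg,
                 repeats = as.integer(repeats)),
            class = "perturbation_spec")
}

#' Apply uniform pose noise to a ground-truth pose
#'
#' Shifts the camera centre by independent uniform noise per coordinate and
#' composes the rotation with an intrinsic XYZ Euler perturbation
#' (`R_new = R_gt %*% E`). Uses the current RNG state; fix the seed for
#' reproducibility. A zero-width spec returns the pose unchanged.
#'
#' @param pose_gt ground-truth [rigid_pose].
#' @param spec a [perturbation_spec].
#' @return perturbed [rigid_pose].
#' @export
perturb_pose <- function(pose_gt, spec = perturbation_spec()) {
  dt <- stats::runif(3L, -spec$translation_range_mm,
                     spec$translation_range_mm)
  ang <- stats::runif(3L, -spec$rotation_range_deg, spec$rotation_range_deg)
  R <- pose_gt$rotation %*% euler_xyz_matrix(ang[1L], ang[2L], ang[3L])
  pose_from_center(R, camera_center(pose_gt) + dt)
}

#' Default configuration of the synthetic benchmark scenes
#'
#' The defaults re-create the benchmark protocol: organ-like shapes of
#' 26.1 mm population mean size inside a hollow cavity (diameter at least 4x
#' the organ) with 1-3 distractor shapes, a random closed surface cue of 3-8
#' keypoints, and 15 randomly placed cameras per scene that look toward the
#' organ with the full cue in view.
#'
#' @param n_scenes number of scenes (504 at full protocol scale).
#' @param n_cameras camera poses per scene.
#' @param image_width,image_height,fx,fy synthetic camera intrinsics (px);
#'   the principal point sits at the image centre.
#' @param organ_size_mm population mean organ size.
#' @param cue_keypoint_range range of cue keypoint counts.
#' @param cue_thickness_px stroke width of the drawn cue (px).
#' @param n_distractor_range range of distractor shape counts.
#' @param cavity_factor cavity radius as a multiple of the organ size.
#' @param camera_distance_factors camera distance from the organ centre as
#'   multiples of the organ size (min, max).
#' @param camera_cone_deg cameras are drawn within this angle of the cue
#'   centre direction (so the cue faces the camera).
#' @param min_cue_area_frac,max_cue_area_frac cue-mask area filter bounds as
#'   fractions of the image area.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(n_scenes = 504L, n_cameras = 15L,
                         image_width = 640L, image_height = 512L,
                         fx = 500, fy = 500,
                         organ_size_mm = 26.1,
                         cue_keypoint_range = c(3L, 8L),
                         cue_thickness_px = 5,
                         n_distractor_range = c(1L, 3L),
                         cavity_factor = 2.2,
                         camera_distance_factors = c(1.4, 2.0),
                         camera_cone_deg = 35,
                         min_cue_area_frac = 0.005,
                         max_cue_area_frac = 0.20) {
  structure(as.list(environment()), class = "scene_config")
}

scene_camera <- function(config) {
  pinhole_camera(config$fx, config$fy, config$image_width / 2,
                 config$image_height / 2, config$image_width,
                 config$image_height)
}

# random unit vector within `cone_deg` of axis w
sample_cone <- function(w, cone_deg) {
  ct <- stats::runif(1L, cos(cone_deg * pi / 180), 1)
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(1L, 0, 2 * pi)
  # orthonormal frame around w
  a <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * w) * w; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(w[2L] * e1[3L] - w[3L] * e1[2L],
          w[3L] * e1[1L] - w[1L] * e1[3L],
          w[1L] * e1[2L] - w[2L] * e1[1L])
  ct * w + st * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate one synthetic scene
#'
#' Builds the organ at the origin inside a cavity shell, adds non-
#' intersecting distractor shapes, draws a random closed cue on the organ
#' surface through the real cue pipeline (project anchor points into a
#' keyframe camera, rasterize the polyline, lift mask and keypoints back
#' onto the mesh), samples camera poses that keep the whole cue in the field
#' of view, and renders the ground-truth cue mask for every camera with
#' z-buffer occlusion against the full scene. Deterministic in `seed`.
#'
#' @param seed RNG seed.
#' @param config a [scene_config].
#' @return object of class `synthetic_scene`: organ, cavity, distractors,
#'   cue, keyframe pose, cameras (ground-truth [rigid_pose]s), per-camera
#'   cue masks, the camera intrinsics and the seed.
#' @export
generate_scene <- function(seed, config = scene_config()) {
  cam <- scene_camera(config)
  organ <- generate_organ_shape(seed, config$organ_size_mm)
  set.seed(wrap_seed(as.numeric(seed) + 1000003))
  ext <- max(apply(organ$vertices, 2L, function(x) diff(range(x))))

  cavity_r <- config$cavity_factor * ext
  cavity <- icosphere(2L)
  cavity <- triangle_mesh(cavity$vertices * cavity_r *
                            (1 + 0.1 * sin(3 * cavity$vertices[, 1L])),
                          cavity$faces)

  n_d <- sample(seq(config$n_distractor_range[1L],
                    config$n_distractor_range[2L]), 1L)
  distractors <- list()
  for (i in seq_len(n_d)) {
    d <- generate_organ_shape(wrap_seed(as.numeric(seed) + 7919 * i),
                              config$organ_size_mm * stats::runif(1L, 0.5, 1))
    set.seed(wrap_seed(as.numeric(seed) + 7919 * i + 1))
    dext <- max(apply(d$vertices, 2L, function(x) diff(range(x))))
    dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
    lo <- (ext + dext) / 2 * 1.2            # clear of the organ
    hi <- max(lo, cavity_r * 0.95 - dext / 2)  # inside the cavity shell
    dist <- stats::runif(1L, lo, hi)
    distractors[[i]] <- triangle_mesh(sweep(d$vertices, 2L, -dir * dist),
                                      d$faces)
  }

  # cue: anchor points on the surface around a random direction
  cue_obj <- NULL; keyframe_pose <- NULL; cue_dir <- NULL
  for (try in 1:40) {
    w <- stats::rnorm(3L); w <- w / sqrt(sum(w^2))
    k <- sample(seq(config$cue_keypoint_range[1L],
                    config$cue_keypoint_range[2L]), 1L)
    theta <- sort(stats::runif(k, 0, 2 * pi))
    if (min(diff(c(theta, theta[1L] + 2 * pi))) < 0.2) next
    polar <- stats::runif(k, 0.25, 0.5)
    # anchors on a ring around w at the prescribed azimuths/polar radii
    a <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * w) * w; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(w[2L] * e1[3L] - w[3L] * e1[2L],
            w[3L] * e1[1L] - w[1L] * e1[3L],
            w[1L] * e1[2L] - w[2L] * e1[1L])
    dirs <- t(vapply(seq_len(k), function(i)
      cos(polar[i]) * w + sin(polar[i]) *
        (cos(theta[i]) * e1 + sin(theta[i]) * e2), numeric(3L)))
    anchors <- cpp_raycast(c(0, 0, 0), dirs, organ$vertices,
                           organ$faces - 1L)$point
    if (any(!is.finite(anchors))) next

    kf_center <- w * stats::runif(1L, config$camera_distance_factors[1L],
                                  config$camera_distance_factors[2L]) * ext
    keyframe_pose <- pose_from_center(look_at_rotation(kf_center, c(0, 0, 0)),
                                      kf_center)
    pr <- project_points(anchors, keyframe_pose, cam)
    mrg <- 0.05
    if (!all(pr$valid) ||
        any(pr$uv[, 1L] < mrg * cam$width | pr$uv[, 1L] > (1 - mrg) * cam$width |
            pr$uv[, 2L] < mrg * cam$height | pr$uv[, 2L] > (1 - mrg) * cam$height))
      next
    mask <- rasterize_polyline_mask(pr$uv, c(cam$width, cam$height),
                                    config$cue_thickness_px, closed = TRUE)
    cue_try <- tryCatch(
      lift_cue_to_mesh(pr$uv, mask, organ, keyframe_pose, cam,
                       closed = TRUE),
      error = function(e) NULL)
    if (!is.null(cue_try)) { cue_obj <- cue_try; cue_dir <- w; break }
  }
  if (is.null(cue_obj))
    stop("scene generation failed to place a cue (seed ", seed, ")")

  organ_rest <- submesh(organ,
                        setdiff(seq_len(nrow(organ$faces)),
                                cue_obj$submesh3d$face_labels))
  occluders <- c(list(organ_rest, cavity), distractors)

  cameras <- vector("list", config$n_cameras)
  masks <- vector("list", config$n_cameras)
  for (ci in seq_len(config$n_cameras)) {
    placed <- FALSE
    for (try in 1:60) {
      dir <- sample_cone(cue_dir, config$camera_cone_deg)
      d <- stats::runif(1L, config$camera_distance_factors[1L],
                        config$camera_distance_factors[2L]) * ext
      center <- dir * d
      R <- look_at_rotation(center, c(0, 0, 0),
                            roll_deg = stats::runif(1L, 0, 360))
      pose <- pose_from_center(R, center)
      pr <- project_points(cue_obj$keypoints3d, pose, cam)
      mrg <- 0.05
      if (!all(pr$valid) ||
          any(pr$uv[, 1L] < mrg * cam$width |
              pr$uv[, 1L] > (1 - mrg) * cam$width |
              pr$uv[, 2L] < mrg * cam$height |
              pr$uv[, 2L] > (1 - mrg) * cam$height)) next
      cameras[[ci]] <- pose
      masks[[ci]] <- render_cue_mask_hard(cue_obj$submesh3d, pose, cam,
                                          occluders)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("scene generation failed to place camera ", ci,
           " (seed ", seed, ")")
  }

  structure(list(organ = organ, cavity = cavity, distractors = distractors,
                 cue = cue_obj, keyframe_pose = keyframe_pose,
                 cameras = cameras, cue_masks = masks, camera = cam,
                 organ_rest = organ_rest, seed = seed, config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene (seed %d): organ %d faces, %d distractors, %d cameras\n",
    x$seed, nrow(x$organ$faces), length(x$distractors), length(x$cameras)))
  invisible(x)
}

#' Filter scene frames by cue area and occlusion
#'
#' Keeps a camera iff the cue-mask area lies inside the given fraction
#' bounds of the image area and no cue pixel is occluded: every pixel where
#' the cue submesh alone is visible must also win the z-buffer against the
#' full scene (rest of the organ, cavity, distractors).
#'
#' @param scene a `synthetic_scene`.
#' @param min_cue_area_frac,max_cue_area_frac area bounds (fractions of the
#'   image area); defaults come from the scene's config.
#' @return integer vector of kept camera indices (possibly empty).
#' @export
filter_frames <- function(scene,
                          min_cue_area_frac = scene$config$min_cue_area_frac,
                          max_cue_area_frac = scene$config$max_cue_area_frac) {
  cam <- scene$camera
  npix <- cam$width * cam$height
  keep <- integer(0L)
  for (ci in seq_along(scene$cameras)) {
    m <- scene$cue_masks[[ci]]
    area <- sum(m != 0) / npix
    if (area < min_cue_area_frac || area > max_cue_area_frac) next
    alone <- render_cue_mask_hard(scene$cue$submesh3d, scene$cameras[[ci]],
                                  cam, occluders = list())
    if (any(alone != 0 & m == 0)) next     # some cue pixel is occluded
    keep <- c(keep, ci)
  }
  keep
}
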