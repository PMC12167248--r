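#' Surface cue: paired 2D polyline/mask and 3D submesh/keypoints
#'
#' A cue is drawn on the visible organ surface in a manually aligned keyframe.
#' Its 2D form is an ordered polyline of keypoints plus the rasterized mask;
#' its 3D form is the set of organ faces hit when the mask is projected onto
#' the mesh, plus the lifted 3D keypoints. The two forms are created together
#' by [lift_cue_to_mesh] and stay in the same order.
#'
#' @param keypoints2d n x 2 matrix of pixel coordinates (ordered polyline).
#' @param mask integer 0/1 matrix (height x width).
#' @param submesh3d [triangle_mesh] of the selected organ faces (world frame);
#'   `face_labels` hold the parent-mesh face indices.
#' @param keypoints3d n x 3 matrix of lifted 3D keypoints (mm), same order as
#'   `keypoints2d`.
#' @param closed logical; does the polyline close on itself?
#' @return object of class `cue`.
#' @export
cue <- function(keypoints2d, mask, submesh3d, keypoints3d, closed = TRUE) {
  keypoints2d <- as.matrix(keypoints2d)
  keypoints3d <- as.matrix(keypoints3d)
  if (nrow(keypoints2d) != nrow(keypoints3d))
    stop("keypoints2d and keypoints3d must have the same length")
  if (!inherits(submesh3d, "triangle_mesh")) stop("submesh3d must be a mesh")
  structure(list(keypoints2d = keypoints2d, mask = mask,
                 submesh3d = submesh3d, keypoints3d = keypoints3d,
                 closed = isTRUE(closed)),
            class = "cue")
}

#' @export
print.cue <- function(x, ...) {
  cat(sprintf("cue: %d keypoints (%s), %d mask px, submesh of %d faces\n",
              nrow(x$keypoints2d), if (x$closed) "closed" else "open",
              sum(x$mask != 0), nrow(x$submesh3d$faces)))
  invisible(x)
}

#' Rasterize a polyline into a thick binary mask
#'
#' Draws the union of thick line segments (capsules of diameter
#' `thickness_px`) between consecutive keypoints, and last-to-first when
#' `closed`. A single keypoint yields a filled disc. Pixel-centre sampling;
#' deterministic for fixed input.
#'
#' @param keypoints2d n x 2 matrix of pixel coordinates (n >= 1).
#' @param image_size c(width, height) in pixels.
#' @param thickness_px stroke thickness in pixels (>= 1).
#' @param closed close the polyline last-to-first?
#' @return integer 0/1 matrix (height x width).
#' @export
rasterize_polyline_mask <- function(keypoints2d, image_size,
                                    thickness_px = 5, closed = TRUE) {
  keypoints2d <- as.matrix(keypoints2d)
  if (nrow(keypoints2d) == 0L) stop("empty keypoint list")
  if (thickness_px < 1) stop("thickness_px must be >= 1")
  w <- as.integer(image_size[1L]); h <- as.integer(image_size[2L])
  inb <- keypoints2d[, 1L] >= 0 & keypoints2d[, 1L] < w &
         keypoints2d[, 2L] >= 0 & keypoints2d[, 2L] < h
  if (!any(inb)) stop("no keypoint lies inside the image bounds")
  storage.mode(keypoints2d) <- "double"
  cpp_polyline_mask(keypoints2d, w, h, as.numeric(thickness_px),
                    isTRUE(closed) && nrow(keypoints2d) > 2L)
}

#' Resample a freehand stroke to evenly spaced keypoints
#'
#' Approximates a dense stroke by keypoints placed every `spacing_px` of arc
#' length (the first and last stroke points are always kept for open
#' strokes).
#'
#' @param stroke n x 2 matrix of dense stroke pixel coordinates.
#' @param spacing_px arc-length spacing between keypoints (px).
#' @param closed treat the stroke as closed?
#' @return m x 2 matrix of keypoints.
#' @export
resample_stroke <- function(stroke, spacing_px = 15, closed = TRUE) {
  stroke <- as.matrix(stroke)
  if (nrow(stroke) < 2L) return(stroke)
  pts <- if (closed) rbind(stroke, stroke[1L, ]) else stroke
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  n_seg <- max(if (closed) 3L else 1L, floor(total / spacing_px))
  at <- seq(0, total, length.out = n_seg + 1L)
  if (closed) at <- at[seq_len(n_seg)]  # last point duplicates the first
  u <- stats::approx(arc, pts[, 1L], xout = at, rule = 2L)$y
  v <- stats::approx(arc, pts[, 2L], xout = at, rule = 2L)$y
  cbind(u, v, deparse.level = 0L)
}

#' World-frame ray directions through pixel centres
#' @param uv n x 2 pixel coordinates.
#' @param pose a [rigid_pose].
#' @param cam a [pinhole_camera].
#' @return list with `origin` (camera centre, world) and `dirs` (n x 3 unit
#'   world directions).
#' @keywords internal
pixel_rays <- function(uv, pose, cam) {
  uv <- as.matrix(uv)
  d_cam <- cbind((uv[, 1L] - cam$cx) / cam$fx,
                 (uv[, 2L] - cam$cy) / cam$fy, 1)
  d_world <- d_cam %*% pose$rotation        # t(R) applied to rows
  d_world <- d_world / sqrt(rowSums(d_world^2))
  list(origin = camera_center(pose), dirs = d_world)
}

#' Lift a 2D cue onto the organ mesh
#'
#' Each keypoint is ray-cast through the camera; the nearest front-facing
#' intersection with the organ gives its 3D position. Every nonzero mask
#' pixel is ray-cast the same way and the set of first-hit faces forms the
#' cue submesh (a face joins the submesh as soon as one mask pixel first hits
#' it).
#'
#' @param keypoints2d n x 2 matrix of pixel coordinates.
#' @param mask integer 0/1 matrix (height x width) at camera resolution.
#' @param organ [triangle_mesh] of the organ (world frame).
#' @param pose keyframe [rigid_pose] (after manual alignment).
#' @param cam a [pinhole_camera].
#' @param closed is the cue polyline closed?
#' @return a [cue].
#' @export
lift_cue_to_mesh <- function(keypoints2d, mask, organ, pose, cam,
                             closed = TRUE) {
  keypoints2d <- as.matrix(keypoints2d)
  rays <- pixel_rays(keypoints2d, pose, cam)
  hit <- cpp_raycast(rays$origin, rays$dirs, organ$vertices,
                     organ$faces - 1L)
  if (any(hit$face == 0L))
    stop("cue keypoint(s) ", paste(which(hit$face == 0L), collapse = ", "),
         " do not project onto the organ mesh")
  keypoints3d <- hit$point

  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("cue mask is empty")
  uv_px <- cbind(px[, 2L] - 1, px[, 1L] - 1)   # (col, row) -> (u, v), 0-based
  mrays <- pixel_rays(uv_px, pose, cam)
  mhit <- cpp_raycast(mrays$origin, mrays$dirs, organ$vertices,
                      organ$faces - 1L)
  sel <- sort(unique(mhit$face[mhit$face > 0L]))
  if (length(sel) == 0L)
    stop("cue mask lies entirely off the organ mesh")

  sub <- submesh(organ, sel)
  cue(keypoints2d, mask, sub, keypoints3d, closed = closed)
}

#' Extract a face subset of a mesh as a standalone mesh
#' @param mesh a [triangle_mesh].
#' @param face_idx indices of faces to keep (1-based rows of `mesh$faces`).
#' @return a [triangle_mesh] with re-indexed vertices; `face_labels` hold the
#'   original face indices.
#' @export
submesh <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[f], ncol = 3L)
  triangle_mesh(mesh$vertices[used, , drop = FALSE], f2,
                face_labels = as.integer(face_idx))
}

#' Hard binary silhouette of a cue submesh
#'
#' A pixel is 1 iff its centre ray hits any submesh face in front of the
#' camera, with z-buffer occlusion against optional occluder meshes.
#'
#' @param cue_submesh [triangle_mesh] of the cue faces (world frame).
#' @param pose a [rigid_pose].
#' @param cam a [pinhole_camera].
#' @param occluders optional list of [triangle_mesh] occluders (e.g. the rest
#'   of the organ, distractors, the cavity shell).
#' @return integer 0/1 matrix (height x width).
#' @export
render_cue_mask_hard <- function(cue_submesh, pose, cam, occluders = list()) {
  ids <- render_scene_ids(c(list(cue_submesh), occluders), pose, cam)
  matrix(as.integer(ids$mesh_id == 1L), cam$height, cam$width)
}

#' Z-buffered scene render returning per-pixel mesh and face identity
#'
#' @param meshes list of [triangle_mesh] (world frame).
#' @param pose a [rigid_pose].
#' @param cam a [pinhole_camera].
#' @param znear near-plane clip distance (mm); faces with any vertex closer
#'   are dropped.
#' @return list with `mesh_id` (integer matrix, 0 = background), `face_id`
#'   (face row within the winning mesh) and `depth` (mm, Inf = background).
#' @export
render_scene_ids <- function(meshes, pose, cam, znear = 1e-3) {
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1L))
  nf <- vapply(meshes, function(m) nrow(m$faces), integer(1L))
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  off_v <- cumsum(c(0L, nv[-length(nv)]))
  faces <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$faces + off_v[i]))
  pr <- project_points(verts, pose, cam)
  out <- cpp_zbuffer_render(pr$uv, pr$depth, faces - 1L,
                            cam$width, cam$height, znear)
  fid <- out$face_id
  mesh_of_face <- rep.int(seq_along(meshes), nf)
  off_f <- cumsum(c(0L, nf[-length(nf)]))
  mesh_id <- matrix(0L, cam$height, cam$width)
  face_local <- matrix(0L, cam$height, cam$width)
  hitpix <- fid > 0L
  mesh_id[hitpix] <- mesh_of_face[fid[hitpix]]
  face_local[hitpix] <- fid[hitpix] - off_f[mesh_id[hitpix]]
  list(mesh_id = mesh_id, face_id = face_local, depth = out$depth)
}
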