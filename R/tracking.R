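#' Tracked 2D keypoints over a frame sequence
#'
#' @param positions array of dim (n_frames, n_points, 2): pixel positions.
#' @param visible logical matrix (n_frames x n_points).
#' @return object of class `tracked_points`.
#' @export
tracked_points <- function(positions, visible) {
  positions <- array(positions, dim = dim(positions))
  if (length(dim(positions)) != 3L || dim(positions)[3L] != 2L)
    stop("positions must be an (frames x points x 2) array")
  if (is.matrix(visible) &&
      !identical(dim(visible), dim(positions)[1:2]))
    stop("visible must be an (frames x points) logical matrix")
  visible <- matrix(visible, dim(positions)[1L], dim(positions)[2L])
  vx <- c(positions[, , 1L])[as.vector(visible)]
  vy <- c(positions[, , 2L])[as.vector(visible)]
  if (any(!is.finite(vx)) || any(!is.finite(vy)))
    stop("visible positions must be finite")
  structure(list(positions = positions, visible = visible),
            class = "tracked_points")
}

#' @export
print.tracked_points <- function(x, ...) {
  cat(sprintf("tracked_points: %d points over %d frames (%.0f%% visible)\n",
              dim(x$positions)[2L], dim(x$positions)[1L],
              100 * mean(x$visible)))
  invisible(x)
}

# positions of one frame as an n x 2 matrix (robust to n = 1)
frame_positions <- function(tracked, i) {
  matrix(tracked$positions[i, , ], ncol = 2L)
}

#' Track 2D keypoints through a frame sequence
#'
#' Pluggable tracker interface. `tracker = "lk"` uses the built-in pyramidal
#' Lucas-Kanade optical-flow tracker (3 levels, 21-px windows,
#' forward-backward visibility check); learned trackers can be plugged in by
#' passing a function `(frames, keypoints) -> tracked_points`. For synthetic
#' scenes with known geometry use [track_points_ground_truth].
#'
#' A point whose estimate leaves the image is marked invisible and its
#' position frozen at the last valid estimate.
#'
#' @param frames list of grayscale frames (numeric matrices in \[0, 1\]),
#'   all the same size.
#' @param initial_keypoints n x 2 matrix of pixel positions in frame 1.
#' @param tracker `"lk"` or a tracking function.
#' @param window_px Lucas-Kanade window size (odd).
#' @param pyramid_levels number of pyramid levels.
#' @param fb_threshold_px forward-backward error above which a point is
#'   marked invisible.
#' @param appearance_threshold mean absolute intensity difference between
#'   the tracked patch in consecutive frames above which a point is marked
#'   invisible (catches texture that disappears, which the forward-backward
#'   check alone cannot).
#' @return a [tracked_points].
#' @export
track_points <- function(frames, initial_keypoints, tracker = "lk",
                         window_px = 21L, pyramid_levels = 3L,
                         fb_threshold_px = 1, appearance_threshold = 0.05) {
  if (length(frames) < 1L) stop("need at least one frame")
  kp <- as.matrix(initial_keypoints)
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  if (any(kp[, 1L] < 0 | kp[, 1L] >= w | kp[, 2L] < 0 | kp[, 2L] >= h))
    stop("initial keypoints must lie inside frame 1")
  if (is.function(tracker)) return(tracker(frames, kp))
  if (!identical(tracker, "lk")) stop("unknown tracker: ", tracker)

  nf <- length(frames); np <- nrow(kp)
  pos <- array(NA_real_, c(nf, np, 2L))
  vis <- matrix(TRUE, nf, np)
  pos[1L, , ] <- kp
  cur <- kp
  for (i in seq_len(nf - 1L)) {
    nxt <- lk_track_pair(frames[[i]], frames[[i + 1L]], cur,
                         window_px, pyramid_levels)
    back <- lk_track_pair(frames[[i + 1L]], frames[[i]], nxt,
                          window_px, pyramid_levels)
    fb <- sqrt(rowSums((back - cur)^2))
    inb <- nxt[, 1L] >= 0 & nxt[, 1L] < w & nxt[, 2L] >= 0 & nxt[, 2L] < h
    resid <- patch_residual(frames[[i]], frames[[i + 1L]], cur, nxt,
                            window_px)
    ok <- is.finite(fb) & fb <= fb_threshold_px & inb &
      resid <= appearance_threshold
    vis[i + 1L, ] <- vis[i, ] & ok
    # frozen at the last estimate when lost
    nxt[!ok, ] <- cur[!ok, , drop = FALSE]
    pos[i + 1L, , ] <- nxt
    cur <- nxt
  }
  tracked_points(pos, vis)
}

# mean absolute intensity difference between the window around p0 in I0
# and the window around p1 in I1, per point
patch_residual <- function(I0, I1, p0, p1, window_px) {
  r <- (window_px - 1L) / 2
  off <- expand.grid(dx = seq(-r, r), dy = seq(-r, r))
  vapply(seq_len(nrow(p0)), function(k) {
    a <- bilinear_sample(I0, p0[k, 1L] + off$dx, p0[k, 2L] + off$dy)
    b <- bilinear_sample(I1, p1[k, 1L] + off$dx, p1[k, 2L] + off$dy)
    mean(abs(a - b))
  }, numeric(1L))
}

# bilinear sampling of image I at continuous (u, v); clamped at borders
bilinear_sample <- function(I, u, v) {
  h <- nrow(I); w <- ncol(I)
  u <- pmin(pmax(u, 0), w - 1 - 1e-9)
  v <- pmin(pmax(v, 0), h - 1 - 1e-9)
  x0 <- floor(u); y0 <- floor(v)
  du <- u - x0; dv <- v - y0
  i00 <- I[cbind(y0 + 1L, x0 + 1L)]
  i01 <- I[cbind(y0 + 1L, pmin(x0 + 2L, w))]
  i10 <- I[cbind(pmin(y0 + 2L, h), x0 + 1L)]
  i11 <- I[cbind(pmin(y0 + 2L, h), pmin(x0 + 2L, w))]
  (1 - dv) * ((1 - du) * i00 + du * i01) + dv * ((1 - du) * i10 + du * i11)
}

downsample2 <- function(I) {
  h <- 2L * (nrow(I) %/% 2L); w <- 2L * (ncol(I) %/% 2L)
  I <- I[seq_len(h), seq_len(w)]
  (I[seq(1L, h, 2L), seq(1L, w, 2L)] + I[seq(2L, h, 2L), seq(1L, w, 2L)] +
   I[seq(1L, h, 2L), seq(2L, w, 2L)] + I[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

# one-step pyramidal Lucas-Kanade from frame I0 to I1
lk_track_pair <- function(I0, I1, pts, window_px = 21L,
                          pyramid_levels = 3L, iters = 15L) {
  pyr0 <- list(I0); pyr1 <- list(I1)
  for (l in seq_len(pyramid_levels - 1L)) {
    if (min(dim(pyr0[[l]])) < 2L * window_px) break
    pyr0[[l + 1L]] <- downsample2(pyr0[[l]])
    pyr1[[l + 1L]] <- downsample2(pyr1[[l]])
  }
  nlev <- length(pyr0)
  r <- (window_px - 1L) / 2
  off <- expand.grid(dx = seq(-r, r), dy = seq(-r, r))
  np <- nrow(pts)
  d <- matrix(0, np, 2L)                 # displacement at the current level
  for (l in seq(nlev, 1L)) {
    s <- 2^(l - 1L)
    p_l <- pts / s
    for (k in seq_len(np)) {
      u0 <- p_l[k, 1L] + off$dx; v0 <- p_l[k, 2L] + off$dy
      t0 <- bilinear_sample(pyr0[[l]], u0, v0)
      gx <- (bilinear_sample(pyr0[[l]], u0 + 1, v0) -
             bilinear_sample(pyr0[[l]], u0 - 1, v0)) / 2
      gy <- (bilinear_sample(pyr0[[l]], u0, v0 + 1) -
             bilinear_sample(pyr0[[l]], u0, v0 - 1)) / 2
      G <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy),
                    sum(gy * gy)), 2L)
      if (abs(det(G)) < 1e-12) next
      Ginv <- solve(G)
      dk <- d[k, ]
      for (s2 in seq_len(iters)) {
        t1 <- bilinear_sample(pyr1[[l]], u0 + dk[1L], v0 + dk[2L])
        e <- t1 - t0
        step <- -as.numeric(Ginv %*% c(sum(gx * e), sum(gy * e)))
        dk <- dk + step
        if (sqrt(sum(step^2)) < 0.01) break
      }
      d[k, ] <- dk
    }
    if (l > 1L) d <- d * 2
  }
  pts + d
}

#' Exact keypoint tracks for a synthetic scene
#'
#' Positions equal the projections of the 3D keypoints under the per-frame
#' ground-truth poses; a point is visible when it projects in front of the
#' camera and inside the image.
#'
#' @param keypoints3d n x 3 matrix of world keypoints (mm).
#' @param poses list of per-frame ground-truth [rigid_pose]s.
#' @param cam a [pinhole_camera].
#' @return a [tracked_points].
#' @export
track_points_ground_truth <- function(keypoints3d, poses, cam) {
  np <- nrow(as.matrix(keypoints3d))
  nf <- length(poses)
  pos <- array(NA_real_, c(nf, np, 2L))
  vis <- matrix(FALSE, nf, np)
  for (i in seq_len(nf)) {
    pr <- project_points(keypoints3d, poses[[i]], cam)
    inb <- pr$valid & pr$uv[, 1L] >= 0 & pr$uv[, 1L] < cam$width &
           pr$uv[, 2L] >= 0 & pr$uv[, 2L] < cam$height
    pos[i, , ] <- pr$uv
    pos[i, !inb, 1L] <- 0; pos[i, !inb, 2L] <- 0
    vis[i, ] <- inb
  }
  tracked_points(pos, vis)
}

#' Per-frame cue masks drawn from tracked keypoints
#'
#' Applies [rasterize_polyline_mask] per frame using only the visible
#' points: segments between consecutive visible keypoints are drawn, so a
#' single lost point removes only its two adjacent segments. Frames with no
#' visible point get an empty mask and a flag.
#'
#' @param tracked a [tracked_points].
#' @param image_size c(width, height) in pixels.
#' @param thickness stroke thickness in pixels.
#' @param closed close the polyline last-to-first?
#' @return list with `masks` (list of 0/1 matrices) and `empty` (logical
#'   vector flagging frames without visible points).
#' @export
masks_from_tracks <- function(tracked, image_size, thickness = 5,
                              closed = TRUE) {
  nf <- dim(tracked$positions)[1L]
  np <- dim(tracked$positions)[2L]
  w <- as.integer(image_size[1L]); h <- as.integer(image_size[2L])
  masks <- vector("list", nf)
  empty <- logical(nf)
  for (i in seq_len(nf)) {
    pts <- frame_positions(tracked, i)
    vis <- tracked$visible[i, ]
    if (!any(vis)) {
      masks[[i]] <- matrix(0L, h, w)
      empty[i] <- TRUE
      next
    }
    if (all(vis)) {
      masks[[i]] <- rasterize_polyline_mask(pts, c(w, h), thickness, closed)
      next
    }
    m <- matrix(0L, h, w)
    nseg <- if (closed && np > 2L) np else np - 1L
    drew <- FALSE
    for (s in seq_len(nseg)) {
      a <- s; b <- s %% np + 1L
      if (vis[a] && vis[b]) {
        m <- m | cpp_polyline_mask(pts[c(a, b), , drop = FALSE], w, h,
                                   as.numeric(thickness), FALSE)
        drew <- TRUE
      }
    }
    if (!drew) {   # isolated visible points: draw their discs
      for (k in which(vis))
        m <- m | cpp_polyline_mask(pts[k, , drop = FALSE], w, h,
                                   as.numeric(thickness), FALSE)
    }
    masks[[i]] <- matrix(as.integer(m), h, w)
  }
  list(masks = masks, empty = empty)
}

#' Midpoints of the connecting lines between annotated keypoints
#'
#' The tracking-evaluation protocol does not score the annotated keypoints
#' themselves (they are chosen to be salient, hence easy); it scores
#' constructed points placed at the midpoint of connecting lines.
#'
#' @param pts n x 2 matrix of annotated pixel positions.
#' @param all_pairs if `TRUE` (default) midpoints of all C(n, 2) point
#'   pairs; if `FALSE`, only consecutive (polyline) pairs.
#' @return m x 2 matrix of midpoints.
#' @export
midpoint_keypoints <- function(pts, all_pairs = TRUE) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  pairs <- if (all_pairs) t(utils::combn(n, 2L))
           else cbind(seq_len(n - 1L), seq(2L, n))
  (pts[pairs[, 1L], , drop = FALSE] + pts[pairs[, 2L], , drop = FALSE]) / 2
}

#' Evaluate a tracker against sparse ground-truth annotations
#'
#' Ground truth: keypoints annotated at a fixed temporal stride (e.g. every
#' second). Constructed midpoints between annotated pairs define the scored
#' points; the tracker's positions for those midpoints are compared with the
#' midpoints of the annotations at every annotated frame. Nothing is
#' interpolated between annotated frames.
#'
#' @param tracked a [tracked_points] for the constructed midpoints (frames
#'   aligned with the full sequence).
#' @param annotations list with `frame_idx` (1-based annotated frame
#'   indices) and `positions` (array annotated_frames x n_points x 2).
#' @param all_pairs midpoint construction rule, see [midpoint_keypoints].
#' @return list with `errors_px` (matrix annotated_frames x midpoints),
#'   `median_px` and `per_point_median_px`.
#' @export
evaluate_tracking <- function(tracked, annotations, all_pairs = TRUE) {
  if (is.null(annotations$frame_idx) || length(annotations$frame_idx) == 0L)
    stop("no annotated frames")
  fidx <- annotations$frame_idx
  A <- annotations$positions
  na <- length(fidx)
  gt_mid <- lapply(seq_len(na), function(i)
    midpoint_keypoints(matrix(A[i, , ], ncol = 2L), all_pairs))
  nm <- nrow(gt_mid[[1L]])
  if (dim(tracked$positions)[2L] != nm)
    stop("tracked point count (", dim(tracked$positions)[2L],
         ") does not match constructed midpoint count (", nm, ")")
  errs <- matrix(NA_real_, na, nm)
  for (i in seq_len(na)) {
    p <- frame_positions(tracked, fidx[i])
    errs[i, ] <- sqrt(rowSums((p - gt_mid[[i]])^2))
  }
  list(errors_px = errs, median_px = stats::median(errs),
       per_point_median_px = apply(errs, 2L, stats::median))
}
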