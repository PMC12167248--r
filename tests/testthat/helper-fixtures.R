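# Shared fixtures and independent oracles, built in code at test time.

test_camera <- function(width = 640L, height = 512L, f = 500) {
  pinhole_camera(f, f, width / 2, height / 2, width, height)
}

# a single world-frame square (two triangles) facing the camera at depth z
square_mesh <- function(half = 10, z = 100) {
  triangle_mesh(rbind(c(-half, -half, z), c(half, -half, z),
                      c(half, half, z), c(-half, half, z)),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

random_pose <- function(max_center = 50) {
  pose_from_center(random_rotation(), stats::runif(3L, -max_center,
                                                   max_center))
}

# memoized synthetic scene shared across test files (generation ~0.5 s)
shared_scene <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 3L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_scene(seed, scene_config())
    cache[[key]]
  }
})

# Oracle: brute-force per-pixel ray-cast rasterizer (independent of the
# z-buffer implementation).  Returns a 0/1 matrix: pixel centre rays that
# hit any face of the mesh.
raycast_mask_oracle <- function(mesh, pose, cam) {
  grid <- expand.grid(u = seq_len(cam$width) - 1L,
                      v = seq_len(cam$height) - 1L)
  origin <- camera_center(pose)
  d_cam <- cbind((grid$u - cam$cx) / cam$fx, (grid$v - cam$cy) / cam$fy, 1)
  dirs <- d_cam %*% pose$rotation
  hit <- cuereg:::cpp_raycast(origin, dirs, mesh$vertices, mesh$faces - 1L)
  m <- matrix(0L, cam$height, cam$width)
  m[cbind(grid$v + 1L, grid$u + 1L)] <- as.integer(hit$face > 0L)
  m
}

# Oracle: Moller-Trumbore in plain R for a single ray (independent of C++)
raycast_oracle_r <- function(origin, dir, mesh) {
  best_t <- Inf; best_pt <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[f, 1L], ]
    b <- mesh$vertices[mesh$faces[f, 2L], ]
    cc <- mesh$vertices[mesh$faces[f, 3L], ]
    e1 <- b - a; e2 <- cc - a
    p <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * p)
    if (abs(det) < 1e-12) next
    tv <- origin - a
    u <- sum(tv * p) / det
    if (u < 0 || u > 1) next
    q <- c(tv[2] * e1[3] - tv[3] * e1[2],
           tv[3] * e1[1] - tv[1] * e1[3],
           tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * q) / det
    if (v < 0 || u + v > 1) next
    t <- sum(e2 * q) / det
    if (t > 1e-9 && t < best_t) { best_t <- t; best_pt <- origin + t * dir }
  }
  list(t = best_t, point = best_pt)
}

# central finite difference of the silhouette loss w.r.t. pose parameters
fd_pose_gradient <- function(submesh, params, cam, ref, settings,
                             step = 1e-4) {
  f <- function(p) pose_gradient(submesh, p, cam, ref, settings,
                                 want_grad = FALSE)$loss
  vapply(seq_along(params), function(k) {
    e <- numeric(length(params)); e[k] <- step
    (f(params + e) - f(params - e)) / (2 * step)
  }, numeric(1L))
}

# Bresenham-style oracle: integer pixels on the straight line between two
# integer endpoints on the same row
row_segment_pixels <- function(u0, u1, v) {
  cbind(u = seq(min(u0, u1), max(u0, u1)), v = v)
}
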