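#' Settings of the differentiable soft-silhouette renderer
#'
#' The renderer blurs triangle edges with a sigmoid of the signed screen-space
#' distance so that the image loss varies smoothly with camera pose; the blur
#' width trades gradient smoothness against edge accuracy (wide blur dilutes
#' the silhouette boundary systematically).
#'
#' @param width,height render resolution in pixels. Decoupled from the video
#'   resolution: reference masks are resampled to this size before the loss.
#' @param blur_sigma edge softness in render pixels (> 0). Default 0.5 px at
#'   a 256-px render width: thin cue strips are only a few render pixels
#'   wide, and a blur comparable to the strip width biases the loss minimum
#'   toward foreshortened (wrongly rotated) poses; see the package vignette.
#' @param faces_per_pixel maximum number of faces aggregated per pixel
#'   (probabilistic union over the faces with the largest signed distance).
#' @param pad_sigmas faces influence pixels up to `pad_sigmas * blur_sigma`
#'   outside their screen bounding box; beyond that the occupancy is below
#'   sigmoid(-pad_sigmas) and is treated as exactly 0.
#' @return object of class `soft_render_settings`.
#' @export
soft_render_settings <- function(width = 256L, height = 205L,
                                 blur_sigma = 0.5, faces_per_pixel = 8L,
                                 pad_sigmas = 14) {
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  if (faces_per_pixel < 1L || faces_per_pixel > 32L)
    stop("faces_per_pixel must be in 1..32")
  structure(list(width = as.integer(width), height = as.integer(height),
                 blur_sigma = as.numeric(blur_sigma),
                 faces_per_pixel = as.integer(faces_per_pixel),
                 pad_sigmas = as.numeric(pad_sigmas)),
            class = "soft_render_settings")
}

# camera rescaled to the render resolution of `settings`
render_camera <- function(cam, settings) {
  sx <- settings$width / cam$width
  sy <- settings$height / cam$height
  # pixel (0,0) is the top-left pixel *centre*, so rescaling maps
  # u -> (u + 0.5) * s - 0.5 (continuous image coordinates scale linearly)
  pinhole_camera(cam$fx * sx, cam$fy * sy,
                 (cam$cx + 0.5) * sx - 0.5, (cam$cy + 0.5) * sy - 0.5,
                 settings$width, settings$height)
}

#' Render a soft silhouette of a mesh
#'
#' Per pixel, each nearby face contributes an occupancy
#' `sigmoid(d / blur_sigma)` where `d` is the signed 2D distance (px) from
#' the pixel centre to the projected triangle (positive inside); the pixel
#' value is the probabilistic union `1 - prod(1 - D)` over the
#' `faces_per_pixel` faces with the largest `d`. Values lie in \[0, 1\] and
#' converge to the hard rasterization as `blur_sigma -> 0`. Faces behind the
#' camera are dropped; if all faces are behind, the image is all zero.
#'
#' @param submesh [triangle_mesh] (world frame), typically a cue submesh.
#' @param pose a [rigid_pose].
#' @param cam a [pinhole_camera] (native resolution; the render happens at
#'   `settings$width x settings$height` with rescaled intrinsics).
#' @param settings a [soft_render_settings].
#' @return numeric matrix (height x width) in \[0, 1\].
#' @export
render_silhouette_soft <- function(submesh, pose, cam, settings) {
  rcam <- render_camera(cam, settings)
  pr <- project_points(submesh$vertices, pose, rcam)
  out <- cpp_soft_render(pr$uv, pr$depth, submesh$faces - 1L,
                         rcam$width, rcam$height, settings$blur_sigma,
                         settings$faces_per_pixel, settings$pad_sigmas,
                         NULL, FALSE)
  out$image
}

#' Mean squared error between a rendered silhouette and a reference mask
#'
#' @param rendered numeric matrix in \[0, 1\].
#' @param reference numeric/integer matrix of the same dimensions.
#' @return scalar in \[0, 1\].
#' @export
silhouette_mse <- function(rendered, reference) {
  if (!all(dim(rendered) == dim(reference)))
    stop("rendered and reference dimensions differ: ",
         paste(dim(rendered), collapse = "x"), " vs ",
         paste(dim(reference), collapse = "x"))
  mean((rendered - reference)^2)
}

#' Resample a mask to the render resolution
#'
#' Area averaging for integer downsampling factors; bilinear interpolation
#' otherwise. The result is a soft reference in \[0, 1\], which the MSE loss
#' tolerates.
#'
#' @param mask numeric/integer matrix (height x width).
#' @param width,height target size.
#' @return numeric matrix (height x width) in \[0, 1\].
#' @export
resample_mask <- function(mask, width, height) {
  h0 <- nrow(mask); w0 <- ncol(mask)
  if (h0 == height && w0 == width) return(mask + 0)
  fx <- w0 / width; fy <- h0 / height
  m <- mask + 0
  if (fx == round(fx) && fy == round(fy) && fx >= 1 && fy >= 1) {
    fx <- as.integer(round(fx)); fy <- as.integer(round(fy))
    dim(m) <- c(fy, height, w0)
    m <- apply(m, c(2L, 3L), mean)
    dim(m) <- c(height, fx, width)
    return(apply(m, c(1L, 3L), mean))
  }
  # bilinear sampling at target pixel centres mapped into source coordinates
  sx <- (seq_len(width) - 0.5) * fx - 0.5
  sy <- (seq_len(height) - 0.5) * fy - 0.5
  x0 <- pmin(pmax(floor(sx), 0), w0 - 1L); x1 <- pmin(x0 + 1L, w0 - 1L)
  y0 <- pmin(pmax(floor(sy), 0), h0 - 1L); y1 <- pmin(y0 + 1L, h0 - 1L)
  wx <- pmin(pmax(sx - x0, 0), 1); wy <- pmin(pmax(sy - y0, 0), 1)
  a00 <- m[cbind(rep(y0 + 1L, width), rep(x0 + 1L, each = height))]
  a01 <- m[cbind(rep(y0 + 1L, width), rep(x1 + 1L, each = height))]
  a10 <- m[cbind(rep(y1 + 1L, width), rep(x0 + 1L, each = height))]
  a11 <- m[cbind(rep(y1 + 1L, width), rep(x1 + 1L, each = height))]
  WY <- rep(wy, width); WX <- rep(wx, each = height)
  out <- (1 - WY) * ((1 - WX) * a00 + WX * a01) +
         WY * ((1 - WX) * a10 + WX * a11)
  matrix(out, height, width)
}

#' Pose parameter vector: 3 translation (mm) + 6D rotation
#' @param pose a [rigid_pose].
#' @return numeric length-9 vector `c(t, r6)`.
#' @export
pose_to_params <- function(pose) {
  c(pose$translation, matrix_to_rotation6d(pose$rotation))
}

#' @rdname pose_to_params
#' @param params numeric length-9 vector.
#' @export
params_to_pose <- function(params) {
  rigid_pose(rotation6d_to_matrix(params[4:9]), params[1:3])
}

#' Silhouette MSE loss and its analytic pose gradient
#'
#' Evaluates the soft-silhouette MSE against a reference mask at the given
#' pose parameters and back-propagates it analytically: through the
#' per-pixel sigmoid/union aggregation to the projected vertex positions
#' (C++), then through the pinhole projection and the Gram-Schmidt 6D
#' rotation map to the 9 pose parameters.
#'
#' @param submesh [triangle_mesh] (world frame).
#' @param pose_params numeric length-9 vector (3 translation + 6D rotation).
#' @param cam a [pinhole_camera] (native resolution).
#' @param reference reference mask at the render resolution (values \[0, 1\]).
#' @param settings a [soft_render_settings].
#' @param want_grad compute the gradient? (FALSE gives loss + image only)
#' @return list with `loss`, `gradient` (length 9, when requested), `image`
#'   and `coverage` (sum of rendered pixel values).
#' @export
pose_gradient <- function(submesh, pose_params, cam, reference, settings,
                          want_grad = TRUE) {
  rcam <- render_camera(cam, settings)
  if (!all(dim(reference) == c(rcam$height, rcam$width)))
    stop("reference mask must be at the render resolution")
  R <- rotation6d_to_matrix(pose_params[4:9])
  t <- pose_params[1:3]
  V <- submesh$vertices
  Vc <- sweep(V %*% t(R), 2L, -t)
  z <- Vc[, 3L]
  valid <- z > 0
  u <- rcam$fx * Vc[, 1L] / z + rcam$cx
  v <- rcam$fy * Vc[, 2L] / z + rcam$cy
  u[!valid] <- NA_real_; v[!valid] <- NA_real_
  out <- cpp_soft_render(cbind(u, v), z, submesh$faces - 1L,
                         rcam$width, rcam$height, settings$blur_sigma,
                         settings$faces_per_pixel, settings$pad_sigmas,
                         reference + 0, isTRUE(want_grad))
  if (!is.finite(out$loss))
    stop("non-finite silhouette loss (pose: t = ",
         paste(signif(t, 4), collapse = ", "), ")")
  res <- list(loss = out$loss, image = out$image,
              coverage = sum(out$image))
  if (!isTRUE(want_grad)) return(res)
  gu <- out$grad_uv[, 1L]; gv <- out$grad_uv[, 2L]
  gu[!valid] <- 0; gv[!valid] <- 0
  z_safe <- ifelse(valid, z, 1)
  # dL/dVc through u = fx X/Z + cx, v = fy Y/Z + cy
  G <- cbind(gu * rcam$fx / z_safe,
             gv * rcam$fy / z_safe,
             -(gu * rcam$fx * Vc[, 1L] + gv * rcam$fy * Vc[, 2L]) / z_safe^2)
  dL_dt <- colSums(G)
  dL_dR <- crossprod(G, V)                   # 3 x 3
  J6 <- rotation6d_jacobian(pose_params[4:9])
  dL_dr6 <- vapply(1:6, function(k) sum(dL_dR * J6[, , k]), numeric(1L))
  res$gradient <- c(dL_dt, dL_dr6)
  res
}
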