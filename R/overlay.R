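#' Composite an anatomical model onto a video frame
#'
#' Hard-renders the given meshes (flat shaded, one colour per structure,
#' z-buffered) under the estimated pose and alpha-blends the rendering onto
#' the frame: `out = (1 - alpha * m) * frame + alpha * m * render`, where
#' `m` is the rendered coverage. With `alpha = 0` the frame is returned
#' bit-exactly; a model entirely behind the camera leaves the frame
#' untouched.
#'
#' @param frame background frame: h x w x 3 array (or grayscale matrix,
#'   promoted to RGB), values in \[0, 1\].
#' @param meshes list of [triangle_mesh] structures (e.g. prostate,
#'   neurovascular bundles, vesicular glands).
#' @param pose estimated [rigid_pose].
#' @param cam a [pinhole_camera] matching the frame size.
#' @param alpha blend opacity in \[0, 1\].
#' @param colors one RGB colour per mesh (list of length-3 vectors or a
#'   vector of hex strings).
#' @return list of class `overlay_frame` with `background`, `layer` (h x w x
#'   4: RGB + alpha coverage) and `composite` (h x w x 3).
#' @export
composite_overlay <- function(frame, meshes, pose, cam, alpha = 0.5,
                              colors = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.matrix(frame)) frame <- array(rep(frame, 3L), c(dim(frame), 3L))
  if (!all(dim(frame)[1:2] == c(cam$height, cam$width)))
    stop("frame size does not match the camera")
  if (is.null(colors))
    colors <- list(c(0.85, 0.45, 0.45), c(0.95, 0.85, 0.30),
                   c(0.40, 0.70, 0.90), c(0.55, 0.85, 0.50),
                   c(0.80, 0.60, 0.85))
  if (is.character(colors))
    colors <- lapply(colors, function(h) as.numeric(grDevices::col2rgb(h)) / 255)
  ids <- render_scene_ids(meshes, pose, cam)
  m <- ids$mesh_id
  layer <- array(0, c(cam$height, cam$width, 4L))
  for (i in seq_along(meshes)) {
    col <- colors[[(i - 1L) %% length(colors) + 1L]]
    sel <- m == i
    for (ch in 1:3) {
      pl <- layer[, , ch]; pl[sel] <- col[ch]; layer[, , ch] <- pl
    }
  }
  layer[, , 4L] <- as.numeric(m > 0L)
  comp <- frame
  cover <- alpha * layer[, , 4L]
  for (ch in 1:3)
    comp[, , ch] <- (1 - cover) * frame[, , ch] + cover * layer[, , ch]
  structure(list(background = frame, layer = layer, composite = comp),
            class = "overlay_frame")
}

#' @export
print.overlay_frame <- function(x, ...) {
  d <- dim(x$composite)
  cat(sprintf("overlay_frame: %dx%d px, %.1f%% covered\n", d[2L], d[1L],
              100 * mean(x$layer[, , 4L])))
  invisible(x)
}
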