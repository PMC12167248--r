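#' Read a triangle mesh from ASCII PLY or OBJ
#'
#' Supports the subset of the two formats this package writes: ASCII PLY with
#' vertex x/y/z (optionally a per-face `source_face` integer property) and OBJ
#' with `v`/`f` records (triangular faces).
#'
#' @param path file path ending in `.ply` or `.obj`.
#' @return a [triangle_mesh]; PLY `source_face` properties populate
#'   `face_labels`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to ASCII PLY or OBJ
#'
#' @param mesh a [triangle_mesh]; integer `face_labels` are written to PLY as
#'   a per-face `source_face` property (used by cue submeshes to keep their
#'   parent-mesh face indices).
#' @param path output path ending in `.ply` or `.obj`.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply")
    stop("not a PLY file: ", path)
  end_hdr <- which(trimws(lines) == "end_header")[1L]
  if (is.na(end_hdr)) stop("malformed PLY (no end_header): ", path)
  hdr <- lines[seq_len(end_hdr)]
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header in ", path)
  has_label <- any(grepl("property int source_face", hdr))
  body <- lines[-seq_len(end_hdr)]
  if (length(body) < nv + nf) stop("truncated PLY: ", path,
                                   " (expected ", nv + nf, " data lines)")
  vraw <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vraw, function(x) as.numeric(x[1:3])))
  if (any(!is.finite(verts))) stop("non-numeric vertex line in ", path)
  fraw <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- matrix(0L, nf, 3L)
  labels <- if (has_label) integer(nf) else NULL
  for (i in seq_len(nf)) {
    x <- as.numeric(fraw[[i]])
    if (is.na(x[1L]) || x[1L] != 3L)
      stop("non-triangular or malformed face line ", i, " in ", path)
    faces[i, ] <- as.integer(x[2:4]) + 1L
    if (has_label) labels[i] <- as.integer(x[5L])
  }
  triangle_mesh(verts, faces, face_labels = labels)
}

write_ply <- function(mesh, path) {
  labels <- mesh$face_labels
  write_labels <- !is.null(labels) && is.numeric(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               if (write_labels) "property int source_face",
               "end_header"), con)
  writeLines(apply(mesh$vertices, 1L, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), con)
  f0 <- mesh$faces - 1L
  flines <- paste(3L, f0[, 1L], f0[, 2L], f0[, 3L])
  if (write_labels) flines <- paste(flines, as.integer(labels))
  writeLines(flines, con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("no vertices/faces found in OBJ: ", path)
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x) {
    idx <- as.integer(sub("/.*$", "", x[-1L]))
    if (length(idx) != 3L) stop("non-triangular face in OBJ: ", path)
    idx
  }))
  triangle_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L, function(v)
    paste("v", paste(format(v, digits = 17, scientific = FALSE,
                            trim = TRUE), collapse = " "))), con)
  writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                   mesh$faces[, 3L]), con)
}

#' Read and write rigid poses as JSON
#'
#' The on-disk form is `{"rotation": [9 numbers, row-major], "translation_mm":
#' [3 numbers], "convention": "camera_from_world"}`.
#'
#' @param path JSON file path.
#' @return a [rigid_pose].
#' @export
read_pose_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$rotation) || length(x$rotation) != 9L)
    stop("pose JSON must contain a 9-element 'rotation' field: ", path)
  if (is.null(x$translation_mm) || length(x$translation_mm) != 3L)
    stop("pose JSON must contain a 3-element 'translation_mm' field: ", path)
  if (!is.null(x$convention) && x$convention != "camera_from_world")
    stop("unsupported pose convention: ", x$convention)
  rigid_pose(matrix(as.numeric(x$rotation), 3L, 3L, byrow = TRUE),
             as.numeric(x$translation_mm))
}

#' @rdname read_pose_json
#' @param pose a [rigid_pose].
#' @export
write_pose_json <- function(pose, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(pose$rotation)),
                            translation_mm = pose$translation,
                            convention = "camera_from_world"),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read and write pinhole camera intrinsics (YAML or JSON)
#'
#' Fields: `fx, fy, cx, cy, width, height`; format chosen by file extension.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return a [pinhole_camera].
#' @export
read_camera <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported camera format: .", ext)
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("camera file ", path, " missing field(s): ",
                         paste(miss, collapse = ", "))
  pinhole_camera(x$fx, x$fy, x$cx, x$cy, x$width, x$height)
}

#' @rdname read_camera
#' @param cam a [pinhole_camera].
#' @export
write_camera <- function(cam, path) {
  ext <- tolower(tools::file_ext(path))
  x <- cam[c("fx", "fy", "cx", "cy", "width", "height")]
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json") jsonlite::write_json(x, path, digits = NA,
                                               auto_unbox = TRUE)
  else stop("unsupported camera format: .", ext)
  invisible(path)
}

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are integer matrices (height x width) with values 0/1 in memory and
#' 0/255 on disk; the round trip is bit-exact.
#'
#' @param path PNG file path.
#' @return integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- matrix(as.integer(img > 0.5), nrow(img), ncol(img))
  m
}

#' @rdname read_mask_png
#' @param mask integer/logical matrix; nonzero means cue.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read and write grayscale or RGB frames as PNG
#' @param path PNG file path.
#' @return numeric matrix (grayscale) or h x w x 3 array in \[0, 1\].
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]
  img
}

#' @rdname read_frame_png
#' @param frame numeric matrix or h x w x 3 array in \[0, 1\].
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame, path)
  invisible(path)
}

#' Read and write 2D keypoints as JSON (list of \[u, v\] pairs)
#' @param path JSON file path.
#' @return n x 2 numeric matrix of pixel coordinates.
#' @export
read_keypoints_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- as.matrix(x)
  if (ncol(k) != 2L) stop("keypoints JSON must be a list of [u, v] pairs: ",
                          path)
  k
}

#' @rdname read_keypoints_json
#' @param keypoints n x 2 matrix.
#' @export
write_keypoints_json <- function(keypoints, path) {
  jsonlite::write_json(apply(as.matrix(keypoints), 1L, c, simplify = FALSE),
                       path, digits = NA)
  invisible(path)
}

#' Read and write point tracks as JSON
#'
#' On-disk dialect: one entry per frame, each a list of `[u, v, visible]`
#' triples; in memory a `tracked_points` object (see [track_points]).
#'
#' @param path JSON file path.
#' @return a `tracked_points` object.
#' @export
read_tracks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  nf <- length(x)
  np <- length(x[[1L]])
  pos <- array(NA_real_, c(nf, np, 2L))
  vis <- matrix(FALSE, nf, np)
  for (i in seq_len(nf)) {
    m <- do.call(rbind, lapply(x[[i]], unlist))
    pos[i, , ] <- m[, 1:2]
    vis[i, ] <- m[, 3L] != 0
  }
  tracked_points(pos, vis)
}

#' @rdname read_tracks_json
#' @param tracked a `tracked_points` object.
#' @export
write_tracks_json <- function(tracked, path) {
  nf <- dim(tracked$positions)[1L]
  out <- lapply(seq_len(nf), function(i)
    cbind(matrix(tracked$positions[i, , ], ncol = 2L),
          as.numeric(tracked$visible[i, ])))
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
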