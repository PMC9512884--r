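# Quaternions are length-4 numeric vectors c(w, x, y, z), unit norm,
# mapping molecule-frame vectors into camera-frame vectors.

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion for a rotation about an axis
#' @param axis Length-3 axis (need not be unit length, but must be nonzero).
#' @param angle_deg Rotation angle in degrees.
#' @return Unit quaternion `c(w, x, y, z)`.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero norm")
  axis <- axis / n
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

# 3x3 rotation matrix of a unit quaternion
quat_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Virtual camera pose
#'
#' The camera looks down its +z axis; +x is right, +y is down (raster
#' convention).  A molecule-frame point `p` maps to camera space as
#' `R(rotation) %*% (p - center) + c(0, 0, distance)`.
#'
#' @param rotation Unit quaternion `c(w, x, y, z)` (molecule to camera frame).
#' @param center Length-3 focus point (Angstrom).
#' @param distance Camera-to-center distance (Angstrom), > 0.
#' @param fov_scale Dimensionless focal factor, > 0; the projected offset of
#'   a point is `fov_scale * image_side * x / z` pixels.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation = quat_identity(), center = c(0, 0, 0),
                        distance = 50, fov_scale = 1) {
  stopifnot(length(rotation) == 4L, length(center) == 3L,
            distance > 0, fov_scale > 0)
  if (abs(sqrt(sum(rotation^2)) - 1) > 1e-6) rotation <- quat_normalize(rotation)
  p <- list(rotation = rotation, center = as.numeric(center),
            distance = as.numeric(distance), fov_scale = as.numeric(fov_scale))
  class(p) <- "camera_pose"
  p
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf("<camera_pose> dist %.2f A, fov %.3g, center (%.2f, %.2f, %.2f)\n",
              x$distance, x$fov_scale, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# Camera-space coordinates of an atom table (matrix n x 3)
camera_space <- function(at, pose) {
  p <- cbind(at$x, at$y, at$z)
  pc <- sweep(p, 2, pose$center) %*% t(quat_matrix(pose$rotation))
  pc[, 3] <- pc[, 3] + pose$distance
  pc
}

#' Project one frame of a structure to image coordinates
#'
#' Perspective projection: pixel position is proportional to
#' `(x_cam / z_cam, y_cam / z_cam)`; the pixel radius of an atom is
#' `vdw_radius * fov_scale * image_side / z_cam`.  Depth is normalized
#' linearly over the in-frustum atoms so the nearest atom has
#' `depth_norm = 1` and the farthest 0 (a lone atom gets 1).  An optional
#' fixed depth window overrides the per-image normalization, which keeps
#' the depth encoding constant across animation frames.
#'
#' @param frame Atom data frame (one frame of a [structure3d()]).
#' @param pose A [camera_pose()].
#' @param table An [element_table()].
#' @param image_side Image side length in pixels.
#' @param depth_window Optional `c(z_near, z_far)` camera-space window used
#'   in place of the per-image min/max depth normalization.
#' @return A data frame of projected atoms: `cx`, `cy` (continuous pixel
#'   coordinates, origin top-left, pixel centers at half-integers),
#'   `pixel_radius`, `depth_norm`, `element`, `serial`.  Atoms behind the
#'   camera are dropped; if nothing remains an error is raised.
#' @export
project <- function(frame, pose, table = element_table(), image_side = 256,
                    depth_window = NULL) {
  if (inherits(frame, "structure3d")) frame <- frame$frames[[1L]]
  stopifnot(image_side > 0)
  pc <- camera_space(frame, pose)
  vis <- pc[, 3] > 1e-9
  if (!any(vis)) stop("nothing visible: all atoms are behind the camera")
  pc <- pc[vis, , drop = FALSE]
  at <- frame[vis, , drop = FALSE]
  z <- pc[, 3]
  f <- pose$fov_scale * image_side
  cx <- image_side / 2 + f * pc[, 1] / z
  cy <- image_side / 2 + f * pc[, 2] / z
  pr <- vdw_radius(at$element, table) * f / z
  if (is.null(depth_window)) {
    zr <- range(z)
    dn <- if (diff(zr) < 1e-12) rep(1, length(z)) else (zr[2] - z) / (zr[2] - zr[1])
  } else {
    stopifnot(length(depth_window) == 2L, depth_window[2] > depth_window[1])
    dn <- pmin(pmax((depth_window[2] - z) / (depth_window[2] - depth_window[1]), 0), 1)
  }
  data.frame(cx = cx, cy = cy, pixel_radius = pr, depth_norm = dn,
             z_cam = z, element = at$element, serial = at$serial,
             stringsAsFactors = FALSE)
}

#' Default camera pose framing a whole structure
#'
#' Centers the view on the centroid of the first frame, with identity
#' rotation, and sets the distance so the molecule's bounding sphere spans
#' roughly 80 percent of the image side at the near face of the sphere.
#'
#' @param s A [structure3d()] or an atom data frame.
#' @param fov_scale Focal factor of the returned pose.
#' @param table An [element_table()] used for atom radii.
#' @return A [camera_pose()].
#' @export
auto_frame <- function(s, fov_scale = 1, table = element_table()) {
  at <- if (inherits(s, "structure3d")) s$frames[[1L]] else s
  p <- cbind(at$x, at$y, at$z)
  ctr <- colMeans(p)
  rad <- sqrt(colSums((t(p) - ctr)^2)) + vdw_radius(at$element, table)
  rb <- max(rad, 1)
  # near face of the bounding sphere at 80% of the half-side:
  # fov_scale * rb / (d - rb) = 0.4  =>  d = rb * (1 + fov_scale / 0.4)
  camera_pose(rotation = quat_identity(), center = ctr,
              distance = rb * (1 + fov_scale / 0.4), fov_scale = fov_scale)
}

#' Serialize / restore a camera pose
#'
#' The viewport is a single-line `key=value` record that can be copied and
#' pasted to restore a view; the round trip preserves every field to 1e-6.
#'
#' @param pose A [camera_pose()].
#' @return `viewport_to_text()` returns a single string;
#'   `text_to_viewport()` returns a [camera_pose()].
#' @export
viewport_to_text <- function(pose) {
  stopifnot(inherits(pose, "camera_pose"))
  num <- function(x) paste(sprintf("%.9g", x), collapse = ",")
  sprintf("viewport rot=%s center=%s dist=%s fov=%s",
          num(pose$rotation), num(pose$center),
          num(pose$distance), num(pose$fov_scale))
}

#' @rdname viewport_to_text
#' @param text A string produced by `viewport_to_text()` (possibly edited).
#' @export
text_to_viewport <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  grab <- function(key, n) {
    m <- regmatches(text, regexec(paste0("\\b", key, "=([-0-9.,eE+]+)"), text))[[1L]]
    if (length(m) < 2L) stop("malformed viewport text: missing field ", sQuote(key))
    v <- suppressWarnings(as.numeric(strsplit(m[2], ",", fixed = TRUE)[[1L]]))
    if (length(v) != n || any(is.na(v)))
      stop("malformed viewport text: field ", sQuote(key), " is not ", n, " number(s)")
    v
  }
  camera_pose(rotation = grab("rot", 4L), center = grab("center", 3L),
              distance = grab("dist", 1L), fov_scale = grab("fov", 1L))
}
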