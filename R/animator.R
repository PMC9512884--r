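#' Animation specification
#'
#' Four animation kinds are supported: `still` (fixed camera; frame count
#' follows the trajectory when the structure is multi-frame), `rock`
#' (sinusoidal oscillation of +/- `rock_amplitude` degrees about `axis`,
#' one full oscillation across the sequence, starting and ending at rest),
#' `turntable` (uniform rotation spanning 360 degrees about `axis`: frame
#' i of n is rotated by `i * 360 / n` degrees), and `zoom` (geometric
#' interpolation of the camera distance between two factors).
#'
#' @param kind One of `"still"`, `"rock"`, `"turntable"`, `"zoom"`.
#' @param n_frames Number of frames (>= 1).
#' @param axis Rotation axis (molecule frame) for rock/turntable.
#' @param rock_amplitude Peak rock angle in degrees.
#' @param zoom_range `c(start_factor, end_factor)` multiplying the base
#'   camera distance.
#' @param fixed_depth_window Optional `c(z_near, z_far)` camera-space
#'   depth window, keeping the blue-channel depth encoding consistent
#'   across frames instead of renormalizing per image.
#' @return A list of class `animation_spec`.
#' @export
animation_spec <- function(kind = c("still", "rock", "turntable", "zoom"),
                           n_frames = 24L, axis = c(0, 1, 0),
                           rock_amplitude = 15, zoom_range = c(1.0, 0.6),
                           fixed_depth_window = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 1)
  if (kind %in% c("rock", "turntable") && sqrt(sum(axis^2)) < 1e-12)
    stop("rotation axis has zero norm")
  structure(list(kind = kind, n_frames = as.integer(n_frames),
                 axis = axis / max(sqrt(sum(axis^2)), 1e-300),
                 rock_amplitude = rock_amplitude, zoom_range = zoom_range,
                 fixed_depth_window = fixed_depth_window),
            class = "animation_spec")
}

#' Plan camera poses for an animation
#'
#' @param base The base [camera_pose()] (frame 0 view).
#' @param spec An [animation_spec()].
#' @param n_structure_frames Number of frames in the structure (a `still`
#'   animation of a multi-frame structure emits one pose per structure
#'   frame).
#' @return List of [camera_pose()] objects.
#' @export
plan_poses <- function(base, spec, n_structure_frames = 1L) {
  stopifnot(inherits(base, "camera_pose"), inherits(spec, "animation_spec"))
  n <- if (spec$kind == "still" && n_structure_frames > 1L)
    n_structure_frames else spec$n_frames
  rotate_by <- function(angle)
    camera_pose(rotation = quat_mul(base$rotation,
                                    quat_axis_angle(spec$axis, angle)),
                center = base$center, distance = base$distance,
                fov_scale = base$fov_scale)
  switch(spec$kind,
    still = rep(list(base), n),
    turntable = lapply(seq_len(n) - 1L, function(i) rotate_by(i * 360 / n)),
    rock = lapply(seq_len(n) - 1L, function(i) {
      ang <- if (n == 1L) 0 else spec$rock_amplitude * sin(2 * pi * i / (n - 1L))
      rotate_by(ang)
    }),
    zoom = lapply(seq_len(n) - 1L, function(i) {
      tfrac <- if (n == 1L) 0 else i / (n - 1L)
      fac <- spec$zoom_range[1] * (spec$zoom_range[2] / spec$zoom_range[1])^tfrac
      camera_pose(rotation = base$rotation, center = base$center,
                  distance = base$distance * fac, fov_scale = base$fov_scale)
    }))
}

#' Render an animation as a numbered PNG sequence
#'
#' For every (structure frame, pose) pair: project, rasterize the sketch,
#' produce the image either with a trained translator or with the
#' analytic style renderer, optionally colorize, and write
#' `frame_%04d.png`.  When the structure is multi-frame and a rotation
#' mode is chosen, structure frames and poses advance together (structure
#' frames cycle if the counts differ).  A JSON manifest records the spec,
#' per-frame poses, file checksums and a ready-to-run encoder command.
#'
#' @param s A [structure3d()]; all frames must have equal atom counts.
#' @param spec An [animation_spec()].
#' @param out_dir Output directory (created if needed).
#' @param style A [style_spec()] used when `model` is `NULL`.
#' @param model Optional `translator_model` used for inference instead of
#'   the analytic renderer.
#' @param colorize Optional [colorize_params()] applied to every frame.
#' @param side Image side in pixels.
#' @param pose Optional base [camera_pose()] (default [auto_frame()]).
#' @param table An [element_table()].
#' @param save_sketches Also write the intermediate sketch of every frame
#'   as `sketch_%04d.png` (useful for inspecting the depth encoding or for
#'   corpus building).
#' @return Character vector of PNG paths, invisibly; the manifest is at
#'   `out_dir/manifest.json`.
#' @export
render_sequence <- function(s, spec, out_dir,
                            style = style_spec("simple_surface"),
                            model = NULL, colorize = NULL, side = 256,
                            pose = NULL, table = element_table(),
                            save_sketches = FALSE) {
  stopifnot(inherits(s, "structure3d"), inherits(spec, "animation_spec"))
  counts <- vapply(s$frames, nrow, 0L)
  if (length(unique(counts)) != 1L)
    stop("trajectory frames differ in atom count (frames ",
         paste(which(counts != counts[1]), collapse = ", "),
         " differ from frame 1); cannot animate")
  if (is.null(pose)) pose <- auto_frame(s, table = table)
  poses <- plan_poses(pose, spec, n_frames(s))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(poses))
  dw <- spec$fixed_depth_window
  for (i in seq_along(poses)) {
    frame <- s$frames[[((i - 1L) %% n_frames(s)) + 1L]]
    pr <- project(frame, poses[[i]], table, side, depth_window = dw)
    sk <- render_sketch(pr, side, table)
    if (save_sketches)
      write_image(sk, file.path(out_dir, sprintf("sketch_%04d.png", i)))
    img <- if (is.null(model)) {
      level_background(render_target(frame, poses[[i]], style, side, table,
                                     depth_window = dw))
    } else {
      infer(model, sk)
    }
    if (!is.null(colorize))
      img <- apply_color(img, intensity_matrix(sk, img, colorize),
                         colorize$color)
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", i))
    write_image(img, paths[i])
  }
  manifest <- list(
    spec = unclass(spec),
    side = side,
    renderer = if (is.null(model)) style$name else "translator",
    poses = vapply(poses, viewport_to_text, ""),
    files = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    encode_hint = sprintf(
      "ffmpeg -framerate 12 -i %s/frame_%%04d.png -pix_fmt yuv420p animation.mp4",
      out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
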