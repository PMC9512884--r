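# angle of a pose's rotation relative to an identity base, in degrees
pose_angle <- function(pose) {
  w <- min(1, max(-1, abs(pose$rotation[1])))
  a <- 2 * acos(w) * 180 / pi
  if (a > 180) 360 - a else a
}

test_that("plan_poses implements the four animation kinds", {
  base <- camera_pose(distance = 30)

  # still over a 48-frame trajectory: one pose per structure frame, all equal
  still <- plan_poses(base, animation_spec("still", n_frames = 10), 48)
  expect_length(still, 48)
  expect_true(all(vapply(still, function(p)
    identical(viewport_to_text(p), viewport_to_text(base)), TRUE)))

  # turntable: uniform 360-degree partition
  tt <- plan_poses(base, animation_spec("turntable", n_frames = 4,
                                        axis = c(0, 1, 0)))
  angles <- vapply(tt, pose_angle, 0)
  expect_equal(angles, c(0, 90, 180, 90))   # quaternion angle folds >180
  v <- c(1, 0, 0)
  rot180 <- protrender:::quat_matrix(tt[[3]]$rotation) %*% v
  expect_equal(as.numeric(rot180), c(-1, 0, 0), tolerance = 1e-12)

  # rock: starts at rest, peaks exactly at the amplitude
  rk <- plan_poses(base, animation_spec("rock", n_frames = 5,
                                        rock_amplitude = 15))
  rka <- vapply(rk, pose_angle, 0)
  expect_equal(rka[1], 0)
  expect_equal(max(rka), 15)

  # zoom: geometric interpolation of the distance
  zm <- plan_poses(base, animation_spec("zoom", n_frames = 3,
                                        zoom_range = c(1, 0.25)))
  expect_equal(vapply(zm, function(p) p$distance, 0), 30 * c(1, 0.5, 0.25))

  expect_error(animation_spec("turntable", axis = c(0, 0, 0)), "zero norm")
})

test_that("render_sequence writes deterministic numbered frames plus manifest", {
  s <- make_fixture(3, seed = 13, n_frames = 12)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- animation_spec("still", n_frames = 5)
  p1 <- render_sequence(s, spec, dir1, style = style_spec("chalky"), side = 48)
  expect_length(p1, 12)                       # trajectory length wins for still
  expect_equal(basename(p1[1]), "frame_0001.png")
  expect_true(all(file.exists(p1)))
  expect_equal(dim(read_image(p1[7])), c(48, 48, 3))

  p2 <- render_sequence(s, spec, dir2, style = style_spec("chalky"), side = 48)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  man <- jsonlite::read_json(file.path(dir1, "manifest.json"))
  expect_length(man$poses, 12)
  expect_length(man$md5, 12)
  expect_match(man$encode_hint, "ffmpeg")

  # a turntable half-rotation of an asymmetric molecule changes the image
  dir3 <- withr::local_tempdir()
  p3 <- render_sequence(make_fixture(4, seed = 3),
                        animation_spec("turntable", n_frames = 4), dir3,
                        style = style_spec("chalky"), side = 48)
  a <- read_image(p3[1]); b <- read_image(p3[3])
  expect_gt(sum(abs(a - b)), 0)

  # unequal frame atom counts are rejected with the frame indices
  bad <- make_fixture(3, seed = 1, n_frames = 2)
  bad$frames[[2]] <- bad$frames[[2]][-1, ]
  expect_error(render_sequence(bad, spec, withr::local_tempdir()),
               "frames .*2.* differ")
})

test_that("a fixed depth window keeps the blue channel steady under rotation", {
  # a centre atom on the rotation axis plus two off-axis atoms displaced in
  # +y (never occluding the centre); the pair is rotationally asymmetric,
  # so per-frame depth renormalization would wobble
  pts <- list(c(0, 0, 0), c(5, 6, 0), c(0, 6, 5))
  at <- do.call(rbind, lapply(seq_along(pts), function(i)
    data.frame(serial = i, element = "C", x = pts[[i]][1], y = pts[[i]][2],
               z = pts[[i]][3], chain_id = "A", residue_name = "ALA",
               residue_number = i, is_hetero = FALSE)))
  s <- structure3d(list(at))
  pose <- camera_pose(center = c(0, 0, 0), distance = 30)
  side <- 64

  blue_at_centre <- function(spec) {
    dir <- withr::local_tempdir()
    paths <- render_sequence(s, spec, dir, style = style_spec("chalky"),
                             side = side, pose = pose, save_sketches = TRUE)
    vapply(seq_along(paths), function(i)
      read_image(file.path(dir, sprintf("sketch_%04d.png", i)))[
        side / 2, side / 2, 3], 0)
  }

  fixed <- blue_at_centre(animation_spec("turntable", n_frames = 6,
                                         axis = c(0, 1, 0),
                                         fixed_depth_window = c(20, 40)))
  expect_lt(max(fixed) - min(fixed), 1 / 255 + 1e-9)

  # without the window, per-frame renormalization moves the encoding
  free <- blue_at_centre(animation_spec("turntable", n_frames = 6,
                                        axis = c(0, 1, 0)))
  expect_gt(max(free) - min(free), 1 / 255)
})

test_that("the command-line driver renders a sketch end to end", {
  cli <- system.file("cli", "protrender.R", package = "protrender")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "fix.pdb")
  png <- file.path(dir, "sketch.png")
  write_pdb(make_fixture(3, seed = 2), pdb)
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "sketch", "--pdb", shQuote(pdb), "--out",
                   shQuote(png), "--size", "64"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(png))
  expect_equal(dim(read_image(png)), c(64, 64, 3))
  expect_match(paste(out, collapse = " "), "viewport")
})
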