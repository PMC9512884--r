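frame_of <- function(...) {
  pts <- list(...)
  do.call(rbind, lapply(seq_along(pts), function(i)
    data.frame(serial = i, element = pts[[i]]$el %||% "C",
               x = pts[[i]]$p[1], y = pts[[i]]$p[2], z = pts[[i]]$p[3],
               chain_id = "A", residue_name = "ALA", residue_number = i,
               is_hetero = FALSE, stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Lambert shading: lit pole brightest, intensity falls toward the limb", {
  fr <- frame_of(list(p = c(0, 0, 0)))
  pose <- camera_pose(distance = 8)
  st <- style_spec("chalky", fog_strength = 0, ao_strength = 0,
                   light = c(0, 0, -1))       # light from the camera
  img <- render_target(fr, pose, st, side = 96)
  g <- protrender:::gray_mean(img)
  centre <- g[48, 48]
  expect_true(all(centre >= g[48, 49:90]))
  scan <- g[48, 48:70]
  hit <- scan < 1                             # sphere pixels on the scanline
  expect_true(all(diff(scan[hit]) <= 1e-9))   # monotone darkening to the limb
})

test_that("fog endpoints: full fog turns the farthest atom white", {
  fr <- frame_of(list(p = c(-3, 0, -3)), list(p = c(3, 0, 3)))
  pose <- camera_pose(distance = 12)
  st <- style_spec("chalky", fog_strength = 1, ao_strength = 0)
  img <- render_target(fr, pose, st, side = 96)
  # the far atom projects right of centre inside this window; under full
  # fog every one of its pixels must be pure white
  pr <- project(fr, pose, image_side = 96)
  far <- which.min(pr$depth_norm)
  rows <- round(pr$cy[far] + c(-1, 1) * (pr$pixel_radius[far] - 1))
  cols <- round(pr$cx[far] + c(-1, 1) * (pr$pixel_radius[far] - 1))
  expect_equal(min(img[rows[1]:rows[2], cols[1]:cols[2], ]), 1)
  # without fog the same window contains shaded (non-white) pixels
  st0 <- style_spec("chalky", fog_strength = 0, ao_strength = 0)
  img0 <- render_target(fr, pose, st0, side = 96)
  expect_lt(min(img0[rows[1]:rows[2], cols[1]:cols[2], ]), 1)
})

test_that("fog whitens receding atoms monotonically under a fixed depth window", {
  st <- style_spec("chalky", fog_strength = 0.8, ao_strength = 0)
  pose <- camera_pose(distance = 12)
  win <- c(6, 20)
  whiteness <- vapply(c(0, 2, 4), function(dz) {
    img <- render_target(frame_of(list(p = c(0, 0, dz))), pose, st,
                         side = 64, depth_window = win)
    g <- protrender:::gray_mean(img)
    mean(g[g < 1])                            # mean intensity of sphere pixels
  }, 0)
  expect_true(all(diff(whiteness) > 0))
})

test_that("ambient occlusion darkens crevices between touching spheres", {
  pair <- frame_of(list(p = c(-1.2, 0, 0)), list(p = c(1.2, 0, 0)))
  pose <- camera_pose(distance = 10)
  with_ao <- render_target(pair, pose,
                           style_spec("chalky", fog_strength = 0,
                                      ao_strength = 0.8), side = 64)
  no_ao <- render_target(pair, pose,
                         style_spec("chalky", fog_strength = 0,
                                    ao_strength = 0), side = 64)
  # the seam between the spheres (image centre column) loses light to AO
  expect_lt(mean(with_ao[30:34, 32, 1]), mean(no_ao[30:34, 32, 1]) - 0.02)
  # a lone sphere has no occluders: AO strength is irrelevant
  lone <- frame_of(list(p = c(0, 0, 0)))
  expect_identical(
    render_target(lone, pose, style_spec("chalky", fog_strength = 0,
                                         ao_strength = 0.8), side = 64),
    render_target(lone, pose, style_spec("chalky", fog_strength = 0,
                                         ao_strength = 0), side = 64))
})

test_that("style presets: element colours vs grayscale chalk", {
  s <- make_fixture(4, seed = 9)               # contains O and N
  pose <- auto_frame(s)
  simple <- render_target(s$frames[[1]], pose, style_spec("simple_surface"), 96)
  chalky <- render_target(s$frames[[1]], pose, style_spec("chalky"), 96)
  # oxygen shows as red-dominant pixels somewhere
  red <- simple[, , 1] > simple[, , 2] + 0.1 & simple[, , 1] > simple[, , 3] + 0.1
  expect_gt(sum(red), 0)
  # chalky is strictly grayscale
  expect_equal(chalky[, , 1], chalky[, , 2], tolerance = 1e-12)
  expect_equal(chalky[, , 2], chalky[, , 3], tolerance = 1e-12)
  # renderer is deterministic
  expect_identical(chalky,
                   render_target(s$frames[[1]], pose, style_spec("chalky"), 96))
})

test_that("chalky_shadow differs from chalky only at and below the molecule", {
  s <- make_fixture(4, seed = 6)
  pose <- auto_frame(s)
  side <- 96
  light <- c(-0.3, -0.8, -0.52)
  a <- render_target(s$frames[[1]], pose, style_spec("chalky", light = light),
                     side)
  b <- render_target(s$frames[[1]], pose,
                     style_spec("chalky_shadow", light = light), side)
  dif <- which(apply(abs(a - b) > 1e-9, c(1, 2), any), arr.ind = TRUE)
  expect_gt(nrow(dif), 0)                      # a shadow was cast
  sil <- which(protrender:::gray_mean(a) < 1, arr.ind = TRUE)
  expect_true(all(dif[, 1] > min(sil[, 1])))   # nothing above the molecule top
  expect_gt(min(dif[, 1]), side / 2)           # shadow lies in the lower half
})

test_that("level_background rescales the connected background to exact white", {
  s <- make_fixture(3, seed = 2)
  pose <- auto_frame(s)
  img <- render_target(s$frames[[1]], pose, style_spec("chalky"), 64)
  dim0 <- dim(img)
  dulled <- img * 0.98                          # background now 0.98
  lv <- level_background(dulled)
  expect_equal(dim(lv), dim0)
  expect_equal(lv[1, 1, ], c(1, 1, 1))
  expect_equal(lv[64, 64, ], c(1, 1, 1))
  # idempotent, and identity on an already-white background
  expect_equal(level_background(lv), lv, tolerance = 1e-12)
  expect_equal(level_background(img), img, tolerance = 1e-12)
})
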