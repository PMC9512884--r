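test_that("augment_structure is seed-deterministic and respects hydrogen rules", {
  s <- make_fixture(6, seed = 3, with_hydrogens = TRUE, with_waters = TRUE)

  a <- augment_structure(s, augment_config(), seed = 5)
  b <- augment_structure(s, augment_config(), seed = 5)
  expect_identical(a$structure$frames, b$structure$frames)
  expect_equal(viewport_to_text(a$pose), viewport_to_text(b$pose))

  # no substitution: element multiset is unchanged apart from drop filters
  cfg0 <- augment_config(h_substitution_prob = 0, drop_waters_prob = 0,
                         drop_hydrogens_prob = 0)
  out0 <- augment_structure(s, cfg0, seed = 9)
  expect_equal(sort(out0$structure$frames[[1]]$element),
               sort(s$frames[[1]]$element))

  # hydrogens dropped: substitution must not fire at all
  cfg1 <- augment_config(drop_hydrogens_prob = 1, h_substitution_prob = 1,
                         drop_waters_prob = 0)
  out1 <- augment_structure(s, cfg1, seed = 9)
  expect_false(any(out1$structure$frames[[1]]$element %in% c("H", "D")))
  expect_true(all(out1$structure$frames[[1]]$element %in%
                  s$frames[[1]]$element))     # nothing exotic appeared

  # hydrogens kept with certain substitution: every H becomes a rare element
  cfg2 <- augment_config(drop_hydrogens_prob = 0, h_substitution_prob = 1,
                         drop_waters_prob = 0)
  out2 <- augment_structure(s, cfg2, seed = 9)
  expect_false(any(out2$structure$frames[[1]]$element == "H"))
  expect_true(any(out2$structure$frames[[1]]$element %in%
                  cfg2$substitute_elements))
})

test_that("scale_and_crop keeps size, pairs share the window, unit scale is identity", {
  set.seed(1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- scale_and_crop(img, crop_scale = 1.117, seed = 3)
  expect_equal(dim(out), dim(img))
  expect_identical(out, scale_and_crop(img, crop_scale = 1.117, seed = 3))
  expect_false(isTRUE(all.equal(out,
    scale_and_crop(img, crop_scale = 1.117, seed = 4))))
  expect_identical(scale_and_crop(img, crop_scale = 1), img)

  # the paired contract: same seed -> same crop window on different content
  img2 <- img; img2[, , 1] <- 1 - img2[, , 1]
  o1 <- scale_and_crop(img, 1.117, seed = 7)
  o2 <- scale_and_crop(img2, 1.117, seed = 7)
  # green/blue channels of the pair were identical, so the crops must agree
  expect_equal(o1[, , 2:3], o2[, , 2:3], tolerance = 1e-12)
})

test_that("build_corpus produces aligned, reproducible, downsampled pairs", {
  pairs <- build_corpus(3, side = 64, style = style_spec("chalky"), seed = 2,
                        render_side = 128, n_residues = 4)
  expect_length(pairs, 3)
  for (p in pairs) {
    expect_equal(dim(p$sketch), c(64, 64, 3))
    expect_equal(dim(p$target), c(64, 64, 3))
    # registration: sketch mask and non-white target region overlap
    m <- sketch_to_mask(p$sketch)
    tgt <- (protrender:::gray_mean(p$target) < 0.999) * 1
    iou <- sum(m * tgt) / sum(pmax(m, tgt))
    expect_gt(iou, 0.5)
  }
  again <- build_corpus(3, side = 64, style = style_spec("chalky"), seed = 2,
                        render_side = 128, n_residues = 4)
  expect_identical(pairs[[2]]$sketch, again[[2]]$sketch)
  expect_identical(pairs[[2]]$target, again[[2]]$target)

  # image-level flips/rotations are never part of the pipeline
  expect_false(augment_config()$flip_rotate_images)
})

test_that("low-resolution targets equal naive block averaging of the full render", {
  pairs <- build_corpus(1, side = 64, style = style_spec("chalky"), seed = 8,
                        render_side = 256, n_residues = 3)
  # independently rebuild the full-resolution target from the recorded seeds
  prov <- pairs[[1]]$provenance
  s <- make_fixture(3, seed = prov$fixture_seed,
                    with_hydrogens = TRUE, with_waters = TRUE)
  aug <- augment_structure(s, augment_config(), seed = prov$augment_seed)
  full <- level_background(
    render_target(aug$structure, aug$pose, style_spec("chalky"), side = 256))
  naive <- array(0, c(64, 64, 3))
  for (i in 1:64) for (j in 1:64) for (ch in 1:3)
    naive[i, j, ch] <- mean(full[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4, ch])
  expect_lt(max(abs(naive - pairs[[1]]$target)), 1 / 255)
})

test_that("a corpus round-trips through its on-disk manifest", {
  dir <- withr::local_tempdir()
  pairs <- build_corpus(2, side = 32, style = style_spec("simple_surface"),
                        seed = 4, render_side = 64, n_residues = 3,
                        out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_setequal(list.files(file.path(dir, "pairs")),
                  c("0001_sketch.png", "0001_target.png",
                    "0002_sketch.png", "0002_target.png"))
  back <- read_corpus(dir)
  expect_length(back, 2)
  for (i in 1:2) {
    # PNG storage quantizes to 8 bits
    expect_lt(max(abs(back[[i]]$sketch - pairs[[i]]$sketch)), 1 / 255)
    expect_lt(max(abs(back[[i]]$target - pairs[[i]]$target)), 1 / 255)
    expect_equal(back[[i]]$provenance$pose, pairs[[i]]$provenance$pose)
    expect_equal(back[[i]]$provenance$fixture_seed,
                 pairs[[i]]$provenance$fixture_seed)
  }
})
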