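#' Augmentation configuration for corpus building
#'
#' Structure-level augmentations mirror how training corpora for the
#' sketch-to-render mapping are diversified: waters and hydrogens are
#' randomly removed, retained hydrogens are occasionally substituted with
#' rarer elements, and each model is viewed under a uniformly random
#' rotation and a random camera-distance factor.  Image-level flips and
#' rotations are deliberately never applied, so the consistent directional
#' lighting of the targets stays learnable.
#'
#' @param drop_waters_prob,drop_hydrogens_prob Probability that the
#'   respective filter is applied to a given variant.
#' @param h_substitution_prob Per-hydrogen probability of substitution
#'   (only when hydrogens are retained).
#' @param substitute_elements Pool of substitute symbols.
#' @param scale_range Multiplicative camera-distance range.
#' @param crop_scale Image scale factor before the random crop (256 -> 286
#'   with the default 1.117).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(drop_waters_prob = 0.5, drop_hydrogens_prob = 0.5,
                           h_substitution_prob = 0.02,
                           substitute_elements = c("S", "P", "FE", "CL", "BR"),
                           scale_range = c(0.85, 1.25), crop_scale = 1.117) {
  stopifnot(crop_scale > 1 || crop_scale == 1,
            all(c(drop_waters_prob, drop_hydrogens_prob,
                  h_substitution_prob) >= 0),
            all(c(drop_waters_prob, drop_hydrogens_prob,
                  h_substitution_prob) <= 1))
  structure(list(drop_waters_prob = drop_waters_prob,
                 drop_hydrogens_prob = drop_hydrogens_prob,
                 h_substitution_prob = h_substitution_prob,
                 substitute_elements = substitute_elements,
                 scale_range = scale_range, crop_scale = crop_scale,
                 flip_rotate_images = FALSE),
            class = "augment_config")
}

#' Randomly augment a structure and draw a viewing pose
#'
#' Deterministic under `seed`: independently applies water removal,
#' hydrogen removal, per-hydrogen element substitution (skipped entirely
#' when hydrogens were dropped), then a uniformly random rotation and a
#' random camera distance within `scale_range` applied to the structure's
#' auto-framed pose.
#'
#' @param s A [structure3d()].
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return List with elements `structure` and `pose`.
#' @export
augment_structure <- function(s, cfg = augment_config(), seed = 1L) {
  stopifnot(inherits(s, "structure3d"))
  with_seed(seed, {
    drop_w <- stats::runif(1) < cfg$drop_waters_prob
    drop_h <- stats::runif(1) < cfg$drop_hydrogens_prob
    out <- tryCatch(edit_structure(s, drop_waters = drop_w,
                                   drop_hydrogens = drop_h),
                    error = function(e) s)
    if (!drop_h && cfg$h_substitution_prob > 0) {
      is_h <- toupper(out$frames[[1L]]$element) %in% c("H", "D")
      sub <- is_h & stats::runif(length(is_h)) < cfg$h_substitution_prob
      if (any(sub)) {
        repl <- sample(cfg$substitute_elements, sum(sub), replace = TRUE)
        out$frames <- lapply(out$frames, function(at) {
          at$element[sub] <- repl
          at
        })
      }
    }
    q <- quat_normalize(stats::rnorm(4))        # uniform over SO(3)
    fac <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    base <- auto_frame(out)
    pose <- camera_pose(rotation = q, center = base$center,
                        distance = base$distance * fac,
                        fov_scale = base$fov_scale)
    list(structure = out, pose = pose)
  })
}

#' Scale-and-crop image augmentation
#'
#' Bilinearly upscales the image to `round(side * crop_scale)` and crops a
#' window of the original size at a seed-determined uniform-random offset.
#' The same seed yields the same window, so the sketch and target of a
#' pair stay registered.  `crop_scale = 1` is the identity.
#'
#' @param img `[H, W, C]` image (square).
#' @param crop_scale Scale factor > 1 (or exactly 1 for a no-op).
#' @param seed Integer seed determining the crop offset.
#' @return Image of the original size.
#' @export
scale_and_crop <- function(img, crop_scale = 1.117, seed = 1L) {
  side <- dim(img)[1]
  stopifnot(dim(img)[2] == side, crop_scale >= 1)
  if (crop_scale == 1) return(img)
  big <- round(side * crop_scale)
  up <- resize_bilinear(img, big, big)
  off <- with_seed(seed, sample.int(big - side + 1L, 2L, replace = TRUE))
  up[off[1]:(off[1] + side - 1L), off[2]:(off[2] + side - 1L), , drop = FALSE]
}

#' Build a paired sketch/target training corpus
#'
#' Each pair is produced from a synthetic fixture (or a user-supplied
#' structure, cycled), augmented with [augment_structure()], projected, and
#' rendered both as a sketch and as a style-oracle target at
#' `render_side`, then area-downsampled to the requested `side`
#' (`render_side` must be an integer multiple of `side`).  Reproducible
#' under `seed`.  When `out_dir` is given, pairs are written as
#' `pairs/{id}_sketch.png` / `pairs/{id}_target.png` plus a JSON manifest.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param side Output resolution (typically 256, 512 or 1024; any divisor
#'   of `render_side` works for tests).
#' @param style A [style_spec()].
#' @param cfg An [augment_config()].
#' @param seed Master seed.
#' @param structures Optional list of [structure3d()] to draw from instead
#'   of synthetic fixtures.
#' @param render_side Internal rendering resolution (default 1024).
#' @param n_residues Size of the synthetic fixtures.
#' @param out_dir Optional output directory.
#' @return List of pairs; each has `sketch`, `target`, `side` and
#'   `provenance` (fixture seed, pose text, augmentation seed).
#' @export
build_corpus <- function(n_pairs, side = 256, style = style_spec("chalky"),
                         cfg = augment_config(), seed = 1L,
                         structures = NULL, render_side = 1024L,
                         n_residues = 8L, out_dir = NULL) {
  stopifnot(n_pairs >= 1, render_side %% side == 0)
  factor <- render_side %/% side
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    fix_seed <- as.integer(seed) * 1000L + i
    s <- if (is.null(structures)) {
      make_fixture(n_residues, seed = fix_seed,
                   with_hydrogens = TRUE, with_waters = TRUE)
    } else structures[[((i - 1L) %% length(structures)) + 1L]]
    aug <- augment_structure(s, cfg, seed = fix_seed + 1L)
    pr <- project(aug$structure, aug$pose, image_side = render_side)
    sketch <- render_sketch(pr, render_side)
    target <- level_background(
      render_target(aug$structure, aug$pose, style, side = render_side))
    pairs[[i]] <- list(
      sketch = box_downsample(sketch, factor),
      target = box_downsample(target, factor),
      side = side,
      provenance = list(fixture_seed = fix_seed, augment_seed = fix_seed + 1L,
                        pose = viewport_to_text(aug$pose),
                        style = style$name))
  }
  if (!is.null(out_dir)) write_corpus(pairs, out_dir)
  pairs
}

#' Write / read a corpus directory
#'
#' @param pairs List of pairs from [build_corpus()].
#' @param dir Corpus directory (created if needed); images go under
#'   `dir/pairs/`, metadata into `dir/manifest.json`.
#' @return `read_corpus()` returns the pair list with images reloaded.
#' @export
write_corpus <- function(pairs, dir) {
  pd <- file.path(dir, "pairs")
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(seq_along(pairs), function(i) {
    id <- sprintf("%04d", i)
    write_image(pairs[[i]]$sketch, file.path(pd, paste0(id, "_sketch.png")))
    write_image(pairs[[i]]$target, file.path(pd, paste0(id, "_target.png")))
    c(list(id = id, side = pairs[[i]]$side), pairs[[i]]$provenance)
  })
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(meta, function(m) {
    list(sketch = read_image(file.path(dir, "pairs", paste0(m$id, "_sketch.png"))),
         target = read_image(file.path(dir, "pairs", paste0(m$id, "_target.png"))),
         side = m$side,
         provenance = m[setdiff(names(m), c("id", "side"))])
  })
}
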