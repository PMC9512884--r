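#' Colorization parameters
#'
#' @param color Length-3 RGB in `[0, 1]`, or a hex string like `"#00ff00"`.
#' @param strength Global colour strength in `[0, 1]`.
#' @param blend_radius Optional blur radius in pixels (>= 0); the
#'   colour-intensity matrix is Gaussian-blurred with
#'   `sigma = blend_radius / 3`, truncated at 3 sigma, so the blur reaches
#'   exactly `blend_radius` pixels and leaves background farther away
#'   untouched.
#' @return A list of class `colorize_params`.
#' @export
colorize_params <- function(color = c(0, 1, 0), strength = 0.5,
                            blend_radius = 0) {
  if (is.character(color)) color <- hex_to_rgb(color)
  stopifnot(length(color) == 3L, all(color >= 0 & color <= 1),
            strength >= 0, strength <= 1, blend_radius >= 0)
  structure(list(color = as.numeric(color), strength = strength,
                 blend_radius = blend_radius),
            class = "colorize_params")
}

hex_to_rgb <- function(hex) {
  hex <- sub("^#", "", hex)
  if (!grepl("^[0-9a-fA-F]{6}$", hex)) stop("not a hex colour: ", sQuote(hex))
  strtoi(substring(hex, c(1, 3, 5), c(2, 4, 6)), 16L) / 255
}

#' Colour-intensity matrix
#'
#' The per-pixel weight `w` in `[0, 1]` that controls how strongly the user
#' colour replaces the rendered colour.  It is the element-wise product of
#' four image-derived matrices: the binary protein mask of the sketch
#' ([sketch_to_mask()]), the grayscale of the render (unweighted channel
#' mean), the depth matrix (the sketch's blue channel; 1 = closest), and a
#' constant matrix equal to the user strength.  A positive `blend_radius`
#' then blurs the product with a normalized Gaussian kernel and re-clamps.
#'
#' @param sketch Sketch image `[H, W, 3]`.
#' @param render Render image `[H, W, 3]` (same dimensions).
#' @param params A [colorize_params()].
#' @return `[H, W]` matrix in `[0, 1]`.
#' @export
intensity_matrix <- function(sketch, render, params = colorize_params()) {
  if (!identical(dim(sketch)[1:2], dim(render)[1:2]))
    stop("sketch and render dimensions differ")
  w <- sketch_to_mask(sketch) * gray_mean(render) * sketch[, , 3] *
    params$strength
  if (params$blend_radius > 0)
    w <- pmin(pmax(gaussian_blur(w, params$blend_radius / 3), 0), 1)
  w
}

#' Blend a user colour into a render
#'
#' Per channel, `out = (1 - w) * render + w * color`: a pixel is unchanged
#' where `w = 0` and replaced by the user colour where `w = 1`.
#'
#' @param render `[H, W, 3]` image.
#' @param w `[H, W]` colour-intensity matrix.
#' @param color Length-3 RGB or hex string.
#' @return Colorized `[H, W, 3]` image.
#' @export
apply_color <- function(render, w, color) {
  if (is.character(color)) color <- hex_to_rgb(color)
  if (!identical(dim(render)[1:2], dim(w)[1:2]))
    stop("render and intensity-matrix dimensions differ")
  out <- render
  for (ch in 1:3) out[, , ch] <- (1 - w) * render[, , ch] + w * color[ch]
  out
}

#' One-call colorization
#'
#' Convenience wrapper: computes the intensity matrix and applies the
#' colour.
#'
#' @inheritParams intensity_matrix
#' @return Colorized render.
#' @export
colorize <- function(sketch, render, params = colorize_params()) {
  apply_color(render, intensity_matrix(sketch, render, params), params$color)
}
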