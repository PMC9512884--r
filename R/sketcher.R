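#' Sketch rendering options
#'
#' Free parameters of the sketch encoding.  The three-step spherical
#' gradient uses concentric radial zones at fractions `[0, 0.5)`,
#' `[0.5, 0.8)` and `[0.8, 1]` of the circle radius with red/green
#' multipliers `gradient_levels`; the highlight center is offset toward the
#' upper left by `highlight_offset * radius` to suggest sphericity.  The
#' outline stroke is centered on the circle boundary with width
#' `max(1, pixel_radius / 12)` px, drawn in a gray that depends on depth:
#' with `outline_near_black = TRUE` (default) the nearest atoms get black
#' outlines and the farthest mid-gray 0.5; the flag flips that direction.
#'
#' @param gradient_breaks Zone edges as fractions of the radius.
#' @param gradient_levels Red/green multiplier per zone.
#' @param highlight_offset Fractional offset of the gradient center.
#' @param outline_near_black Direction of the outline depth shading.
#' @param supersample Supersampling factor (rendered at `side * supersample`
#'   then box-downsampled).
#' @return A list of class `sketch_config`.
#' @export
sketch_config <- function(gradient_breaks = c(0.5, 0.8),
                          gradient_levels = c(1.0, 0.85, 0.7),
                          highlight_offset = 0.2,
                          outline_near_black = TRUE,
                          supersample = 2L) {
  stopifnot(length(gradient_levels) == length(gradient_breaks) + 1L,
            supersample >= 1L)
  structure(list(gradient_breaks = gradient_breaks,
                 gradient_levels = gradient_levels,
                 highlight_offset = highlight_offset,
                 outline_near_black = outline_near_black,
                 supersample = as.integer(supersample)),
            class = "sketch_config")
}

#' Rasterize projected atoms into a sketch image
#'
#' Atoms are drawn back to front (ascending `depth_norm`, ties broken by
#' serial) as filled discs over a black background.  The fill colour is
#' `(r * m, g * m, b)` where `(r, g)` is the element encoding, `b` the
#' depth encoding and `m` the three-step gradient multiplier of the radial
#' zone (the blue channel is not gradient-modulated).  Each disc gets a
#' depth-shaded gray outline.  Rendering is supersampled then
#' box-downsampled, so edges are anti-aliased.
#'
#' @param atoms Data frame from [project()].
#' @param side Output image side in pixels.
#' @param table An [element_table()].
#' @param config A [sketch_config()].
#' @return `[side, side, 3]` array of class `sketch_image`.
#' @export
render_sketch <- function(atoms, side, table = element_table(),
                          config = sketch_config()) {
  if (side <= 0) stop("image side must be positive")
  ss <- config$supersample
  S <- side * ss
  img <- array(0, c(S, S, 3L))
  if (!is.null(atoms) && nrow(atoms)) {
    ord <- order(atoms$depth_norm, atoms$serial)
    atoms <- atoms[ord, , drop = FALSE]
    chan <- t(vapply(atoms$element, element_channels, numeric(2), table = table))
    bs <- depth_channel(atoms$depth_norm)
    gray0 <- if (config$outline_near_black) (1 - atoms$depth_norm) * 0.5
             else atoms$depth_norm * 0.5
    for (i in seq_len(nrow(atoms))) {
      cx <- atoms$cx[i] * ss; cy <- atoms$cy[i] * ss
      r  <- atoms$pixel_radius[i] * ss
      wout <- max(1, atoms$pixel_radius[i] / 12) * ss
      rmax <- r + wout / 2
      x0 <- max(1L, floor(cx - rmax)); x1 <- min(S, ceiling(cx + rmax) + 1L)
      y0 <- max(1L, floor(cy - rmax)); y1 <- min(S, ceiling(cy + rmax) + 1L)
      if (x0 > x1 || y0 > y1 || r <= 0) next
      xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
      dx <- xs - cx; dy <- ys - cy
      d2 <- outer(dy^2, dx^2, "+")            # [ny, nx] distance^2 to center
      inside <- d2 <= rmax^2
      if (!any(inside)) next
      d <- sqrt(d2[inside])
      # gradient zone from the offset highlight center
      hx <- cx - config$highlight_offset * r
      hy <- cy - config$highlight_offset * r
      dh <- sqrt(outer((ys - hy)^2, (xs - hx)^2, "+")[inside])
      zone <- findInterval(pmin(dh / r, 1), config$gradient_breaks) + 1L
      m <- config$gradient_levels[zone]
      colR <- chan[i, 1] * m; colG <- chan[i, 2] * m
      colB <- rep(bs[i], length(d))
      ring <- d >= r - wout / 2
      colR[ring] <- gray0[i]; colG[ring] <- gray0[i]; colB[ring] <- gray0[i]
      ix <- which(inside)
      patch <- img[y0:y1, x0:x1, 1]; patch[ix] <- colR; img[y0:y1, x0:x1, 1] <- patch
      patch <- img[y0:y1, x0:x1, 2]; patch[ix] <- colG; img[y0:y1, x0:x1, 2] <- patch
      patch <- img[y0:y1, x0:x1, 3]; patch[ix] <- colB; img[y0:y1, x0:x1, 3] <- patch
    }
  }
  out <- box_downsample(img, ss)
  class(out) <- c("sketch_image", class(out))
  out
}

#' Binary protein mask of a sketch
#'
#' A pixel belongs to the protein surface iff any channel is nonzero (the
#' background is exactly black, so no threshold is needed).
#'
#' @param img A sketch image (`[H, W, 3]`).
#' @return `[H, W]` matrix of 0/1.
#' @export
sketch_to_mask <- function(img) {
  m <- pmax(img[, , 1], img[, , 2], img[, , 3])
  (m > 0) * 1.0
}
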