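# Images throughout the package are numeric arrays [H, W, 3] with values in
# [0, 1], row 1 at the top (raster convention, matching png::readPNG).

#' Read / write an image as 8-bit RGB PNG
#' @param img `[H, W, 3]` array in `[0, 1]`.
#' @param path File path.
#' @return `read_image()` returns an `[H, W, 3]` array.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

# Integer-factor box (area) downsampling: mean over factor x factor blocks.
box_downsample <- function(img, factor) {
  stopifnot(factor >= 1, dim(img)[1] %% factor == 0, dim(img)[2] %% factor == 0)
  if (factor == 1) return(img)
  h <- dim(img)[1] %/% factor; w <- dim(img)[2] %/% factor
  out <- array(0, c(h, w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    m <- img[, , ch]
    dim(m) <- c(factor, h * factor * w)
    m <- colMeans(m)                       # rows pooled: h * (factor*w)
    dim(m) <- c(h, factor * w)
    m <- t(m)                              # (factor*w) x h
    dim(m) <- c(factor, w * h)
    m <- colMeans(m)                       # columns pooled: w * h
    dim(m) <- c(w, h)
    out[, , ch] <- t(m)
  }
  out
}

# Bilinear resize to new_h x new_w (EBImage backend; EBImage stores x first).
resize_bilinear <- function(img, new_h, new_w) {
  e <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(e, w = new_w, h = new_h, filter = "bilinear")
  aperm(EBImage::imageData(r), c(2, 1, 3))
}

# Isotropic Gaussian blur of a matrix, sigma in pixels, kernel truncated at
# 3 sigma (separable convolution with replicated edges).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_apply <- function(mat) {   # convolve columns with k
    n <- nrow(mat)
    padded <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                    mat[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

# Mean of the three channels.
gray_mean <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
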