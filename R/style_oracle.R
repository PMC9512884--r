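#' Rendering style presets
#'
#' Three named photorealistic-style presets drive the analytic renderer:
#' `simple_surface` colours atoms by element (carbon light silver, oxygen
#' red, nitrogen blue, sulfur yellow, hydrogen white; other elements fall
#' back to the carbon colour), `chalky` renders every atom in the same
#' white, diffuse material, and `chalky_shadow` is chalky plus a shadow
#' cast by the light onto a pure-white floor below the molecule.  All
#' styles share fade-to-white fog and an ambient-occlusion proxy.
#'
#' @param name One of `"simple_surface"`, `"chalky"`, `"chalky_shadow"`.
#' @param fog_strength Fraction of the fade-to-white effect in `[0, 1]`.
#' @param ao_strength Ambient-occlusion darkening in `[0, 1]`.
#' @param light Unit 3-vector pointing from the surface toward the light
#'   (camera space: x right, y down, z away from the camera).
#' @return A list of class `style_spec`.
#' @export
style_spec <- function(name = c("simple_surface", "chalky", "chalky_shadow"),
                       fog_strength = 0.5, ao_strength = NULL,
                       light = c(-0.45, -0.6, -0.66)) {
  name <- match.arg(name)
  light <- light / sqrt(sum(light^2))
  silver <- c(0.85, 0.85, 0.88)
  colors <- if (name == "simple_surface") {
    list(C = silver, O = c(0.80, 0.10, 0.10), N = c(0.15, 0.25, 0.80),
         S = c(0.90, 0.85, 0.20), H = c(1, 1, 1))
  } else {
    list(C = c(1, 1, 1), O = c(1, 1, 1), N = c(1, 1, 1),
         S = c(1, 1, 1), H = c(1, 1, 1))
  }
  if (is.null(ao_strength)) ao_strength <- if (name == "simple_surface") 0.6 else 0.7
  structure(list(name = name, colors = colors, light = light,
                 fog_strength = fog_strength, ao_strength = ao_strength,
                 shadow = name == "chalky_shadow"),
            class = "style_spec")
}

style_color <- function(element, style) {
  col <- style$colors[[toupper(element)]]
  if (is.null(col)) style$colors$C else col
}

# 12 fixed hemisphere directions (z > 0) used for the ambient-occlusion
# proxy; a deterministic golden-spiral set.
ao_directions <- function(n = 12L) {
  i <- seq_len(n)
  z <- (i - 0.5) / n * 0.85 + 0.1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Render a photorealistic-style target image
#'
#' Deterministic analytic renderer: per-pixel nearest ray/sphere
#' intersection, Lambertian shading (`max(0, n.l)` plus 0.3 ambient), an
#' ambient-occlusion proxy (fraction of 12 fixed hemisphere directions from
#' the hit point blocked by neighbouring atom spheres, darkening by
#' `ao_strength * occlusion`), and fade-to-white fog
#' (`fog_strength * (1 - depth_norm)` lerp toward white).  The background
#' is pure white; the `chalky_shadow` style additionally casts soft gray
#' shadows onto a white floor plane at the lower edge of the molecule.
#'
#' @param frame Atom data frame (one frame of a [structure3d()]).
#' @param pose A [camera_pose()].
#' @param style A [style_spec()].
#' @param side Image side in pixels.
#' @param table An [element_table()].
#' @param depth_window Optional fixed `c(z_near, z_far)` for the fog depth
#'   normalization (see [project()]).
#' @return `[side, side, 3]` array of class `render_image`.
#' @export
render_target <- function(frame, pose, style = style_spec("simple_surface"),
                          side = 256, table = element_table(),
                          depth_window = NULL) {
  if (inherits(frame, "structure3d")) frame <- frame$frames[[1L]]
  pc <- camera_space(frame, pose)
  vis <- pc[, 3] > 1e-9
  if (!any(vis)) stop("nothing visible: all atoms are behind the camera")
  pc <- pc[vis, , drop = FALSE]
  el <- frame$element[vis]
  vr <- vdw_radius(el, table)
  z <- pc[, 3]
  if (is.null(depth_window)) {
    zr <- range(z)
    dn <- if (diff(zr) < 1e-12) rep(1, length(z)) else (zr[2] - z) / (zr[2] - zr[1])
  } else {
    dn <- pmin(pmax((depth_window[2] - z) / (depth_window[2] - depth_window[1]), 0), 1)
  }
  f <- pose$fov_scale * side
  n_at <- nrow(pc)

  tbuf <- matrix(Inf, side, side)
  abuf <- matrix(0L, side, side)
  # per-atom z-buffer fill over the atom's silhouette bounding box
  for (a in seq_len(n_at)) {
    cx <- side / 2 + f * pc[a, 1] / z[a]
    cy <- side / 2 + f * pc[a, 2] / z[a]
    pr <- vr[a] * f / z[a] * 1.2 + 2        # padded silhouette bound
    x0 <- max(1L, floor(cx - pr)); x1 <- min(side, ceiling(cx + pr))
    y0 <- max(1L, floor(cy - pr)); y1 <- min(side, ceiling(cy + pr))
    if (x0 > x1 || y0 > y1) next
    u <- ((x0:x1) - 0.5 - side / 2) / f
    v <- ((y0:y1) - 0.5 - side / 2) / f
    U <- matrix(u, length(v), length(u), byrow = TRUE)
    V <- matrix(v, length(v), length(u))
    dd <- U * U + V * V + 1
    db <- U * pc[a, 1] + V * pc[a, 2] + pc[a, 3]
    cc <- sum(pc[a, ]^2) - vr[a]^2
    disc <- db * db - dd * cc
    hit <- disc >= 0
    if (!any(hit)) next
    t0 <- (db - sqrt(pmax(disc, 0))) / dd
    t0[!hit | t0 <= 1e-9] <- Inf
    sub_t <- tbuf[y0:y1, x0:x1]
    closer <- t0 < sub_t
    if (!any(closer)) next
    sub_t[closer] <- t0[closer]
    tbuf[y0:y1, x0:x1] <- sub_t
    sub_a <- abuf[y0:y1, x0:x1]
    sub_a[closer] <- a
    abuf[y0:y1, x0:x1] <- sub_a
  }

  img <- array(1, c(side, side, 3L))
  hit_ix <- which(abuf > 0L)
  l <- style$light
  dirs <- ao_directions()
  if (length(hit_ix)) {
    rows <- ((hit_ix - 1L) %% side) + 1L
    cols <- ((hit_ix - 1L) %/% side) + 1L
    u <- (cols - 0.5 - side / 2) / f
    v <- (rows - 0.5 - side / 2) / f
    tt <- tbuf[hit_ix]
    P <- cbind(u * tt, v * tt, tt)          # hit points, camera space
    A <- abuf[hit_ix]
    N <- (P - pc[A, , drop = FALSE]) / vr[A]
    lam <- pmax(0, N[, 1] * l[1] + N[, 2] * l[2] + N[, 3] * l[3])
    shade <- pmin(1, lam + 0.3)

    # ambient-occlusion proxy, grouped by hit atom
    ao_range <- 5
    occ <- numeric(length(hit_ix))
    for (a in unique(A)) {
      sel <- which(A == a)
      nb <- which(sqrt(colSums((t(pc) - pc[a, ])^2)) < vr + vr[a] + ao_range)
      nb <- setdiff(nb, a)
      if (!length(nb)) next
      Np <- N[sel, , drop = FALSE]
      Pp <- P[sel, , drop = FALSE]
      # per-pixel tangent basis (t1, t2, n)
      ref <- cbind(0, 0, 1)[rep(1, nrow(Np)), , drop = FALSE]
      flat <- abs(Np[, 3]) > 0.9
      ref[flat, ] <- rep(c(1, 0, 0), each = sum(flat))
      t1 <- cbind(Np[, 2] * ref[, 3] - Np[, 3] * ref[, 2],
                  Np[, 3] * ref[, 1] - Np[, 1] * ref[, 3],
                  Np[, 1] * ref[, 2] - Np[, 2] * ref[, 1])
      t1 <- t1 / sqrt(rowSums(t1^2))
      t2 <- cbind(Np[, 2] * t1[, 3] - Np[, 3] * t1[, 2],
                  Np[, 3] * t1[, 1] - Np[, 1] * t1[, 3],
                  Np[, 1] * t1[, 2] - Np[, 2] * t1[, 1])
      blocked <- matrix(FALSE, length(sel), nrow(dirs))
      for (k in seq_len(nrow(dirs))) {
        W <- dirs[k, 1] * t1 + dirs[k, 2] * t2 + dirs[k, 3] * Np
        for (b in nb) {
          Q <- sweep(Pp, 2, pc[b, ])
          bq <- -(Q[, 1] * W[, 1] + Q[, 2] * W[, 2] + Q[, 3] * W[, 3])
          cq <- rowSums(Q^2) - vr[b]^2
          ds <- bq * bq - cq
          ok <- ds >= 0
          tq <- bq - sqrt(pmax(ds, 0))
          blocked[, k] <- blocked[, k] | (ok & tq > 1e-6 & tq < ao_range)
        }
      }
      occ[sel] <- rowMeans(blocked)
    }
    shade <- shade * (1 - style$ao_strength * occ)
    fog <- style$fog_strength * (1 - dn[A])
    base <- t(vapply(el, function(e) style_color(e, style), numeric(3)))
    for (ch in 1:3) {
      colv <- base[A, ch] * shade
      colv <- colv * (1 - fog) + fog        # lerp toward white
      plane <- img[, , ch]
      plane[hit_ix] <- pmin(pmax(colv, 0), 1)
      img[, , ch] <- plane
    }
  }

  if (style$shadow) {
    y_floor <- max(pc[, 2] + vr)
    miss_ix <- which(abuf == 0L)
    if (length(miss_ix)) {
      rows <- ((miss_ix - 1L) %% side) + 1L
      cols <- ((miss_ix - 1L) %/% side) + 1L
      u <- (cols - 0.5 - side / 2) / f
      v <- (rows - 0.5 - side / 2) / f
      on_floor <- v > 1e-9
      tf <- ifelse(on_floor, y_floor / v, Inf)
      keep <- which(on_floor & is.finite(tf))
      if (length(keep)) {
        Q <- cbind(u[keep] * tf[keep], y_floor, tf[keep])
        jit <- rbind(c(0, 0, 0), c(0.08, 0, 0), c(-0.08, 0, 0),
                     c(0, 0, 0.08), c(0, 0, -0.08))
        frac <- numeric(nrow(Q))
        for (j in seq_len(nrow(jit))) {
          w <- l + jit[j, ]; w <- w / sqrt(sum(w^2))
          hitj <- rep(FALSE, nrow(Q))
          for (b in seq_len(n_at)) {
            D <- sweep(Q, 2, pc[b, ])
            bq <- -(D[, 1] * w[1] + D[, 2] * w[2] + D[, 3] * w[3])
            cq <- rowSums(D^2) - vr[b]^2
            ds <- bq * bq - cq
            hitj <- hitj | (ds >= 0 & (bq - sqrt(pmax(ds, 0))) > 1e-6)
          }
          frac <- frac + hitj
        }
        frac <- frac / nrow(jit)
        sh <- 1 - 0.35 * frac
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[miss_ix[keep]] <- sh
          img[, , ch] <- plane
        }
      }
    }
  }
  class(img) <- c("render_image", class(img))
  img
}

#' Level an image so the background is exactly white
#'
#' Finds the background as the region flood-connected to the image corners
#' (tolerance 0.1 in mean intensity), then rescales the whole image by the
#' reciprocal of the maximum background intensity, clamping to `[0, 1]`.
#' Applying it twice gives the same result as applying it once.
#'
#' @param img `[H, W, 3]` image.
#' @return Leveled image of the same shape.
#' @export
level_background <- function(img) {
  g <- gray_mean(img)
  h <- nrow(g); w <- ncol(g)
  mask <- matrix(FALSE, h, w)
  for (pt in list(c(1, 1), c(1, w), c(h, 1), c(h, w))) {
    if (mask[pt[1], pt[2]]) next
    filled <- EBImage::floodFill(g, matrix(c(pt[2], pt[1]), 1), col = 2,
                                 tolerance = 0.1)
    mask <- mask | (filled == 2)
  }
  if (!any(mask)) return(img)
  m <- max(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
  if (m <= 0) return(img)
  out <- pmin(pmax(img / m, 0), 1)
  class(out) <- class(img)
  out
}
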