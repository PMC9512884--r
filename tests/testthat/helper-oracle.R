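# Shared helpers: hand-built projected-atom tables and a brute-force
# per-pixel reference for the sketch encoding.

# A projected-atom data frame built directly (bypassing project()) so pixel
# geometry is fully controlled in tests.
proj_atoms <- function(cx, cy, radius, depth, element = "C",
                       serial = seq_along(cx)) {
  data.frame(cx = cx, cy = cy, pixel_radius = radius, depth_norm = depth,
             z_cam = 1 - depth, element = rep(element, length.out = length(cx)),
             serial = serial, stringsAsFactors = FALSE)
}

# Brute-force nearest-covering-atom resolution: for every pixel center,
# return the index of the covering atom with the largest depth_norm (ties:
# larger serial wins, matching painter order), or 0 for background.
# `shrink` contracts each disc so outline/anti-aliased rims are excluded.
nearest_atom_map <- function(atoms, side, shrink = 0) {
  winner <- matrix(0L, side, side)
  depth <- matrix(-Inf, side, side)
  xs <- seq_len(side) - 0.5
  for (a in seq_len(nrow(atoms))) {
    dx2 <- (xs - atoms$cx[a])^2
    dy2 <- (xs - atoms$cy[a])^2
    r <- atoms$pixel_radius[a] - shrink
    if (r <= 0) next
    cover <- outer(dy2, dx2, "+") <= r^2
    better <- cover & (atoms$depth_norm[a] > depth |
                       (atoms$depth_norm[a] == depth & a > winner))
    winner[better] <- a
    depth[better] <- atoms$depth_norm[a]
  }
  winner
}

# Pixels safely inside exactly one atom's fill region: at least `margin` px
# inside the winner's fill (excluding its outline stroke) and at least
# `margin` px away from every other circle's edge band.
interior_pixels <- function(atoms, side, margin = 2) {
  winner <- nearest_atom_map(atoms, side)
  ok <- winner > 0L
  xs <- seq_len(side) - 0.5
  for (a in seq_len(nrow(atoms))) {
    d <- sqrt(outer((xs - atoms$cy[a])^2, (xs - atoms$cx[a])^2, "+"))
    r <- atoms$pixel_radius[a]
    w <- max(1, r / 12)
    fill_edge <- r - w / 2                  # outline stroke spans [r-w/2, r+w/2]
    ok <- ok & !(winner != a & d <= r + w / 2 + margin & d >= fill_edge - margin)
    ok <- ok & !(winner == a & d > fill_edge - margin)
  }
  which(ok)
}

# Deterministic random scene of n projected atoms inside the image.
random_scene <- function(n, side, seed, elements = c("C", "N", "O", "H", "P")) {
  set.seed(seed)
  proj_atoms(cx = runif(n, side * 0.2, side * 0.8),
             cy = runif(n, side * 0.2, side * 0.8),
             radius = runif(n, side * 0.06, side * 0.14),
             depth = round(runif(n), 3),
             element = sample(elements, n, replace = TRUE))
}
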