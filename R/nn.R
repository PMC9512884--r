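# Minimal convolutional-network engine used by the sketch-to-render
# translator.  Tensors are numeric arrays [H, W, C] (one sample at a time;
# batches are accumulated by looping).  Convolutions are im2col gathers
# followed by BLAS matrix products; the geometry (gather indices) is cached
# per input shape, so the networks are fully convolutional.

conv_geom <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  pr <- rep(seq_len(k), times = k * C)
  pc <- rep(rep(seq_len(k), each = k), times = C)
  pch <- rep(seq_len(C), each = k * k)
  II <- outer(pr, (io - 1L) * stride, "+")
  JJ <- outer(pc, (jo - 1L) * stride, "+")
  idx <- II + (JJ - 1L) * Hp + (pch - 1L) * (Hp * Wp)
  storage.mode(idx) <- "integer"
  idxv <- as.vector(idx)
  # precomputed scatter plan for the backward pass: sort the gather indices
  # once; group sums are then two cumsum-difference passes at run time
  ord <- order(idxv)
  sorted <- idxv[ord]
  ends <- which(sorted != c(sorted[-1L], -1L))
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       idxv = idxv, nrow = k * k * C, ncol = Ho * Wo,
       ord = ord, ends = ends, uidx = sorted[ends])
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

new_conv <- function(Cin, Cout, k, stride, pad) {
  e <- new.env(parent = emptyenv())
  e$Cin <- Cin; e$Cout <- Cout; e$k <- k; e$stride <- stride; e$pad <- pad
  e$W <- matrix(stats::rnorm(Cout * k * k * Cin, sd = 0.02), Cout)
  e$b <- numeric(Cout)
  e$geoms <- list()
  e$kind <- "conv"
  e
}

conv_fwd <- function(e, x) {
  d <- dim(x)
  key <- paste(d, collapse = "x")
  g <- e$geoms[[key]]
  if (is.null(g)) {
    g <- conv_geom(d[1], d[2], d[3], e$k, e$stride, e$pad)
    e$geoms[[key]] <- g
  }
  xp <- pad_array(x, e$pad)
  cols <- xp[g$idxv]
  dim(cols) <- c(g$nrow, g$ncol)
  out <- e$W %*% cols + e$b
  e$last <- list(g = g, cols = cols)
  array(t(out), c(g$Ho, g$Wo, e$Cout))
}

conv_bwd <- function(e, dy) {
  g <- e$last$g
  dim(dy) <- c(g$Ho * g$Wo, e$Cout)
  dmat <- t(dy)
  e$dW <- e$dW + dmat %*% t(e$last$cols)
  e$db <- e$db + rowSums(dmat)
  dcols <- crossprod(e$W, dmat)
  cs <- cumsum(dcols[g$ord])
  sums <- cs[g$ends] - c(0, cs[g$ends[-length(g$ends)]])
  dxp <- numeric(g$Hp * g$Wp * g$C)
  dxp[g$uidx] <- sums
  dim(dxp) <- c(g$Hp, g$Wp, g$C)
  if (e$pad > 0L)
    dxp <- dxp[e$pad + seq_len(g$H), e$pad + seq_len(g$W), , drop = FALSE]
  dxp
}

new_inorm <- function(C) {
  e <- new.env(parent = emptyenv())
  e$C <- C; e$g <- rep(1, C); e$b <- numeric(C)
  e$kind <- "inorm"
  e
}

inorm_fwd <- function(e, x, eps = 1e-5) {
  d <- dim(x)
  if (d[1] * d[2] <= 1L) { e$last <- NULL; return(x) }  # degenerate 1x1 map
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  sd <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, sd, "/")
  y <- sweep(sweep(xhat, 2, e$g, "*"), 2, e$b, "+")
  e$last <- list(xhat = xhat, sd = sd, d = d)
  array(y, d)
}

inorm_bwd <- function(e, dy) {
  if (is.null(e$last)) return(dy)
  d <- e$last$d
  dym <- matrix(dy, d[1] * d[2], d[3])
  xhat <- e$last$xhat
  e$dg <- e$dg + colSums(dym * xhat)
  e$db <- e$db + colSums(dym)
  dxhat <- sweep(dym, 2, e$g, "*")
  mdx <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2, mdx) - sweep(xhat, 2, mdxx, "*"),
              2, e$last$sd, "/")
  array(dx, d)
}

new_act <- function(kind = c("lrelu", "relu", "tanh")) {
  e <- new.env(parent = emptyenv())
  e$kind <- match.arg(kind)
  e
}

act_fwd <- function(e, x) {
  pos <- x > 0
  y <- switch(e$kind,
              lrelu = x * (0.2 + 0.8 * pos),
              relu  = x * pos,
              tanh  = tanh(x))
  e$last <- if (e$kind == "tanh") y else pos
  y
}

act_bwd <- function(e, dy) {
  switch(e$kind,
         lrelu = dy * (0.2 + 0.8 * e$last),
         relu  = dy * e$last,
         tanh  = dy * (1 - e$last^2))
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  s <- dy[seq(1L, d[1], 2L), , , drop = FALSE] +
       dy[seq(2L, d[1], 2L), , , drop = FALSE]
  s[, seq(1L, d[2], 2L), , drop = FALSE] +
    s[, seq(2L, d[2], 2L), , drop = FALSE]
}

# -- parameter bookkeeping ---------------------------------------------------

layer_params <- function(e) {
  switch(e$kind,
         conv  = c("W", "b"),
         inorm = c("g", "b"),
         character(0))
}

zero_grads <- function(layers) {
  for (e in layers) {
    for (p in layer_params(e)) {
      gname <- paste0("d", p)
      e[[gname]] <- e[[p]] * 0
    }
  }
}

adam_step <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (e in layers) {
    for (p in layer_params(e)) {
      g <- e[[paste0("d", p)]]
      st <- e$adam
      if (is.null(st)) st <- e$adam <- new.env(parent = emptyenv())
      mn <- paste0("m_", p); vn <- paste0("v_", p); tn <- paste0("t_", p)
      if (is.null(st[[mn]])) { st[[mn]] <- g * 0; st[[vn]] <- g * 0; st[[tn]] <- 0 }
      t1 <- st[[tn]] <- st[[tn]] + 1
      m <- st[[mn]] <- beta1 * st[[mn]] + (1 - beta1) * g
      v <- st[[vn]] <- beta2 * st[[vn]] + (1 - beta2) * g * g
      # bias-corrected update with the corrections folded into scalars
      c1 <- lr / (1 - beta1^t1)
      c2 <- sqrt(1 - beta2^t1)
      e[[p]] <- e[[p]] - c1 * m / (sqrt(v) / c2 + eps)
    }
  }
}

collect_weights <- function(layers) {
  lapply(layers, function(e) {
    w <- lapply(layer_params(e), function(p) e[[p]])
    names(w) <- layer_params(e)
    w
  })
}

restore_weights <- function(layers, weights) {
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    for (p in names(weights[[i]])) {
      stopifnot(identical(dim(layers[[i]][[p]]), dim(weights[[i]][[p]])),
                length(layers[[i]][[p]]) == length(weights[[i]][[p]]))
      layers[[i]][[p]] <- weights[[i]][[p]]
    }
  }
  invisible(layers)
}

# numerically stable binary cross-entropy with logits; returns loss and
# gradient w.r.t. the logits
bce_logits <- function(z, target) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  grad <- (1 / (1 + exp(-z)) - target) / n
  list(loss = loss, grad = grad)
}
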