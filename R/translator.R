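#' Training configuration for the sketch-to-render translator
#'
#' The training schedule follows the two-phase convention: a constant
#' learning rate for `epochs_const` epochs, then a linear decay to zero
#' over `epochs_decay` further epochs.  The loss is the adversarial
#' objective plus `l1_weight` times the L1 distance between generated and
#' target images.  Normalization is per-image instance normalization.
#'
#' @param epochs_const Epochs at the constant initial learning rate.
#' @param epochs_decay Epochs of linear decay to zero.
#' @param initial_lr Initial Adam learning rate.
#' @param l1_weight Weight of the L1 reconstruction term.
#' @param batch_size Images per optimizer step.
#' @param generator_depth Number of downsampling stages of the U-Net
#'   generator (7 at the 128-pixel reference resolution; input sides must
#'   be divisible by `2^generator_depth`).
#' @param ngf,ndf Base channel widths of generator and discriminator.
#' @param seed Master seed for weight initialization and data order.
#' @param use_gan Include the adversarial term and train the
#'   discriminator; with `FALSE` training reduces to (weighted) L1 only.
#' @param augment Apply per-epoch [scale_and_crop()] augmentation to the
#'   training pairs (same window for sketch and target).
#' @param checkpoint_every,checkpoint_dir Optional periodic checkpoints
#'   written with [save_model()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs_const = 1000L, epochs_decay = 1000L,
                         initial_lr = 2e-4, l1_weight = 100,
                         batch_size = 1L, generator_depth = 7L,
                         ngf = 24L, ndf = 24L, seed = 1L,
                         use_gan = TRUE, augment = FALSE,
                         checkpoint_every = 0L, checkpoint_dir = NULL) {
  stopifnot(epochs_const >= 0, epochs_decay >= 0,
            epochs_const + epochs_decay >= 1,
            initial_lr > 0, l1_weight >= 0, batch_size >= 1,
            generator_depth >= 1)
  structure(list(epochs_const = as.integer(epochs_const),
                 epochs_decay = as.integer(epochs_decay),
                 initial_lr = initial_lr, l1_weight = l1_weight,
                 batch_size = as.integer(batch_size),
                 normalization = "instance",
                 generator_depth = as.integer(generator_depth),
                 ngf = as.integer(ngf), ndf = as.integer(ndf),
                 seed = as.integer(seed), use_gan = isTRUE(use_gan),
                 augment = isTRUE(augment),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' `lr(e) = initial_lr` for `e <= epochs_const`, then
#' `initial_lr * (1 - (e - epochs_const) / epochs_decay)`, reaching exactly
#' zero at the final epoch.
#'
#' @param epoch Epoch number (1-based); may be a vector.
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, cfg) {
  ifelse(epoch <= cfg$epochs_const, cfg$initial_lr,
         cfg$initial_lr *
           pmax(0, 1 - (epoch - cfg$epochs_const) / cfg$epochs_decay))
}

# -- generator: U-Net encoder/decoder with skip connections -----------------
# Encoder blocks are stride-2 k4 convolutions (instance norm from the
# second block on, leaky ReLU).  The decoder uses nearest-neighbour
# upsampling followed by a stride-1 k3 convolution (a resize-convolution,
# which avoids checkerboard artifacts), instance norm and ReLU, with the
# matching encoder activation concatenated after each step; the final
# block maps to 3 channels through tanh.

unet_channels <- function(depth, ngf) pmin(ngf * 2^(seq_len(depth) - 1L), ngf * 8L)

new_generator <- function(depth, ngf, in_ch = 3L, out_ch = 3L) {
  cf <- unet_channels(depth, ngf)
  enc <- vector("list", depth)
  prev <- in_ch
  for (i in seq_len(depth)) {
    enc[[i]] <- list(conv = new_conv(prev, cf[i], 4L, 2L, 1L),
                     norm = if (i > 1L) new_inorm(cf[i]),
                     act = new_act("lrelu"))
    prev <- cf[i]
  }
  dec <- vector("list", depth)
  for (i in seq_len(depth)) {
    cin <- if (i == depth) cf[depth] else 2L * cf[i]
    if (i > 1L) {
      dec[[i]] <- list(conv = new_conv(cin, cf[i - 1L], 3L, 1L, 1L),
                       norm = new_inorm(cf[i - 1L]),
                       act = new_act("relu"))
    } else {
      dec[[i]] <- list(conv = new_conv(cin, out_ch, 3L, 1L, 1L),
                       norm = NULL,
                       act = new_act("tanh"))
    }
  }
  list(depth = depth, cf = cf, enc = enc, dec = dec)
}

gen_fwd <- function(gmod, x) {
  d <- gmod$depth
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    bl <- gmod$enc[[i]]
    x <- conv_fwd(bl$conv, x)
    if (!is.null(bl$norm)) x <- inorm_fwd(bl$norm, x)
    x <- act_fwd(bl$act, x)
    skips[[i]] <- x
  }
  x <- skips[[d]]
  for (i in rev(seq_len(d))) {
    bl <- gmod$dec[[i]]
    y <- conv_fwd(bl$conv, upsample2(x))
    if (!is.null(bl$norm)) y <- inorm_fwd(bl$norm, y)
    y <- act_fwd(bl$act, y)
    x <- if (i > 1L) abind3(y, skips[[i - 1L]]) else y
  }
  x
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

gen_bwd <- function(gmod, dout) {
  d <- gmod$depth
  cf <- gmod$cf
  ds <- vector("list", d)       # gradients w.r.t. encoder activations
  dt <- dout
  for (i in seq_len(d)) {       # decoder blocks, shallow to deep
    bl <- gmod$dec[[i]]
    if (i == 1L) {
      dy <- dt
    } else {
      cy <- cf[i - 1L]          # concat was [y_i (cy ch), skip_{i-1} (cy ch)]
      dy <- dt[, , seq_len(cy), drop = FALSE]
      ds[[i - 1L]] <- dt[, , cy + seq_len(cy), drop = FALSE]
    }
    dy <- act_bwd(bl$act, dy)
    if (!is.null(bl$norm)) dy <- inorm_bwd(bl$norm, dy)
    dt <- upsample2_bwd(conv_bwd(bl$conv, dy))
  }
  ds[[d]] <- dt
  dinput <- NULL
  for (i in rev(seq_len(d))) {  # encoder blocks, deep to shallow
    bl <- gmod$enc[[i]]
    g <- act_bwd(bl$act, ds[[i]])
    if (!is.null(bl$norm)) g <- inorm_bwd(bl$norm, g)
    g <- conv_bwd(bl$conv, g)
    if (i > 1L) ds[[i - 1L]] <- ds[[i - 1L]] + g else dinput <- g
  }
  dinput
}

# -- discriminator: patch classifier on concatenated (sketch, image) --------

new_discriminator <- function(ndf, in_ch = 6L) {
  list(
    list(conv = new_conv(in_ch, ndf, 4L, 2L, 1L), norm = NULL,
         act = new_act("lrelu")),
    list(conv = new_conv(ndf, 2L * ndf, 4L, 2L, 1L),
         norm = new_inorm(2L * ndf), act = new_act("lrelu")),
    list(conv = new_conv(2L * ndf, 4L * ndf, 4L, 2L, 1L),
         norm = new_inorm(4L * ndf), act = new_act("lrelu")),
    list(conv = new_conv(4L * ndf, 8L * ndf, 4L, 1L, 1L),
         norm = new_inorm(8L * ndf), act = new_act("lrelu")),
    list(conv = new_conv(8L * ndf, 1L, 4L, 1L, 1L), norm = NULL, act = NULL)
  )
}

disc_fwd <- function(dmod, x) {
  for (bl in dmod) {
    x <- conv_fwd(bl$conv, x)
    if (!is.null(bl$norm)) x <- inorm_fwd(bl$norm, x)
    if (!is.null(bl$act)) x <- act_fwd(bl$act, x)
  }
  x
}

disc_bwd <- function(dmod, dy) {
  for (bl in rev(dmod)) {
    if (!is.null(bl$act)) dy <- act_bwd(bl$act, dy)
    if (!is.null(bl$norm)) dy <- inorm_bwd(bl$norm, dy)
    dy <- conv_bwd(bl$conv, dy)
  }
  dy
}

disc_layers <- function(dmod) {
  out <- list()
  for (bl in dmod)
    for (e in bl[c("conv", "norm")]) if (!is.null(e)) out <- c(out, list(e))
  out
}

gen_layers <- function(gmod) {
  out <- list()
  for (bl in c(gmod$enc, gmod$dec))
    for (e in bl[c("conv", "norm")]) if (!is.null(e)) out <- c(out, list(e))
  out
}

# -- model object ------------------------------------------------------------

new_translator <- function(cfg) {
  with_seed(cfg$seed, {
    g <- new_generator(cfg$generator_depth, cfg$ngf)
    d <- new_discriminator(cfg$ndf)
    structure(list(generator = g, discriminator = d, config = cfg,
                   version = translator_version()),
              class = "translator_model")
  })
}

translator_version <- function() "protrender-translator-1"

#' @export
print.translator_model <- function(x, ...) {
  cat(sprintf("<translator_model> U-Net depth %d (ngf %d), patch discriminator (ndf %d), instance norm\n",
              x$generator$depth, x$config$ngf, x$config$ndf))
  invisible(x)
}

check_side <- function(side, depth) {
  if (side %% (2^depth) != 0)
    stop(sprintf(
      "image side %d is not divisible by 2^%d = %d (the generator's downsampling factor)",
      side, depth, 2^depth))
}

#' Train the sketch-to-render translator
#'
#' Conditional adversarial training: the generator maps a sketch to a
#' render; the patch discriminator sees the (sketch, image) concatenation
#' and classifies real versus generated.  The generator loss is the
#' adversarial term plus `l1_weight` times the mean absolute error to the
#' target; the discriminator minimizes binary cross-entropy on real/fake.
#' Deterministic under `cfg$seed`.
#'
#' @param pairs List of training pairs, each a list with `sketch` and
#'   `target` images (`[S, S, 3]`, all the same side, divisible by
#'   `2^generator_depth`).
#' @param cfg A [train_config()].
#' @param model Optional existing model to continue training.
#' @param quiet Suppress per-epoch progress messages.
#' @return A `translator_model` with an attached `$log` data frame
#'   (`epoch`, `lr`, `g_gan`, `d_loss`, `l1`), where `l1` is the mean
#'   absolute error on the `[0, 1]` intensity scale.
#' @export
train_translator <- function(pairs, cfg = train_config(), model = NULL,
                             quiet = TRUE) {
  stopifnot(length(pairs) >= 1)
  sides <- c(vapply(pairs, function(p) dim(p$sketch)[1], 0),
             vapply(pairs, function(p) dim(p$target)[1], 0))
  if (length(unique(sides)) != 1L)
    stop("all training pairs must share a single image side; got: ",
         paste(sort(unique(sides)), collapse = ", "))
  check_side(sides[1], cfg$generator_depth)
  if (is.null(model)) model <- new_translator(cfg)
  gl <- gen_layers(model$generator)
  dl <- disc_layers(model$discriminator)
  epochs <- cfg$epochs_const + cfg$epochs_decay
  log <- data.frame(epoch = seq_len(epochs),
                    lr = lr_schedule(seq_len(epochs), cfg),
                    g_gan = 0, d_loss = 0, l1 = 0)
  with_seed(cfg$seed + 7L, {
    for (ep in seq_len(epochs)) {
      lr <- log$lr[ep]
      ord <- sample.int(length(pairs))
      ep_g <- ep_d <- ep_l1 <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        nb <- length(idx)
        xs <- ys <- yh <- vector("list", nb)
        # generator pass: accumulate G gradients for the whole batch
        zero_grads(gl)
        for (j in seq_len(nb)) {
          p <- pairs[[idx[j]]]
          sk <- p$sketch; tg <- p$target
          if (cfg$augment) {
            cs <- sample.int(2^30, 1L)
            sk <- scale_and_crop(sk, seed = cs)
            tg <- scale_and_crop(tg, seed = cs)
          }
          x <- 2 * sk - 1; dim(x) <- dim(sk)[1:3]
          y <- 2 * tg - 1; dim(y) <- dim(tg)[1:3]
          yhat <- gen_fwd(model$generator, x)
          xs[[j]] <- x; ys[[j]] <- y; yh[[j]] <- yhat
          dyhat <- cfg$l1_weight * sign(yhat - y) / length(yhat) / nb
          ep_l1 <- ep_l1 + mean(abs(yhat - y)) / 2
          if (cfg$use_gan) {
            zf <- disc_fwd(model$discriminator, abind3(x, yhat))
            bg <- bce_logits(zf, 1)
            ep_g <- ep_g + bg$loss
            dinp <- disc_bwd(model$discriminator, array(bg$grad / nb, dim(zf)))
            dyhat <- dyhat + dinp[, , 4:6, drop = FALSE]
          }
          gen_bwd(model$generator, dyhat)
        }
        adam_step(gl, lr)
        # discriminator pass (G gradients above used the pre-update D)
        if (cfg$use_gan) {
          zero_grads(dl)
          for (j in seq_len(nb)) {
            zr <- disc_fwd(model$discriminator, abind3(xs[[j]], ys[[j]]))
            br <- bce_logits(zr, 1)
            disc_bwd(model$discriminator, array(0.5 * br$grad / nb, dim(zr)))
            zf <- disc_fwd(model$discriminator, abind3(xs[[j]], yh[[j]]))
            bf <- bce_logits(zf, 0)
            disc_bwd(model$discriminator, array(0.5 * bf$grad / nb, dim(zf)))
            ep_d <- ep_d + 0.5 * (br$loss + bf$loss)
          }
          adam_step(dl, lr)
        }
      }
      n <- length(pairs)
      log$g_gan[ep] <- ep_g / n
      log$d_loss[ep] <- ep_d / n
      log$l1[ep] <- ep_l1 / n
      if (!quiet && (ep %% 10L == 0L || ep == epochs))
        message(sprintf("epoch %d/%d lr %.2e L1 %.4f", ep, epochs, lr,
                        log$l1[ep]))
      if (cfg$checkpoint_every > 0L && !is.null(cfg$checkpoint_dir) &&
          ep %% cfg$checkpoint_every == 0L) {
        dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_model(model, file.path(cfg$checkpoint_dir,
                                    sprintf("checkpoint_%05d.ptr", ep)))
      }
    }
  })
  model$log <- log
  model
}

#' Run inference on a sketch
#'
#' Fully convolutional: any square sketch whose side is divisible by
#' `2^generator_depth` works.  Deterministic for fixed weights.
#'
#' @param model A `translator_model`.
#' @param sketch `[S, S, 3]` sketch image in `[0, 1]`.
#' @return `[S, S, 3]` render image in `[0, 1]`.
#' @export
infer <- function(model, sketch) {
  stopifnot(inherits(model, "translator_model"))
  check_side(dim(sketch)[1], model$generator$depth)
  x <- 2 * sketch - 1
  dim(x) <- dim(sketch)[1:3]
  out <- (gen_fwd(model$generator, x) + 1) / 2
  out <- pmin(pmax(out, 0), 1)
  class(out) <- c("render_image", class(out))
  out
}

#' Mean absolute error of a model on a pair list
#'
#' @param model A `translator_model`.
#' @param pairs List of pairs with `sketch`/`target`.
#' @return Mean per-pixel L1 distance on the `[0, 1]` scale.
#' @export
translator_l1 <- function(model, pairs) {
  mean(vapply(pairs, function(p)
    mean(abs(infer(model, p$sketch) - p$target)), 0))
}

#' Save / load a translator model
#'
#' The file is a serialized archive holding a header (format version,
#' architecture hyper-parameters, training configuration) and the network
#' weights.  Loading reconstructs the architecture from the header and
#' restores the weights; a version-tag mismatch produces a warning and a
#' best-effort load, a corrupt file an error.
#'
#' @param model A `translator_model`.
#' @param path File path.
#' @return `load_model()` returns the restored `translator_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "translator_model"))
  obj <- list(
    header = list(version = model$version,
                  config = unclass(model$config),
                  saved = format(Sys.time(), tz = "UTC")),
    weights = list(generator = collect_weights(gen_layers(model$generator)),
                   discriminator = collect_weights(disc_layers(model$discriminator))),
    log = model$log)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("corrupt or unreadable model file ", sQuote(path), ": ",
         conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$header) || is.null(obj$weights))
    stop("corrupt model file ", sQuote(path), ": missing header or weights")
  if (!identical(obj$header$version, translator_version()))
    warning("model version tag ", sQuote(obj$header$version %||% "<none>"),
            " does not match ", sQuote(translator_version()),
            "; attempting a best-effort load")
  cfg <- do.call(train_config, obj$header$config[names(formals(train_config))[
    names(formals(train_config)) %in% names(obj$header$config)]])
  model <- new_translator(cfg)
  restore_weights(gen_layers(model$generator), obj$weights$generator)
  restore_weights(disc_layers(model$discriminator), obj$weights$discriminator)
  model$log <- obj$log
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
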