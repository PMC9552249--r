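#' Training configuration for the reference segmenter
#'
#' Defaults mirror the full-scale training recipe: 448 px input tiles cut at
#' stride 376, batches of 5, 100 epochs, cosine-annealed learning rate,
#' Dice + 0.5 * BCE loss, 0.5 softmax threshold. `width` is the base channel
#' count of the network (doubled at each depth); the compact default suits
#' CPU-scale experiments — the segmenter is pluggable, so a heavyweight
#' external model can replace it behind the same contract.
#'
#' @param epochs Training epochs. Default 100.
#' @param batch_size Tiles per optimizer step. Default 5.
#' @param input_tile Training tile side in pixels. Default 448.
#' @param train_stride Stride for cropping training tiles. Default 376.
#' @param lr_max,lr_min Cosine-annealing endpoints. Defaults 1e-3, 0.
#' @param loss_weights Named `c(dice = 1, bce = 0.5)`.
#' @param prob_threshold Softmax threshold for mask conversion. Default 0.5.
#' @param width Base channel width of the network. Default 8.
#' @param dice_eps Dice smoothing. Default 1.
#' @param checkpoint_alpha Precision weight of the per-image validation
#'   metric `m(alpha P + (1 - alpha) R)` used for checkpoint selection.
#'   Default 0.5 (the arithmetic precision/recall mean).
#' @param seed Integer seed for initialization and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 100, batch_size = 5, input_tile = 448,
                            train_stride = 376, lr_max = 1e-3, lr_min = 0,
                            loss_weights = c(dice = 1, bce = 0.5),
                            prob_threshold = 0.5, width = 8, dice_eps = 1,
                            checkpoint_alpha = 0.5, seed = 42L) {
  stopifnot(epochs >= 1, batch_size >= 1, input_tile >= 4, train_stride >= 1,
            lr_max > 0, lr_min >= 0, width >= 1,
            prob_threshold > 0, prob_threshold < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 input_tile = as.integer(input_tile),
                 train_stride = as.integer(train_stride),
                 lr_max = lr_max, lr_min = lr_min, loss_weights = loss_weights,
                 prob_threshold = prob_threshold, width = as.integer(width),
                 dice_eps = dice_eps, checkpoint_alpha = checkpoint_alpha,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Crop an annotated image into training tiles
#'
#' Cuts an image/mask pair into square tiles on a regular grid (exact policy:
#' a 1200 px image with 448 px tiles at stride 376 yields nine tiles).
#'
#' @param image RGB array.
#' @param masks Matching [label_masks()].
#' @param tile,stride Grid parameters. Defaults 448 / 376.
#' @return A tibble with columns `row`, `col` and list-columns `image`, `masks`.
#' @export
crop_training_patches <- function(image, masks, tile = 448, stride = 376) {
  grid <- plan_tiles(as_extent(image), tile, stride, "exact")
  out <- tibble::as_tibble(grid[, c("row", "col")])
  out$image <- purrr::map2(grid$row, grid$col, function(r, c) {
    image[(r + 1L):(r + tile), (c + 1L):(c + tile), , drop = FALSE]
  })
  out$masks <- purrr::map2(grid$row, grid$col, crop_masks, masks = masks,
                           h = tile, w = tile)
  out
}

## ---- minimal conv-net machinery (im2col convolutions, Adam) ----

im2col3 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  k <- 0L
  for (du in 0:2) for (dv in 0:2) {
    blk <- xp[(1L + du):(h + du), (1L + dv):(w + dv), , drop = FALSE]
    dim(blk) <- c(h * w, cin)
    cols[, (k * cin + 1L):((k + 1L) * cin)] <- blk
    k <- k + 1L
  }
  cols
}

conv_fwd <- function(x, W, b) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  cols <- im2col3(x)
  y <- sweep(cols %*% W, 2L, b, `+`)
  dim(y) <- c(h, w, length(b))
  list(y = y, cols = cols)
}

conv_bwd <- function(dy, cache_cols, W, cin, hw) {
  h <- hw[1L]; w <- hw[2L]
  cout <- ncol(W)
  dym <- dy; dim(dym) <- c(h * w, cout)
  dW <- crossprod(cache_cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(W)
  dxp <- array(0, c(h + 2L, w + 2L, cin))
  k <- 0L
  for (du in 0:2) for (dv in 0:2) {
    blk <- dcols[, (k * cin + 1L):((k + 1L) * cin)]
    dim(blk) <- c(h, w, cin)
    dxp[(1L + du):(h + du), (1L + dv):(w + dv), ] <-
      dxp[(1L + du):(h + du), (1L + dv):(w + dv), ] + blk
    k <- k + 1L
  }
  list(dx = dxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE], dW = dW, db = db)
}

pool2_fwd <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  (x[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
     x[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
     x[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE] +
     x[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]) / 4
}

pool2_bwd <- function(dy) {
  h2 <- dim(dy)[1L]; w2 <- dim(dy)[2L]
  dy[rep(seq_len(h2), each = 2L), rep(seq_len(w2), each = 2L), , drop = FALSE] / 4
}

up2_fwd <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  x[rep(seq_len(h), each = 2L), rep(seq_len(w), each = 2L), , drop = FALSE]
}

up2_bwd <- function(dy) pool2_fwd(dy) * 4

cat3 <- function(...) {
  xs <- list(...)
  h <- dim(xs[[1L]])[1L]; w <- dim(xs[[1L]])[2L]
  array(unlist(xs, use.names = FALSE), c(h, w, sum(vapply(xs, function(x) dim(x)[3L], 0))))
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax3 <- function(z) {
  m <- pmax(z[, , 1L], z[, , 2L], z[, , 3L])
  e1 <- exp(z[, , 1L] - m); e2 <- exp(z[, , 2L] - m); e3 <- exp(z[, , 3L] - m)
  s <- e1 + e2 + e3
  array(c(e1 / s, e2 / s, e3 / s), dim(z))
}

# He-initialized parameters for the nested encoder-decoder.
init_params <- function(width, seed) {
  mk <- function(cin, cout, k = 3L) {
    fan <- k * k * cin
    list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / fan)),
                    k * k * cin, cout),
         b = rep(0, cout), cin = cin)
  }
  with_seed(seed, {
    w <- width
    list(b00 = mk(3L, w), b10 = mk(w, 2L * w), b20 = mk(2L * w, 4L * w),
         b01 = mk(3L * w, w), b11 = mk(6L * w, 2L * w), b02 = mk(4L * w, w),
         h1 = mk(w, 3L, 1L), h2 = mk(w, 3L, 1L))
  })
}

conv1_fwd <- function(x, W, b) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; cin <- dim(x)[3L]
  xm <- x; dim(xm) <- c(h * w, cin)
  y <- sweep(xm %*% W, 2L, b, `+`)
  dim(y) <- c(h, w, ncol(W))
  list(y = y, xm = xm)
}

conv1_bwd <- function(dy, xm, W, hw) {
  dym <- dy; dim(dym) <- c(hw[1L] * hw[2L], ncol(W))
  dx <- dym %*% t(W)
  dim(dx) <- c(hw[1L], hw[2L], nrow(W))
  list(dx = dx, dW = crossprod(xm, dym), db = colSums(dym))
}

# Forward pass; returns both deep-supervision softmax heads and caches.
unetpp_forward <- function(x, par) {
  c00 <- conv_fwd(x, par$b00$W, par$b00$b); x00 <- relu(c00$y)
  p0 <- pool2_fwd(x00)
  c10 <- conv_fwd(p0, par$b10$W, par$b10$b); x10 <- relu(c10$y)
  p1 <- pool2_fwd(x10)
  c20 <- conv_fwd(p1, par$b20$W, par$b20$b); x20 <- relu(c20$y)
  in01 <- cat3(x00, up2_fwd(x10))
  c01 <- conv_fwd(in01, par$b01$W, par$b01$b); x01 <- relu(c01$y)
  in11 <- cat3(x10, up2_fwd(x20))
  c11 <- conv_fwd(in11, par$b11$W, par$b11$b); x11 <- relu(c11$y)
  in02 <- cat3(x00, x01, up2_fwd(x11))
  c02 <- conv_fwd(in02, par$b02$W, par$b02$b); x02 <- relu(c02$y)
  h1 <- conv1_fwd(x01, par$h1$W, par$h1$b)
  h2 <- conv1_fwd(x02, par$h2$W, par$h2$b)
  list(p1 = softmax3(h1$y), p2 = softmax3(h2$y),
       cache = list(c00 = c00, x00 = x00, c10 = c10, x10 = x10, c20 = c20,
                    x20 = x20, c01 = c01, x01 = x01, c11 = c11, x11 = x11,
                    c02 = c02, x02 = x02, h1 = h1, h2 = h2, x = x))
}

# Gradient of the combined Dice + 0.5*BCE loss w.r.t. head logits, through
# the 3-way softmax. g_int / g_not are binary matrices.
loss_and_grad_head <- function(p, g_int, g_not, weights, eps) {
  n <- length(g_int)
  dLdp <- array(0, dim(p))
  loss <- 0
  for (k in 1:2) {
    pc <- p[, , k + 1L]
    g <- if (k == 1L) g_int else g_not
    spg <- sum(pc * g); sp <- sum(pc); sg <- sum(g)
    den <- sp + sg + eps
    loss <- loss + weights[["dice"]] * (1 - (2 * spg + eps) / den) / 2
    ddice <- -(2 * g * den - (2 * spg + eps)) / den^2
    pcc <- pmin(pmax(pc, 1e-7), 1 - 1e-7)
    loss <- loss + weights[["bce"]] * (-mean(g * log(pcc) + (1 - g) * log(1 - pcc))) / 2
    dbce <- -(g / pcc - (1 - g) / (1 - pcc)) / n
    dLdp[, , k + 1L] <- weights[["dice"]] * ddice / 2 + weights[["bce"]] * dbce / 2
  }
  dot <- dLdp[, , 1L] * p[, , 1L] + dLdp[, , 2L] * p[, , 2L] + dLdp[, , 3L] * p[, , 3L]
  dz <- p * (dLdp - array(rep(dot, 3L), dim(p)))
  list(loss = loss, dz = dz)
}

unetpp_backward <- function(fw, g_int, g_not, par, weights, eps) {
  ch <- fw$cache
  hw0 <- dim(ch$x00)[1:2]; hw1 <- dim(ch$x10)[1:2]; hw2 <- dim(ch$x20)[1:2]
  l1 <- loss_and_grad_head(fw$p1, g_int, g_not, weights, eps)
  l2 <- loss_and_grad_head(fw$p2, g_int, g_not, weights, eps)
  # deep supervision: average the two heads
  g1 <- conv1_bwd(l1$dz / 2, ch$h1$xm, par$h1$W, hw0)
  g2 <- conv1_bwd(l2$dz / 2, ch$h2$xm, par$h2$W, hw0)
  grads <- list(h1 = list(W = g1$dW, b = g1$db), h2 = list(W = g2$dW, b = g2$db))

  d02 <- g2$dx * (ch$c02$y > 0)
  b02 <- conv_bwd(d02, ch$c02$cols, par$b02$W, 4L * dim(ch$x01)[3L] / 1L, hw0)
  grads$b02 <- list(W = b02$dW, b = b02$db)
  wch <- dim(ch$x01)[3L]   # base width
  dx00 <- b02$dx[, , 1:wch, drop = FALSE]
  dx01 <- b02$dx[, , (wch + 1L):(2L * wch), drop = FALSE]
  dx11up <- b02$dx[, , (2L * wch + 1L):(4L * wch), drop = FALSE]

  dx01 <- dx01 + g1$dx
  d01 <- dx01 * (ch$c01$y > 0)
  b01 <- conv_bwd(d01, ch$c01$cols, par$b01$W, 3L * wch, hw0)
  grads$b01 <- list(W = b01$dW, b = b01$db)
  dx00 <- dx00 + b01$dx[, , 1:wch, drop = FALSE]
  dx10 <- up2_bwd(b01$dx[, , (wch + 1L):(3L * wch), drop = FALSE])

  dx11 <- up2_bwd(dx11up)
  d11 <- dx11 * (ch$c11$y > 0)
  b11 <- conv_bwd(d11, ch$c11$cols, par$b11$W, 6L * wch, hw1)
  grads$b11 <- list(W = b11$dW, b = b11$db)
  dx10 <- dx10 + b11$dx[, , 1:(2L * wch), drop = FALSE]
  dx20 <- up2_bwd(b11$dx[, , (2L * wch + 1L):(6L * wch), drop = FALSE])

  d20 <- dx20 * (ch$c20$y > 0)
  b20 <- conv_bwd(d20, ch$c20$cols, par$b20$W, 2L * wch, hw2)
  grads$b20 <- list(W = b20$dW, b = b20$db)
  dx10 <- dx10 + pool2_bwd(b20$dx)

  d10 <- dx10 * (ch$c10$y > 0)
  b10 <- conv_bwd(d10, ch$c10$cols, par$b10$W, wch, hw1)
  grads$b10 <- list(W = b10$dW, b = b10$db)
  dx00 <- dx00 + pool2_bwd(b10$dx)

  d00 <- dx00 * (ch$c00$y > 0)
  b00 <- conv_bwd(d00, ch$c00$cols, par$b00$W, 3L, hw0)
  grads$b00 <- list(W = b00$dW, b = b00$db)

  list(loss = (l1$loss + l2$loss) / 2, grads = grads)
}

adam_init <- function(par) {
  lapply(par, function(p) list(mW = p$W * 0, vW = p$W * 0,
                               mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(par, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      adam_eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    s <- state[[nm]]; g <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    par[[nm]]$W <- par[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + adam_eps)
    par[[nm]]$b <- par[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + adam_eps)
    state[[nm]] <- s
  }
  list(par = par, state = state)
}

# Pad an RGB tile (edge replication) so both sides are multiples of 4.
pad_to_mult4 <- function(x) {
  h <- dim(x)[1L]; w <- dim(x)[2L]
  ph <- (4L - h %% 4L) %% 4L; pw <- (4L - w %% 4L) %% 4L
  if (ph == 0L && pw == 0L) return(list(x = x, h = h, w = w))
  xp <- x[c(seq_len(h), rep(h, ph)), c(seq_len(w), rep(w, pw)), , drop = FALSE]
  list(x = xp, h = h, w = w)
}

unetpp_predict <- function(par, tile) {
  pd <- pad_to_mult4(tile)
  fw <- unetpp_forward(pd$x, par)
  p <- (fw$p1 + fw$p2) / 2   # average the supervision heads at inference
  p <- p[seq_len(pd$h), seq_len(pd$w), , drop = FALSE]
  dimnames(p) <- list(NULL, NULL, prob_classes())
  prob_map(p)
}

#' Train the reference nested encoder-decoder segmenter
#'
#' Trains a compact UNet++-style network — a three-level encoder with
#' re-designed dense skip pathways and two deep-supervision heads whose
#' softmax outputs are averaged at inference — to label each pixel
#' background, intact or not-intact. The loss is the combined
#' Dice + 0.5 * BCE of [combined_loss()], optimized with Adam under a
#' [cosine_annealing_lr()] schedule, gradients accumulated over
#' `batch_size` tiles per step. When a validation set is supplied, the
#' checkpoint with the best per-image `m(alpha P + (1 - alpha) R)` score
#' (default alpha = 0.5) is kept; otherwise the final epoch is returned.
#'
#' @param dataset Training tiles: a tibble with list-columns `image` and
#'   `masks` (e.g. from [generate_patch_dataset()] or
#'   [crop_training_patches()]).
#' @param config A [training_config()].
#' @param val Optional validation tiles in the same format.
#' @return An [new_segmenter()] whose `meta` holds the parameters, config,
#'   per-epoch `history` tibble (`epoch`, `lr`, `train_loss`, `val_metric`)
#'   and `best_epoch`.
#' @export
train_segmenter <- function(dataset, config = training_config(), val = NULL) {
  stopifnot(inherits(config, "training_config"))
  tiles <- dataset$image; masks <- dataset$masks
  if (is.null(tiles) || !length(tiles)) stop("empty training dataset", call. = FALSE)
  dims <- unique(purrr::map(tiles, dim))
  if (length(dims) != 1L) stop("training tiles must share one size", call. = FALSE)
  par <- init_params(config$width, config$seed)
  state <- adam_init(par)
  step <- 0L
  history <- vector("list", config$epochs)
  best_par <- par; best_metric <- -Inf; best_epoch <- NA_integer_
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_annealing_lr(epoch - 1L, config$epochs, config$lr_max, config$lr_min)
      ord <- sample(seq_along(tiles))
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- 0
        for (i in idx) {
          fw <- unetpp_forward(tiles[[i]], par)
          bw <- unetpp_backward(fw, masks[[i]]$intact * 1, masks[[i]]$not_intact * 1,
                                par, config$loss_weights, config$dice_eps)
          bl <- bl + bw$loss
          if (is.null(acc)) acc <- bw$grads
          else for (nm in names(acc)) {
            acc[[nm]]$W <- acc[[nm]]$W + bw$grads[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + bw$grads[[nm]]$b
          }
        }
        for (nm in names(acc)) {
          acc[[nm]]$W <- acc[[nm]]$W / length(idx)
          acc[[nm]]$b <- acc[[nm]]$b / length(idx)
        }
        step <- step + 1L
        upd <- adam_step(par, acc, state, lr, step)
        par <- upd$par; state <- upd$state
        losses <- c(losses, bl / length(idx))
      }
      val_metric <- NA_real_
      if (!is.null(val)) {
        counts <- purrr::map_dfr(seq_len(nrow(val)), function(i) {
          pred <- threshold_probabilities(unetpp_predict(par, val$image[[i]]),
                                          config$prob_threshold)
          confusion_counts(pred, val$masks[[i]], image_id = as.character(i))
        })
        val_metric <- weighted_pr(counts, config$checkpoint_alpha)
        if (val_metric > best_metric) {
          best_metric <- val_metric; best_par <- par; best_epoch <- epoch
        }
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                         train_loss = mean(losses),
                                         val_metric = val_metric)
    }
  })
  final_par <- if (is.null(val)) par else best_par
  meta <- list(params = final_par, config = config,
               history = dplyr::bind_rows(history),
               best_epoch = if (is.null(val)) config$epochs else best_epoch)
  predict_fn <- function(tile, offset, size) {
    if (is.null(tile)) stop("model segmenter needs pixel data", call. = FALSE)
    unetpp_predict(final_par, tile)
  }
  new_segmenter(predict_fn, name = sprintf("unetpp (width %d)", config$width),
                meta = meta)
}

#' Save or load a trained segmenter
#'
#' Checkpoints serialize the parameters with the training config embedded.
#'
#' @param segmenter A model segmenter from [train_segmenter()].
#' @param path Checkpoint file path (RDS).
#' @export
save_segmenter <- function(segmenter, path) {
  stopifnot(inherits(segmenter, "eos_segmenter"), !is.null(segmenter$meta$params))
  saveRDS(list(params = segmenter$meta$params, config = segmenter$meta$config,
               history = segmenter$meta$history, best_epoch = segmenter$meta$best_epoch),
          path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  ck <- readRDS(path)
  predict_fn <- function(tile, offset, size) {
    if (is.null(tile)) stop("model segmenter needs pixel data", call. = FALSE)
    unetpp_predict(ck$params, tile)
  }
  new_segmenter(predict_fn, name = sprintf("unetpp (width %d)", ck$config$width),
                meta = ck)
}
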