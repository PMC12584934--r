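# 3D U-Net air-cavity segmenter: a three-level encoder-decoder. Each
# block is (conv3 k3 -> batch norm -> ReLU) x 2; 2x2x2 max pooling
# downsamples, transposed convolutions (kernel 2, stride 2) upsample,
# with concatenative skip connections; a final 1x1x1 convolution with a
# sigmoid yields a per-voxel cavity probability. Fully convolutional:
# the parameter count is independent of the input shape, which only
# needs to be divisible by 4 (two poolings).
#
# Feature maps are arrays (D, H, W, C); convolutions run as im2col +
# GEMM through the C++ kernels in src/conv3d.cpp.

#' U-Net configuration
#'
#' @param encoder_filters two encoder block widths (reference: 32, 64).
#' @param bottleneck_filters bottleneck width (reference: 128).
#' @param in_channels input channels (1 for MRI).
#' @param out_bias_init initial output-layer bias, the logit of the
#'   expected cavity fraction. Cavities occupy about 1% of a cuboid, so
#'   starting near the class-prior logit (default -4) avoids spending
#'   many updates just drifting the bias under the extreme imbalance.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(encoder_filters = c(32, 64),
                        bottleneck_filters = 128, in_channels = 1,
                        out_bias_init = -4) {
  structure(list(encoder_filters = as.integer(encoder_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 in_channels = as.integer(in_channels),
                 conv_kernel = 3L, up_kernel = 2L,
                 out_bias_init = out_bias_init),
            class = "unet_config")
}

# conv blocks carry no bias: the following batch norm absorbs it
conv_init <- function(cin, cout, k = 3) {
  fan <- cin * k^3
  list(W = uniform_init(c(k^3 * cin, cout), fan))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rm = rep(0, c), rv = rep(1, c))
}

init_unet_params <- function(cfg) {
  f1 <- cfg$encoder_filters[1]
  f2 <- cfg$encoder_filters[2]
  fb <- cfg$bottleneck_filters
  ci <- cfg$in_channels
  p <- list()
  blocks <- list(enc1a = c(ci, f1), enc1b = c(f1, f1),
                 enc2a = c(f1, f2), enc2b = c(f2, f2),
                 bota = c(f2, fb), botb = c(fb, fb),
                 dec1a = c(f2 + f2, f2), dec1b = c(f2, f2),
                 dec2a = c(f1 + f1, f1), dec2b = c(f1, f1))
  for (nm in names(blocks)) {
    cc <- blocks[[nm]]
    cv <- conv_init(cc[1], cc[2])
    bn <- bn_init(cc[2])
    p[[paste0(nm, "_W")]] <- cv$W
    p[[paste0(nm, "_gamma")]] <- bn$gamma
    p[[paste0(nm, "_beta")]] <- bn$beta
    attr(p, "running")[[nm]] <- list(rm = bn$rm, rv = bn$rv)
  }
  # transposed convs: weight (Cin, Cout*8), block offsets od,oh,ow fastest
  p$up1_W <- uniform_init(c(fb, f2 * 8), fb * 8)
  p$up1_b <- rep(0, f2)
  p$up2_W <- uniform_init(c(f2, f1 * 8), f2 * 8)
  p$up2_b <- rep(0, f1)
  p$out_W <- uniform_init(c(f1, 1), f1)
  p$out_b <- cfg$out_bias_init %||% 0
  p
}

as_mat4 <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

# conv3 + BN + ReLU over a batch (list of (D,H,W,Cin) arrays).
# BN statistics are taken over batch x spatial in training mode; running
# stats (kept outside the optimized parameter list) are used in eval.
conv_bn_relu_forward <- function(params, running, nm, xs, train,
                                 momentum = 0.1, eps = 1e-5) {
  W <- params[[paste0(nm, "_W")]]
  gamma <- params[[paste0(nm, "_gamma")]]
  beta <- params[[paste0(nm, "_beta")]]
  B <- length(xs)
  d <- dim(xs[[1]])
  cout <- ncol(W)
  zs <- vector("list", B)
  cols_cache <- if (train) vector("list", B)
  for (i in seq_len(B)) {
    cols <- cpp_im2col3(as.numeric(xs[[i]]), d, 3L, 1L)
    zs[[i]] <- cols %*% W               # (Nvox, Cout)
    if (train) cols_cache[[i]] <- cols
  }
  if (train) {
    n <- B * nrow(zs[[1]])
    mom <- Reduce(`+`, lapply(zs, cpp_col_moments))
    mu <- mom[1, ] / n
    varc <- pmax(mom[2, ] / n - mu^2, 0)
    running[[nm]]$rm <- (1 - momentum) * running[[nm]]$rm + momentum * mu
    running[[nm]]$rv <- (1 - momentum) * running[[nm]]$rv + momentum * varc
  } else {
    mu <- running[[nm]]$rm
    varc <- running[[nm]]$rv
  }
  istd <- 1 / sqrt(varc + eps)
  fused <- lapply(zs, function(z) cpp_bn_relu(z, mu, istd, gamma, beta))
  ys <- lapply(fused, function(o) array(o$y, c(d[1:3], cout)))
  xhat <- lapply(fused, `[[`, "xhat")
  list(ys = ys, running = running,
       cache = list(xs = xs, cols = if (train) cols_cache,
                    xhat = xhat, istd = istd, d = d, nm = nm,
                    cout = cout))
}

conv_bn_relu_backward <- function(params, cache, dys, grads) {
  nm <- cache$nm
  W <- params[[paste0(nm, "_W")]]
  gamma <- params[[paste0(nm, "_gamma")]]
  B <- length(dys)
  d <- cache$d
  n <- B * prod(d[1:3])
  # back through ReLU (y > 0 iff gamma*xhat+beta > 0; recompute), with
  # the per-channel reductions needed by the BN backward
  beta <- params[[paste0(nm, "_beta")]]
  dy_act <- vector("list", B)
  dgamma <- 0
  dbeta <- 0
  for (i in seq_len(B)) {
    mr <- cpp_relu_mask_reduce(as_mat4(dys[[i]]), cache$xhat[[i]],
                               gamma, beta)
    dy_act[[i]] <- mr$dy
    dgamma <- dgamma + mr$sum_dyxh
    dbeta <- dbeta + mr$sum_dy
  }
  mean_dy <- dbeta / n
  mean_dyxh <- dgamma / n
  dW <- array(0, dim(W))
  dxs <- vector("list", B)
  for (i in seq_len(B)) {
    dz <- cpp_bn_backward(dy_act[[i]], cache$xhat[[i]], gamma,
                          cache$istd, mean_dy, mean_dyxh)
    cols <- if (!is.null(cache$cols)) cache$cols[[i]] else
      cpp_im2col3(as.numeric(cache$xs[[i]]), dim(cache$xs[[i]]), 3L, 1L)
    dW <- dW + crossprod(cols, dz)
    dcols <- tcrossprod(dz, W)
    dxs[[i]] <- array(cpp_col2im3(dcols, dim(cache$xs[[i]]), 3L, 1L),
                      dim(cache$xs[[i]]))
  }
  grads[[paste0(nm, "_W")]] <- dW
  grads[[paste0(nm, "_gamma")]] <- dgamma
  grads[[paste0(nm, "_beta")]] <- dbeta
  list(dxs = dxs, grads = grads)
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

#' Forward pass of the air-cavity U-Net
#'
#' @param params parameter list (see [init_unet_params()] via
#'   [train_unet_ac()]).
#' @param running running batch-norm statistics.
#' @param xs list of input arrays `(D, H, W, C)`; spatial dims must be
#'   divisible by 4.
#' @param cfg a [unet_config()].
#' @param train training mode (batch statistics) or eval (running).
#' @return List with `p` (list of probability arrays `(D, H, W)`),
#'   `logits`, updated `running`, and `cache` when `train`.
#' @export
unet_ac_forward <- function(params, running, xs, cfg, train = FALSE) {
  d <- dim(xs[[1]])
  if (any(d[1:3] %% 4 != 0))
    stop("shape error: U-Net input dims must be divisible by 4, got ",
         paste(d[1:3], collapse = "x"))
  B <- length(xs)
  e1 <- conv_bn_relu_forward(params, running, "enc1a", xs, train)
  running <- e1$running
  e1b <- conv_bn_relu_forward(params, running, "enc1b", e1$ys, train)
  running <- e1b$running
  p1 <- lapply(e1b$ys, function(y) cpp_maxpool3(as.numeric(y), dim(y)))
  x2 <- lapply(seq_len(B), function(i)
    array(p1[[i]]$values, c(dim(e1b$ys[[i]])[1:3] / 2,
                            dim(e1b$ys[[i]])[4])))
  e2 <- conv_bn_relu_forward(params, running, "enc2a", x2, train)
  running <- e2$running
  e2b <- conv_bn_relu_forward(params, running, "enc2b", e2$ys, train)
  running <- e2b$running
  p2 <- lapply(e2b$ys, function(y) cpp_maxpool3(as.numeric(y), dim(y)))
  x3 <- lapply(seq_len(B), function(i)
    array(p2[[i]]$values, c(dim(e2b$ys[[i]])[1:3] / 2,
                            dim(e2b$ys[[i]])[4])))
  bo <- conv_bn_relu_forward(params, running, "bota", x3, train)
  running <- bo$running
  bob <- conv_bn_relu_forward(params, running, "botb", bo$ys, train)
  running <- bob$running
  # up 1: bottleneck -> level 2, concat skip
  u1 <- lapply(bob$ys, function(y) {
    yc <- as_mat4(y) %*% params$up1_W
    yc <- sweep(yc, 2, rep(params$up1_b, each = 8), "+")
    dy <- dim(y)
    array(cpp_upsample2_scatter(yc, dy[1:3], length(params$up1_b)),
          c(dy[1:3] * 2, length(params$up1_b)))
  })
  c1 <- Map(concat_channels, u1, e2b$ys)
  d1 <- conv_bn_relu_forward(params, running, "dec1a", c1, train)
  running <- d1$running
  d1b <- conv_bn_relu_forward(params, running, "dec1b", d1$ys, train)
  running <- d1b$running
  u2 <- lapply(d1b$ys, function(y) {
    yc <- as_mat4(y) %*% params$up2_W
    yc <- sweep(yc, 2, rep(params$up2_b, each = 8), "+")
    dy <- dim(y)
    array(cpp_upsample2_scatter(yc, dy[1:3], length(params$up2_b)),
          c(dy[1:3] * 2, length(params$up2_b)))
  })
  c2 <- Map(concat_channels, u2, e1b$ys)
  d2 <- conv_bn_relu_forward(params, running, "dec2a", c2, train)
  running <- d2$running
  d2b <- conv_bn_relu_forward(params, running, "dec2b", d2$ys, train)
  running <- d2b$running
  logits <- lapply(d2b$ys, function(y)
    array(as_mat4(y) %*% params$out_W + params$out_b, dim(y)[1:3]))
  p <- lapply(logits, function(l) 1 / (1 + exp(-l)))
  out <- list(p = p, logits = logits, running = running)
  if (train)
    out$cache <- list(e1 = e1$cache, e1b = e1b$cache, p1 = p1,
                      e2 = e2$cache, e2b = e2b$cache, p2 = p2,
                      bo = bo$cache, bob = bob$cache, bob_ys = bob$ys,
                      c1 = c1, d1 = d1$cache, d1b = d1b$cache,
                      d1b_ys = d1b$ys, c2 = c2, d2 = d2$cache,
                      d2b = d2b$cache, d2b_ys = d2b$ys, dims = d)
  out
}

# Backward from dlogits (list of (D,H,W) arrays); returns grads.
unet_ac_backward <- function(params, cfg, cache, dlogits) {
  B <- length(dlogits)
  grads <- list()
  f1 <- cfg$encoder_filters[1]
  f2 <- cfg$encoder_filters[2]
  dW_out <- array(0, dim(params$out_W))
  db_out <- 0
  d_d2b <- vector("list", B)
  for (i in seq_len(B)) {
    dl <- matrix(as.numeric(dlogits[[i]]), ncol = 1)
    ymat <- as_mat4(cache$d2b_ys[[i]])
    dW_out <- dW_out + crossprod(ymat, dl)
    db_out <- db_out + sum(dl)
    d_d2b[[i]] <- array(dl %*% t(params$out_W),
                        dim(cache$d2b_ys[[i]]))
  }
  grads$out_W <- dW_out
  grads$out_b <- db_out
  bk <- conv_bn_relu_backward(params, cache$d2b, d_d2b, grads)
  grads <- bk$grads
  bk <- conv_bn_relu_backward(params, cache$d2, bk$dxs, grads)
  grads <- bk$grads
  # split concat: first f1 channels -> up2, rest -> skip e1b
  d_u2 <- lapply(bk$dxs, function(dx) {
    d <- dim(dx)
    dx[, , , seq_len(f1), drop = FALSE]
  })
  d_e1b_skip <- lapply(bk$dxs, function(dx) {
    d <- dim(dx)
    dx[, , , f1 + seq_len(f1), drop = FALSE]
  })
  dW_up2 <- array(0, dim(params$up2_W))
  db_up2 <- rep(0, length(params$up2_b))
  d_d1b <- vector("list", B)
  for (i in seq_len(B)) {
    din <- dim(cache$d1b_ys[[i]])
    dyc <- cpp_upsample2_gather(as.numeric(d_u2[[i]]), din[1:3], f1)
    xmat <- as_mat4(cache$d1b_ys[[i]])
    dW_up2 <- dW_up2 + crossprod(xmat, dyc)
    db_up2 <- db_up2 + colSums(matrix(colSums(dyc), nrow = 8))
    d_d1b[[i]] <- array(tcrossprod(dyc, params$up2_W), din)
  }
  grads$up2_W <- dW_up2
  grads$up2_b <- db_up2
  bk <- conv_bn_relu_backward(params, cache$d1b, d_d1b, grads)
  grads <- bk$grads
  bk <- conv_bn_relu_backward(params, cache$d1, bk$dxs, grads)
  grads <- bk$grads
  d_u1 <- lapply(bk$dxs, function(dx) dx[, , , seq_len(f2), drop = FALSE])
  d_e2b_skip <- lapply(bk$dxs, function(dx)
    dx[, , , f2 + seq_len(f2), drop = FALSE])
  dW_up1 <- array(0, dim(params$up1_W))
  db_up1 <- rep(0, length(params$up1_b))
  d_bob <- vector("list", B)
  for (i in seq_len(B)) {
    din <- dim(cache$bob_ys[[i]])
    dyc <- cpp_upsample2_gather(as.numeric(d_u1[[i]]), din[1:3], f2)
    xmat <- as_mat4(cache$bob_ys[[i]])
    dW_up1 <- dW_up1 + crossprod(xmat, dyc)
    db_up1 <- db_up1 + colSums(matrix(colSums(dyc), nrow = 8))
    d_bob[[i]] <- array(tcrossprod(dyc, params$up1_W), din)
  }
  grads$up1_W <- dW_up1
  grads$up1_b <- db_up1
  bk <- conv_bn_relu_backward(params, cache$bob, d_bob, grads)
  grads <- bk$grads
  bk <- conv_bn_relu_backward(params, cache$bo, bk$dxs, grads)
  grads <- bk$grads
  # back through pool 2
  d_e2b <- vector("list", B)
  for (i in seq_len(B)) {
    xin_dim <- c(dim(bk$dxs[[i]])[1:3] * 2, dim(bk$dxs[[i]])[4])
    d_e2b[[i]] <- array(
      cpp_maxpool3_backward(as.numeric(bk$dxs[[i]]),
                            cache$p2[[i]]$argmax, prod(xin_dim)),
      xin_dim) + d_e2b_skip[[i]]
  }
  bk <- conv_bn_relu_backward(params, cache$e2b, d_e2b, grads)
  grads <- bk$grads
  bk <- conv_bn_relu_backward(params, cache$e2, bk$dxs, grads)
  grads <- bk$grads
  d_e1b <- vector("list", B)
  for (i in seq_len(B)) {
    xin_dim <- c(dim(bk$dxs[[i]])[1:3] * 2, dim(bk$dxs[[i]])[4])
    d_e1b[[i]] <- array(
      cpp_maxpool3_backward(as.numeric(bk$dxs[[i]]),
                            cache$p1[[i]]$argmax, prod(xin_dim)),
      xin_dim) + d_e1b_skip[[i]]
  }
  bk <- conv_bn_relu_backward(params, cache$e1b, d_e1b, grads)
  grads <- bk$grads
  bk <- conv_bn_relu_backward(params, cache$e1, bk$dxs, grads)
  bk$grads
}

bce_loss <- function(p_list, a_list, eps = 1e-7) {
  tot <- 0
  n <- 0
  for (i in seq_along(p_list)) {
    p <- pmin(pmax(p_list[[i]], eps), 1 - eps)
    a <- a_list[[i]]
    tot <- tot - sum(a * log(p) + (1 - a) * log(1 - p))
    n <- n + length(p)
  }
  tot / n
}

#' Train the U-Net cavity segmenter
#'
#' Binary cross-entropy on MRI -> cavity-mask cuboids; Adam; the
#' checkpoint with the lowest validation loss is returned.
#'
#' @inheritParams train_dose_lstm
#' @param cfg a [unet_config()].
#' @param crop_depth optional depth (z) crop size for training batches;
#'   random depth windows are drawn per sample (the network is fully
#'   convolutional, so inference still runs on full cuboids).
#'   Validation uses a central crop of the same depth.
#' @param val_max cap on the number of validation samples scored per
#'   epoch (first `val_max` samples, deterministic).
#' @return List with `params`, `running` (batch-norm statistics),
#'   `cfg`, `history`, `best_epoch`.
#' @export
train_unet_ac <- function(train_samples, val_samples,
                          cfg = unet_config(),
                          schedule = train_schedule(),
                          crop_depth = NULL, val_max = Inf,
                          verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training dataset")
  nz <- dim(train_samples[[1]]$mri)[1]
  if (!is.null(crop_depth) && crop_depth > nz) crop_depth <- NULL
  val_samples <- val_samples[seq_len(min(length(val_samples), val_max))]
  with_seed(schedule$seed, {
    params <- init_unet_params(cfg)
    running <- attr(params, "running")
    attr(params, "running") <- NULL
    opt <- adam_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(loss = Inf, params = params, running = running,
                 epoch = 0)
    get_x <- function(s, z0 = NULL) {
      m <- if (is.null(z0)) s$mri else
        s$mri[z0:(z0 + crop_depth - 1), , , drop = FALSE]
      array(m, c(dim(m), 1))
    }
    get_a <- function(s, z0 = NULL) {
      if (is.null(z0)) s$ac else
        s$ac[z0:(z0 + crop_depth - 1), , , drop = FALSE]
    }
    val_z0 <- if (is.null(crop_depth)) NULL else
      (nz - crop_depth) %/% 2 + 1
    for (ep in seq_len(schedule$epochs)) {
      idx <- sample(length(train_samples))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(idx), by = schedule$batch)) {
        bidx <- idx[start:min(start + schedule$batch - 1, length(idx))]
        z0s <- if (is.null(crop_depth)) NULL else
          sample(nz - crop_depth + 1, length(bidx), replace = TRUE)
        xs <- Map(get_x, train_samples[bidx],
                  if (is.null(z0s)) vector("list", length(bidx)) else z0s)
        as_ <- Map(get_a, train_samples[bidx],
                   if (is.null(z0s)) vector("list", length(bidx)) else z0s)
        fw <- unet_ac_forward(params, running, xs, cfg, train = TRUE)
        running <- fw$running
        n_tot <- sum(vapply(fw$p, length, 0))
        dlogits <- Map(function(p, a) (p - a) / n_tot, fw$p, as_)
        grads <- unet_ac_backward(params, cfg, fw$cache, dlogits)
        st <- adam_step(params, grads, opt, schedule$lr)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + bce_loss(fw$p, as_)
        nb <- nb + 1
      }
      # validation in eval mode, batched to bound memory
      vl <- 0
      nv <- 0
      for (start in seq(1, length(val_samples), by = 8)) {
        vs <- val_samples[start:min(start + 7, length(val_samples))]
        fw <- unet_ac_forward(params, running,
                              lapply(vs, get_x, z0 = val_z0), cfg,
                              train = FALSE)
        vl <- vl + bce_loss(fw$p, lapply(vs, get_a, z0 = val_z0)) *
          length(vs)
        nv <- nv + length(vs)
      }
      vl <- vl / nv
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / nb,
                                  val_loss = vl))
      if (vl < best$loss)
        best <- list(loss = vl, params = params, running = running,
                     epoch = ep)
      if (verbose)
        message(sprintf("unet epoch %d: train %.4f val %.4f", ep,
                        ep_loss / nb, vl))
    }
    list(params = best$params, running = best$running, cfg = cfg,
         history = history, best_epoch = best$epoch,
         best_val_loss = best$loss)
  })
}

#' Select the cavity binarization threshold on validation data
#'
#' Sweeps candidate thresholds and returns the one with the highest
#' mean validation Dice coefficient, the same selection procedure that
#' fixed the reference threshold of 0.4.
#'
#' @param model trained U-Net from [train_unet_ac()].
#' @param val_samples validation sample list (fields `mri`, `ac`).
#' @param thresholds candidate thresholds.
#' @param max_samples cap on validation samples scored.
#' @return The selected threshold, with the per-threshold mean DSC in
#'   attribute `dsc`.
#' @export
select_binarize_threshold <- function(model, val_samples,
                                      thresholds = seq(0.3, 0.7, 0.1),
                                      max_samples = 40) {
  val_samples <- val_samples[seq_len(min(length(val_samples),
                                         max_samples))]
  ps <- lapply(val_samples, function(s) predict_unet_ac(model, s$mri))
  dsc <- vapply(thresholds, function(th) {
    mean(vapply(seq_along(ps), function(i)
      dice_local(binarize_probability(ps[[i]], th),
                 val_samples[[i]]$ac), numeric(1)))
  }, numeric(1))
  structure(thresholds[which.max(dsc)], dsc = setNames(dsc, thresholds))
}

#' Predict a cavity probability cuboid
#'
#' @param model result of [train_unet_ac()].
#' @param mri MRI cuboid array `(D, H, W)`.
#' @return Probability array of the same shape, values in \[0, 1\].
#' @export
predict_unet_ac <- function(model, mri) {
  fw <- unet_ac_forward(model$params, model$running,
                        list(array(mri, c(dim(mri), 1))), model$cfg,
                        train = FALSE)
  fw$p[[1]]
}
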