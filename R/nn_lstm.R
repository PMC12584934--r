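# Sequence dose engine: a unidirectional single-layer LSTM walks the
# BEV cuboid slice by slice in depth (causal: step t sees steps <= t),
# followed by a two-layer fully-connected head. Each input step is one
# flattened 32 x 32 (or scaled) transverse slice; for MRI+AC input the
# two slices of the same depth are concatenated along the flattened
# width. The stated head sizes (two layers "of 100 neurons") cannot
# literally emit a 1024-wide slice, so the head is
# LSTM(H) -> FC(H -> fc_hidden, ReLU) -> FC(fc_hidden -> output, linear).

#' LSTM dose-engine configuration
#'
#' @param input_width flattened slice width (one slice, or two
#'   concatenated for MRI+AC input).
#' @param hidden LSTM hidden state size (reference config: 1000).
#' @param fc_hidden width of the intermediate FC layer (reference: 100).
#' @param output_width flattened output slice width.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(input_width = 1024, hidden = 1000,
                        fc_hidden = 100, output_width = 1024) {
  structure(list(input_width = as.integer(input_width),
                 hidden = as.integer(hidden),
                 fc_hidden = as.integer(fc_hidden),
                 output_width = as.integer(output_width)),
            class = "lstm_config")
}

# Gate column blocks in order i (input), f (forget), g (cell), o (output).
init_lstm_params <- function(cfg) {
  H <- cfg$hidden
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1    # forget-gate bias
  list(Wx = uniform_init(c(cfg$input_width, 4 * H), H),
       Wh = uniform_init(c(H, 4 * H), H),
       b = b,
       W1 = uniform_init(c(H, cfg$fc_hidden), H),
       b1 = rep(0, cfg$fc_hidden),
       W2 = uniform_init(c(cfg$fc_hidden, cfg$output_width), cfg$fc_hidden),
       b2 = rep(0, cfg$output_width))
}

#' Forward pass of the LSTM dose engine
#'
#' @param params parameter list from training.
#' @param x input array `(batch, input_width, steps)` of flattened BEV
#'   slices.
#' @param cfg the [lstm_config()].
#' @param cache logical; keep intermediates for backprop.
#' @return List with `y` `(batch, output_width, steps)` and optionally
#'   `cache`.
#' @export
lstm_dose_forward <- function(params, x, cfg, cache = FALSE) {
  d <- dim(x)
  if (length(d) != 3 || d[2] != cfg$input_width)
    stop("shape error: expected (batch, ", cfg$input_width, ", steps) input")
  B <- d[1]; TT <- d[3]; H <- cfg$hidden
  h <- matrix(0, B, H)
  cs <- matrix(0, B, H)
  gates <- if (cache) vector("list", TT)
  cells <- if (cache) vector("list", TT)
  hs_prev <- if (cache) vector("list", TT)
  h_all <- matrix(0, TT * B, H)
  for (t in seq_len(TT)) {
    z <- x[, , t, drop = FALSE]
    dim(z) <- c(B, cfg$input_width)
    a <- z %*% params$Wx + h %*% params$Wh +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    gi <- sigmoid(a[, 1:H, drop = FALSE])
    gf <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    go <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    if (cache) {
      hs_prev[[t]] <- h
      cells[[t]] <- cs
    }
    cs <- gf * cs + gi * gg
    tc <- tanh(cs)
    h <- go * tc
    if (cache) gates[[t]] <- list(i = gi, f = gf, g = gg, o = go, c = cs,
                                  tc = tc)
    h_all[((t - 1) * B + 1):(t * B), ] <- h
  }
  a1 <- h_all %*% params$W1
  a1 <- sweep(a1, 2, params$b1, "+")
  r1 <- relu(a1)
  y <- r1 %*% params$W2
  y <- sweep(y, 2, params$b2, "+")
  yarr <- array(0, c(B, cfg$output_width, TT))
  for (t in seq_len(TT)) yarr[, , t] <- y[((t - 1) * B + 1):(t * B), ]
  out <- list(y = yarr)
  if (cache)
    out$cache <- list(x = x, gates = gates, cells = cells,
                      hs_prev = hs_prev, h_all = h_all, r1 = r1, B = B,
                      TT = TT)
  out
}

# Backward pass; dy is (B, output_width, steps). Returns gradients and dx.
lstm_dose_backward <- function(params, cfg, cache, dy) {
  B <- cache$B; TT <- cache$TT; H <- cfg$hidden
  dy_flat <- matrix(0, TT * B, cfg$output_width)
  for (t in seq_len(TT)) dy_flat[((t - 1) * B + 1):(t * B), ] <- dy[, , t]
  dW2 <- crossprod(cache$r1, dy_flat)
  db2 <- colSums(dy_flat)
  dr1 <- tcrossprod(dy_flat, params$W2)
  dr1[cache$r1 <= 0] <- 0
  dW1 <- crossprod(cache$h_all, dr1)
  db1 <- colSums(dr1)
  dh_all <- tcrossprod(dr1, params$W1)

  dWx <- array(0, dim(params$Wx))
  dWh <- array(0, dim(params$Wh))
  db <- rep(0, length(params$b))
  dx <- array(0, dim(cache$x))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(TT))) {
    g <- cache$gates[[t]]
    dh <- dh_all[((t - 1) * B + 1):(t * B), , drop = FALSE] + dh_next
    dc <- dc_next + dh * g$o * (1 - g$tc^2)
    di <- dc * g$g * g$i * (1 - g$i)
    df <- dc * cache$cells[[t]] * g$f * (1 - g$f)
    dg <- dc * g$i * (1 - g$g^2)
    do_ <- dh * g$tc * g$o * (1 - g$o)
    da <- cbind(di, df, dg, do_)
    xt <- cache$x[, , t, drop = FALSE]
    dim(xt) <- c(B, cfg$input_width)
    dWx <- dWx + crossprod(xt, da)
    dWh <- dWh + crossprod(cache$hs_prev[[t]], da)
    db <- db + colSums(da)
    dx[, , t] <- tcrossprod(da, params$Wx)
    dh_next <- tcrossprod(da, params$Wh)
    dc_next <- dc * g$f
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2),
       dx = dx)
}

# Assemble the (B, width, T) input array for a list of samples.
# input: "ct" (one channel), "mri" (one channel) or "mri_ac"
# (MRI and AC slices concatenated along the flattened width).
lstm_input_array <- function(samples, input, ac_override = NULL) {
  d <- dim(samples[[1]]$mri)
  w <- prod(d[2:3])
  B <- length(samples)
  width <- if (input == "mri_ac") 2 * w else w
  x <- array(0, c(B, width, d[1]))
  for (b in seq_len(B)) {
    s <- samples[[b]]
    if (input == "ct") {
      x[b, , ] <- t(matrix(s$ct, d[1], w))
    } else if (input == "mri") {
      x[b, , ] <- t(matrix(s$mri, d[1], w))
    } else {
      ac <- if (is.null(ac_override)) s$ac else ac_override[[b]]
      x[b, 1:w, ] <- t(matrix(s$mri, d[1], w))
      x[b, (w + 1):(2 * w), ] <- t(matrix(ac, d[1], w))
    }
  }
  x
}

lstm_target_arrays <- function(samples) {
  d <- dim(samples[[1]]$dose)
  w <- prod(d[2:3])
  B <- length(samples)
  dd <- array(0, c(B, w, d[1]))
  aa <- array(0, c(B, w, d[1]))
  for (b in seq_len(B)) {
    dd[b, , ] <- t(matrix(samples[[b]]$dose, d[1], w))
    aa[b, , ] <- t(matrix(samples[[b]]$ac, d[1], w))
  }
  list(dose = dd, ac = aa)
}

# Eq-style loss and output gradient on (B, w, T) arrays.
dose_loss_and_grad <- function(y, dose, ac, lambda) {
  r <- y - dose
  n <- length(r)
  loss <- sum(r^2) / n + lambda * sum((ac * r)^2) / n
  list(loss = loss, dy = 2 * r / n + 2 * lambda * ac * r / n)
}

#' Train the LSTM dose engine
#'
#' Minimizes the cavity-weighted dose loss with Adam; returns the
#' parameters of the epoch with the lowest validation loss.
#'
#' @param train_samples,val_samples sample lists from
#'   [build_beam_dataset()] (fields `mri`, `ac`, `ct`, `dose`).
#' @param input `"ct"`, `"mri"` or `"mri_ac"`.
#' @param cfg an [lstm_config()]; NULL derives widths from the data.
#' @param schedule a [train_schedule()].
#' @param verbose print per-epoch losses.
#' @return List with `params`, `cfg`, `input`, `history` and
#'   `best_epoch`.
#' @export
train_dose_lstm <- function(train_samples, val_samples,
                            input = c("mri_ac", "ct", "mri"),
                            cfg = NULL, schedule = train_schedule(),
                            verbose = FALSE) {
  input <- match.arg(input)
  if (length(train_samples) == 0) stop("empty training dataset")
  tr_ids <- unique(vapply(train_samples, `[[`, 0, "patient"))
  va_ids <- unique(vapply(val_samples, `[[`, 0, "patient"))
  if (length(intersect(tr_ids, va_ids)) > 0)
    stop("training and validation splits share patients")
  d <- dim(train_samples[[1]]$dose)
  w <- prod(d[2:3])
  if (is.null(cfg))
    cfg <- lstm_config(input_width = if (input == "mri_ac") 2 * w else w,
                       hidden = 1000, fc_hidden = 100, output_width = w)
  with_seed(schedule$seed, {
    params <- init_lstm_params(cfg)
    opt <- adam_init(params)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(loss = Inf, params = params, epoch = 0)
    lam <- if (input == "ct") 0 else schedule$lambda_ac
    val_x <- lstm_input_array(val_samples, input)
    val_t <- lstm_target_arrays(val_samples)
    for (ep in seq_len(schedule$epochs)) {
      idx <- sample(length(train_samples))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(idx), by = schedule$batch)) {
        bidx <- idx[start:min(start + schedule$batch - 1, length(idx))]
        bs <- train_samples[bidx]
        x <- lstm_input_array(bs, input)
        tg <- lstm_target_arrays(bs)
        fw <- lstm_dose_forward(params, x, cfg, cache = TRUE)
        lg <- dose_loss_and_grad(fw$y, tg$dose, tg$ac, lam)
        bw <- lstm_dose_backward(params, cfg, fw$cache, lg$dy)
        st <- adam_step(params, bw$grads, opt, schedule$lr)
        params <- st$params
        opt <- st$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1
      }
      vfw <- lstm_dose_forward(params, val_x, cfg)
      vl <- dose_loss_and_grad(vfw$y, val_t$dose, val_t$ac, lam)$loss
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / nb,
                                  val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params,
                                       epoch = ep)
      if (verbose)
        message(sprintf("epoch %d: train %.3e val %.3e", ep,
                        ep_loss / nb, vl))
    }
    list(params = best$params, cfg = cfg, input = input,
         history = history, best_epoch = best$epoch,
         best_val_loss = best$loss)
  })
}

#' Predict a dose cuboid with a trained LSTM engine
#'
#' @param model result of [train_dose_lstm()].
#' @param sample a dataset sample (or list with the required input
#'   arrays).
#' @param ac_override optional cavity array replacing `sample$ac` (used
#'   for inference with a predicted mask).
#' @return Dose array with the cuboid shape.
#' @export
predict_dose_lstm <- function(model, sample, ac_override = NULL) {
  x <- lstm_input_array(list(sample), model$input,
                        ac_override = if (is.null(ac_override)) NULL
                        else list(ac_override))
  y <- lstm_dose_forward(model$params, x, model$cfg)$y
  d <- dim(sample$mri)
  array(aperm(y[1, , , drop = FALSE], c(3, 2, 1)), dim = d)
}
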