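# The four training/inference variants of the dose engine:
#   Model 0 - LSTM on CT cuboids (baseline), plain MSE loss.
#   Model 1 - LSTM on MRI + manually contoured AC, cavity-weighted loss.
#   Model 2 - U-Net (BCE) and the Model-1 LSTM trained separately;
#             joint inference: U-Net -> binarize -> concat with MRI ->
#             LSTM, all weights frozen.
#   Model 3 - U-Net and LSTM trained jointly; loss = BCE + the
#             cavity-weighted dose loss (unit task weighting), with the
#             continuous U-Net probability fed to the LSTM so dose
#             gradients also reach the segmenter.

#' Train a dose-calculation model variant
#'
#' @param variant 0, 1, 2 or 3 (see module description).
#' @param dataset result of [build_beam_dataset()] (needs `train` and
#'   `val` splits).
#' @param schedule a [train_schedule()] for the LSTM (and the joint
#'   variant).
#' @param lstm_cfg,unet_cfg optional network configurations; defaults
#'   derive widths from the data (LSTM) and use the reference U-Net.
#' @param unet_schedule separate schedule for the U-Net of Model 2.
#' @param verbose print per-epoch losses.
#' @return A checkpoint list with `variant`, `lstm`, optionally `unet`,
#'   and the dataset `normalization`.
#' @export
train_model <- function(variant, dataset, schedule = train_schedule(),
                        lstm_cfg = NULL, unet_cfg = NULL,
                        unet_schedule = schedule,
                        unet_crop_depth = NULL, unet_val_max = Inf,
                        verbose = FALSE) {
  if (!variant %in% 0:3) stop("variant must be 0, 1, 2 or 3")
  tr <- dataset$train
  va <- dataset$val
  if (length(tr) == 0 || length(va) == 0) stop("empty dataset split")
  ck <- list(variant = variant, normalization = dataset$normalization,
             ct_global_max = dataset$ct_global_max,
             geometry = dataset$geometry, seed = schedule$seed,
             threshold = schedule$ac_binarize_threshold)
  if (variant == 0) {
    ck$lstm <- train_dose_lstm(tr, va, input = "ct", cfg = lstm_cfg,
                               schedule = schedule, verbose = verbose)
  } else if (variant == 1) {
    ck$lstm <- train_dose_lstm(tr, va, input = "mri_ac", cfg = lstm_cfg,
                               schedule = schedule, verbose = verbose)
  } else if (variant == 2) {
    if (is.null(unet_cfg)) unet_cfg <- unet_config()
    ck$unet <- train_unet_ac(tr, va, cfg = unet_cfg,
                             schedule = unet_schedule,
                             crop_depth = unet_crop_depth,
                             val_max = unet_val_max, verbose = verbose)
    ck$lstm <- train_dose_lstm(tr, va, input = "mri_ac", cfg = lstm_cfg,
                               schedule = schedule, verbose = verbose)
  } else {
    if (is.null(unet_cfg)) unet_cfg <- unet_config()
    ck <- c(ck, train_model3_joint(tr, va, schedule, lstm_cfg, unet_cfg,
                                   verbose = verbose))
  }
  class(ck) <- "mrdose_checkpoint"
  ck
}

# Joint training of Model 3: one optimizer over both networks.
train_model3_joint <- function(tr, va, schedule, lstm_cfg, unet_cfg,
                               verbose = FALSE) {
  d <- dim(tr[[1]]$dose)
  w <- prod(d[2:3])
  if (is.null(lstm_cfg))
    lstm_cfg <- lstm_config(input_width = 2 * w, hidden = 1000,
                            fc_hidden = 100, output_width = w)
  with_seed(schedule$seed, {
    lp <- init_lstm_params(lstm_cfg)
    up <- init_unet_params(unet_cfg)
    running <- attr(up, "running")
    attr(up, "running") <- NULL
    lopt <- adam_init(lp)
    uopt <- adam_init(up)
    lam <- schedule$lambda_ac
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best <- list(loss = Inf)
    eval_loss <- function(samples) {
      tot <- 0
      for (start in seq(1, length(samples), by = 8)) {
        ss <- samples[start:min(start + 7, length(samples))]
        xs <- lapply(ss, function(s) array(s$mri, c(dim(s$mri), 1)))
        fw <- unet_ac_forward(up, running, xs, unet_cfg, train = FALSE)
        x <- lstm_input_array(ss, "mri_ac", ac_override = fw$p)
        y <- lstm_dose_forward(lp, x, lstm_cfg)$y
        tg <- lstm_target_arrays(ss)
        dl <- dose_loss_and_grad(y, tg$dose, tg$ac, lam)$loss
        tot <- tot + (dl + bce_loss(fw$p, lapply(ss, `[[`, "ac"))) *
          length(ss)
      }
      tot / length(samples)
    }
    for (ep in seq_len(schedule$epochs)) {
      idx <- sample(length(tr))
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, length(idx), by = schedule$batch)) {
        bs <- tr[idx[start:min(start + schedule$batch - 1, length(idx))]]
        xs <- lapply(bs, function(s) array(s$mri, c(dim(s$mri), 1)))
        as_ <- lapply(bs, `[[`, "ac")
        ufw <- unet_ac_forward(up, running, xs, unet_cfg, train = TRUE)
        running <- ufw$running
        x <- lstm_input_array(bs, "mri_ac", ac_override = ufw$p)
        lfw <- lstm_dose_forward(lp, x, lstm_cfg, cache = TRUE)
        tg <- lstm_target_arrays(bs)
        lg <- dose_loss_and_grad(lfw$y, tg$dose, tg$ac, lam)
        lbw <- lstm_dose_backward(lp, lstm_cfg, lfw$cache, lg$dy)
        # route the AC-channel input gradient back into the U-Net
        n_bce <- sum(vapply(ufw$p, length, 0))
        dlogits <- vector("list", length(bs))
        dd <- dim(bs[[1]]$mri)
        for (i in seq_along(bs)) {
          dac <- lbw$dx[i, (w + 1):(2 * w), , drop = FALSE]  # (1, w, T)
          dac <- array(aperm(dac, c(3, 2, 1)), dd)
          dlogits[[i]] <- (ufw$p[[i]] - as_[[i]]) / n_bce +
            dac * ufw$p[[i]] * (1 - ufw$p[[i]])
        }
        ugr <- unet_ac_backward(up, unet_cfg, ufw$cache, dlogits)
        st <- adam_step(lp, lbw$grads, lopt, schedule$lr)
        lp <- st$params
        lopt <- st$state
        st <- adam_step(up, ugr, uopt, schedule$lr)
        up <- st$params
        uopt <- st$state
        ep_loss <- ep_loss + lg$loss + bce_loss(ufw$p, as_)
        nb <- nb + 1
      }
      vl <- eval_loss(va)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / nb,
                                  val_loss = vl))
      if (vl < best$loss)
        best <- list(loss = vl, lp = lp, up = up, running = running,
                     epoch = ep)
      if (verbose)
        message(sprintf("joint epoch %d: train %.3e val %.3e", ep,
                        ep_loss / nb, vl))
    }
    list(lstm = list(params = best$lp, cfg = lstm_cfg, input = "mri_ac",
                     history = history, best_epoch = best$epoch,
                     best_val_loss = best$loss),
         unet = list(params = best$up, running = best$running,
                     cfg = unet_cfg, history = history,
                     best_epoch = best$epoch))
  })
}

#' Model-2 inference: MRI cuboid to cavity mask and dose cuboid
#'
#' U-Net probability -> binarize at `threshold` -> concatenate with the
#' MRI -> LSTM; all parameters frozen.
#'
#' @param mri MRI cuboid array `(D, H, W)` (normalized).
#' @param unet trained U-Net (from [train_unet_ac()] or a checkpoint).
#' @param lstm trained LSTM engine with `input = "mri_ac"`.
#' @param threshold binarization threshold, default 0.4.
#' @return List with `ac` (binary array) and `dose` (array).
#' @export
predict_model2 <- function(mri, unet, lstm, threshold = 0.4) {
  if (is.null(unet$params) || is.null(lstm$params))
    stop("untrained or missing model parameters")
  if (lstm$input != "mri_ac")
    stop("the dose engine must have been trained on MRI + AC input")
  p <- predict_unet_ac(unet, mri)
  ac <- binarize_probability(p, threshold)
  dose <- predict_dose_lstm(lstm, list(mri = mri, ac = ac, ct = NULL,
                                       dose = array(0, dim(mri))),
                            ac_override = ac)
  list(ac = ac, p = p, dose = dose)
}

#' Predict a dose cuboid with any trained variant checkpoint
#'
#' @param ck checkpoint from [train_model()].
#' @param sample dataset sample (needs `mri` and, per variant, `ct` or
#'   `ac`).
#' @return List with `dose` and, for variants 2/3, `ac`.
#' @export
predict_checkpoint <- function(ck, sample) {
  if (ck$variant == 0) {
    list(dose = predict_dose_lstm(ck$lstm, sample))
  } else if (ck$variant == 1) {
    list(dose = predict_dose_lstm(ck$lstm, sample))
  } else {
    predict_model2(sample$mri, ck$unet, ck$lstm,
                   threshold = ck$threshold %||% 0.4)
  }
}
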