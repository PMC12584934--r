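tiny_lstm <- function(seed = 1) {
  cfg <- mrdose:::lstm_config(input_width = 8, hidden = 6, fc_hidden = 5,
                              output_width = 8)
  set.seed(seed)
  list(cfg = cfg, params = mrdose:::init_lstm_params(cfg))
}

test_that("cavity-weighted loss obeys its algebraic identities", {
  set.seed(30)
  d <- array(runif(60), c(3, 4, 5))
  dh <- array(runif(60), c(3, 4, 5))
  ac <- array(rbinom(60, 1, 0.4), c(3, 4, 5))
  expect_equal(combined_loss(d, dh, ac, 0), mean((d - dh)^2),
               tolerance = 1e-7)
  ones <- array(1, c(3, 4, 5))
  expect_equal(combined_loss(d, dh, ones, 10), 11 * mean((d - dh)^2),
               tolerance = 1e-7)
  # hand-evaluated two-voxel case
  expect_equal(combined_loss(c(1, 0), c(0, 0), c(1, 0), 10), 5.5)
  expect_error(combined_loss(d, dh[, , 1:4], ac, 1), "shape mismatch")
})

test_that("probability binarization is inclusive at the threshold", {
  p <- c(0, 0.39999, 0.4, 0.41, 1)
  expect_equal(binarize_probability(p, 0.4), c(0, 0, 1, 1, 1))
  expect_equal(sum(binarize_probability(rep(0, 10))), 0)
  # sweeping the threshold up monotonically shrinks the mask
  set.seed(31)
  pr <- runif(200)
  sizes <- vapply(seq(0.3, 0.7, by = 0.1),
                  function(th) sum(binarize_probability(pr, th)), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the dose engine is causal in depth and deterministic", {
  m <- tiny_lstm()
  set.seed(32)
  x <- array(rnorm(2 * 8 * 7), c(2, 8, 7))
  y1 <- lstm_dose_forward(m$params, x, m$cfg)$y
  y2 <- lstm_dose_forward(m$params, x, m$cfg)$y
  expect_identical(y1, y2)
  # perturb step 4: steps 1-3 unchanged, some later step changes
  xp <- x
  xp[, , 4] <- xp[, , 4] + 1
  yp <- lstm_dose_forward(m$params, xp, m$cfg)$y
  expect_identical(yp[, , 1:3], y1[, , 1:3])
  expect_false(identical(yp[, , 4:7], y1[, , 4:7]))
  expect_error(lstm_dose_forward(m$params, array(0, c(2, 9, 7)), m$cfg),
               "shape error")
})

test_that("LSTM gradients agree with finite differences", {
  m <- tiny_lstm(2)
  set.seed(33)
  B <- 2; TT <- 4
  x <- array(rnorm(B * 8 * TT), c(B, 8, TT))
  d <- array(rnorm(B * 8 * TT), c(B, 8, TT))
  ac <- array(rbinom(B * 8 * TT, 1, 0.3), c(B, 8, TT))
  lossf <- function(pp) {
    y <- lstm_dose_forward(pp, x, m$cfg)$y
    mrdose:::dose_loss_and_grad(y, d, ac, 10)$loss
  }
  fw <- lstm_dose_forward(m$params, x, m$cfg, cache = TRUE)
  lg <- mrdose:::dose_loss_and_grad(fw$y, d, ac, 10)
  bw <- mrdose:::lstm_dose_backward(m$params, m$cfg, fw$cache, lg$dy)
  eps <- 1e-6
  for (k in names(m$params)) {
    i <- sample(length(m$params[[k]]), 1)
    pp <- m$params
    pp[[k]][i] <- pp[[k]][i] + eps
    num <- (lossf(pp) - lossf(m$params)) / eps
    expect_equal(bw$grads[[k]][i], num, tolerance = 1e-3)
  }
})

test_that("the U-Net keeps shape, bounds output and rejects bad shapes", {
  cfg <- unet_config(encoder_filters = c(3, 4), bottleneck_filters = 6)
  set.seed(34)
  p <- mrdose:::init_unet_params(cfg)
  running <- attr(p, "running")
  attr(p, "running") <- NULL
  x <- list(array(rnorm(16 * 8 * 8), c(16, 8, 8, 1)))
  fw <- unet_ac_forward(p, running, x, cfg, train = FALSE)
  expect_identical(dim(fw$p[[1]]), c(16L, 8L, 8L))
  expect_true(min(fw$p[[1]]) >= 0 && max(fw$p[[1]]) <= 1)
  expect_error(
    unet_ac_forward(p, running, list(array(0, c(17, 8, 8, 1))), cfg),
    "divisible by 4")
  # fully convolutional: the same parameters run on another shape
  x2 <- list(array(rnorm(20 * 12 * 8), c(20, 12, 8, 1)))
  fw2 <- unet_ac_forward(p, running, x2, cfg, train = FALSE)
  expect_identical(dim(fw2$p[[1]]), c(20L, 12L, 8L))
})

test_that("U-Net gradients agree with finite differences", {
  cfg <- unet_config(encoder_filters = c(2, 3), bottleneck_filters = 4)
  set.seed(35)
  p <- mrdose:::init_unet_params(cfg)
  running <- attr(p, "running")
  attr(p, "running") <- NULL
  xs <- lapply(1:2, function(i) array(rnorm(8 * 4 * 4), c(8, 4, 4, 1)))
  as_ <- lapply(1:2, function(i) array(rbinom(8 * 4 * 4, 1, 0.3),
                                       c(8, 4, 4)))
  lossf <- function(pp) {
    fw <- unet_ac_forward(pp, running, xs, cfg, train = TRUE)
    mrdose:::bce_loss(fw$p, as_)
  }
  fw <- unet_ac_forward(p, running, xs, cfg, train = TRUE)
  n_tot <- sum(vapply(fw$p, length, 0))
  dlog <- Map(function(pr, a) (pr - a) / n_tot, fw$p, as_)
  gr <- mrdose:::unet_ac_backward(p, cfg, fw$cache, dlog)
  eps <- 1e-6
  for (k in names(p)) {
    i <- sample(length(p[[k]]), 1)
    pp <- p
    pp[[k]][i] <- pp[[k]][i] + eps
    num <- (lossf(pp) - lossf(p)) / eps
    if (abs(num) + abs(gr[[k]][i]) > 1e-9)
      expect_equal(gr[[k]][i], num, tolerance = 5e-3)
  }
})

test_that("seeded training runs are reproducible and splits must be disjoint", {
  # two-sample toy dataset with distinct patients
  mk_sample <- function(pid, seed) {
    set.seed(seed)
    list(patient = pid, mri = array(runif(8 * 4 * 4), c(8, 4, 4)),
         ac = array(rbinom(8 * 4 * 4, 1, 0.2), c(8, 4, 4)),
         ct = array(runif(8 * 4 * 4), c(8, 4, 4)),
         dose = array(runif(8 * 4 * 4), c(8, 4, 4)))
  }
  tr <- lapply(1:4, function(i) mk_sample(1, i))
  va <- lapply(5:6, function(i) mk_sample(2, i))
  cfg <- mrdose:::lstm_config(input_width = 32, hidden = 8, fc_hidden = 6,
                              output_width = 16)
  sched <- train_schedule(lr = 1e-3, batch = 2, epochs = 2, seed = 9)
  r1 <- train_dose_lstm(tr, va, "mri_ac", cfg, sched)
  r2 <- train_dose_lstm(tr, va, "mri_ac", cfg, sched)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$params, r2$params)
  expect_error(train_dose_lstm(tr, tr, "mri_ac", cfg, sched),
               "share patients")
  expect_error(train_dose_lstm(list(), va, "mri_ac", cfg, sched),
               "empty")
})

test_that("model-2 inference is frozen, deterministic and shape-stable", {
  mk_sample <- function(pid, seed) {
    set.seed(seed)
    list(patient = pid, mri = array(runif(8 * 4 * 4), c(8, 4, 4)),
         ac = array(rbinom(8 * 4 * 4, 1, 0.2), c(8, 4, 4)),
         ct = array(runif(8 * 4 * 4), c(8, 4, 4)),
         dose = array(runif(8 * 4 * 4), c(8, 4, 4)))
  }
  tr <- lapply(1:4, function(i) mk_sample(1, i))
  va <- lapply(5:6, function(i) mk_sample(2, i))
  ucfg <- unet_config(encoder_filters = c(2, 3), bottleneck_filters = 4)
  lcfg <- mrdose:::lstm_config(input_width = 32, hidden = 8,
                               fc_hidden = 6, output_width = 16)
  sched <- train_schedule(lr = 1e-3, batch = 2, epochs = 1, seed = 3)
  un <- train_unet_ac(tr, va, ucfg, sched)
  lm <- train_dose_lstm(tr, va, "mri_ac", lcfg, sched)
  s <- va[[1]]
  p1 <- predict_model2(s$mri, un, lm)
  p2 <- predict_model2(s$mri, un, lm)
  expect_identical(p1$dose, p2$dose)
  expect_identical(dim(p1$dose), dim(s$mri))
  expect_true(all(p1$ac %in% c(0, 1)))
  expect_error(predict_model2(s$mri, list(params = NULL), lm),
               "untrained")
  lm0 <- train_dose_lstm(tr, va, "ct", lcfg_ct <- mrdose:::lstm_config(
    input_width = 16, hidden = 8, fc_hidden = 6, output_width = 16),
    sched)
  expect_error(predict_model2(s$mri, un, lm0), "MRI \\+ AC")
})
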