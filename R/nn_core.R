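# Shared neural-network plumbing: parameter containers are flat named
# lists of numeric arrays; the optimizer is Adam. Everything runs on
# double precision through BLAS, which keeps seeded runs bitwise
# reproducible on a fixed platform.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

uniform_init <- function(dims, fan_in, scale = 1) {
  b <- scale / sqrt(fan_in)
  array(runif(prod(dims), -b, b), dim = dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training schedule
#'
#' Defaults follow the reference configuration of the dose engine:
#' Adam, learning rate 1e-5, batch size 4, cavity loss weight
#' lambda = 10 and an AC binarization threshold of 0.4. Scaled-down
#' experiments override `lr` and `epochs`.
#'
#' @param lr learning rate (> 0).
#' @param batch batch size (>= 1).
#' @param epochs maximum epochs; the checkpoint with the lowest
#'   validation loss is returned.
#' @param lambda_ac weight of the cavity-masked dose loss term.
#' @param ac_binarize_threshold probability threshold for the predicted
#'   cavity mask.
#' @param seed RNG seed for init and shuffling.
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(lr = 1e-5, batch = 4, epochs = 20,
                           lambda_ac = 10, ac_binarize_threshold = 0.4,
                           seed = 1) {
  if (lr <= 0) stop("lr must be positive")
  if (batch < 1) stop("batch must be >= 1")
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), lambda_ac = lambda_ac,
                 ac_binarize_threshold = ac_binarize_threshold,
                 seed = as.integer(seed)),
            class = "train_schedule")
}

#' Cavity-weighted dose loss
#'
#' `L = MSE(D, Dhat) + lambda * MSE(AC * D, AC * Dhat)` with
#' mean-reduction MSE over all cuboid voxels in both terms. With
#' `lambda = 0` it reduces to the plain MSE; with `AC` identically 1 it
#' equals `(1 + lambda) * MSE`.
#'
#' @param d reference dose array.
#' @param dhat predicted dose array, same shape.
#' @param ac binary cavity array, same shape.
#' @param lambda nonnegative weight.
#' @return Scalar loss.
#' @export
combined_loss <- function(d, dhat, ac, lambda = 10) {
  if (!identical(dim(d) %||% length(d), dim(dhat) %||% length(dhat)) ||
      !identical(dim(d) %||% length(d), dim(ac) %||% length(ac)))
    stop("shape mismatch between dose, prediction and AC arrays")
  if (lambda < 0) stop("lambda must be nonnegative")
  r <- dhat - d
  mean(r^2) + lambda * mean((ac * r)^2)
}

#' Binarize a probability map
#'
#' Voxels with probability `>= threshold` (inclusive) become 1.
#'
#' @param p probability array or `volume_grid`/`bev_cuboid` in \[0, 1\].
#' @param threshold cut in \[0, 1\], default 0.4.
#' @return Same container type with binary values.
#' @export
binarize_probability <- function(p, threshold = 0.4) {
  vals <- if (is.list(p)) p$values else p
  if (min(vals) < 0 || max(vals) > 1)
    stop("probabilities must lie in [0, 1]")
  bin <- as.numeric(vals >= threshold)
  if (!is.null(dim(vals))) dim(bin) <- dim(vals)
  if (inherits(p, "volume_grid")) {
    mask_grid(bin, grid = p$grid)
  } else if (inherits(p, "bev_cuboid")) {
    out <- p
    out$values <- bin
    out$quantity <- "MASK"
    out
  } else {
    bin
  }
}
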