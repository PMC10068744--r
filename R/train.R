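# Training: Adam, stepped learning-rate decay, BCE loss, augmentation.

#' Training hyperparameter configuration
#'
#' The optimizer is Adam with an initial learning rate of 0.001 that drops
#' to 98% of its previous value every 10 epochs, so the learning rate at
#' epoch `e` is `lr0 * lr_decay^floor(e / 10)`.  The loss is binary
#' cross-entropy on voxel probabilities.  Augmentation applies a random
#' crop to `patch_shape`, a random permutation of the three spatial axes,
#' and a random multiplicative brightness factor drawn uniformly from
#' `brightness_range` (applied after normalization, clipped to `[0, 1]`).
#'
#' @param epochs number of training epochs.
#' @param lr0 initial learning rate.
#' @param lr_decay decay factor applied every 10 epochs.
#' @param batch_size samples per optimizer step (gradients averaged).
#' @param patch_shape training patch shape; cropped randomly from each
#'   dataset block.
#' @param brightness_range multiplicative brightness augmentation range.
#' @param augment enable augmentation.
#' @param seed training seed (shuffling, cropping, augmentation).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, lr0 = 0.001, lr_decay = 0.98,
                         batch_size = 1, patch_shape = c(32, 32, 32),
                         brightness_range = c(0.7, 1.3), augment = TRUE,
                         seed = 1) {
  structure(list(optimizer = "adam", epochs = as.integer(epochs), lr0 = lr0,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 patch_shape = as.integer(as_triple(patch_shape)),
                 brightness_range = brightness_range, augment = augment,
                 loss = "bce", seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#' @param tc a [train_config()].
#' @param epoch 1-based epoch number.
#' @return `lr0 * lr_decay^floor(epoch / 10)`.
#' @export
learning_rate_at <- function(tc, epoch) tc$lr0 * tc$lr_decay^(epoch %/% 10)

bce_loss <- function(prob, truth) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

augment_sample <- function(img, tru, tc) {
  d <- dim(img)
  ps <- pmin(tc$patch_shape, d)
  o <- c(sample(0:(d[1] - ps[1]), 1), sample(0:(d[2] - ps[2]), 1),
         sample(0:(d[3] - ps[3]), 1))
  img <- img[(o[1] + 1):(o[1] + ps[1]), (o[2] + 1):(o[2] + ps[2]),
             (o[3] + 1):(o[3] + ps[3])]
  tru <- tru[(o[1] + 1):(o[1] + ps[1]), (o[2] + 1):(o[2] + ps[2]),
             (o[3] + 1):(o[3] + ps[3])]
  perm <- sample(3)
  img <- aperm(img, perm)
  tru <- aperm(tru, perm)
  # brightness acts on the raw crop (acquisition-gain variability), before
  # the network's input normalization
  f <- runif(1, tc$brightness_range[1], tc$brightness_range[2])
  img <- normalize_block(pmin(pmax(img * f, 0), 255))
  list(image = img, truth = tru)
}

adam_init <- function(params) {
  list(m = lapply(params, function(l) list(w = array(0, dim(l$w) %||% length(l$w)),
                                           b = rep(0, length(l$b)))),
       v = lapply(params, function(l) list(w = array(0, dim(l$w) %||% length(l$w)),
                                           b = rep(0, length(l$b)))),
       t = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (f in c("w", "b")) {
      g <- grads[[nm]][[f]]
      state$m[[nm]][[f]] <- beta1 * state$m[[nm]][[f]] + (1 - beta1) * g
      state$v[[nm]][[f]] <- beta2 * state$v[[nm]][[f]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[f]] / bc1
      vhat <- state$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# validation Dice on the centered patch_shape crop of each block (keeps
# per-epoch model selection cheap; final evaluation uses full volumes).
# The prediction is lumen-filled first, mirroring what the pipeline
# emits: ground truth includes lumens the raw network cannot see, so the
# filled prediction is the quantity the pipeline's Dice is measured on.
val_dice <- function(net, blocks, patch_shape = NULL, threshold = 0.5) {
  if (length(blocks) == 0) return(NA_real_)
  ds <- vapply(blocks, function(b) {
    img <- b$image; tru <- b$truth
    if (!is.null(patch_shape) && any(dim(img) > patch_shape)) {
      o <- pmax(0, (dim(img) - patch_shape) %/% 2)
      img <- img[(o[1] + 1):(o[1] + patch_shape[1]),
                 (o[2] + 1):(o[2] + patch_shape[2]),
                 (o[3] + 1):(o[3] + patch_shape[3])]
      tru <- tru[(o[1] + 1):(o[1] + patch_shape[1]),
                 (o[2] + 1):(o[2] + patch_shape[2]),
                 (o[3] + 1):(o[3] + patch_shape[3])]
    }
    pred <- fill_holes_planewise(predict_block(net, img, threshold))
    overlap_metrics(pred, tru)$dice
  }, numeric(1))
  mean(ds)
}

#' Train the segmentation network on a phantom dataset
#'
#' Runs seeded stochastic gradient training with Adam, the stepped
#' learning-rate schedule and BCE loss of [train_config()], logging the
#' training loss and validation Dice each epoch and returning the weights
#' of the best validation epoch.
#'
#' @param net a [build_network()] result.
#' @param dataset a [make_dataset()] result with non-empty train and val
#'   splits.
#' @param tc a [train_config()].
#' @param log_file optional CSV path for the per-epoch log (epoch, lr,
#'   train_loss, val_dice).
#' @param verbose print per-epoch progress.
#' @return `list(net, log)` where `net` carries the best-validation
#'   weights and `log` is the per-epoch data frame.
#' @export
train_network <- function(net, dataset, tc = train_config(),
                          log_file = NULL, verbose = FALSE) {
  splits <- vapply(dataset$blocks, `[[`, character(1), "split")
  tr <- dataset$blocks[splits == "train"]
  va <- dataset$blocks[splits == "val"]
  if (length(tr) == 0) stop("training split is empty")
  if (length(va) == 0) stop("validation split is empty")
  local_seed(tc$seed, {
    state <- adam_init(net$params)
    log <- data.frame()
    best <- list(dice = -Inf, params = net$params)
    for (epoch in seq_len(tc$epochs)) {
      lr <- learning_rate_at(tc, epoch)
      ord <- sample(length(tr))
      losses <- numeric(0)
      i <- 1
      while (i <= length(ord)) {
        take <- ord[i:min(length(ord), i + tc$batch_size - 1)]
        i <- i + tc$batch_size
        acc <- NULL
        bl <- 0
        for (j in take) {
          b <- tr[[j]]
          s <- if (tc$augment) augment_sample(b$image, b$truth, tc)
               else list(image = normalize_block(b$image), truth = b$truth)
          fw <- net_forward(net, s$image, cache = TRUE)
          bl <- bl + bce_loss(fw$prob, s$truth)
          dlogit <- (fw$prob - s$truth) / length(fw$prob)
          g <- net_backward(net, fw$cache, dlogit)
          acc <- if (is.null(acc)) g else
            mapply(function(a, gg) list(w = a$w + gg$w, b = a$b + gg$b),
                   acc, g, SIMPLIFY = FALSE)
        }
        nb <- length(take)
        if (nb > 1)
          acc <- lapply(acc, function(a) list(w = a$w / nb, b = a$b / nb))
        st <- adam_step(net$params, acc, state, lr)
        net$params <- st$params
        state <- st$state
        losses <- c(losses, bl / nb)
      }
      vd <- val_dice(net, va, tc$patch_shape)
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses), val_dice = vd))
      if (!is.na(vd) && vd > best$dice)
        best <- list(dice = vd, params = net$params)
      if (verbose)
        message(sprintf("epoch %3d  lr %.6f  loss %.4f  val dice %.4f",
                        epoch, lr, mean(losses), vd))
    }
    net$params <- best$params
    if (!is.null(log_file)) write.csv(log, log_file, row.names = FALSE)
    list(net = net, log = log)
  })
}
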