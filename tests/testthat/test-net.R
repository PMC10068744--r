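# Small-width configurations keep these structural tests fast; the
# reference configuration is exercised where the property depends on it.

tiny_cfg <- function(...) net_config(branch_widths = c(2, 2, 2),
                                     cbam_reduction = 2, head_width = 4, ...)

test_that("parameter count matches the closed-form per-layer sum", {
  conv3 <- function(i, o) 27 * i * o + o
  conv1 <- function(i, o) i * o + o
  tconv <- function(i, o) 8 * i * o + o
  bottle <- function(w, r) conv1(w, w / r) + conv3(w / r, w / r) + conv1(w / r, w)
  link <- function(w, e) conv3(w, e * w) + conv3(e * w, e * w) +
    tconv(e * w, w) + conv3(2 * w, w)
  widths <- c(8, 12, 16)
  branches <- sum(vapply(seq_along(widths), function(s) {
    w <- widths[s]
    conv3(1, w) + 2 * bottle(w, 2) + link(w, 2) + (s - 1) * tconv(w, w)
  }, numeric(1)))
  cs <- sum(widths)
  cbam <- (cs * (cs %/% 6) + cs %/% 6) + ((cs %/% 6) * cs + cs) +
    (7^3 * 2 + 1)
  head <- conv3(cs, 24) + conv3(24, 1)
  expected <- branches + cbam + head
  net <- build_network(net_config(), seed = 1)
  expect_equal(count_parameters(net), expected)
  # invariant to input patch size (count is structural)
  expect_equal(count_parameters(build_network(net_config(), seed = 99)),
               expected)
})

test_that("parameter count grows with scale count", {
  p1 <- count_parameters(build_network(net_config(n_scales = 1,
                                                  branch_widths = 8), 1))
  p3 <- count_parameters(build_network(net_config(), 1))
  expect_lt(p1, p3)
})

test_that("forward output is input-shaped, sigmoid-bounded, deterministic", {
  net <- build_network(tiny_cfg(), seed = 2)
  x <- array(runif(16^3), c(16, 16, 16))
  f1 <- net_forward(net, x)
  expect_equal(dim(f1$prob), c(16, 16, 16))
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  expect_identical(f1$prob, net_forward(net, x)$prob)
  # non-constant: permuting the input changes the output
  xp <- aperm(x, c(2, 1, 3))
  expect_false(identical(f1$prob, net_forward(net, xp)$prob))
  expect_error(net_forward(net, array(0, c(12, 16, 16))), "divisible")
})

test_that("reference configuration accepts a 64^3 patch", {
  net <- build_network(net_config(), seed = 1)
  out <- net_forward(net, array(runif(64^3), c(64, 64, 64)))
  expect_equal(dim(out$prob), c(64, 64, 64))
})

test_that("ablation toggles change the computation and the parameters", {
  x <- array(runif(16^3), c(16, 16, 16))
  base <- net_forward(build_network(tiny_cfg(), seed = 5), x)$prob
  nocbam <- net_forward(build_network(tiny_cfg(use_cbam = FALSE), seed = 5), x)$prob
  expect_false(identical(base, nocbam))
  # disabled LinkConv/BottleConv are plain equal-width 3^3 convolutions
  nl <- build_network(tiny_cfg(use_linkconv = FALSE), seed = 5)
  expect_true(any(grepl("lk.plain", names(nl$params))))
  nb <- build_network(tiny_cfg(use_bottleconv = FALSE), seed = 5)
  expect_true(any(grepl("b1.plain", names(nb$params))))
})

test_that("the stepped learning-rate schedule follows the decay rule", {
  tc <- train_config()
  expect_equal(learning_rate_at(tc, 25), 0.001 * 0.98^2)
  expect_equal(learning_rate_at(tc, 5), 0.001)
  expect_equal(learning_rate_at(tc, 10), 0.001 * 0.98)
})

test_that("backpropagation matches finite differences off the ReLU kink", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 3)
  # biases start at zero, which parks pre-activations exactly on the ReLU
  # kink; nudge them so the finite-difference check is well-posed
  for (nm in names(net$params))
    net$params[[nm]]$b <- rnorm(length(net$params[[nm]]$b), sd = 0.2)
  set.seed(4)
  x <- array(runif(8^3), c(8, 8, 8))
  tr <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
  lossfn <- function(n) {
    p <- net_forward(n, x)$prob
    -mean(tr * log(pmax(p, 1e-12)) + (1 - tr) * log(pmax(1 - p, 1e-12)))
  }
  fw <- net_forward(net, x, cache = TRUE)
  g <- vesselpipe:::net_backward(net, fw$cache, (fw$prob - tr) / length(fw$prob))
  # the conv contraction runs in single precision, so central differences
  # carry float-level noise; 2% relative agreement is the meaningful bound
  eps <- 1e-4
  for (nm in c("s1.in", "s2.lk.fuse", "s3.up2", "cbam.spat", "head.c1")) {
    for (f in c("w", "b")) {
      idx <- 1 + (length(net$params[[nm]][[f]]) - 1) %/% 2
      n2 <- net; n2$params[[nm]][[f]][idx] <- n2$params[[nm]][[f]][idx] + eps
      n3 <- net; n3$params[[nm]][[f]][idx] <- n3$params[[nm]][[f]][idx] - eps
      fd <- (lossfn(n2) - lossfn(n3)) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][[f]][idx]) /
                  max(abs(fd), abs(g[[nm]][[f]][idx]), 1e-6), 0.02)
    }
  }
})

test_that("training is seeded and reduces the loss on an easy dataset", {
  spec <- phantom_spec(shape = c(48, 48, 48), n_trees = 2, n_speckles = 3,
                       seed = 8)
  ds <- make_dataset(spec, n_blocks = 8, block_shape = c(32, 32, 32),
                     seed = 8, background_fraction = 0.25)
  net <- build_network(tiny_cfg(), seed = 2)
  tc <- train_config(epochs = 3, patch_shape = c(16, 16, 16), seed = 9)
  r1 <- train_network(net, ds, tc)
  r2 <- train_network(net, ds, tc)
  expect_identical(r1$log$train_loss[1], r2$log$train_loss[1])
  expect_equal(nrow(r1$log), 3)
  expect_true(all(c("epoch", "lr", "train_loss", "val_dice") %in%
                    names(r1$log)))
  expect_error(train_network(net, within(ds, blocks <- list()), tc))
})

test_that("prediction is binary, batch-invariant and threshold-sensitive", {
  net <- build_network(tiny_cfg(), seed = 6)
  set.seed(7)
  blocks <- replicate(3, array(runif(16^3), c(16, 16, 16)), simplify = FALSE)
  single <- lapply(blocks, function(b) predict_block(net, b))
  batch <- predict_block(net, blocks)
  expect_identical(single, batch)
  expect_true(all(unlist(batch) %in% c(0L, 1L)))
  expect_true(all(predict_block(net, blocks[[1]], threshold = 1.0) == 0L))
})

test_that("checkpoints round trip weights and configuration", {
  net <- build_network(tiny_cfg(), seed = 10)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  back <- load_checkpoint(f)
  expect_equal(back$config, net$config)
  x <- array(runif(16^3), c(16, 16, 16))
  expect_identical(net_forward(net, x)$prob, net_forward(back, x)$prob)
})
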