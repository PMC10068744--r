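# The lightweight multi-resolution segmentation network.
#
# Per scale k (0-based), the input is average-pooled by 2^k, lifted to
# W_k channels by a 3^3 convolution, passed through BottleConv -> LinkConv
# -> BottleConv, and upsampled back to full resolution by k stride-2
# transposed convolutions.  Branch outputs are concatenated, reweighted by
# CBAM (channel then spatial attention), and reduced to one channel by two
# 3^3 convolutions followed by a sigmoid.
#
# Submodules:
#   BottleConv(W): 1x1x1 conv W -> W/r, 3^3 conv, 1x1x1 conv W/r -> W,
#                  additive skip (bottleneck for parameter economy).
#   LinkConv(W):   pool/2 -> 3^3 conv W -> eW -> 3^3 conv -> transposed
#                  conv eW -> W -> concat with input skip -> 3^3 conv
#                  2W -> W (a one-level U-Net inside the branch).
#   CBAM:          channel attention (shared two-layer MLP on global max +
#                  avg pooled channel vectors) then spatial attention
#                  (7^3 conv over channelwise max + avg maps).
#
# Feature maps are (Z, Y, X, C) double arrays; all convolutions use
# symmetric "same" zero padding, so spatial shape is preserved.

#' Network architecture configuration
#'
#' The reference configuration (three scales, branch widths 8/12/16,
#' expansion 2, bottleneck ratio 2, attention reduction 6, head width 24)
#' totals about 0.147M trainable parameters.  The `use_*` toggles support
#' ablations: a disabled LinkConv or BottleConv is replaced by a plain 3^3
#' convolution of equal input/output channels, a disabled CBAM by the
#' identity.
#'
#' @param n_scales number of resolution branches (1-4).
#' @param branch_widths per-scale channel counts; defaults to
#'   `c(8, 12, 16)[seq_len(n_scales)]` extended with 20 for a fourth scale.
#' @param linkconv_expansion inner-width multiplier of LinkConv.
#' @param bottleneck_ratio channel squeeze divisor of BottleConv.
#' @param cbam_reduction channel-attention MLP reduction.
#' @param head_width channels of the penultimate convolution.
#' @param use_linkconv,use_bottleconv,use_cbam ablation toggles.
#' @return An object of class `net_config`.
#' @export
net_config <- function(n_scales = 3, branch_widths = NULL,
                       linkconv_expansion = 2, bottleneck_ratio = 2,
                       cbam_reduction = 6, head_width = 24,
                       use_linkconv = TRUE, use_bottleconv = TRUE,
                       use_cbam = TRUE) {
  if (!n_scales %in% 1:4) stop("n_scales must be in 1..4")
  if (is.null(branch_widths))
    branch_widths <- c(8, 12, 16, 20)[seq_len(n_scales)]
  if (length(branch_widths) != n_scales)
    stop("branch_widths must have one entry per scale")
  if (any(branch_widths %% bottleneck_ratio != 0))
    stop("all branch widths must be divisible by bottleneck_ratio")
  structure(list(n_scales = as.integer(n_scales),
                 branch_widths = as.integer(branch_widths),
                 linkconv_expansion = as.integer(linkconv_expansion),
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 cbam_reduction = as.integer(cbam_reduction),
                 head_width = as.integer(head_width),
                 use_linkconv = use_linkconv, use_bottleconv = use_bottleconv,
                 use_cbam = use_cbam,
                 conv_kernel = 3L, pool_kernel = 2L),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("<net_config> %d scale(s), widths (%s), head %d%s\n",
              x$n_scales, paste(x$branch_widths, collapse = ", "),
              x$head_width,
              paste0(if (!x$use_linkconv) ", -LinkConv" else "",
                     if (!x$use_bottleconv) ", -BottleConv" else "",
                     if (!x$use_cbam) ", -CBAM" else "")))
  invisible(x)
}

he_conv <- function(k, cin, cout) {
  w <- array(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
             c(k, k, k, cin, cout))
  list(w = w, b = rep(0, cout))
}

he_lin <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

he_tconv <- function(cin, cout) {
  list(w = array(rnorm(8 * cin * cout, sd = sqrt(2 / (8 * cin))),
                 c(2, 2, 2, cin, cout)),
       b = rep(0, cout))
}

#' Build the segmentation network
#'
#' Assembles all parameter arrays for the configured architecture with
#' seeded He-normal initialization.  The final bias is initialized to -2 so
#' an untrained network starts close to the background prior.
#'
#' @param config a [net_config()].
#' @param seed seed for weight initialization.
#' @return An object of class `vessel_net` holding `config` and a flat
#'   named list `params` of weight arrays.
#' @export
build_network <- function(config = net_config(), seed = 1) {
  local_seed(seed, {
    p <- list()
    r <- config$bottleneck_ratio
    e <- config$linkconv_expansion
    for (s in seq_len(config$n_scales)) {
      W <- config$branch_widths[s]
      pre <- sprintf("s%d", s)
      p[[paste0(pre, ".in")]] <- he_conv(3, 1, W)
      if (config$use_bottleconv) {
        for (bn in c(".b1", ".b2")) {
          p[[paste0(pre, bn, ".sq")]] <- he_lin(W, W %/% r)
          p[[paste0(pre, bn, ".core")]] <- he_conv(3, W %/% r, W %/% r)
          p[[paste0(pre, bn, ".ex")]] <- he_lin(W %/% r, W)
        }
      } else {
        p[[paste0(pre, ".b1.plain")]] <- he_conv(3, W, W)
        p[[paste0(pre, ".b2.plain")]] <- he_conv(3, W, W)
      }
      if (config$use_linkconv) {
        p[[paste0(pre, ".lk.c1")]] <- he_conv(3, W, e * W)
        p[[paste0(pre, ".lk.c2")]] <- he_conv(3, e * W, e * W)
        p[[paste0(pre, ".lk.up")]] <- he_tconv(e * W, W)
        p[[paste0(pre, ".lk.fuse")]] <- he_conv(3, 2 * W, W)
      } else {
        p[[paste0(pre, ".lk.plain")]] <- he_conv(3, W, W)
      }
      if (s > 1) for (j in seq_len(s - 1))
        p[[sprintf("%s.up%d", pre, j)]] <- he_tconv(W, W)
    }
    Csum <- sum(config$branch_widths)
    if (config$use_cbam) {
      red <- max(1L, Csum %/% config$cbam_reduction)
      p[["cbam.mlp1"]] <- he_lin(Csum, red)
      p[["cbam.mlp2"]] <- he_lin(red, Csum)
      p[["cbam.spat"]] <- he_conv(7, 2, 1)
    }
    p[["head.c1"]] <- he_conv(3, Csum, config$head_width)
    p[["head.c2"]] <- he_conv(3, config$head_width, 1)
    p[["head.c2"]]$b <- -2
    structure(list(config = config, params = p), class = "vessel_net")
  })
}

#' @export
print.vessel_net <- function(x, ...) {
  cat(sprintf("<vessel_net> %d scale(s), %s trainable parameters\n",
              x$config$n_scales,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars, equal to the closed-form per-layer
#' sums (3^3 conv: `27*in*out + out`; 1x1x1 conv: `in*out + out`; stride-2
#' transposed conv: `8*in*out + out`).  Invariant to input patch size.
#'
#' @param net a [build_network()] result.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, function(l) length(l$w) + length(l$b), numeric(1)))
}

check_patch_shape <- function(config, d) {
  div <- 2^config$n_scales
  if (any(d %% div != 0))
    stop(sprintf("patch shape (%s) must be divisible by %d (2^n_scales; pooling inside LinkConv at the coarsest scale)",
                 paste(d, collapse = "x"), div))
}

# -- layer forwards (each returns list(out, cache)) -------------------------

conv1_fwd <- function(x, p, relu = FALSE) conv1x1_fwd(x, p$w, p$b, relu)

conv1_bwd <- function(x, dy, p) {
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4])
  dym <- matrix(dy, prod(d[1:3]), dim(dy)[4])
  list(dx = array(dym %*% t(p$w), d),
       dw = crossprod(xm, dym), db = colSums(dym))
}

rot_w <- function(w) {
  k <- dim(w)[1]
  aperm(w[k:1, k:1, k:1, , , drop = FALSE], c(1, 2, 3, 5, 4))
}

conv3_bwd_x <- function(dy, p) conv3d_fwd(dy, rot_w(p$w), rep(0, dim(p$w)[4]))

bottle_fwd <- function(x, pre, p, cache) {
  h1 <- conv1_fwd(x, p[[paste0(pre, ".sq")]], relu = TRUE)
  h2 <- conv3d_fwd(h1, p[[paste0(pre, ".core")]]$w,
                  p[[paste0(pre, ".core")]]$b, relu = TRUE)
  h3 <- conv1_fwd(h2, p[[paste0(pre, ".ex")]])
  out <- relu(h3 + x)
  if (!is.null(cache)) { cache[[pre]] <- list(x = x, h1 = h1, h2 = h2, out = out) }
  list(out = out, cache = cache)
}

bottle_bwd <- function(pre, p, cache, dout, grads) {
  cc <- cache[[pre]]
  dsum <- relu_bwd_inplace(dout, cc$out)
  g3 <- conv1_bwd(cc$h2, dsum, p[[paste0(pre, ".ex")]])
  grads[[paste0(pre, ".ex")]] <- list(w = g3$dw, b = g3$db)
  dh2 <- relu_bwd_inplace(g3$dx, cc$h2)
  gw <- conv3d_bwd_w(cc$h1, dh2, 3L)
  grads[[paste0(pre, ".core")]] <- list(w = gw$dw, b = gw$db)
  dh1 <- relu_bwd_inplace(conv3_bwd_x(dh2, p[[paste0(pre, ".core")]]), cc$h1)
  g1 <- conv1_bwd(cc$x, dh1, p[[paste0(pre, ".sq")]])
  grads[[paste0(pre, ".sq")]] <- list(w = g1$dw, b = g1$db)
  list(dx = g1$dx + dsum, grads = grads)
}

plain_fwd <- function(x, name, p, cache) {
  out <- conv3d_fwd(x, p[[name]]$w, p[[name]]$b, relu = TRUE)
  if (!is.null(cache)) cache[[name]] <- list(x = x, out = out)
  list(out = out, cache = cache)
}

plain_bwd <- function(name, p, cache, dout, grads) {
  cc <- cache[[name]]
  dpre <- relu_bwd_inplace(dout, cc$out)
  gw <- conv3d_bwd_w(cc$x, dpre, 3L)
  grads[[name]] <- list(w = gw$dw, b = gw$db)
  list(dx = conv3_bwd_x(dpre, p[[name]]), grads = grads)
}

link_fwd <- function(x, pre, p, cache) {
  dpool <- pool_mean_fwd(x, c(2L, 2L, 2L))
  c1 <- conv3d_fwd(dpool, p[[paste0(pre, ".c1")]]$w,
                  p[[paste0(pre, ".c1")]]$b, relu = TRUE)
  c2 <- conv3d_fwd(c1, p[[paste0(pre, ".c2")]]$w,
                  p[[paste0(pre, ".c2")]]$b, relu = TRUE)
  up <- relu(tconv2_fwd(c2, p[[paste0(pre, ".up")]]$w,
                        p[[paste0(pre, ".up")]]$b))
  cat_ <- abind4(x, up)
  out <- conv3d_fwd(cat_, p[[paste0(pre, ".fuse")]]$w,
                   p[[paste0(pre, ".fuse")]]$b, relu = TRUE)
  if (!is.null(cache))
    cache[[pre]] <- list(x = x, dpool = dpool, c1 = c1, c2 = c2, up = up,
                         cat_ = cat_, out = out)
  list(out = out, cache = cache)
}

link_bwd <- function(pre, p, cache, dout, grads) {
  cc <- cache[[pre]]
  W <- dim(cc$x)[4]
  dpre <- relu_bwd_inplace(dout, cc$out)
  gw <- conv3d_bwd_w(cc$cat_, dpre, 3L)
  grads[[paste0(pre, ".fuse")]] <- list(w = gw$dw, b = gw$db)
  dcat <- conv3_bwd_x(dpre, p[[paste0(pre, ".fuse")]])
  dx_skip <- dcat[, , , seq_len(W), drop = FALSE]
  dup <- relu_bwd_inplace(dcat[, , , W + seq_len(dim(cc$up)[4]), drop = FALSE], cc$up)
  gt <- tconv2_bwd_full(cc$c2, dup, p[[paste0(pre, ".up")]]$w)
  grads[[paste0(pre, ".up")]] <- list(w = gt$dw, b = gt$db)
  dc2 <- relu_bwd_inplace(gt$dx, cc$c2)
  gw2 <- conv3d_bwd_w(cc$c1, dc2, 3L)
  grads[[paste0(pre, ".c2")]] <- list(w = gw2$dw, b = gw2$db)
  dc1 <- relu_bwd_inplace(conv3_bwd_x(dc2, p[[paste0(pre, ".c2")]]), cc$c1)
  gw1 <- conv3d_bwd_w(cc$dpool, dc1, 3L)
  grads[[paste0(pre, ".c1")]] <- list(w = gw1$dw, b = gw1$db)
  ddpool <- conv3_bwd_x(dc1, p[[paste0(pre, ".c1")]])
  dx <- dx_skip + pool_mean_bwd(ddpool, dim(cc$x), c(2L, 2L, 2L))
  list(dx = dx, grads = grads)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

mlp_fwd <- function(s, p) {
  h <- relu(s %*% p[["cbam.mlp1"]]$w + rep(p[["cbam.mlp1"]]$b, each = 1))
  list(out = h %*% p[["cbam.mlp2"]]$w + rep(p[["cbam.mlp2"]]$b, each = 1),
       h = h)  # s, h, out are 1-row matrices
}

cbam_fwd <- function(x, p, cache) {
  d <- dim(x)
  N <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, N, C)
  s_avg <- colMeans(xm)
  imax <- max.col(t(xm))            # row index of max per channel
  s_max <- xm[cbind(imax, seq_len(C))]
  ma <- mlp_fwd(rbind(s_avg), p)
  mm <- mlp_fwd(rbind(s_max), p)
  a <- sigmoid(ma$out + mm$out)     # channel attention, length C
  f1m <- scale_cols(array(xm, c(d[1:3], C)), as.vector(a))
  f1 <- matrix(f1m, N, C)
  m_avg <- rowMeans(f1)
  jmax <- max.col(f1)               # channel index of max per voxel
  m_max <- f1[cbind(seq_len(N), jmax)]
  m2 <- array(c(m_max, m_avg), c(d[1:3], 2))
  sp_pre <- conv3d_fwd(m2, p[["cbam.spat"]]$w, p[["cbam.spat"]]$b)
  A <- sigmoid(as.vector(sp_pre))   # spatial attention, length N
  out <- array(f1 * A, d)
  if (!is.null(cache))
    cache[["cbam"]] <- list(x = x, xm = xm, s_avg = s_avg, s_max = s_max,
                            imax = imax, ma = ma, mm = mm, a = a, f1 = f1,
                            jmax = jmax, m2 = m2, A = A)
  list(out = out, cache = cache)
}

mlp_bwd <- function(s, h, dout, p, grads, acc) {
  dh <- (dout %*% t(p[["cbam.mlp2"]]$w)) * (h > 0)
  g2w <- crossprod(h, dout)
  g1w <- crossprod(s, dh)
  if (acc) {
    grads[["cbam.mlp2"]]$w <- grads[["cbam.mlp2"]]$w + g2w
    grads[["cbam.mlp2"]]$b <- grads[["cbam.mlp2"]]$b + as.vector(dout)
    grads[["cbam.mlp1"]]$w <- grads[["cbam.mlp1"]]$w + g1w
    grads[["cbam.mlp1"]]$b <- grads[["cbam.mlp1"]]$b + as.vector(dh)
  } else {
    grads[["cbam.mlp2"]] <- list(w = g2w, b = as.vector(dout))
    grads[["cbam.mlp1"]] <- list(w = g1w, b = as.vector(dh))
  }
  list(ds = as.vector(dh %*% t(p[["cbam.mlp1"]]$w)), grads = grads)
}

cbam_bwd <- function(p, cache, dout, grads) {
  cc <- cache[["cbam"]]
  d <- dim(cc$x)
  N <- prod(d[1:3]); C <- d[4]
  dom <- matrix(dout, N, C)
  # spatial attention
  df1 <- dom * cc$A
  dA <- rowSums(dom * cc$f1)
  dsp <- dA * cc$A * (1 - cc$A)
  dsp_arr <- array(dsp, c(d[1:3], 1))
  gsp <- conv3d_bwd_w(cc$m2, dsp_arr, 7L)
  grads[["cbam.spat"]] <- list(w = gsp$dw, b = gsp$db)
  dm2 <- conv3_bwd_x(dsp_arr, p[["cbam.spat"]])
  dm_max <- as.vector(dm2[, , , 1])
  dm_avg <- as.vector(dm2[, , , 2])
  df1 <- df1 + dm_avg / C
  df1[cbind(seq_len(N), cc$jmax)] <-
    df1[cbind(seq_len(N), cc$jmax)] + dm_max
  # channel attention
  dxm <- sweep(df1, 2, cc$a, "*")
  da <- colSums(df1 * cc$xm)
  dz <- da * cc$a * (1 - cc$a)
  ra <- mlp_bwd(rbind(cc$s_avg), cc$ma$h, rbind(dz), p, grads, acc = FALSE)
  rm_ <- mlp_bwd(rbind(cc$s_max), cc$mm$h, rbind(dz), p, ra$grads, acc = TRUE)
  grads <- rm_$grads
  dxm <- dxm + matrix(ra$ds / N, N, C, byrow = TRUE)
  dxm[cbind(cc$imax, seq_len(C))] <-
    dxm[cbind(cc$imax, seq_len(C))] + rm_$ds
  list(dx = array(dxm, d), grads = grads)
}

#' Forward pass of the network
#'
#' @param net a [build_network()] result.
#' @param x 3D image block `(z, y, x)` with intensities in `[0, 1]` (see
#'   [predict_block()] for normalization), or a `(z, y, x, 1)` array.
#' @param cache keep intermediate activations for backpropagation.
#' @return `list(prob = <(z,y,x) array in (0,1)>, logit, cache)`.
#' @export
net_forward <- function(net, x, cache = FALSE) {
  cfg <- net$config
  p <- net$params
  x <- as.array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_patch_shape(cfg, dim(x)[1:3])
  cc <- if (cache) list() else NULL
  branches <- vector("list", cfg$n_scales)
  for (s in seq_len(cfg$n_scales)) {
    pre <- sprintf("s%d", s)
    xp <- if (s > 1) pool_mean_fwd(x, rep(2L^(s - 1), 3)) else x
    a0 <- conv3d_fwd(xp, p[[paste0(pre, ".in")]]$w,
                  p[[paste0(pre, ".in")]]$b, relu = TRUE)
    if (cache) cc[[paste0(pre, ".in")]] <- list(x = xp, out = a0)
    if (cfg$use_bottleconv) {
      r1 <- bottle_fwd(a0, paste0(pre, ".b1"), p, cc); a1 <- r1$out; cc <- r1$cache
    } else {
      r1 <- plain_fwd(a0, paste0(pre, ".b1.plain"), p, cc); a1 <- r1$out; cc <- r1$cache
    }
    if (cfg$use_linkconv) {
      r2 <- link_fwd(a1, paste0(pre, ".lk"), p, cc); a2 <- r2$out; cc <- r2$cache
    } else {
      r2 <- plain_fwd(a1, paste0(pre, ".lk.plain"), p, cc); a2 <- r2$out; cc <- r2$cache
    }
    if (cfg$use_bottleconv) {
      r3 <- bottle_fwd(a2, paste0(pre, ".b2"), p, cc); a3 <- r3$out; cc <- r3$cache
    } else {
      r3 <- plain_fwd(a2, paste0(pre, ".b2.plain"), p, cc); a3 <- r3$out; cc <- r3$cache
    }
    if (s > 1) for (j in seq_len(s - 1)) {
      nm <- sprintf("%s.up%d", pre, j)
      a3in <- a3
      a3 <- relu(tconv2_fwd(a3, p[[nm]]$w, p[[nm]]$b))
      if (cache) cc[[nm]] <- list(x = a3in, out = a3)
    }
    branches[[s]] <- a3
  }
  feat <- Reduce(abind4, branches)
  if (cache) cc[["concat.widths"]] <- vapply(branches, function(b) dim(b)[4], integer(1))
  if (cfg$use_cbam) {
    rc <- cbam_fwd(feat, p, cc); f2 <- rc$out; cc <- rc$cache
  } else f2 <- feat
  h <- conv3d_fwd(f2, p[["head.c1"]]$w, p[["head.c1"]]$b, relu = TRUE)
  if (cache) cc[["head.c1"]] <- list(x = f2, out = h)
  logit <- conv3d_fwd(h, p[["head.c2"]]$w, p[["head.c2"]]$b)
  if (cache) cc[["head.c2"]] <- list(x = h)
  prob <- sigmoid(array(logit, dim(logit)[1:3]))
  list(prob = prob, logit = logit, cache = cc)
}

# Backward pass: gradient of the loss w.r.t. every parameter, given the
# gradient w.r.t. the logit map.  Returns a flat named list mirroring
# net$params.
net_backward <- function(net, cache, dlogit) {
  cfg <- net$config
  p <- net$params
  grads <- list()
  if (length(dim(dlogit)) == 3) dim(dlogit) <- c(dim(dlogit), 1L)
  g2 <- conv3d_bwd_w(cache[["head.c2"]]$x, dlogit, 3L)
  grads[["head.c2"]] <- list(w = g2$dw, b = g2$db)
  dh <- relu_bwd_inplace(conv3_bwd_x(dlogit, p[["head.c2"]]), cache[["head.c1"]]$out)
  g1 <- conv3d_bwd_w(cache[["head.c1"]]$x, dh, 3L)
  grads[["head.c1"]] <- list(w = g1$dw, b = g1$db)
  dfeat <- conv3_bwd_x(dh, p[["head.c1"]])
  if (cfg$use_cbam) {
    rb <- cbam_bwd(p, cache, dfeat, grads)
    dfeat <- rb$dx; grads <- rb$grads
  }
  widths <- cache[["concat.widths"]]
  off <- 0
  for (s in seq_len(cfg$n_scales)) {
    pre <- sprintf("s%d", s)
    dbr <- dfeat[, , , off + seq_len(widths[s]), drop = FALSE]
    off <- off + widths[s]
    if (s > 1) for (j in rev(seq_len(s - 1))) {
      nm <- sprintf("%s.up%d", pre, j)
      ccu <- cache[[nm]]
      dbr <- relu_bwd_inplace(dbr, ccu$out)
      gt <- tconv2_bwd_full(ccu$x, dbr, p[[nm]]$w)
      grads[[nm]] <- list(w = gt$dw, b = gt$db)
      dbr <- gt$dx
    }
    if (cfg$use_bottleconv) {
      r3 <- bottle_bwd(paste0(pre, ".b2"), p, cache, dbr, grads)
    } else r3 <- plain_bwd(paste0(pre, ".b2.plain"), p, cache, dbr, grads)
    grads <- r3$grads
    if (cfg$use_linkconv) {
      r2 <- link_bwd(paste0(pre, ".lk"), p, cache, r3$dx, grads)
    } else r2 <- plain_bwd(paste0(pre, ".lk.plain"), p, cache, r3$dx, grads)
    grads <- r2$grads
    if (cfg$use_bottleconv) {
      r1 <- bottle_bwd(paste0(pre, ".b1"), p, cache, r2$dx, grads)
    } else r1 <- plain_bwd(paste0(pre, ".b1.plain"), p, cache, r2$dx, grads)
    grads <- r1$grads
    cci <- cache[[paste0(pre, ".in")]]
    din <- relu_bwd_inplace(r1$dx, cci$out)
    gi <- conv3d_bwd_w(cci$x, din, 3L)
    grads[[paste0(pre, ".in")]] <- list(w = gi$dw, b = gi$db)
    # input is data; no gradient needed below this point
  }
  grads
}

#' Predict a binary mask for one or more image blocks
#'
#' Each block is min-max normalized to `[0, 1]`, passed through the
#' network, and thresholded.  Blocks are processed independently, so
#' batching can never change results.
#'
#' @param net a trained (or freshly built) `vessel_net`.
#' @param blocks a 3D array or a list of 3D arrays.
#' @param threshold binarization threshold on the sigmoid output
#'   (default 0.5).
#' @return A binary integer array (or list of them) with values in
#'   \{0, 1\}.
#' @export
predict_block <- function(net, blocks, threshold = 0.5) {
  one <- function(b) {
    b <- normalize_block(as.array(voxels_of(b)))
    pr <- net_forward(net, b)$prob
    array(as.integer(pr >= threshold), dim(pr))
  }
  if (is.list(blocks) && !inherits(blocks, "volume_stack"))
    lapply(blocks, one)
  else one(blocks)
}

#' Save a weight checkpoint
#'
#' The checkpoint embeds the architecture configuration and a schema
#' version alongside the weights.
#'
#' @param net a `vessel_net`.
#' @param path output file.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(schema = 1L, config = net$config, params = net$params), path)
  invisible(path)
}

#' Load a weight checkpoint
#' @param path a file written by [save_checkpoint()].
#' @return A `vessel_net`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schema) || ck$schema != 1L)
    stop("unrecognized checkpoint schema in ", path)
  structure(list(config = ck$config, params = ck$params),
            class = "vessel_net")
}
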