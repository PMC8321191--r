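#' Mixed-scale dense network configuration
#'
#' A densely connected segmentation CNN: every layer applies 3x3 dilated
#' convolutions over the input and all previous feature maps, with the
#' dilation cycling over `dilations` along the depth, followed by ReLU.
#' The final layer is a 1x1 convolution over all maps to `n_classes`
#' channels followed by a per-pixel softmax. Width `w` feature maps per
#' layer (the classic choice is `w = 1`).
#'
#' @param depth Number of dilated layers (full-scale default 100).
#' @param width Feature maps per layer (default 1).
#' @param dilations Dilation cycle (default 1:10).
#' @param n_classes Number of output classes.
#' @param in_channels Number of input channels.
#' @return An `msd_config`.
#' @export
msd_config <- function(depth = 100L, width = 1L, dilations = 1:10,
                       n_classes = 2L, in_channels = 2L) {
  if (depth < 1 || width < 1 || any(dilations < 1))
    stop("depth, width and dilations must be positive")
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 dilations = as.integer(dilations),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "msd_config")
}

#' U-Net configuration
#'
#' Two-level encoder/decoder: 3x3 zero-padded convolutions (each followed
#' by ReLU), 2x2 max-pool downsampling with stride 2 applied twice,
#' bilinear upsampling, and skip concatenations. With base width `c1` the
#' channel schedule is `c2 = c5 = 2*c1`, `c3 = 4*c1`, `c4 = 6*c1`
#' (= c3 + c2 after concatenation), `c6 = 3*c1` (= c5 + c1) and `c7 = c1`,
#' ending in a 1x1 convolution to `n_classes` plus softmax. Input spatial
#' dimensions must be divisible by 4.
#'
#' @param c1 Base channel count (full-scale default 128).
#' @param n_classes Number of output classes.
#' @param in_channels Number of input channels.
#' @return A `unet_config`.
#' @export
unet_config <- function(c1 = 128L, n_classes = 2L, in_channels = 2L) {
  if (c1 < 1) stop("c1 must be >= 1")
  c1 <- as.integer(c1)
  structure(list(c1 = c1, c2 = 2L * c1, c3 = 4L * c1, c4 = 6L * c1,
                 c5 = 2L * c1, c6 = 3L * c1, c7 = c1,
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "unet_config")
}

msd_dilation <- function(config, i) {
  config$dilations[(i - 1L) %% length(config$dilations) + 1L]
}

#' Initialize backbone parameters
#'
#' MSD: Xavier (Glorot-normal) convolution weights, all biases zero.
#' U-Net: weights and biases uniform on `(-k, k)` with
#' `k = 1 / sqrt(c_in * a^2)` for kernel size `a` (the standard fan-in
#' bound). Deterministic given the seed.
#'
#' @param config An `msd_config` or `unet_config`.
#' @param kind `"msd"` or `"unet"`.
#' @param seed Integer seed.
#' @return `backbone_params` for the matching forward pass.
#' @export
init_backbone <- function(config, kind = c("msd", "unet"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "msd") {
    stopifnot(inherits(config, "msd_config"))
    withr::with_seed(seed, {
      c0 <- config$in_channels; w <- config$width
      layers <- lapply(seq_len(config$depth), function(i) {
        cin <- c0 + (i - 1L) * w
        fan_in <- 9 * cin; fan_out <- 9 * w
        W <- array(stats::rnorm(9 * cin * w,
                                sd = sqrt(2 / (fan_in + fan_out))),
                   dim = c(3, 3, cin, w))
        list(W = W, b = numeric(w))
      })
      ctot <- c0 + config$depth * w
      fin <- list(W = matrix(stats::rnorm(ctot * config$n_classes,
                                          sd = sqrt(2 / (ctot + config$n_classes))),
                             ctot, config$n_classes),
                  b = numeric(config$n_classes))
      structure(list(kind = "msd", layers = layers, final = fin),
                class = "backbone_params")
    })
  } else {
    stopifnot(inherits(config, "unet_config"))
    withr::with_seed(seed, {
      mk3 <- function(cin, cout) {
        k <- 1 / sqrt(cin * 9)
        list(W = array(stats::runif(9 * cin * cout, -k, k),
                       dim = c(3, 3, cin, cout)),
             b = stats::runif(cout, -k, k))
      }
      cfg <- config
      fin_k <- 1 / sqrt(cfg$c7)
      structure(list(
        kind = "unet",
        enc1 = mk3(cfg$in_channels, cfg$c1),
        enc2 = mk3(cfg$c1, cfg$c2),
        enc3 = mk3(cfg$c2, cfg$c3),
        dec1 = mk3(cfg$c4, cfg$c5),
        dec2 = mk3(cfg$c6, cfg$c7),
        final = list(W = matrix(stats::runif(cfg$c7 * cfg$n_classes,
                                             -fin_k, fin_k),
                                cfg$c7, cfg$n_classes),
                     b = stats::runif(cfg$n_classes, -fin_k, fin_k))),
        class = "backbone_params")
    })
  }
}

softmax_rows <- function(pre) {
  m <- pre - apply(pre, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Mixed-scale dense network forward pass
#'
#' @param x `(H, W, in_channels)` input array.
#' @param params `backbone_params` from [init_backbone()].
#' @param config The matching `msd_config`.
#' @return `(H, W, n_classes)` per-pixel class probabilities (softmax; each
#'   pixel sums to 1).
#' @export
msd_forward <- function(x, params, config) {
  msd_fw_cache(x, params, config)$prob
}

msd_fw_cache <- function(x, params, config) {
  d <- dim(x)
  if (length(d) != 3 || d[3] != config$in_channels)
    stop(sprintf("input has %s channels; config expects %d",
                 if (length(d) == 3) d[3] else "?", config$in_channels))
  H <- d[1]; W <- d[2]
  c0 <- config$in_channels; w <- config$width
  ctot <- c0 + config$depth * w
  stack <- array(0, c(H, W, ctot))
  stack[, , seq_len(c0)] <- x
  msd_fw_cpp(stack, H, W, c0, w,
             lapply(params$layers, `[[`, "W"),
             matrix(unlist(lapply(params$layers, `[[`, "b")), nrow = w),
             config$dilations)
  s <- matrix(stack, H * W, ctot)
  pre <- sweep(s %*% params$final$W, 2, params$final$b, "+")
  p <- softmax_rows(pre)
  list(prob = array(p, c(H, W, config$n_classes)), stack = stack,
       pflat = p, H = H, W = W)
}

# dpre: (H*W) x n_classes gradient w.r.t. the pre-softmax logits
msd_bw <- function(cache, params, config, dpre) {
  H <- cache$H; W <- cache$W
  c0 <- config$in_channels; w <- config$width
  ctot <- c0 + config$depth * w
  s <- matrix(cache$stack, H * W, ctot)
  dfin <- list(W = t(s) %*% dpre, b = colSums(dpre))
  g <- array(dpre %*% t(params$final$W), c(H, W, ctot))
  gr <- msd_bw_cpp(cache$stack, g, H, W, c0, w,
                   lapply(params$layers, `[[`, "W"), config$dilations)
  dlayers <- lapply(seq_len(config$depth), function(i)
    list(W = gr$dWs[[i]], b = gr$dbs[, i]))
  list(layers = dlayers, final = dfin,
       dinput = g[, , seq_len(c0), drop = FALSE])
}

cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

#' U-Net forward pass
#'
#' @param x `(H, W, in_channels)` input array; `H` and `W` divisible by 4.
#' @param params `backbone_params` from [init_backbone()].
#' @param config The matching `unet_config`.
#' @return `(H, W, n_classes)` per-pixel class probabilities.
#' @export
unet_forward <- function(x, params, config) {
  unet_fw_cache(x, params, config)$prob
}

unet_fw_cache <- function(x, params, config) {
  d <- dim(x)
  if (length(d) != 3 || d[3] != config$in_channels)
    stop("input channel count does not match config")
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0)
    stop("spatial dimensions must be divisible by 4")
  relu <- function(a) pmax(a, 0)
  z1 <- relu(conv3x3_fw(x, params$enc1$W, params$enc1$b, 1L))
  p1 <- maxpool2_fw(z1)
  z2 <- relu(conv3x3_fw(p1$y, params$enc2$W, params$enc2$b, 1L))
  p2 <- maxpool2_fw(z2)
  z3 <- relu(conv3x3_fw(p2$y, params$enc3$W, params$enc3$b, 1L))
  u1 <- upsample2_fw(z3)
  c4 <- cat3(u1, z2)
  z4 <- relu(conv3x3_fw(c4, params$dec1$W, params$dec1$b, 1L))
  u2 <- upsample2_fw(z4)
  c6 <- cat3(u2, z1)
  z5 <- relu(conv3x3_fw(c6, params$dec2$W, params$dec2$b, 1L))
  H <- d[1]; W <- d[2]
  s <- matrix(z5, H * W, config$c7)
  pre <- sweep(s %*% params$final$W, 2, params$final$b, "+")
  p <- softmax_rows(pre)
  list(prob = array(p, c(H, W, config$n_classes)), pflat = p,
       x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2, z3 = z3,
       c4 = c4, z4 = z4, c6 = c6, z5 = z5, H = H, W = W)
}

unet_bw <- function(cache, params, config, dpre) {
  H <- cache$H; W <- cache$W
  s <- matrix(cache$z5, H * W, config$c7)
  dfin <- list(W = t(s) %*% dpre, b = colSums(dpre))
  dz5 <- array(dpre %*% t(params$final$W), c(H, W, config$c7)) *
    (cache$z5 > 0)
  g5 <- conv3x3_bw_weights(cache$c6, dz5, 1L)
  dc6 <- conv3x3_bw_input(dz5, params$dec2$W, 1L)
  du2 <- dc6[, , seq_len(config$c5), drop = FALSE]
  dz1_skip <- dc6[, , config$c5 + seq_len(config$c1), drop = FALSE]
  dz4 <- upsample2_bw(du2) * (cache$z4 > 0)
  g4 <- conv3x3_bw_weights(cache$c4, dz4, 1L)
  dc4 <- conv3x3_bw_input(dz4, params$dec1$W, 1L)
  du1 <- dc4[, , seq_len(config$c3), drop = FALSE]
  dz2_skip <- dc4[, , config$c3 + seq_len(config$c2), drop = FALSE]
  dz3 <- upsample2_bw(du1) * (cache$z3 > 0)
  g3 <- conv3x3_bw_weights(cache$p2$y, dz3, 1L)
  dp2 <- conv3x3_bw_input(dz3, params$enc3$W, 1L)
  dz2 <- (maxpool2_bw(dp2, cache$p2$idx) + dz2_skip) * (cache$z2 > 0)
  g2 <- conv3x3_bw_weights(cache$p1$y, dz2, 1L)
  dp1 <- conv3x3_bw_input(dz2, params$enc2$W, 1L)
  dz1 <- (maxpool2_bw(dp1, cache$p1$idx) + dz1_skip) * (cache$z1 > 0)
  g1 <- conv3x3_bw_weights(cache$x, dz1, 1L)
  dx <- conv3x3_bw_input(dz1, params$enc1$W, 1L)
  list(enc1 = list(W = g1$dw, b = g1$db),
       enc2 = list(W = g2$dw, b = g2$db),
       enc3 = list(W = g3$dw, b = g3$db),
       dec1 = list(W = g4$dw, b = g4$db),
       dec2 = list(W = g5$dw, b = g5$db),
       final = dfin, dinput = dx)
}

#' Total number of trainable scalars in backbone parameters
#' @param params `backbone_params`.
#' @return Integer count.
#' @export
backbone_param_count <- function(params) {
  n <- 0
  count <- function(l) length(l$W) + length(l$b)
  if (params$kind == "msd") {
    for (l in params$layers) n <- n + count(l)
    n + count(params$final)
  } else {
    sum(vapply(params[c("enc1", "enc2", "enc3", "dec1", "dec2", "final")],
               count, numeric(1)))
  }
}
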