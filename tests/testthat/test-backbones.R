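test_that("MSD outputs per-pixel probabilities and w=1 map growth", {
  cfg <- msd_config(depth = 6, n_classes = 3, in_channels = 2)
  bb <- init_backbone(cfg, "msd", seed = 2)
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  cache <- hyperdr:::msd_fw_cache(x, bb, cfg)
  expect_equal(dim(cache$prob), c(12, 12, 3))
  sums <- apply(cache$prob, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 144), tolerance = 1e-6)
  # width 1: exactly depth single-channel intermediate maps
  expect_equal(dim(cache$stack)[3], 2 + 6)
  expect_length(bb$layers, 6)
  for (l in bb$layers) expect_equal(dim(l$W)[4], 1)
})

test_that("all-zero convolution weights give uniform class probabilities", {
  cfg <- msd_config(depth = 3, n_classes = 4, in_channels = 2)
  bb <- init_backbone(cfg, "msd", seed = 1)
  for (i in seq_along(bb$layers)) bb$layers[[i]]$W[] <- 0
  bb$final$W[] <- 0
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  p <- msd_forward(x, bb, cfg)
  expect_equal(as.vector(p), rep(0.25, 8 * 8 * 4), tolerance = 1e-12)
})

test_that("MSD initialization: zero biases, Xavier weights, seeded", {
  cfg <- msd_config(depth = 5, n_classes = 2, in_channels = 3)
  a <- init_backbone(cfg, "msd", seed = 9)
  b <- init_backbone(cfg, "msd", seed = 9)
  expect_identical(a, b)
  c <- init_backbone(cfg, "msd", seed = 10)
  expect_false(identical(a, c))
  for (l in a$layers) expect_true(all(l$b == 0))
  expect_true(all(a$final$b == 0))
})

test_that("MSD receptive field is bounded by accumulated dilations", {
  cfg <- msd_config(depth = 3, dilations = c(1, 2, 3), n_classes = 2,
                    in_channels = 1)
  bb <- init_backbone(cfg, "msd", seed = 3)
  x <- withr::with_seed(30, array(rnorm(24 * 24), c(24, 24, 1)))
  p0 <- msd_forward(x, bb, cfg)
  # accumulated radius = 1 + 2 + 3 = 6; a perturbation 15 pixels away from
  # the probe pixel cannot change its output
  x2 <- x
  x2[23, 23, 1] <- x2[23, 23, 1] + 100
  p1 <- msd_forward(x2, bb, cfg)
  expect_equal(p1[8, 8, ], p0[8, 8, ], tolerance = 1e-12)
  # but a perturbation just next to the probe does
  x3 <- x
  x3[8, 9, 1] <- x3[8, 9, 1] + 100
  p2 <- msd_forward(x3, bb, cfg)
  expect_gt(max(abs(p2[8, 8, ] - p0[8, 8, ])), 1e-8)
})

test_that("MSD dense connectivity: every layer feeds the output", {
  cfg <- msd_config(depth = 5, n_classes = 2, in_channels = 1)
  bb <- init_backbone(cfg, "msd", seed = 4)
  x <- array(rnorm(16 * 16), c(16, 16, 1))
  p0 <- msd_forward(x, bb, cfg)
  for (l in 1:5) {
    # zero out every connection reading map l (in later convs and the
    # final layer): the output must change
    bb2 <- bb
    ch <- 1 + l      # map l sits at channel 1 + l of the stack
    for (m in seq(l + 1, 5)) {
      if (m > 5) break
      bb2$layers[[m]]$W[, , ch, ] <- 0
    }
    bb2$final$W[ch, ] <- 0
    p1 <- msd_forward(x, bb2, cfg)
    expect_false(isTRUE(all.equal(p1, p0)),
                 info = sprintf("ablating layer %d", l))
  }
})

test_that("U-Net channel schedule follows the c1 relations", {
  cfg <- unet_config(c1 = 128)
  expect_equal(cfg$c2, 256)
  expect_equal(cfg$c3, 512)
  expect_equal(cfg$c4, 768)
  expect_equal(cfg$c5, 256)
  expect_equal(cfg$c6, 384)
  expect_equal(cfg$c7, 128)
  expect_equal(cfg$c4, cfg$c3 + cfg$c2)   # concat consistency
  expect_equal(cfg$c6, cfg$c5 + cfg$c1)
})

test_that("U-Net outputs probabilities at the input resolution", {
  cfg <- unet_config(c1 = 4, n_classes = 3, in_channels = 2)
  bb <- init_backbone(cfg, "unet", seed = 5)
  x <- array(rnorm(16 * 20 * 2), c(16, 20, 2))
  p <- unet_forward(x, bb, cfg)
  expect_equal(dim(p), c(16, 20, 3))
  expect_equal(as.vector(apply(p, c(1, 2), sum)), rep(1, 320),
               tolerance = 1e-6)
  expect_error(unet_forward(array(0, c(10, 12, 2)), bb, cfg),
               "divisible by 4")
})

test_that("U-Net init bounds weights and biases by the fan-in rule", {
  cfg <- unet_config(c1 = 8, n_classes = 2, in_channels = 3)
  bb <- init_backbone(cfg, "unet", seed = 6)
  k1 <- 1 / sqrt(3 * 9)
  expect_true(all(abs(bb$enc1$W) < k1))
  expect_true(all(abs(bb$enc1$b) < k1))
  k2 <- 1 / sqrt(cfg$c1 * 9)
  expect_true(all(abs(bb$enc2$W) < k2))
  expect_identical(bb, init_backbone(cfg, "unet", seed = 6))
})

test_that("backbone parameter counts match closed forms", {
  d <- 7; c0 <- 3; nc <- 2
  cfg <- msd_config(depth = d, n_classes = nc, in_channels = c0)
  bb <- init_backbone(cfg, "msd", seed = 1)
  # each layer i: 9 * (c0 + i - 1) weights + 1 bias; final: (c0+d)*nc + nc
  expected <- sum(sapply(seq_len(d), function(i) 9 * (c0 + i - 1) + 1)) +
    (c0 + d) * nc + nc
  expect_equal(backbone_param_count(bb), expected)

  ucfg <- unet_config(c1 = 4, n_classes = 3, in_channels = 2)
  ub <- init_backbone(ucfg, "unet", seed = 1)
  conv_n <- function(ci, co) 9 * ci * co + co
  expected_u <- conv_n(2, 4) + conv_n(4, 8) + conv_n(8, 16) +
    conv_n(24, 8) + conv_n(12, 4) + (4 * 3 + 3)
  expect_equal(backbone_param_count(ub), expected_u)
})

test_that("backbones are translation-covariant away from boundaries", {
  shift4 <- function(a) {
    d <- dim(a)
    out <- array(0, d)
    out[5:d[1], 5:d[2], ] <- a[1:(d[1] - 4), 1:(d[2] - 4), ]
    out
  }
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  xs <- shift4(x)

  cfg <- msd_config(depth = 4, dilations = 1:2, n_classes = 2,
                    in_channels = 2)
  bb <- init_backbone(cfg, "msd", seed = 7)
  p <- msd_forward(x, bb, cfg)
  ps <- msd_forward(xs, bb, cfg)
  m <- 25:40   # interior window well clear of the boundary effects
  expect_equal(ps[m + 4, m + 4, ], p[m, m, ], tolerance = 1e-5)

  ucfg <- unet_config(c1 = 4, n_classes = 2, in_channels = 2)
  ub <- init_backbone(ucfg, "unet", seed = 8)
  q <- unet_forward(x, ub, ucfg)
  qs <- unet_forward(xs, ub, ucfg)
  expect_equal(qs[m + 4, m + 4, ], q[m, m, ], tolerance = 1e-5)
})

test_that("analytic gradients match numeric differentiation end to end", {
  withr::with_seed(11, {
    H <- 6; W <- 6; B <- 4; Nc <- 2
    cube <- array(runif(H * W * B), c(H, W, B))
    lab <- matrix(sample(0:1, H * W, TRUE), H, W)
    yflat <- matrix(one_hot(lab, Nc), H * W, Nc)
    sch <- reduction_scheme(c(B, 2))
    red <- init_reduction(sch, mode = "xavier", seed = 3)
    cfg <- msd_config(depth = 3, n_classes = Nc, in_channels = 2)
    bb <- init_backbone(cfg, "msd", seed = 5)
    loss_of <- function() {
      rc <- hyperdr:::reduction_fw_cache(matrix(cube, H * W, B), red)
      cache <- hyperdr:::msd_fw_cache(array(rc$z, c(H, W, 2)), bb, cfg)
      hyperdr:::ce_loss_grad(cache$pflat, yflat)$loss
    }
    rc <- hyperdr:::reduction_fw_cache(matrix(cube, H * W, B), red)
    cache <- hyperdr:::msd_fw_cache(array(rc$z, c(H, W, 2)), bb, cfg)
    lg <- hyperdr:::ce_loss_grad(cache$pflat, yflat)
    bg <- hyperdr:::msd_bw(cache, bb, cfg, lg$dpre)
    rg <- hyperdr:::reduction_bw(rc, red, matrix(bg$dinput, H * W, 2))
    eps <- 1e-6
    check_slot <- function(get, set, ana, n = 4) {
      for (k in seq_len(n)) {
        v <- get(); i <- sample(length(v), 1)
        v2 <- v; v2[i] <- v[i] + eps; set(v2); up <- loss_of()
        v2[i] <- v[i] - eps; set(v2); dn <- loss_of()
        set(v)
        expect_equal((up - dn) / (2 * eps), ana[i], tolerance = 1e-4)
      }
    }
    check_slot(function() bb$layers[[2]]$W,
               function(v) bb$layers[[2]]$W <<- v, bg$layers[[2]]$W)
    check_slot(function() bb$final$W,
               function(v) bb$final$W <<- v, bg$final$W)
    check_slot(function() red$layers[[1]]$W,
               function(v) red$layers[[1]]$W <<- v, rg$layers[[1]]$W)

    # U-Net with the BCE+dice loss (dims divisible by 4)
    ucube <- array(runif(8 * 8 * B), c(8, 8, B))
    ulab <- matrix(sample(0:1, 64, TRUE), 8, 8)
    uyflat <- matrix(one_hot(ulab, Nc), 64, Nc)
    ucfg <- unet_config(c1 = 3, n_classes = Nc, in_channels = B)
    ub <- init_backbone(ucfg, "unet", seed = 7)
    uloss <- function() {
      c2 <- hyperdr:::unet_fw_cache(ucube, ub, ucfg)
      hyperdr:::bce_dice_loss_grad(c2$pflat, uyflat)$loss
    }
    c2 <- hyperdr:::unet_fw_cache(ucube, ub, ucfg)
    lg2 <- hyperdr:::bce_dice_loss_grad(c2$pflat, uyflat)
    ug <- hyperdr:::unet_bw(c2, ub, ucfg, lg2$dpre)
    for (nm in c("enc2", "dec1", "final")) {
      v <- ub[[nm]]$W; ana <- ug[[nm]]$W
      for (k in 1:3) {
        i <- sample(length(v), 1)
        v2 <- v; v2[i] <- v[i] + eps; ub[[nm]]$W <- v2; up <- uloss()
        v2[i] <- v[i] - eps; ub[[nm]]$W <- v2; dn <- uloss()
        ub[[nm]]$W <- v
        expect_equal((up - dn) / (2 * eps), ana[i], tolerance = 1e-4)
      }
    }
  })
})
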