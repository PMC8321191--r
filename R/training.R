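#' One-hot encoding of a label map
#'
#' @param labels `(H, W)` integer matrix with values in `0..n_classes-1`.
#' @param n_classes Number of classes.
#' @return `(H, W, n_classes)` indicator array; channel `c+1` is 1 exactly
#'   where the label is `c`.
#' @export
one_hot <- function(labels, n_classes) {
  if (any(labels < 0 | labels >= n_classes))
    stop("labels out of range for n_classes")
  H <- nrow(labels); W <- ncol(labels)
  out <- array(0, c(H, W, n_classes))
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)),
               as.vector(labels) + 1L)
  out[idx] <- 1
  out
}

# deterministic per-pixel argmax (ties toward the lowest class index)
argmax_labels <- function(prob) {
  d <- dim(prob)
  pm <- matrix(prob, d[1] * d[2], d[3])
  matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
}

rot90_arr <- function(a, k = 1L) {
  # counter-clockwise rotation of (H, W) or (H, W, C)
  k <- k %% 4L
  if (k == 0L) return(a)
  m <- if (is.matrix(a)) array(a, c(dim(a), 1)) else a
  d <- dim(m)
  out <- m
  for (i in seq_len(k)) {
    d <- dim(out)
    res <- array(0, c(d[2], d[1], d[3]))
    for (c in seq_len(d[3]))
      res[, , c] <- t(out[, , c, drop = TRUE])[d[2]:1, , drop = FALSE]
    out <- res
  }
  if (is.matrix(a)) out[, , 1] else out
}

flip_h_arr <- function(a) {
  if (is.matrix(a)) return(a[, ncol(a):1, drop = FALSE])
  a[, dim(a)[2]:1, , drop = FALSE]
}

#' Eight-fold dihedral augmentation
#'
#' Applies the 8 symmetries of the square (4 rotations, each optionally
#' horizontally flipped) identically to every cube and its label map; 70
#' training images become 560.
#'
#' @param cubes List of square `(H, H, C)` arrays.
#' @param labels List of matching `(H, H)` label matrices.
#' @return List with the augmented `cubes` and `labels` (length 8x input,
#'   identity transform first).
#' @export
dihedral_augment <- function(cubes, labels) {
  stopifnot(length(cubes) == length(labels))
  for (cb in cubes)
    if (dim(cb)[1] != dim(cb)[2]) stop("augmentation requires square images")
  out_c <- vector("list", 8L * length(cubes))
  out_l <- vector("list", 8L * length(cubes))
  k <- 0L
  for (i in seq_along(cubes)) {
    for (rot in 0:3) {
      for (flip in c(FALSE, TRUE)) {
        k <- k + 1L
        cb <- rot90_arr(cubes[[i]], rot)
        lb <- rot90_arr(labels[[i]], rot)
        if (flip) { cb <- flip_h_arr(cb); lb <- flip_h_arr(lb) }
        out_c[[k]] <- cb
        out_l[[k]] <- lb
      }
    }
  }
  list(cubes = out_c, labels = out_l)
}

# --- losses (operate on flat (npix x Nc) probabilities) -------------------

ce_loss_grad <- function(p, y) {
  n <- nrow(p)
  loss <- -sum(y * log(pmax(p, 1e-12))) / n
  list(loss = loss, dpre = (p - y) / n)
}

bce_dice_loss_grad <- function(p, y) {
  n <- nrow(p); nc <- ncol(p)
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -sum(y * log(pc) + (1 - y) * log(1 - pc)) / (n * nc)
  g_bce <- -(y / pc - (1 - y) / (1 - pc)) / (n * nc)
  sp <- colSums(p); sy <- colSums(y); spy <- colSums(p * y)
  deps <- 1e-7
  dice <- 1 - mean((2 * spy + deps) / (sp + sy + deps))
  g_dice <- -(2 * sweep(y, 2, sp + sy + deps, "*") -
                matrix(2 * spy + deps, n, nc, byrow = TRUE)) /
    matrix((sp + sy + deps)^2, n, nc, byrow = TRUE) / nc
  g <- (g_bce + g_dice) / 2
  # chain through the softmax
  dpre <- p * (g - rowSums(g * p))
  list(loss = (bce + dice) / 2, dpre = dpre)
}

loss_fn <- function(name) {
  switch(name,
         cross_entropy = ce_loss_grad,
         bce_plus_dice = bce_dice_loss_grad,
         stop("unknown loss: ", name))
}

# --- ADAM over nested parameter lists -------------------------------------

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- map2_params(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

zeros_like <- function(a) {
  if (is.list(a)) lapply(a, zeros_like) else a * 0
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# global-norm gradient clipping over a nested parameter list
sumsq_params <- function(g) {
  if (is.list(g)) sum(vapply(g, sumsq_params, numeric(1))) else sum(g * g)
}


adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads,
                         function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads,
                         function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) /
                       (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# --- metrics ---------------------------------------------------------------

#' Average class accuracy
#'
#' Mean over the classes present in the ground truth of the per-class
#' recall `TP_c / (TP_c + FN_c)`; classes absent from the truth are
#' excluded from the mean. Equals 1 exactly when the prediction matches
#' the truth on every pixel of every present class; a constant one-class
#' prediction scores `1/|C|`.
#'
#' @param pred,truth Integer label matrices of identical shape.
#' @return Accuracy in `[0, 1]`.
#' @export
average_class_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  cls <- sort(unique(as.vector(truth)))
  recalls <- vapply(cls, function(c) {
    inc <- truth == c
    sum(pred[inc] == c) / sum(inc)
  }, numeric(1))
  mean(recalls)
}

confusion_counts <- function(pred, truth, n_classes) {
  tp <- fn <- numeric(n_classes)
  for (c in seq_len(n_classes) - 1L) {
    inc <- truth == c
    tp[c + 1L] <- sum(pred[inc] == c)
    fn[c + 1L] <- sum(inc) - tp[c + 1L]
  }
  list(tp = tp, fn = fn)
}

# --- splits ----------------------------------------------------------------

#' Train/validation/test split of a dataset
#'
#' Random disjoint index sets drawn from the image indices (full-scale
#' default 70/20/10; the desk-scale 25-image configurations use 15/5/5).
#'
#' @param n Number of images.
#' @param n_train,n_val,n_test Counts; must sum to at most `n`.
#' @param seed Integer seed.
#' @return List of index vectors `train`, `val`, `test`.
#' @export
make_splits <- function(n, n_train, n_val, n_test, seed = 1L) {
  if (n_train + n_val + n_test > n)
    stop("split counts exceed the number of images")
  withr::with_seed(seed, {
    perm <- sample.int(n)
    list(train = perm[seq_len(n_train)],
         val = perm[n_train + seq_len(n_val)],
         test = perm[n_train + n_val + seq_len(n_test)])
  })
}

default_split_counts <- function(n) {
  if (n < 3) stop("need at least 3 images for train/val/test splits")
  # 70/20/10 proportions with at least one image per split
  n_val <- max(1, floor(0.2 * n))
  n_train <- max(1, floor(0.7 * n))
  n_test <- n - n_train - n_val
  if (n_test < 1) {
    n_train <- n - n_val - 1
    n_test <- 1
  }
  c(train = n_train, val = n_val, test = n_test)
}

#' Training configuration
#'
#' @param epochs Number of epochs (>= 1); each epoch passes once over the
#'   (augmented) training images in random order, full-image batches of 1.
#' @param lr ADAM learning rate (default 1e-3, betas 0.9/0.999).
#' @param loss `"cross_entropy"` (MSD default) or `"bce_plus_dice"` (U-Net
#'   default); `NULL` picks by backbone.
#' @param clip Global-norm gradient clipping threshold applied jointly to
#'   backbone and reduction gradients each step (stabilizes the zero-
#'   initialized joint training); `Inf` disables.
#' @param anneal_patience Halve the learning rate after this many epochs
#'   without a new best validation score (0 disables annealing).
#' @param augment Apply 8-fold dihedral augmentation to the training split.
#' @param n_train,n_val,n_test Split counts; `NULL` = 70/20/10 of the
#'   dataset (15/5/5 at 25 images).
#' @param seed Integer seed controlling splits, initialization and epoch
#'   shuffling.
#' @param verbose Print per-epoch progress.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 1e-3, loss = NULL,
                         clip = 1, anneal_patience = 20L, augment = TRUE,
                         n_train = NULL, n_val = NULL, n_test = NULL,
                         seed = 1L, verbose = FALSE) {
  if (epochs < 1) stop("must train at least one epoch")
  if (lr <= 0) stop("learning rate must be positive")
  structure(list(epochs = as.integer(epochs), lr = lr, loss = loss,
                 clip = clip,
                 anneal_patience = as.integer(anneal_patience),
                 beta1 = 0.9, beta2 = 0.999, augment = augment,
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

apply_reduction_any <- function(cube, reduction) {
  if (inherits(reduction, "reduction_params")) {
    reduction_forward(cube, reduction)
  } else {
    apply_reducer(cube, reduction)
  }
}

#' Jointly train the reduction subnetwork and a segmentation CNN
#'
#' End-to-end ADAM minimization of the configured loss over the backbone
#' parameters and - when the reduction is learnable - the reduction
#' weights and biases. A frozen [fit_reducer()] baseline may be supplied
#' instead of a `reduction_scheme`, in which case only the backbone is
#' trained; both cases run the identical training loop, differing only in
#' the reduction operator. After every epoch the model is scored by
#' average class accuracy on the validation split and the best-scoring
#' parameters are kept.
#'
#' @param container A `dataset_container`.
#' @param reduction A `reduction_scheme` (learned, zero-initialized), a
#'   `reduction_params`, or a frozen `linear_reducer`.
#' @param backbone `"msd"` or `"unet"`.
#' @param config A `train_config`.
#' @param backbone_config Optional `msd_config`/`unet_config`;
#'   `in_channels` and `n_classes` are filled in from the data.
#' @return A `trained_model`: best reduction/backbone parameters, configs,
#'   per-epoch history, split indices and the best epoch.
#' @export
train_segmenter <- function(container, reduction, backbone = c("msd", "unet"),
                            config = train_config(),
                            backbone_config = NULL) {
  backbone <- match.arg(backbone)
  stopifnot(inherits(container, "dataset_container"),
            inherits(config, "train_config"))
  n_classes <- length(container$class_names)
  nb <- container$grid$n_bins

  learnable <- inherits(reduction, "reduction_scheme") ||
    inherits(reduction, "reduction_params")
  if (inherits(reduction, "reduction_scheme")) {
    if (reduction$n_in != nb)
      stop("reduction scheme r0 must equal the number of bins")
    red_params <- init_reduction(reduction)
    n_red <- reduction$n_out
  } else if (inherits(reduction, "reduction_params")) {
    red_params <- reduction
    n_red <- reduction$scheme$n_out
  } else if (inherits(reduction, "linear_reducer")) {
    red_params <- reduction
    n_red <- nrow(reduction$transform)
  } else stop("reduction must be a scheme, params or linear_reducer")

  if (is.null(backbone_config)) {
    backbone_config <- if (backbone == "msd")
      msd_config(depth = 100L, n_classes = n_classes, in_channels = n_red)
    else unet_config(n_classes = n_classes, in_channels = n_red)
  } else {
    backbone_config$in_channels <- as.integer(n_red)
    backbone_config$n_classes <- as.integer(n_classes)
  }
  loss_name <- if (is.null(config$loss)) {
    if (backbone == "msd") "cross_entropy" else "bce_plus_dice"
  } else config$loss
  lgrad <- loss_fn(loss_name)

  n <- n_images(container)
  cnts <- default_split_counts(n)
  splits <- make_splits(n,
                        config$n_train %||% cnts["train"],
                        config$n_val %||% cnts["val"],
                        config$n_test %||% cnts["test"],
                        seed = config$seed)

  train_cubes <- container$cubes[splits$train]
  train_labels <- container$labels[splits$train]
  if (config$augment) {
    aug <- dihedral_augment(train_cubes, train_labels)
    train_cubes <- aug$cubes
    train_labels <- aug$labels
  }
  train_onehot <- lapply(train_labels, one_hot, n_classes = n_classes)

  bb_params <- init_backbone(backbone_config, backbone,
                             seed = config$seed)
  opt_bb <- adam_init(lapply(unclass(bb_params)[-1], identity))
  opt_rd <- if (learnable) adam_init(red_params$layers) else NULL

  fw_cache <- if (backbone == "msd") msd_fw_cache else unet_fw_cache
  bw_fn <- if (backbone == "msd") msd_bw else unet_bw

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric())
  best <- list(score = -Inf, red = red_params, bb = bb_params, epoch = 0L)
  n_tr <- length(train_cubes)

  val_score <- function(red_p, bb_p) {
    counts <- list(tp = numeric(n_classes), fn = numeric(n_classes))
    for (i in splits$val) {
      r <- apply_reduction_any(container$cubes[[i]], red_p)
      p <- fw_cache(r, bb_p, backbone_config)$prob
      pred <- argmax_labels(p)
      cc <- confusion_counts(pred, container$labels[[i]], n_classes)
      counts$tp <- counts$tp + cc$tp
      counts$fn <- counts$fn + cc$fn
    }
    present <- counts$tp + counts$fn > 0
    mean(counts$tp[present] / (counts$tp + counts$fn)[present])
  }

  epoch_orders <- withr::with_seed(config$seed + 1L,
    lapply(seq_len(config$epochs), function(e) sample.int(n_tr)))

  lr_cur <- config$lr
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    tot_loss <- 0
    for (i in epoch_orders[[epoch]]) {
      cube <- train_cubes[[i]]
      dims <- dim(cube)
      if (learnable) {
        xflat <- matrix(cube, dims[1] * dims[2], dims[3])
        rcache <- reduction_fw_cache(xflat, red_params)
        red <- array(rcache$z, c(dims[1], dims[2], ncol(rcache$z)))
      } else {
        red <- apply_reducer(cube, red_params)
      }
      cache <- fw_cache(red, bb_params, backbone_config)
      yflat <- matrix(train_onehot[[i]], dims[1] * dims[2], n_classes)
      lg <- lgrad(cache$pflat, yflat)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d (lr %g)", epoch,
                     config$lr))
      tot_loss <- tot_loss + lg$loss
      bb_grads <- bw_fn(cache, bb_params, backbone_config, lg$dpre)
      dinput <- bb_grads$dinput
      bb_grads$dinput <- NULL
      rgrads <- NULL
      if (learnable) {
        dz <- matrix(dinput, dims[1] * dims[2], dim(dinput)[3])
        rgrads <- reduction_bw(rcache, red_params, dz)$layers
      }
      if (is.finite(config$clip)) {
        nrm <- sqrt(sumsq_params(bb_grads) +
                      if (learnable) sumsq_params(rgrads) else 0)
        if (is.finite(nrm) && nrm > config$clip) {
          s <- config$clip / nrm
          bb_grads <- map2_params(bb_grads, bb_grads, function(g, ...) g * s)
          if (learnable)
            rgrads <- map2_params(rgrads, rgrads, function(g, ...) g * s)
        }
      }
      st <- adam_step(lapply(unclass(bb_params)[-1], identity), bb_grads,
                      opt_bb, lr = lr_cur, beta1 = config$beta1,
                      beta2 = config$beta2)
      opt_bb <- st$state
      for (nm in names(st$params)) bb_params[[nm]] <- st$params[[nm]]
      if (learnable) {
        st <- adam_step(red_params$layers, rgrads, opt_rd,
                        lr = lr_cur, beta1 = config$beta1,
                        beta2 = config$beta2)
        opt_rd <- st$state
        red_params$layers <- st$params
      }
    }
    score <- val_score(red_params, bb_params)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tot_loss / n_tr,
                                val_accuracy = score))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.5f  val ACA %.4f  lr %.2g", epoch,
                      tot_loss / n_tr, score, lr_cur))
    if (score > best$score) {
      best <- list(score = score, red = red_params, bb = bb_params,
                   epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (config$anneal_patience > 0L &&
          stall >= config$anneal_patience && lr_cur > config$lr / 32) {
        lr_cur <- lr_cur / 2
        stall <- 0L
      }
    }
  }

  structure(list(reduction = best$red, backbone = best$bb,
                 backbone_kind = backbone,
                 backbone_config = backbone_config,
                 train_config = config, loss = loss_name,
                 history = history, splits = splits,
                 best_epoch = best$epoch,
                 best_val_accuracy = best$score,
                 class_names = container$class_names,
                 grid = container$grid),
            class = "trained_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model: %s backbone, %d epochs (best %d, val ACA %.4f)\n",
    x$backbone_kind, nrow(x$history), x$best_epoch, x$best_val_accuracy))
  invisible(x)
}

#' Predict a label map for one cube
#'
#' Per-pixel argmax of the class probability maps; ties break toward the
#' lowest class index.
#'
#' @param model A `trained_model`.
#' @param cube `(H, W, n_bins)` array.
#' @return Integer label matrix.
#' @export
predict_labels <- function(model, cube) {
  r <- apply_reduction_any(cube, model$reduction)
  p <- if (model$backbone_kind == "msd")
    msd_forward(r, model$backbone, model$backbone_config)
  else unet_forward(r, model$backbone, model$backbone_config)
  argmax_labels(p)
}

#' Evaluate a trained model on a dataset split
#'
#' Aggregates confusion counts over all images of the split before
#' averaging per class (split-level aggregation), and reports per-class
#' recalls, the average class accuracy and a per-image breakdown.
#'
#' @param model A `trained_model`.
#' @param container The `dataset_container` it was trained on (or a
#'   compatible one).
#' @param split `"test"` (default), `"val"`, `"train"`, or an integer
#'   vector of image indices.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, container, split = "test") {
  idx <- if (is.character(split)) model$splits[[split]] else split
  if (is.null(idx) || !length(idx)) stop("empty evaluation split")
  n_classes <- length(model$class_names)
  tp <- fn <- numeric(n_classes)
  per_image <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    pred <- predict_labels(model, container$cubes[[i]])
    truth <- container$labels[[i]]
    cc <- confusion_counts(pred, truth, n_classes)
    tp <- tp + cc$tp
    fn <- fn + cc$fn
    per_image[k] <- average_class_accuracy(pred, truth)
  }
  present <- tp + fn > 0
  recalls <- ifelse(present, tp / (tp + fn), NA_real_)
  structure(list(per_class_recall = stats::setNames(recalls,
                                                    model$class_names),
                 average_class_accuracy = mean(recalls[present]),
                 tp = tp, fn = fn, per_image = per_image,
                 images = idx),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: average class accuracy %.4f over %d images\n",
              x$average_class_accuracy, length(x$images)))
  for (i in seq_along(x$per_class_recall))
    cat(sprintf("  %-12s recall %.4f\n", names(x$per_class_recall)[i],
                x$per_class_recall[i]))
  invisible(x)
}

#' Repeat a training run over independent seeds
#'
#' @param run_fn Function `seed -> numeric score` performing one full
#'   train/evaluate cycle.
#' @param n_runs Number of runs (>= 2).
#' @param base_seed Seeds are `base_seed + 0:(n_runs-1)`.
#' @return List with `scores`, `mean` and `sd`.
#' @export
repeated_runs <- function(run_fn, n_runs = 8L, base_seed = 1L) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  scores <- vapply(seq_len(n_runs) - 1L,
                   function(k) run_fn(base_seed + k), numeric(1))
  list(scores = scores, mean = mean(scores), sd = stats::sd(scores))
}
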