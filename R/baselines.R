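#' Subsample pixels from the training images of a dataset
#'
#' Takes every `k`-th pixel in flattened raster order across the selected
#' images (start offset 0), optionally pairing each pixel with its label -
#' the sampling used to fit the linear baseline reducers on large cubes.
#' Conventional steps: 2 for PCA, 5 for NMF, 6 for LDA.
#'
#' @param container A `dataset_container`.
#' @param indices Image indices to draw from (e.g. the training split).
#' @param step Sampling step `k >= 1` (`k = 1` keeps all pixels).
#' @param with_labels Also return the paired label vector.
#' @return List with `pixels` (`n_pixels` x `n_bins` matrix) and, when
#'   requested, `labels`.
#' @export
subsample_pixels <- function(container, indices = NULL, step = 1L,
                             with_labels = FALSE) {
  stopifnot(inherits(container, "dataset_container"))
  if (step < 1) stop("step must be >= 1")
  if (is.null(indices)) indices <- seq_len(n_images(container))
  nb <- container$grid$n_bins
  px <- list(); lb <- list()
  for (j in seq_along(indices)) {
    i <- indices[j]
    cube <- container$cubes[[i]]
    npix <- dim(cube)[1] * dim(cube)[2]
    keep <- seq(1L, npix, by = step)
    px[[j]] <- matrix(cube, npix, nb)[keep, , drop = FALSE]
    if (with_labels)
      lb[[j]] <- as.vector(container$labels[[i]])[keep]
  }
  out <- list(pixels = do.call(rbind, px))
  if (with_labels) out$labels <- unlist(lb)
  out
}

# multiplicative-update Frobenius NMF (Lee-Seung), seeded
nmf_factorize <- function(x, nr, seed = 1L, tol = 1e-4, max_iter = 200L) {
  n <- nrow(x); b <- ncol(x)
  eps <- 1e-10
  withr::with_seed(seed, {
    scale0 <- sqrt(mean(x) / nr + eps)
    w <- matrix(stats::runif(n * nr, 0, scale0), n, nr)
    h <- matrix(stats::runif(nr * b, 0, scale0), nr, b)
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, x) + eps) / (crossprod(w, w %*% h) + eps)
      w <- w * (x %*% t(h) + eps) / (w %*% tcrossprod(h) + eps)
      err <- sqrt(sum((x - w %*% h)^2))
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
    list(w = w, h = h, error = err, iterations = it)
  })
}

#' Fit a linear baseline reducer (PCA, NMF or LDA)
#'
#' PCA keeps the top `nr` right singular vectors of the centered pixel
#' matrix; NMF computes a rank-`nr` nonnegative factorization (seeded
#' multiplicative updates minimizing Frobenius error, tolerance 1e-4, at
#' most 200 iterations) and stores the least-squares projection onto the
#' nonnegative basis; LDA takes the top discriminant directions of the
#' between- versus within-class scatter and is capped at
#' `n_classes - 1` components (with a warning when more are requested -
#' two-class problems reduce to a single channel).
#'
#' @param pixels `n_pixels` x `n_bins` matrix (from [subsample_pixels()]).
#' @param labels Class labels per pixel; required for LDA.
#' @param kind `"pca"`, `"nmf"` or `"lda"`.
#' @param nr Number of reduced channels requested.
#' @param seed Integer seed (NMF initialization).
#' @return A `linear_reducer` with the `transform` (`nr` x `n_bins`),
#'   `offset` (mean spectrum for PCA/LDA, zero for NMF) and fit metadata.
#' @export
fit_reducer <- function(pixels, labels = NULL, kind = c("pca", "nmf", "lda"),
                        nr = 2L, seed = 1L) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  nb <- ncol(pixels)
  if (nrow(pixels) < nr)
    stop("fewer pixels than requested components")
  extras <- list()
  if (kind == "pca") {
    pr <- stats::prcomp(pixels, center = TRUE, scale. = FALSE)
    if (nr > ncol(pr$rotation)) stop("nr exceeds available components")
    transform <- t(pr$rotation[, seq_len(nr), drop = FALSE])
    offset <- pr$center
  } else if (kind == "nmf") {
    if (any(pixels < 0)) {
      warning("negative pixel values clipped to 0 for NMF")
      pixels[pixels < 0] <- 0
    }
    f <- nmf_factorize(pixels, nr, seed = seed)
    # least-squares coefficients on the nonnegative basis H: a fixed
    # linear map (H H^T)^-1 H, so reduction stays a per-pixel affine op
    transform <- solve(tcrossprod(f$h) + 1e-10 * diag(nr), f$h)
    offset <- numeric(nb)
    extras <- list(basis = f$h, fit_error = f$error,
                   iterations = f$iterations)
  } else {
    if (is.null(labels)) stop("LDA requires labels")
    labels <- as.factor(labels)
    ncl <- nlevels(labels)
    if (ncl < 2) stop("LDA requires at least 2 classes")
    max_nr <- ncl - 1L
    if (nr > max_nr) {
      warning(sprintf("LDA yields at most %d component(s); reducing nr",
                      max_nr))
      nr <- max_nr
    }
    fit <- MASS::lda(pixels, grouping = labels)
    transform <- t(fit$scaling[, seq_len(nr), drop = FALSE])
    offset <- colMeans(pixels)
  }
  structure(list(kind = kind, transform = unname(transform),
                 offset = unname(offset), nr = as.integer(nr),
                 n_bins = nb, n_pixels = nrow(pixels), extras = extras),
            class = "linear_reducer")
}

#' @export
print.linear_reducer <- function(x, ...) {
  cat(sprintf("linear_reducer: %s, %d bins -> %d channel(s), fit on %d pixels\n",
              toupper(x$kind), x$n_bins, x$nr, x$n_pixels))
  invisible(x)
}

#' Apply a fitted linear reducer to a hyperspectral cube
#'
#' Per-pixel affine map `(x - offset) %*% t(transform)`; purely spectral.
#'
#' @param cube `(H, W, n_bins)` array.
#' @param reducer A `linear_reducer`.
#' @return `(H, W, nr)` reduced array.
#' @export
apply_reducer <- function(cube, reducer) {
  stopifnot(inherits(reducer, "linear_reducer"))
  d <- dim(cube)
  if (length(d) != 3 || d[3] != reducer$n_bins)
    stop(sprintf("cube has %s bins; reducer expects %d",
                 if (length(d) == 3) d[3] else "?", reducer$n_bins))
  x <- matrix(cube, d[1] * d[2], d[3])
  z <- sweep(x, 2, reducer$offset, "-") %*% t(reducer$transform)
  array(z, c(d[1], d[2], reducer$nr))
}
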